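test_that("Kendall tau and its R-squared reading match pair enumeration", {
  # strictly increasing: tau = 1, all variation attributed to time
  ds <- make_ds(matrix(c(20, 21, 22, 23), ncol = 1,
                       dimnames = list(NULL, "g")),
                timepoint = 0:3)
  tc <- time_correlation(ds, "g")
  expect_equal(tc$tau, 1)
  expect_equal(tc$r2_percent, 100)

  # worked 4-point example: 5 concordant, 1 discordant -> tau = 2/3
  ds2 <- make_ds(matrix(c(20, 22, 21, 23), ncol = 1,
                        dimnames = list(NULL, "g")),
                 timepoint = 1:4)
  tc2 <- time_correlation(ds2, "g")
  expect_equal(tc2$tau, 2 / 3, tolerance = 1e-12)
  expect_equal(tc2$r2_percent, 44.4, tolerance = 1e-2)
})

test_that("tau equals the exhaustive tie-corrected count on random instances", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    tp <- sample(0:4, n, replace = TRUE)
    cq <- round(runif(n, 20, 28), 1)   # rounding forces occasional Cq ties
    if (length(unique(tp)) < 2 || sd(cq) == 0) next
    ds <- make_ds(matrix(cq, ncol = 1, dimnames = list(NULL, "g")),
                  timepoint = tp)
    expect_equal(time_correlation(ds, "g")$tau, oracle_tau_b(cq, tp),
                 tolerance = 1e-12)
  }
})

test_that("undefined time correlations are reported as missing", {
  ds <- make_ds(matrix(c(25, 25, 25), ncol = 1, dimnames = list(NULL, "g")),
                timepoint = 0:2)
  expect_true(is.na(time_correlation(ds, "g")$tau))
  ds2 <- make_ds(matrix(c(24, 25, 26), ncol = 1, dimnames = list(NULL, "g")))
  expect_true(is.na(time_correlation(ds2, "g")$tau))  # single timepoint
})

test_that("a 5-cycle group shift makes all three of its pairwise comparisons significant", {
  set.seed(62)
  grp <- rep(c("A", "B", "C", "D"), each = 7)
  cq <- 24 + rnorm(28, sd = 0.3)
  cq[grp == "D"] <- cq[grp == "D"] + 5
  ds <- make_ds(matrix(cq, ncol = 1, dimnames = list(NULL, "g")), group = grp)
  res <- within_timepoint_tests(ds, "g")
  expect_equal(res$sig_count, 3L)
  sig <- res$pairwise[res$pairwise$significant, ]
  expect_true(all(sig$group_a == "D" | sig$group_b == "D"))
})

test_that("identically drawn groups rarely produce significant comparisons", {
  set.seed(63)
  hits <- replicate(60, {
    grp <- rep(c("A", "B", "C", "D"), each = 7)
    ds <- make_ds(matrix(24 + rnorm(28, sd = 0.5), ncol = 1,
                         dimnames = list(NULL, "g")), group = grp)
    within_timepoint_tests(ds, "g")$sig_count > 0
  })
  expect_lte(sum(hits), 6)   # nominal 5% plus slack at 60 draws
})

test_that("timepoints without at least two usable groups are skipped with a warning", {
  ds <- make_ds(matrix(c(20, 21, 22, 23), ncol = 1, dimnames = list(NULL, "g")),
                group = c("A", "A", "A", "A"), timepoint = c(0, 0, 1, 1))
  w <- capture_warnings(res <- within_timepoint_tests(ds, "g"))
  expect_match(w, "skipped", all = TRUE)
  expect_equal(res$sig_count, 0L)
})

test_that("variability summaries report cell means, SEMs and their spread", {
  ds <- make_ds(matrix(rep(25, 8), ncol = 1, dimnames = list(NULL, "g")),
                group = rep(c("A", "B"), each = 4))
  vs <- variability_summary(ds, "g")
  expect_equal(vs$cells$sem, c(0, 0))
  expect_equal(vs$overall_se_cycles, 0)

  # two cells with means 20 and 22: SE of the means is sd/sqrt(2) = 1
  ds2 <- make_ds(matrix(c(19, 21, 21, 23), ncol = 1, dimnames = list(NULL, "g")),
                 group = rep(c("A", "B"), each = 2))
  expect_equal(variability_summary(ds2, "g")$overall_se_cycles, 1.0)
})

test_that("consensus ranking respects dominance and documented tie-breaking", {
  s <- data.frame(gene = c("worse", "better"),
                  sig_count = c(4L, 0L),
                  overall_se = c(1.2, 0.3),
                  r2_percent = c(30, 2))
  cons <- consensus_ranking(s)
  expect_equal(attr(cons, "order"), c("better", "worse"))

  # full criterion tie resolved by overall_se, deterministically
  s2 <- data.frame(gene = c("a", "b"),
                   sig_count = c(1L, 1L),
                   overall_se = c(0.5, 0.4),
                   r2_percent = c(5, 5))
  expect_equal(attr(consensus_ranking(s2), "order"), c("b", "a"))
  expect_equal(attr(consensus_ranking(s2[2:1, ]), "order"), c("b", "a"))

  # a missing criterion is imputed worst and flagged
  s3 <- data.frame(gene = c("a", "b"),
                   sig_count = c(1L, 0L),
                   overall_se = c(0.6, 0.5),
                   r2_percent = c(NA, 5))
  cons3 <- consensus_ranking(s3)
  expect_equal(attr(cons3, "order"), c("b", "a"))
  expect_match(cons3$flag[cons3$gene == "a"], "imputed worst")
})

test_that("independent validation assembles per-gene summaries coherently", {
  set.seed(64)
  sim <- simulate_cq(preset_spec("juvenile_like", seed = 64))
  v <- suppressWarnings(independent_validation(sim$dataset))
  expect_setequal(v$summary$gene, sim$dataset$genes)
  expect_true(all(v$summary$overall_se >= 0))
  expect_true(all(v$summary$r2_percent >= 0 & v$summary$r2_percent <= 100,
                  na.rm = TRUE))
  expect_equal(nrow(as.data.frame(v$consensus)), 3L)
})
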