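# Build a two-group dataset with exact group means for ratio arithmetic.
ratio_ds <- function(target_ctrl, target_trt, ref_ctrl, ref_trt,
                     extra = NULL, n = 4) {
  spread <- function(m) m + seq(-0.3, 0.3, length.out = n)  # mean-preserving
  cols <- list(tgt = c(spread(target_ctrl), spread(target_trt)),
               ref = c(spread(ref_ctrl), spread(ref_trt)))
  if (!is.null(extra)) cols <- c(cols, extra)
  cq <- do.call(cbind, cols)
  make_ds(cq, group = rep(c("ctrl", "trt"), each = n))
}

test_that("the worked 8x/2x example yields a 4-fold ratio", {
  ds <- ratio_ds(25, 22, 20, 19)
  er <- expression_ratio(ds, NULL, "tgt", "ref", "ctrl", "trt")
  expect_equal(er$ratio, 4.0)
  expect_equal(er$n_control, 4L)
  expect_equal(er$n_treatment, 4L)
})

test_that("identical groups and self-normalization give ratio 1", {
  ds <- ratio_ds(25, 25, 20, 20)
  expect_equal(expression_ratio(ds, NULL, "tgt", "ref", "ctrl", "trt")$ratio, 1)
  ds2 <- ratio_ds(25, 22, 20, 19)
  expect_equal(expression_ratio(ds2, NULL, "tgt", "tgt", "ctrl", "trt")$ratio, 1)
})

test_that("multiple references combine by the geometric mean of their factors", {
  # ref factors 2x and 8x -> combined 4x
  ds <- ratio_ds(25, 22, 20, 19, extra = list(ref2 = c(rep(23, 4), rep(20, 4))))
  er <- expression_ratio(ds, NULL, "tgt", c("ref", "ref2"), "ctrl", "trt")
  expect_equal(er$ratio, 8 / sqrt(2 * 8))
})

test_that("swapping control and treatment inverts the ratio", {
  set.seed(41)
  cq <- matrix(runif(24, 20, 26), 12, 2, dimnames = list(NULL, c("t", "r")))
  ds <- make_ds(cq, group = rep(c("A", "B"), each = 6))
  ab <- expression_ratio(ds, NULL, "t", "r", "A", "B")$ratio
  ba <- expression_ratio(ds, NULL, "t", "r", "B", "A")$ratio
  expect_equal(ab * ba, 1)
})

test_that("efficiencies enter through the per-gene amplification base", {
  ds <- ratio_ds(25, 22, 20, 19)
  assays <- list(tgt = gene_assay("tgt", 0.9), ref = gene_assay("ref", 0.8))
  er <- expression_ratio(ds, assays, "tgt", "ref", "ctrl", "trt")
  expect_equal(er$ratio, 1.9^3 / 1.8^1)
})

test_that("the randomization test is bit-reproducible and correctly corrected", {
  set.seed(42)
  grp <- rep(c("ctrl", "trt"), each = 10)
  cq <- cbind(tgt = 25 + rnorm(20, sd = 0.3) - 5 * (grp == "trt"),
              ref = 20 + rnorm(20, sd = 0.3))
  ds <- make_ds(cq, group = grp)
  r1 <- randomization_test(ds, NULL, "tgt", "ref", "ctrl", "trt",
                           n_perm = 1999, seed = 7)
  r2 <- randomization_test(ds, NULL, "tgt", "ref", "ctrl", "trt",
                           n_perm = 1999, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  # the 5-cycle effect dwarfs the noise: no permutation reaches the observed
  # statistic with this seed, so the add-one correction gives 1/2000 exactly
  expect_identical(r1$p_value, 1 / 2000)

  r3 <- randomization_test(ds, NULL, "tgt", "ref", "ctrl", "trt",
                           n_perm = 1999, seed = 8)
  expect_equal(r3$p_value, r1$p_value, tolerance = 0.05)  # same conclusion
})

test_that("null data give unremarkable permutation p-values", {
  set.seed(43)
  highp <- replicate(20, {
    grp <- rep(c("ctrl", "trt"), each = 7)
    cq <- cbind(tgt = 25 + rnorm(14, sd = 0.5), ref = 20 + rnorm(14, sd = 0.5))
    randomization_test(make_ds(cq, group = grp), NULL, "tgt", "ref",
                       "ctrl", "trt", n_perm = 400, seed = 1)$p_value > 0.05
  })
  expect_gte(sum(highp), 17)
})

test_that("discordance between reference sets is detected when injected", {
  set.seed(44)
  grp <- rep(c("ctrl", "trt"), each = 7)
  # target truly unchanged; refB responds to treatment, biasing the ratio
  cq <- cbind(tgt = 25 + rnorm(14, sd = 0.2),
              refA = 20 + rnorm(14, sd = 0.2),
              refB = 22 + rnorm(14, sd = 0.2) + 3 * (grp == "trt"))
  ds <- make_ds(cq, group = grp)
  tab <- compare_normalizations(ds, NULL, "tgt", "refA", "refB",
                                contrasts = list(c("ctrl", "trt")),
                                n_perm = 500, seed = 2)
  expect_false(tab$significant_a)
  expect_true(tab$significant_b)
  expect_true(tab$discordant)

  same <- compare_normalizations(ds, NULL, "tgt", "refA", "refA",
                                 contrasts = list(c("ctrl", "trt")),
                                 n_perm = 500, seed = 2)
  expect_false(same$discordant)
})

test_that("bad inputs are rejected", {
  ds <- ratio_ds(25, 22, 20, 19)
  expect_error(expression_ratio(ds, NULL, "tgt", character(0), "ctrl", "trt"),
               "at least one reference")
  expect_error(expression_ratio(ds, NULL, "nope", "ref", "ctrl", "trt"),
               "not in dataset")
  expect_error(expression_ratio(ds, NULL, "tgt", "ref", "ghost", "trt"),
               "empty")
  expect_error(expression_ratio(ds, list(ref = gene_assay("ref", 1)),
                                "tgt", "ref", "ctrl", "trt"),
               "no assay")
  expect_error(randomization_test(ds, NULL, "tgt", "ref", "ctrl", "trt",
                                  n_perm = 10), "at least 100")
})
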