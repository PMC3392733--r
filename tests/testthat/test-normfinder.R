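test_that("identical genes across all samples give zero components", {
  qmat <- matrix(rep(c(1, .5, .25, .5, 1, .25), 3), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  q <- make_q(qmat, group = rep(c("G1", "G2"), each = 3))
  res <- normfinder(q)
  expect_equal(unname(res$intergroup_d), matrix(0, 3, 2), tolerance = 1e-12)
  expect_equal(unname(res$intragroup_var), matrix(0, 3, 2), tolerance = 1e-12)
  expect_equal(unname(res$stability), rep(0, 3), tolerance = 1e-12)
})

test_that("with a single group the ranking reduces to residual variance order", {
  set.seed(31)
  y <- cbind(a = rnorm(40, sd = 0.1), b = rnorm(40, sd = 0.4),
             c = rnorm(40, sd = 0.9), d = rnorm(40, sd = 0.2))
  q <- make_q(2^y)
  res <- normfinder(q)
  expect_true(all(res$intergroup_d == 0))
  expect_equal(order(res$stability), order(res$intragroup_var[, 1]))
  # stability is exactly sqrt(sigma2/n) here: no intergroup term survives
  expect_equal(unname(res$stability),
               unname(sqrt(res$intragroup_var[, 1] / res$group_sizes[1])))
})

test_that("intergroup deviations are translation invariant and size-balanced", {
  set.seed(55)
  y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  grp <- rep(c("G1", "G2"), c(8, 12))
  res <- normfinder(make_q(2^y, group = grp))
  # weighted sum of d over groups is zero per gene
  w <- res$group_sizes
  expect_equal(unname(res$intergroup_d %*% w)[, 1], rep(0, 3), tolerance = 1e-12)

  y2 <- y; y2[, 2] <- y2[, 2] + 5   # shift one gene everywhere
  res2 <- normfinder(make_q(2^y2, group = grp))
  expect_equal(res2$intergroup_d, res$intergroup_d, tolerance = 1e-12)
  expect_equal(res2$intragroup_var, res$intragroup_var, tolerance = 1e-12)
  expect_equal(res2$stability, res$stability, tolerance = 1e-12)
})

test_that("relabeling groups permutes d columns and leaves stability unchanged", {
  set.seed(56)
  y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  grp <- rep(c("G1", "G2"), each = 10)
  res <- normfinder(make_q(2^y, group = grp))
  swap <- c(G1 = "Z2", G2 = "A1")[grp]
  res_sw <- normfinder(make_q(2^y, group = swap))
  expect_equal(res_sw$intergroup_d[, c("Z2", "A1")],
               res$intergroup_d[, c("G1", "G2")],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(res_sw$stability, res$stability, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or dropped with warnings", {
  qmat <- random_qmat(2, 8)
  expect_error(normfinder(make_q(qmat)), "at least 3 genes")
  set.seed(3)
  q <- make_q(random_qmat(3, 7), group = c(rep("A", 6), "lone"))
  expect_warning(res <- normfinder(q), "single sample")
  expect_equal(colnames(res$intergroup_d), "A")
})

test_that("a constructed opposite-sign pair is selected as the best combination", {
  set.seed(77)
  n <- 30
  grp <- rep(c("G1", "G2"), each = n / 2)
  shift <- ifelse(grp == "G1", 0.5, -0.5)
  y <- cbind(up = shift + rnorm(n, sd = 0.05),
             down = -shift + rnorm(n, sd = 0.05),
             noisy = rnorm(n, sd = 0.6),
             drift = ifelse(grp == "G1", -0.4, 0.4) + rnorm(n, sd = 0.5))
  res <- normfinder(make_q(2^y, group = grp))
  expect_setequal(res$best_pair$genes, c("up", "down"))
  expect_lt(res$best_pair$stability, min(res$stability))
})

test_that("the best pair matches exhaustive enumeration and beats singles for exchangeable genes", {
  set.seed(78)
  pair_beats_single <- logical(10)
  for (i in 1:10) {
    y <- matrix(rnorm(4 * 24, sd = 0.3), 24, 4,
                dimnames = list(NULL, paste0("g", 1:4)))
    res <- normfinder(make_q(2^y, group = rep(c("G1", "G2"), each = 12)))
    # independent enumeration over pairs using the reported components
    v <- sweep(res$intragroup_var, 2, res$group_sizes, "/")
    ds <- res$intergroup_d_shrunk
    combos <- combn(4, 2)
    stab <- apply(combos, 2, function(ix) {
      mean(abs((ds[ix[1], ] + ds[ix[2], ]) / 2) +
             sqrt((v[ix[1], ] + v[ix[2], ]) / 4))
    })
    expect_setequal(res$best_pair$genes, rownames(ds)[combos[, which.min(stab)]])
    expect_equal(res$best_pair$stability, min(stab), tolerance = 1e-12)
    pair_beats_single[i] <- res$best_pair$stability <= min(res$stability)
  }
  # averaging halves the sampling term, so the best pair typically (not
  # always: a single gene can draw an unusually small variance) beats the
  # best single gene for exchangeable panels
  expect_gte(sum(pair_beats_single), 8)
})

test_that("an injected group shift shows up in d at its decomposed magnitude", {
  # one gene of three shifted by 1 log2 unit in group 2: under the two-way
  # decomposition the true deviation is +/- 1/3 (k = 3 genes, 2 equal groups)
  set.seed(90)
  errs <- replicate(10, {
    grp <- rep(c("G1", "G2"), each = 50)
    y <- matrix(rnorm(300, sd = 0.5), 100, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y[grp == "G2", "c"] <- y[grp == "G2", "c"] + 1
    res <- normfinder(make_q(2^y, group = grp))
    abs(abs(res$intergroup_d["c", "G2"]) - 1 / 3)
  })
  expect_lt(mean(errs), 0.1)
})
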