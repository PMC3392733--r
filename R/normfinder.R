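#' NormFinder model-based stability analysis
#'
#' Decomposes log2 relative expression into intergroup and intragroup
#' components per gene and scores each candidate by a stability value that
#' combines the magnitude of its (variance-shrunken) intergroup deviation
#' with the sampling uncertainty of its intragroup variation; lower values
#' indicate more stable genes. Also reports the best single gene and the
#' best two-gene combination (intergroup deviations of opposite sign can
#' cancel when genes are combined).
#'
#' The model for `y = log2(q)` is `y_igj = alpha_ig + b_gj + e_igj` with
#' sample effect `b_gj` shared by all genes of sample `j` in group `g` and
#' `e_igj ~ N(0, sigma2_ig)`. Estimation (see the methods vignette for the
#' derivation):
#' \itemize{
#'   \item intergroup deviation `d_ig = ybar_ig. - ybar_i.. - ybar_.g. +
#'     ybar_...`, with gene and grand means weighted by group size so that
#'     the size-weighted sum of `d_ig` over groups is zero for every gene;
#'   \item intragroup variance `sigma2_ig = max(0, k/(k-2) * (s2_ig -
#'     mean_i(s2_ig)/(k-1)))` where `s2_ig` is the mean-square of the
#'     within-group two-way residuals; the correction removes the bias
#'     introduced by estimating the per-sample effect from only `k` genes;
#'   \item empirical-Bayes shrinkage of `d_ig` toward zero with prior
#'     variance `gamma2` estimated by moments over all genes and groups;
#'   \item stability `rho_ig = |shrunken d_ig| + sqrt(sigma2_ig / n_g)`,
#'     averaged over groups.
#' }
#'
#' With a single group every `d_ig` is zero and the ranking reduces to
#' ordering by intragroup variance.
#'
#' @param q a [relative_quantities()] object with at least 3 genes.
#' @param groups per-sample group labels; defaults to the dataset's `group`
#'   column. Groups with fewer than 2 samples are dropped with a warning.
#' @return An object of class `normfinder_result` with elements `stability`
#'   (named, ascending = better), `ranks`, `intergroup_d` (genes x groups),
#'   `intragroup_var` (genes x groups), `group_sizes`, `gamma2`,
#'   `best_gene` and `best_pair` (list with `genes` and `stability`).
#' @export
normfinder <- function(q, groups = NULL) {
  stopifnot(inherits(q, "rel_quantities"))
  groups <- groups %||% q$samples$group
  if (length(groups) != nrow(q$q)) stopf("groups length does not match samples")
  k <- length(q$genes)
  if (k < 3) stopf("NormFinder requires at least 3 genes (residual decomposition is degenerate below that)")

  y <- log2(q$q)
  complete <- stats::complete.cases(y)
  if (!all(complete)) {
    warnf("dropping %d sample(s) with missing values for the NormFinder decomposition",
          sum(!complete))
    y <- y[complete, , drop = FALSE]
    groups <- groups[complete]
  }

  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warnf("dropping group(s) with a single sample: %s", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    y <- y[keep, , drop = FALSE]
    groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 1) stopf("no usable groups remain")
  glev <- names(sizes)
  ng <- length(glev)
  n_g <- as.integer(sizes[glev])
  names(n_g) <- glev

  # Per-group means and within-group two-way residual variances.
  group_mean <- matrix(NA_real_, k, ng, dimnames = list(q$genes, glev))
  s2 <- matrix(NA_real_, k, ng, dimnames = list(q$genes, glev))
  for (g in glev) {
    yg <- y[groups == g, , drop = FALSE]      # samples x genes
    gm <- colMeans(yg)
    sm <- rowMeans(yg)
    tot <- mean(yg)
    r <- sweep(sweep(yg, 2, gm), 1, sm) + tot
    group_mean[, g] <- gm
    s2[, g] <- colSums(r^2) / (nrow(yg) - 1)
  }

  # Bias-corrected intragroup variance (requires k >= 3).
  sigma2 <- s2
  for (g in glev) {
    sbar <- mean(s2[, g])
    sigma2[, g] <- pmax(0, k / (k - 2) * (s2[, g] - sbar / (k - 1)))
  }

  # Intergroup deviations with group-size weighting.
  w <- n_g / sum(n_g)
  gene_mean <- drop(group_mean %*% w)               # per-gene weighted mean
  grp_mean <- colMeans(group_mean)                  # per-group mean over genes
  grand <- sum(grp_mean * w)
  d <- group_mean - outer(gene_mean, rep(1, ng)) -
    outer(rep(1, k), grp_mean) + grand
  dimnames(d) <- dimnames(group_mean)
  if (ng == 1) d[] <- 0

  # Sampling variance of d_ig and empirical-Bayes shrinkage.
  v <- sweep(sigma2, 2, n_g, "/")
  if (ng > 1) {
    gamma2 <- max(0, sum(d^2) / ((k - 1) * (ng - 1)) - mean(v))
  } else {
    gamma2 <- 0
  }
  d_shrunk <- if (gamma2 > 0) d * gamma2 / (gamma2 + v) else d * 0

  rho <- abs(d_shrunk) + sqrt(v)
  stability <- rowMeans(rho)
  ranks <- rank(stability, ties.method = "first")
  ord <- order(stability)

  # Best two-gene combination: averaged shrunken deviations (allowing
  # opposite signs to cancel) plus the sampling uncertainty of the averaged
  # quantities.
  best_pair <- NULL
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    pair_stab <- apply(pairs, 2, function(idx) {
      dp <- (d_shrunk[idx[1], ] + d_shrunk[idx[2], ]) / 2
      vp <- (v[idx[1], ] + v[idx[2], ]) / 4
      mean(abs(dp) + sqrt(vp))
    })
    bi <- which.min(pair_stab)
    best_pair <- list(genes = q$genes[pairs[, bi]],
                      stability = unname(pair_stab[bi]))
  }

  structure(list(stability = stability,
                 ranks = stats::setNames(as.integer(ranks), q$genes),
                 intergroup_d = d,
                 intergroup_d_shrunk = d_shrunk,
                 intragroup_var = sigma2,
                 group_sizes = n_g,
                 gamma2 = gamma2,
                 best_gene = q$genes[ord[1]],
                 best_pair = best_pair),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability analysis\n")
  tab <- data.frame(gene = names(x$stability),
                    stability = round(x$stability, 3),
                    rank = x$ranks)
  print(tab[order(tab$rank), ], row.names = FALSE)
  cat(sprintf("best gene: %s\n", x$best_gene))
  if (!is.null(x$best_pair)) {
    cat(sprintf("best pair: %s + %s (combined stability %.3f)\n",
                x$best_pair$genes[1], x$best_pair$genes[2],
                x$best_pair$stability))
  }
  invisible(x)
}
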