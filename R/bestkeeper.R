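#' BestKeeper descriptive statistics for one gene
#'
#' Follows the BestKeeper conventions on raw Cq: the location is the
#' geometric mean of Cq, and the reported "SD" is the mean absolute
#' deviation of Cq from that geometric mean (in cycles), with
#' `CV% = SD / GM * 100`. The classical standard deviation is reported
#' alongside.
#'
#' @param cq numeric vector of raw Cq values (positive; >= 2 present values).
#' @return A one-row data frame with `n`, `geo_mean`, `ar_mean`, `min`,
#'   `max`, `sd_mad` (mean absolute deviation from the geometric mean),
#'   `sd_classic` and `cv_pct`.
#' @export
bk_descriptives <- function(cq) {
  cq <- cq[!is.na(cq)]
  if (length(cq) < 2) stopf("descriptives require at least 2 observed Cq values")
  if (any(cq <= 0)) stopf("nonpositive Cq value")
  gm <- geomean(cq)
  mad_gm <- mean(abs(cq - gm))
  data.frame(n = length(cq), geo_mean = gm, ar_mean = mean(cq),
             min = min(cq), max = max(cq), sd_mad = mad_gm,
             sd_classic = stats::sd(cq), cv_pct = 100 * mad_gm / gm)
}

#' Per-sample BestKeeper index
#'
#' The index of a sample is the geometric mean of its raw Cq over the
#' included genes; samples missing any included gene get a missing index.
#'
#' @param ds a [cq_dataset()].
#' @param include nonempty character vector of genes to include.
#' @return Named numeric vector of per-sample index values.
#' @export
bestkeeper_index <- function(ds, include = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  include <- include %||% ds$genes
  if (length(include) == 0) stopf("index gene subset must be nonempty")
  missing_g <- setdiff(include, ds$genes)
  if (length(missing_g) > 0) stopf("gene '%s' not in dataset", missing_g[1])
  m <- ds$cq[, include, drop = FALSE]
  idx <- exp(rowMeans(log(m)))          # NA propagates for incomplete samples
  stats::setNames(idx, ds$samples$sample_id)
}

#' BestKeeper analysis on raw Cq
#'
#' Computes per-gene descriptive statistics, all pairwise Pearson
#' correlations between genes on raw Cq (pairwise-complete), the per-sample
#' geometric-mean index over the included genes, and each gene's Pearson
#' correlation (with two-sided p from the t transform) against the index.
#' Genes are ranked by descending index correlation; a higher coefficient
#' indicates a more stable gene.
#'
#' The original BestKeeper exclusion of genes whose Cq variation exceeds
#' one cycle can be enabled through `exclude_sd_above` (it applies to the
#' mean-absolute-deviation statistic and only affects index membership;
#' excluded genes are still correlated against the index and ranked). It is
#' off by default.
#'
#' @param ds a [cq_dataset()].
#' @param include genes to consider (default all).
#' @param exclude_sd_above optional threshold in cycles; genes with
#'   `sd_mad` above it are dropped from the index.
#' @return An object of class `bestkeeper_result` with `descriptives`,
#'   `pair_corr`, `index`, `index_genes`, `index_corr` (data frame with
#'   `gene`, `r`, `p`, `rank`, `flag`).
#' @export
bestkeeper <- function(ds, include = NULL, exclude_sd_above = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  include <- include %||% ds$genes
  ds <- subset_genes(ds, include)
  genes <- ds$genes

  desc <- do.call(rbind, lapply(genes, function(g) {
    cbind(data.frame(gene = g), bk_descriptives(ds$cq[, g]))
  }))

  k <- length(genes)
  pair_corr <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  diag(pair_corr) <- 1
  if (k >= 2) {
    for (j in seq_len(k - 1)) {
      for (l in seq(j + 1, k)) {
        x <- ds$cq[, j]; y <- ds$cq[, l]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          r <- NA_real_
        } else {
          r <- stats::cor(x[ok], y[ok])
        }
        pair_corr[j, l] <- pair_corr[l, j] <- r
      }
    }
  }

  index_genes <- genes
  if (!is.null(exclude_sd_above)) {
    keep <- desc$sd_mad <= exclude_sd_above
    if (!any(keep)) stopf("all genes excluded by the SD rule (threshold %g)", exclude_sd_above)
    index_genes <- genes[keep]
  }
  index <- bestkeeper_index(ds, index_genes)

  idx_ok <- !is.na(index)
  corr <- do.call(rbind, lapply(genes, function(g) {
    x <- ds$cq[, g]
    ok <- idx_ok & !is.na(x)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(index[ok]) == 0) {
      return(data.frame(gene = g, r = NA_real_, p = NA_real_,
                        flag = "undefined (constant gene or too few samples)"))
    }
    ct <- stats::cor.test(x[ok], index[ok], method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value, flag = "")
  }))
  # Descending r; undefined correlations rank last.
  r_for_rank <- ifelse(is.na(corr$r), -Inf, corr$r)
  corr$rank <- as.integer(rank(-r_for_rank, ties.method = "first"))

  structure(list(descriptives = desc, pair_corr = pair_corr, index = index,
                 index_genes = index_genes, index_corr = corr),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper analysis (raw Cq)\n")
  d <- x$descriptives
  d[-1] <- lapply(d[-1], function(col) round(col, 3))
  print(d, row.names = FALSE)
  cat(sprintf("index over genes: %s\n", paste(x$index_genes, collapse = ", ")))
  cc <- x$index_corr
  cc$r <- round(cc$r, 3)
  cc$p <- signif(cc$p, 3)
  print(cc, row.names = FALSE)
  invisible(x)
}
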