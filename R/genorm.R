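#' Pairwise variation between two genes
#'
#' The geNorm pairwise variation `V_jk` is the sample standard deviation
#' (n - 1 denominator) of `log2(q_j / q_k)` across samples where both genes
#' are observed. Two perfectly proportional genes have `V = 0`.
#'
#' @param qj,qk relative-quantity vectors for the two genes.
#' @return `V_jk`, or `NA` (with a warning) when fewer than 2 complete
#'   sample pairs exist.
#' @export
pairwise_variation <- function(qj, qk) {
  ok <- !is.na(qj) & !is.na(qk)
  if (sum(ok) < 2) {
    warnf("fewer than 2 complete sample pairs: pairwise variation undefined")
    return(NA_real_)
  }
  stats::sd(log2(qj[ok] / qk[ok]))
}

# All pairwise variations for a quantity matrix (symmetric, zero diagonal).
pairwise_variation_matrix <- function(qmat) {
  k <- ncol(qmat)
  v <- matrix(0, k, k, dimnames = list(colnames(qmat), colnames(qmat)))
  if (k < 2) return(v)
  for (j in seq_len(k - 1)) {
    for (l in seq(j + 1, k)) {
      v[j, l] <- v[l, j] <- suppressWarnings(pairwise_variation(qmat[, j], qmat[, l]))
    }
  }
  v
}

#' Per-gene geNorm stability measure M
#'
#' `M_j` is the arithmetic mean of the pairwise variations `V_jk` of gene
#' `j` with every other gene in the panel (or subset). Lower M indicates a
#' more stable gene.
#'
#' @param q a [relative_quantities()] object.
#' @param genes optional subset of genes; defaults to the whole panel.
#' @return Named numeric vector of M values.
#' @export
gene_stability <- function(q, genes = NULL) {
  stopifnot(inherits(q, "rel_quantities"))
  genes <- genes %||% q$genes
  if (length(genes) < 2) stopf("gene stability requires at least 2 genes")
  qmat <- q$q[, genes, drop = FALSE]
  v <- pairwise_variation_matrix(qmat)
  m <- vapply(seq_along(genes), function(j) {
    vj <- v[j, -j]
    if (anyNA(vj)) {
      warnf("undefined pairwise variation: M for gene '%s' averages defined pairs only",
            genes[j])
      vj <- vj[!is.na(vj)]
      if (length(vj) == 0) return(NA_real_)
    }
    mean(vj)
  }, numeric(1))
  stats::setNames(m, genes)
}

#' Per-sample geNorm normalization factor
#'
#' The normalization factor of a sample is the geometric mean of its
#' relative quantities over the selected reference genes. A sample missing
#' any selected gene gets a missing factor.
#'
#' @param q a [relative_quantities()] object.
#' @param genes nonempty character vector of reference genes.
#' @return Named numeric vector of per-sample normalization factors.
#' @export
normalization_factor <- function(q, genes) {
  stopifnot(inherits(q, "rel_quantities"))
  if (length(genes) == 0) stopf("reference gene subset must be nonempty")
  missing_g <- setdiff(genes, q$genes)
  if (length(missing_g) > 0) stopf("gene '%s' not in quantity matrix", missing_g[1])
  qmat <- q$q[, genes, drop = FALSE]
  nf <- exp(rowMeans(log(qmat)))
  stats::setNames(nf, q$samples$sample_id)
}

#' Pairwise variation of successive normalization factors
#'
#' For a stability-ranked gene list, `V_{n,n+1}` is the sample standard
#' deviation of `log2(NF_n / NF_{n+1})` where `NF_n` is the normalization
#' factor built from the `n` most stable genes. Large values indicate that
#' the added gene changes the normalization factor appreciably.
#'
#' @param q a [relative_quantities()] object.
#' @param ordered_genes genes ordered from most to least stable (>= 3).
#' @return Data frame with columns `n` and `v` (the `V_{n,n+1}` series for
#'   `n = 2 .. k - 1`).
#' @export
nf_variation <- function(q, ordered_genes) {
  if (length(ordered_genes) < 3) stopf("V_{n,n+1} requires at least 3 ranked genes")
  ns <- seq(2, length(ordered_genes) - 1)
  v <- vapply(ns, function(n) {
    nf_n <- normalization_factor(q, ordered_genes[seq_len(n)])
    nf_n1 <- normalization_factor(q, ordered_genes[seq_len(n + 1)])
    ok <- !is.na(nf_n) & !is.na(nf_n1)
    if (sum(ok) < 2) return(NA_real_)
    stats::sd(log2(nf_n[ok] / nf_n1[ok]))
  }, numeric(1))
  data.frame(n = ns, v = v)
}

#' geNorm stability analysis
#'
#' Computes the full-panel pairwise-variation matrix and per-gene stability
#' M, then repeatedly eliminates the gene with the highest M recomputed on
#' the surviving subset until two genes remain. The reported per-gene M
#' (`full_panel_M`) is the full-panel value before any elimination; the
#' elimination ranking is reported separately, with the final two genes
#' sharing rank 1. Ties in the elimination step are broken by removing the
#' gene appearing later in column order (and are flagged).
#'
#' @param q a [relative_quantities()] object with at least 3 genes (2 genes
#'   are allowed, in which case no elimination is performed).
#' @return An object of class `genorm_result` with elements `full_panel_M`,
#'   `elimination_order`, `ranks`, `stability_order` (most stable first),
#'   `pairwise_V`, `nf_pairwise_variation` and `ties` (logical).
#' @export
#' @examples
#' qmat <- cbind(g1 = c(1, .5, .25), g2 = c(1, .5, .25), g3 = c(1, 1, 1))
#' ds <- cq_dataset(matrix(25, 3, 3, dimnames = list(NULL, colnames(qmat))),
#'                  paste0("s", 1:3), rep("A", 3), rep(0, 3))
#' q <- relative_quantities(ds); q$q <- qmat
#' genorm(q)
genorm <- function(q) {
  stopifnot(inherits(q, "rel_quantities"))
  genes <- q$genes
  k <- length(genes)
  if (k < 2) stopf("geNorm requires at least 2 genes")
  full_m <- gene_stability(q)
  v <- pairwise_variation_matrix(q$q)

  elim <- character(0)
  ties <- FALSE
  surviving <- genes
  while (length(surviving) > 2) {
    m <- gene_stability(q, surviving)
    worst <- max(m, na.rm = TRUE)
    cand <- which(!is.na(m) & m == worst)
    if (length(cand) > 1) ties <- TRUE
    drop_idx <- max(cand)   # later column wins the tie-break
    elim <- c(elim, surviving[drop_idx])
    surviving <- surviving[-drop_idx]
  }

  ranks <- stats::setNames(integer(k), genes)
  ranks[surviving] <- 1L
  if (length(elim) > 0) {
    ranks[elim] <- k - seq_along(elim) + 1L
  }

  # Most stable first: the final pair ordered by full-panel M, then the
  # eliminated genes in reverse elimination order.
  pair_sorted <- surviving[order(full_m[surviving])]
  stability_order <- c(pair_sorted, rev(elim))

  nf_v <- if (k >= 3) nf_variation(q, stability_order) else
    data.frame(n = integer(0), v = numeric(0))

  structure(list(full_panel_M = full_m,
                 elimination_order = elim,
                 ranks = ranks,
                 stability_order = stability_order,
                 pairwise_V = v,
                 nf_pairwise_variation = nf_v,
                 ties = ties),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability analysis\n")
  tab <- data.frame(gene = names(x$full_panel_M),
                    M = round(x$full_panel_M, 3),
                    rank = x$ranks[names(x$full_panel_M)])
  print(tab, row.names = FALSE)
  if (nrow(x$nf_pairwise_variation) > 0) {
    cat("Normalization-factor pairwise variation V(n, n+1):\n")
    with(x$nf_pairwise_variation,
         cat(paste(sprintf("  V(%d,%d) = %.3f", n, n + 1, v), collapse = "\n"), "\n"))
  }
  if (x$ties) cat("note: elimination tie broken by column order\n")
  invisible(x)
}
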