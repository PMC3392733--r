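#' Transform raw Cq to efficiency-corrected relative quantities
#'
#' Applies the delta-Cq method per gene: `Q = (E + 1)^(minCq - Cq)`, where
#' `minCq` is the gene's minimum observed Cq over the whole dataset (the
#' most expressed sample) and `E` its fractional amplification efficiency.
#' Every quantity lies in `(0, 1]` and the sample with minimum Cq for a gene
#' gets exactly `Q = 1`. Missing Cq values yield missing quantities.
#'
#' `minCq` is taken over the full dataset being analysed, not per group or
#' timepoint, so that each dataset receives a single transform before
#' stability analysis.
#'
#' @param ds a [cq_dataset()].
#' @param assays named list of [gene_assay()] objects covering every gene in
#'   `ds`, or `NULL` to assume perfect doubling (`E = 1`, base 2) for all
#'   genes.
#' @return An object of class `rel_quantities` with elements `q` (matrix of
#'   relative quantities), `base` (named per-gene amplification base
#'   `E + 1`), `samples` and `genes`.
#' @export
#' @examples
#' ds <- cq_dataset(matrix(c(20, 21, 22), ncol = 1, dimnames = list(NULL, "g")),
#'                  sample_id = c("a", "b", "c"), group = rep("A", 3),
#'                  timepoint = rep(0, 3))
#' relative_quantities(ds)$q  # 1, 0.5, 0.25
relative_quantities <- function(ds, assays = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (is.null(assays)) {
    base <- stats::setNames(rep(2, length(ds$genes)), ds$genes)
  } else {
    base <- vapply(ds$genes, function(g) {
      a <- assays[[g]]
      if (is.null(a)) stopf("no assay provided for gene '%s'", g)
      a$efficiency + 1
    }, numeric(1))
  }
  q <- ds$cq
  for (g in ds$genes) {
    col <- ds$cq[, g]
    if (all(is.na(col))) stopf("gene '%s' has no observed Cq values", g)
    min_cq <- min(col, na.rm = TRUE)
    q[, g] <- base[[g]]^(min_cq - col)
  }
  structure(list(q = q, base = base, samples = ds$samples, genes = ds$genes),
            class = "rel_quantities")
}

#' @export
print.rel_quantities <- function(x, ...) {
  cat(sprintf("Relative quantities: %d samples x %d genes (delta-Cq, Q in (0, 1])\n",
              nrow(x$q), length(x$genes)))
  cat("  amplification bases:",
      paste(sprintf("%s=%.3f", x$genes, x$base), collapse = ", "), "\n")
  invisible(x)
}

#' Write relative quantities to CSV
#'
#' Same sample layout as [write_cq()], with one `Q_<gene>` column per gene.
#'
#' @param q a [relative_quantities()] object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_quantities <- function(q, file) {
  stopifnot(inherits(q, "rel_quantities"))
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  header <- c("sample_id", "group", "timepoint", paste0("Q_", q$genes))
  rows <- vapply(seq_len(nrow(q$q)), function(i) {
    paste(c(q$samples$sample_id[i], q$samples$group[i],
            as.character(q$samples$timepoint[i]), num(q$q[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), file, useBytes = TRUE)
  invisible(file)
}
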