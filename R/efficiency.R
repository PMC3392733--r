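#' Construct a gene assay record
#'
#' An assay stores the amplification efficiency of a primer pair as the
#' fractional per-cycle gain `E`, so that the per-cycle amplification base is
#' `E + 1` (`E = 1` means perfect doubling). Standard-curve fit metadata
#' (slope in cycles per log10 template amount, R squared, amplicon length)
#' are optional.
#'
#' @param gene gene name.
#' @param efficiency fractional efficiency `E`, in `(0, 1.5)`.
#' @param slope optional standard-curve slope; must be negative.
#' @param r_squared optional coefficient of determination in `[0, 1]`.
#' @param amplicon_bp optional amplicon length in base pairs.
#' @return An object of class `gene_assay`.
#' @export
#' @examples
#' gene_assay("Hprt1", efficiency = 0.963, r_squared = 0.999)
gene_assay <- function(gene, efficiency, slope = NA_real_,
                       r_squared = NA_real_, amplicon_bp = NA_integer_) {
  if (!is.numeric(efficiency) || length(efficiency) != 1 || is.na(efficiency)) {
    stopf("efficiency must be a single number")
  }
  if (efficiency <= 0 || efficiency >= 1.5) {
    stopf("efficiency %g outside (0, 1.5) for gene '%s'", efficiency, gene)
  }
  if (!is.na(slope) && slope >= 0) stopf("standard-curve slope must be negative")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stopf("r_squared must lie in [0, 1]")
  }
  structure(list(gene = as.character(gene), efficiency = efficiency,
                 slope = slope, r_squared = r_squared,
                 amplicon_bp = amplicon_bp),
            class = "gene_assay")
}

#' @export
print.gene_assay <- function(x, ...) {
  cat(sprintf("Assay %s: E = %.3f (base %.3f)", x$gene, x$efficiency,
              x$efficiency + 1))
  if (!is.na(x$slope)) cat(sprintf(", slope = %.4f", x$slope))
  if (!is.na(x$r_squared)) cat(sprintf(", R2 = %.3f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Fit amplification efficiency from a standard curve
#'
#' Fits the least-squares regression of Cq on log10 relative template amount
#' and converts the slope `M` to a fractional efficiency with
#' `E = 10^(-1/M) - 1`. A perfect doubling assay has slope
#' `-1/log10(2) = -3.3219` and `E = 1`.
#'
#' @param log10_amount log10 relative template amounts of the dilution
#'   points; at least 3 distinct levels are required (replicates may be
#'   repeated points).
#' @param cq observed Cq at each point.
#' @param gene gene name recorded in the returned assay.
#' @return A [gene_assay()] with the fitted `efficiency`, `slope` and
#'   `r_squared`. A non-negative slope is rejected as an invalid assay.
#' @export
#' @examples
#' fit_efficiency(c(0, -1, -2), c(20, 23.321928, 26.643856))  # E = 1
fit_efficiency <- function(log10_amount, cq, gene = "assay") {
  ok <- stats::complete.cases(log10_amount, cq)
  log10_amount <- log10_amount[ok]
  cq <- cq[ok]
  if (length(unique(log10_amount)) < 3) {
    stopf("at least 3 distinct dilution levels are required")
  }
  fit <- stats::lm(cq ~ log10_amount)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stopf("standard curve has non-negative slope (%g): invalid assay", slope)
  efficiency <- 10^(-1 / slope) - 1
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  gene_assay(gene, efficiency = efficiency, slope = slope, r_squared = r2)
}

#' Check an assay against quality thresholds
#'
#' A verdict, not an exception: the assay passes when both its efficiency
#' and its standard-curve R squared meet the thresholds (defaults mirror the
#' common acceptance levels of 0.96 and 0.95).
#'
#' @param assay a [gene_assay()].
#' @param min_efficiency minimum acceptable fractional efficiency.
#' @param min_r_squared minimum acceptable R squared.
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   empty when passing), of class `assay_check`.
#' @export
validate_assay <- function(assay, min_efficiency = 0.96, min_r_squared = 0.95) {
  stopifnot(inherits(assay, "gene_assay"))
  if (min_efficiency <= 0 || min_efficiency >= 1.5) stopf("min_efficiency outside (0, 1.5)")
  if (min_r_squared <= 0 || min_r_squared > 1) stopf("min_r_squared outside (0, 1]")
  reasons <- character(0)
  if (assay$efficiency < min_efficiency) {
    reasons <- c(reasons, sprintf("efficiency %.3f below threshold %.3f",
                                  assay$efficiency, min_efficiency))
  }
  if (!is.na(assay$r_squared) && assay$r_squared < min_r_squared) {
    reasons <- c(reasons, sprintf("fit quality R2 %.3f below threshold %.3f",
                                  assay$r_squared, min_r_squared))
  }
  structure(list(gene = assay$gene, pass = length(reasons) == 0,
                 reasons = reasons),
            class = "assay_check")
}

#' @export
print.assay_check <- function(x, ...) {
  cat(sprintf("Assay %s: %s\n", x$gene, if (x$pass) "pass" else "warn"))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Read an assay table
#'
#' Reads a CSV with columns `gene,efficiency` and optional `slope`,
#' `r_squared`.
#'
#' @param file path to the assay CSV.
#' @return A named list of [gene_assay()] objects.
#' @export
read_assays <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("gene", "efficiency")) {
    if (!col %in% names(tab)) stopf("assay table must have a '%s' column", col)
  }
  assays <- lapply(seq_len(nrow(tab)), function(i) {
    gene_assay(tab$gene[i], efficiency = tab$efficiency[i],
               slope = if ("slope" %in% names(tab)) tab$slope[i] else NA_real_,
               r_squared = if ("r_squared" %in% names(tab)) tab$r_squared[i] else NA_real_)
  })
  names(assays) <- tab$gene
  assays
}
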