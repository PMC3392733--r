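#' REST-style relative expression ratio
#'
#' Computes the efficiency-corrected fold change of a target gene between a
#' control and a treatment group, normalized to one or more reference
#' genes: `ratio = (E_t + 1)^dCq_t / geomean_r((E_r + 1)^dCq_r)` with
#' `dCq = mean control Cq - mean treatment Cq` per gene (unpaired group
#' means). Multiple reference genes are combined by the geometric mean of
#' their individual correction factors.
#'
#' @param ds a [cq_dataset()].
#' @param assays named list of [gene_assay()] objects (or `NULL` for E = 1).
#' @param target target gene name.
#' @param refs nonempty character vector of reference genes.
#' @param control,treatment group labels.
#' @return An object of class `expression_ratio`: a list with `ratio`,
#'   `target`, `refs`, `control`, `treatment`, `n_control`, `n_treatment`.
#' @export
#' @examples
#' # control mean 25 vs treatment 22 for the target (8x at E = 1), reference
#' # 20 vs 19 (2x): ratio = 4
expression_ratio <- function(ds, assays, target, refs, control, treatment) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (length(refs) == 0) stopf("at least one reference gene is required")
  genes <- c(target, refs)
  missing_g <- setdiff(genes, ds$genes)
  if (length(missing_g) > 0) stopf("gene '%s' not in dataset", missing_g[1])
  base <- ratio_bases(genes, assays)
  ctrl <- ds$samples$group == control
  trt <- ds$samples$group == treatment
  if (!any(ctrl)) stopf("control group '%s' is empty", control)
  if (!any(trt)) stopf("treatment group '%s' is empty", treatment)
  ratio <- compute_ratio(ds$cq, ctrl, trt, target, refs, base)
  structure(list(ratio = ratio, target = target, refs = refs,
                 control = control, treatment = treatment,
                 n_control = sum(ctrl), n_treatment = sum(trt)),
            class = "expression_ratio")
}

ratio_bases <- function(genes, assays) {
  if (is.null(assays)) return(stats::setNames(rep(2, length(genes)), genes))
  vapply(genes, function(g) {
    a <- assays[[g]]
    if (is.null(a)) stopf("no assay provided for gene '%s'", g)
    a$efficiency + 1
  }, numeric(1))
}

# Core ratio arithmetic shared by the observed statistic and permutations.
compute_ratio <- function(cq, ctrl, trt, target, refs, base) {
  dcq <- function(g) mean(cq[ctrl, g], na.rm = TRUE) - mean(cq[trt, g], na.rm = TRUE)
  target_factor <- base[[target]]^dcq(target)
  ref_factors <- vapply(refs, function(g) base[[g]]^dcq(g), numeric(1))
  target_factor / geomean(ref_factors)
}

#' @export
print.expression_ratio <- function(x, ...) {
  cat(sprintf("%s normalized to %s: %s vs %s ratio = %.4g",
              x$target, paste(x$refs, collapse = "+"),
              x$treatment, x$control, x$ratio))
  if (!is.null(x$p_value)) cat(sprintf(" (p = %.4g, %d permutations)",
                                       x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Fixed-reallocation randomization test for an expression ratio
#'
#' Tests the null hypothesis of no treatment effect on the normalized
#' target expression by repeatedly reallocating the control/treatment
#' labels among the samples of the two groups (group sizes preserved) and
#' recomputing the ratio. The two-sided p-value is the proportion of
#' permutations with `|log ratio|` at least as large as observed, with the
#' add-one correction `p = (b + 1) / (n_perm + 1)`.
#'
#' @inheritParams expression_ratio
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed; permutation p-values are reproducible
#'   bit-exactly given `seed` and `n_perm`.
#' @return An `expression_ratio` object with added `p_value` and `n_perm`.
#' @export
randomization_test <- function(ds, assays, target, refs, control, treatment,
                               n_perm = 2000, seed = 1) {
  if (n_perm < 100) stopf("n_perm must be at least 100")
  er <- expression_ratio(ds, assays, target, refs, control, treatment)
  base <- ratio_bases(c(target, refs), assays)
  in_test <- ds$samples$group %in% c(control, treatment)
  cq <- ds$cq[in_test, , drop = FALSE]
  is_ctrl <- ds$samples$group[in_test] == control
  n <- nrow(cq); nc <- sum(is_ctrl)
  if (nc < 1 || n - nc < 1 || n < 3) {
    warnf("groups too small for a meaningful permutation test")
    er$p_value <- NA_real_
    er$n_perm <- n_perm
    return(er)
  }
  obs <- abs(log(er$ratio))
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, nc)
      ctrl_p <- logical(n); ctrl_p[idx] <- TRUE
      abs(log(compute_ratio(cq, ctrl_p, !ctrl_p, target, refs, base))) >= obs
    }, logical(1)))
  })
  er$p_value <- (b + 1) / (n_perm + 1)
  er$n_perm <- n_perm
  er
}

#' Compare two normalization strategies for a target gene
#'
#' For each group contrast, computes the randomization-test significance of
#' the target's expression change under reference set A and reference set
#' B, and flags discordant conclusions. This quantifies how the choice of
#' reference genes changes the biological conclusion.
#'
#' @inheritParams randomization_test
#' @param refs_a,refs_b the two reference gene sets.
#' @param contrasts list of `c(control, treatment)` character pairs.
#' @param alpha significance level for the discordance call.
#' @return Data frame with one row per contrast: ratios, p-values and
#'   significance under each reference set, and `discordant`.
#' @export
compare_normalizations <- function(ds, assays, target, refs_a, refs_b,
                                   contrasts, alpha = 0.05, n_perm = 2000,
                                   seed = 1) {
  if (!is.list(contrasts)) contrasts <- list(contrasts)
  out <- lapply(seq_along(contrasts), function(i) {
    ctr <- contrasts[[i]]
    ra <- randomization_test(ds, assays, target, refs_a, ctr[1], ctr[2],
                             n_perm = n_perm, seed = seed + i - 1)
    rb <- randomization_test(ds, assays, target, refs_b, ctr[1], ctr[2],
                             n_perm = n_perm, seed = seed + i - 1)
    sig_a <- !is.na(ra$p_value) && ra$p_value <= alpha
    sig_b <- !is.na(rb$p_value) && rb$p_value <= alpha
    data.frame(control = ctr[1], treatment = ctr[2],
               ratio_a = ra$ratio, p_a = ra$p_value, significant_a = sig_a,
               ratio_b = rb$ratio, p_b = rb$p_value, significant_b = sig_b,
               discordant = xor(sig_a, sig_b))
  })
  do.call(rbind, out)
}
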