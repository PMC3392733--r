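#' Nonparametric within-timepoint group comparisons for one gene
#'
#' At each timepoint, groups with at least 2 samples are compared with a
#' Kruskal-Wallis omnibus test. The omnibus p-values are Bonferroni-corrected
#' across the timepoints tested; where the corrected omnibus is significant
#' at `alpha`, all pairwise group comparisons are run as two-sided
#' Wilcoxon rank-sum tests and counted as significant at the
#' Bonferroni-corrected pairwise level (corrected across the pairs within
#' that timepoint). The total count of significant pairwise comparisons is
#' the gene's "sets of comparison" statistic.
#'
#' @param ds a [cq_dataset()].
#' @param gene gene name.
#' @param alpha nominal significance level before correction (default 0.05).
#' @return A list with `by_timepoint` (data frame: `timepoint`, `n_groups`,
#'   `p`, `p_adj`, `n_significant_pairs`), `pairwise` (data frame of the
#'   post-hoc tests run) and `sig_count` (integer total).
#' @export
within_timepoint_tests <- function(ds, gene, alpha = 0.05) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (!gene %in% ds$genes) stopf("gene '%s' not in dataset", gene)
  cq <- ds$cq[, gene]
  tps <- sort(unique(ds$samples$timepoint))

  rows <- list(); pair_rows <- list()
  for (tp in tps) {
    sel <- ds$samples$timepoint == tp & !is.na(cq)
    g <- ds$samples$group[sel]
    x <- cq[sel]
    sizes <- table(g)
    usable <- names(sizes)[sizes >= 2]
    if (length(usable) < 2) {
      warnf("timepoint %d skipped: fewer than 2 groups with >= 2 samples", tp)
      next
    }
    keep <- g %in% usable
    kw <- stats::kruskal.test(x[keep], factor(g[keep]))
    rows[[length(rows) + 1]] <- data.frame(timepoint = tp,
                                           n_groups = length(usable),
                                           p = kw$p.value)
  }
  if (length(rows) == 0) {
    return(list(by_timepoint = data.frame(), pairwise = data.frame(),
                sig_count = 0L))
  }
  by_tp <- do.call(rbind, rows)
  by_tp$p_adj <- pmin(1, by_tp$p * nrow(by_tp))
  by_tp$n_significant_pairs <- 0L

  for (i in seq_len(nrow(by_tp))) {
    if (is.na(by_tp$p_adj[i]) || by_tp$p_adj[i] > alpha) next
    tp <- by_tp$timepoint[i]
    sel <- ds$samples$timepoint == tp & !is.na(cq)
    g <- ds$samples$group[sel]
    x <- cq[sel]
    sizes <- table(g)
    usable <- names(sizes)[sizes >= 2]
    prs <- utils::combn(usable, 2)
    npairs <- ncol(prs)
    for (jp in seq_len(npairs)) {
      a <- prs[1, jp]; b <- prs[2, jp]
      wt <- suppressWarnings(stats::wilcox.test(x[g == a], x[g == b]))
      p_adj <- min(1, wt$p.value * npairs)
      sig <- !is.na(p_adj) && p_adj <= alpha
      pair_rows[[length(pair_rows) + 1]] <-
        data.frame(timepoint = tp, group_a = a, group_b = b,
                   p = wt$p.value, p_adj = p_adj, significant = sig)
      if (sig) by_tp$n_significant_pairs[i] <- by_tp$n_significant_pairs[i] + 1L
    }
  }

  pairwise <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(timepoint = integer(0), group_a = character(0),
               group_b = character(0), p = numeric(0), p_adj = numeric(0),
               significant = logical(0))
  list(by_timepoint = by_tp, pairwise = pairwise,
       sig_count = sum(by_tp$n_significant_pairs))
}

#' Kendall correlation between Cq and sampling time
#'
#' Kendall's rank correlation (tie-corrected tau-b; timepoints always tie
#' across fish sampled together) between a gene's raw Cq and the timepoint
#' index over all samples, with a two-sided p-value. The share of Cq
#' variation attributed to sampling time is reported as
#' `r2_percent = 100 * tau^2`, following the convention of squaring the
#' correlation coefficient itself.
#'
#' @param ds a [cq_dataset()].
#' @param gene gene name.
#' @return A list with `tau`, `p_value` and `r2_percent` (all `NA` when the
#'   correlation is undefined, e.g. constant Cq or a single timepoint).
#' @export
time_correlation <- function(ds, gene) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (!gene %in% ds$genes) stopf("gene '%s' not in dataset", gene)
  cq <- ds$cq[, gene]
  ok <- !is.na(cq)
  x <- cq[ok]
  t <- ds$samples$timepoint[ok]
  if (length(x) < 3 || length(unique(t)) < 2 || stats::sd(x) == 0) {
    return(list(tau = NA_real_, p_value = NA_real_, r2_percent = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, t, method = "kendall", exact = FALSE))
  tau <- unname(ct$estimate)
  list(tau = tau, p_value = ct$p.value, r2_percent = 100 * tau^2)
}

#' Group-cell variability summary for one gene
#'
#' Per (group, timepoint) cell: mean Cq and its standard error (SEM). The
#' overall variability statistic is the standard error across the set of
#' cell means (their SD divided by the square root of the number of cells),
#' in cycles.
#'
#' @param ds a [cq_dataset()].
#' @param gene gene name.
#' @return A list with `cells` (data frame: `group`, `timepoint`, `n`,
#'   `mean_cq`, `sem`) and `overall_se_cycles`.
#' @export
variability_summary <- function(ds, gene) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (!gene %in% ds$genes) stopf("gene '%s' not in dataset", gene)
  cq <- ds$cq[, gene]
  combos <- unique(ds$samples[, c("group", "timepoint")])
  cells <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    grp <- combos$group[i]; tp <- combos$timepoint[i]
    sel <- ds$samples$group == grp & ds$samples$timepoint == tp & !is.na(cq)
    if (!any(sel)) {
      return(data.frame(group = grp, timepoint = tp, n = 0L,
                        mean_cq = NA_real_, sem = NA_real_))
    }
    x <- cq[sel]
    data.frame(group = grp, timepoint = tp, n = length(x),
               mean_cq = mean(x), sem = sem(x))
  }))
  cells <- cells[order(cells$timepoint, cells$group), ]
  rownames(cells) <- NULL
  mu <- cells$mean_cq[!is.na(cells$mean_cq)]
  overall <- if (length(mu) >= 2) stats::sd(mu) / sqrt(length(mu)) else NA_real_
  list(cells = cells, overall_se_cycles = overall)
}

#' Consensus stability ranking from validation summaries
#'
#' Ranks genes by the sum of their ranks on three criteria, each ascending
#' (smaller = more stable): the count of significant pairwise comparisons,
#' the overall standard error of the cell means, and the percentage of Cq
#' variation attributed to sampling time. Rank-sum ties are broken by the
#' overall standard error, then input order. A missing criterion is imputed
#' the worst rank and flagged.
#'
#' @param summaries data frame with columns `gene`, `sig_count`,
#'   `overall_se` and `r2_percent` (one row per gene, >= 2 genes).
#' @return An object of class `consensus_ranking`: the input with added
#'   `rank_sum`, `consensus_rank` and `flag` columns, ordered most stable
#'   first; the ordered gene vector is in attribute `"order"` and element
#'   `$order`.
#' @export
consensus_ranking <- function(summaries) {
  need <- c("gene", "sig_count", "overall_se", "r2_percent")
  if (!all(need %in% names(summaries))) {
    stopf("summaries must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(summaries) < 2) stopf("consensus ranking requires at least 2 genes")
  s <- summaries
  s$flag <- ""
  crit <- c("sig_count", "overall_se", "r2_percent")
  ranks <- sapply(crit, function(cn) {
    x <- s[[cn]]
    miss <- is.na(x)
    if (any(miss)) {
      s$flag[miss] <<- paste0(s$flag[miss], sprintf("missing %s imputed worst;", cn))
      x[miss] <- Inf
    }
    rank(x, ties.method = "average")
  })
  s$rank_sum <- rowSums(ranks)
  se_tie <- ifelse(is.na(s$overall_se), Inf, s$overall_se)
  ord <- order(s$rank_sum, se_tie, seq_len(nrow(s)))
  s <- s[ord, ]
  s$consensus_rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  out <- structure(s, class = c("consensus_ranking", "data.frame"))
  attr(out, "order") <- s$gene
  out
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("Consensus stability ranking:",
      paste(attr(x, "order"), collapse = " > "), "\n")
  df <- as.data.frame(x)
  df$overall_se <- round(df$overall_se, 3)
  df$r2_percent <- round(df$r2_percent, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Independent nonparametric validation of candidate reference genes
#'
#' Runs, for each gene, the within-timepoint Kruskal-Wallis/Bonferroni
#' procedure ([within_timepoint_tests()]), the Kendall Cq-time correlation
#' ([time_correlation()]) and the cell-mean variability summary
#' ([variability_summary()]), then combines them into a consensus stability
#' ranking ([consensus_ranking()]).
#'
#' @param ds a [cq_dataset()].
#' @param genes genes to validate (default all).
#' @param alpha nominal significance level (default 0.05).
#' @return An object of class `validation_result` with `summary` (per-gene
#'   data frame), `consensus` (a [consensus_ranking()]) and `detail`
#'   (per-gene lists of the underlying tests).
#' @export
independent_validation <- function(ds, genes = NULL, alpha = 0.05) {
  stopifnot(inherits(ds, "cq_dataset"))
  genes <- genes %||% ds$genes
  detail <- lapply(genes, function(g) {
    wt <- within_timepoint_tests(ds, g, alpha = alpha)
    tc <- time_correlation(ds, g)
    vs <- variability_summary(ds, g)
    list(gene = g, tests = wt, time = tc, variability = vs)
  })
  names(detail) <- genes
  summary <- do.call(rbind, lapply(detail, function(dd) {
    data.frame(gene = dd$gene,
               sig_count = dd$tests$sig_count,
               overall_se = dd$variability$overall_se_cycles,
               tau = dd$time$tau,
               tau_p = dd$time$p_value,
               r2_percent = dd$time$r2_percent)
  }))
  rownames(summary) <- NULL
  consensus <- consensus_ranking(summary)
  structure(list(summary = summary, consensus = consensus, detail = detail,
                 alpha = alpha),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Independent nonparametric validation (alpha =", x$alpha, ")\n")
  print(x$consensus)
  invisible(x)
}
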