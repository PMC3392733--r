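#' Rank candidate reference genes by expression stability
#'
#' The central fitting function of the package: runs any combination of the
#' geNorm, NormFinder and BestKeeper algorithms plus the independent
#' nonparametric validation on a Cq dataset, and consolidates per-gene
#' statistics and ranks into one table (one row per gene, one
#' rank/statistic column pair per method).
#'
#' geNorm and NormFinder operate on efficiency-corrected relative
#' quantities (delta-Cq transform, [relative_quantities()]); BestKeeper and
#' the independent validation operate on raw Cq.
#'
#' @param ds a [cq_dataset()].
#' @param assays named list of [gene_assay()] objects; `NULL` assumes
#'   perfect doubling for all genes (see `uniform_efficiency`).
#' @param methods subset of `c("genorm", "normfinder", "bestkeeper",
#'   "independent")`.
#' @param groups grouping scheme for NormFinder: `"group"` uses the
#'   treatment groups collapsed over time (the default), `"cell"` uses
#'   group-by-timepoint cells, or a vector of per-sample labels.
#' @param alpha significance level for the independent validation.
#' @param uniform_efficiency if `TRUE`, ignore `assays` for the delta-Cq
#'   transform and use `E = 1` for every gene.
#' @return An object of class `refstab` with one element per method run
#'   (`genorm`, `normfinder`, `bestkeeper`, `validation`), the consolidated
#'   `table`, and the inputs. Methods: [print.refstab()],
#'   [summary.refstab()], [plot.refstab()].
#' @export
#' @examples
#' sim <- simulate_cq(preset_spec("juvenile_like", seed = 42))
#' fit <- rank_references(sim$dataset, sim$assays)
#' fit
rank_references <- function(ds, assays = NULL,
                            methods = c("genorm", "normfinder",
                                        "bestkeeper", "independent"),
                            groups = "group", alpha = 0.05,
                            uniform_efficiency = FALSE) {
  stopifnot(inherits(ds, "cq_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(ds$genes) == 0) stopf("dataset has no genes")

  q <- NULL
  if (any(c("genorm", "normfinder") %in% methods)) {
    q <- relative_quantities(ds, if (uniform_efficiency) NULL else assays)
  }
  group_labels <- if (is.character(groups) && length(groups) == 1) {
    switch(groups,
           group = ds$samples$group,
           cell = paste(ds$samples$group, ds$samples$timepoint, sep = "/"),
           stopf("unknown grouping scheme '%s'", groups))
  } else groups

  res <- list(dataset = ds, assays = assays, alpha = alpha,
              methods = methods)
  tab <- data.frame(gene = ds$genes)

  if ("bestkeeper" %in% methods) {
    res$bestkeeper <- bestkeeper(ds)
    ic <- res$bestkeeper$index_corr
    tab$bestkeeper_r <- ic$r[match(tab$gene, ic$gene)]
    tab$bestkeeper_rank <- ic$rank[match(tab$gene, ic$gene)]
  }
  if ("normfinder" %in% methods) {
    res$normfinder <- normfinder(q, groups = group_labels)
    tab$normfinder_stability <- unname(res$normfinder$stability[tab$gene])
    tab$normfinder_rank <- unname(res$normfinder$ranks[tab$gene])
  }
  if ("genorm" %in% methods) {
    res$genorm <- genorm(q)
    tab$genorm_m <- unname(res$genorm$full_panel_M[tab$gene])
    tab$genorm_rank <- unname(res$genorm$ranks[tab$gene])
  }
  if ("independent" %in% methods) {
    res$validation <- independent_validation(ds, alpha = alpha)
    cons <- res$validation$consensus
    tab$sig_count <- cons$sig_count[match(tab$gene, cons$gene)]
    tab$overall_se <- cons$overall_se[match(tab$gene, cons$gene)]
    tab$r2_percent <- cons$r2_percent[match(tab$gene, cons$gene)]
    tab$consensus_rank <- cons$consensus_rank[match(tab$gene, cons$gene)]
  }

  res$table <- tab
  structure(res, class = "refstab")
}

#' @export
print.refstab <- function(x, digits = 3, ...) {
  cat(sprintf("Reference gene stability analysis: %d genes, %d samples\n",
              length(x$dataset$genes), nrow(x$dataset$cq)))
  cat("methods:", paste(x$methods, collapse = ", "), "\n\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1)) & !grepl("rank|count", names(tab))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$validation)) {
    cat("\nconsensus:", paste(attr(x$validation$consensus, "order"),
                              collapse = " > "), "\n")
  }
  invisible(x)
}

#' Summarize a reference-gene stability fit
#'
#' @param object a [rank_references()] fit.
#' @param ... unused.
#' @return The consolidated table with per-method details printed.
#' @export
summary.refstab <- function(object, ...) {
  print(object)
  if (!is.null(object$genorm)) { cat("\n"); print(object$genorm) }
  if (!is.null(object$normfinder)) { cat("\n"); print(object$normfinder) }
  if (!is.null(object$bestkeeper)) { cat("\n"); print(object$bestkeeper) }
  invisible(object$table)
}

#' Consolidated rank table of a stability fit
#'
#' @param x a [rank_references()] fit.
#' @return Data frame with one row per gene and the per-method statistics
#'   and ranks.
#' @export
stability_ranks <- function(x) {
  stopifnot(inherits(x, "refstab"))
  x$table
}

#' Plot group-mean Cq profiles of a stability fit
#'
#' One panel per gene: mean Cq (+/- SEM) per group at each timepoint, the
#' standard presentation of reference-gene screening experiments. Lower Cq
#' means higher expression.
#'
#' @param x a [rank_references()] fit.
#' @param genes genes to plot (default all).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.refstab <- function(x, genes = NULL, ...) {
  ds <- x$dataset
  genes <- genes %||% ds$genes
  old <- graphics::par(mfrow = c(length(genes), 1),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  groups <- sort(unique(ds$samples$group))
  tps <- sort(unique(ds$samples$timepoint))
  for (g in genes) {
    vs <- variability_summary(ds, g)$cells
    m <- matrix(NA_real_, length(tps), length(groups),
                dimnames = list(tps, groups))
    s <- m
    for (i in seq_len(nrow(vs))) {
      m[as.character(vs$timepoint[i]), vs$group[i]] <- vs$mean_cq[i]
      s[as.character(vs$timepoint[i]), vs$group[i]] <- vs$sem[i]
    }
    graphics::matplot(tps, m, type = "b", pch = 19, lty = 1,
                      xlab = "timepoint", ylab = "mean Cq (cycles)",
                      main = g, ...)
    for (j in seq_along(groups)) {
      graphics::arrows(tps, m[, j] - s[, j], tps, m[, j] + s[, j],
                       angle = 90, code = 3, length = 0.03, col = j)
    }
    graphics::legend("topleft", legend = groups, col = seq_along(groups),
                     pch = 19, bty = "n", cex = 0.8)
  }
  invisible(x)
}
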