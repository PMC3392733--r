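# Command-line backends: thin, file-oriented wrappers around the package
# functions, used by inst/cli/qpcrstab.R. Machine-readable outputs keep full
# precision; the consolidated summary rounds to 3 decimals.

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Run a full stability ranking from input files
#'
#' Reads a Cq table and optional assay table, runs [rank_references()], and
#' writes per-method TSV tables plus a consolidated rank table to an output
#' directory.
#'
#' @param cq_file path to the Cq CSV/TSV (see [read_cq()]).
#' @param out_dir output directory (created if needed).
#' @param assay_file optional assay CSV (see [read_assays()]).
#' @param sample_col,group_col,timepoint_col,sep schema of the Cq table.
#' @param methods,groups,alpha passed to [rank_references()].
#' @return The [rank_references()] fit, invisibly.
#' @export
run_rank <- function(cq_file, out_dir, assay_file = NULL,
                     sample_col = "sample_id", group_col = "group",
                     timepoint_col = "timepoint", sep = ",",
                     methods = c("genorm", "normfinder", "bestkeeper",
                                 "independent"),
                     groups = "group", alpha = 0.05) {
  ds <- read_cq(cq_file, sample_col = sample_col, group_col = group_col,
                timepoint_col = timepoint_col, sep = sep)
  assays <- if (!is.null(assay_file)) read_assays(assay_file) else NULL
  fit <- rank_references(ds, assays, methods = methods, groups = groups,
                         alpha = alpha)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  write_tsv(fit$table, file.path(out_dir, "rank_table.tsv"))
  if (!is.null(fit$genorm)) {
    gn <- fit$genorm
    elim_step <- stats::setNames(rep(NA_integer_, length(ds$genes)), ds$genes)
    elim_step[gn$elimination_order] <- seq_along(gn$elimination_order)
    write_tsv(data.frame(gene = names(gn$full_panel_M),
                         M_full_panel = gn$full_panel_M,
                         rank = gn$ranks[names(gn$full_panel_M)],
                         eliminated_at_step = elim_step[names(gn$full_panel_M)]),
              file.path(out_dir, "genorm.tsv"))
    write_tsv(stats::setNames(gn$nf_pairwise_variation, c("n", "V_n_nplus1")),
              file.path(out_dir, "genorm_v.tsv"))
  }
  if (!is.null(fit$normfinder)) {
    nf <- fit$normfinder
    write_tsv(data.frame(gene = names(nf$stability),
                         stability = nf$stability, rank = nf$ranks),
              file.path(out_dir, "normfinder.tsv"))
    pg <- expand.grid(gene = rownames(nf$intergroup_d),
                      group = colnames(nf$intergroup_d),
                      stringsAsFactors = FALSE)
    pg$d <- nf$intergroup_d[cbind(pg$gene, pg$group)]
    pg$var <- nf$intragroup_var[cbind(pg$gene, pg$group)]
    write_tsv(pg, file.path(out_dir, "normfinder_groups.tsv"))
  }
  if (!is.null(fit$bestkeeper)) {
    bk <- fit$bestkeeper
    write_tsv(bk$descriptives, file.path(out_dir, "bestkeeper_descriptives.tsv"))
    write_tsv(cbind(data.frame(gene = rownames(bk$pair_corr)),
                    as.data.frame(bk$pair_corr)),
              file.path(out_dir, "bestkeeper_correlations.tsv"))
    write_tsv(bk$index_corr[, c("gene", "r", "p", "rank")],
              file.path(out_dir, "bestkeeper_index.tsv"))
  }
  if (!is.null(fit$validation)) {
    write_tsv(as.data.frame(fit$validation$consensus),
              file.path(out_dir, "validation.tsv"))
    per_tp <- do.call(rbind, lapply(fit$validation$detail, function(dd) {
      bt <- dd$tests$by_timepoint
      if (nrow(bt) == 0) return(NULL)
      cbind(data.frame(gene = dd$gene), bt)
    }))
    if (!is.null(per_tp)) write_tsv(per_tp, file.path(out_dir, "validation_timepoints.tsv"))
  }
  summary_txt <- utils::capture.output(print(fit))
  writeLines(summary_txt, file.path(out_dir, "summary.txt"))
  invisible(fit)
}

#' Simulate a dataset and write it to disk
#'
#' @param out_dir output directory.
#' @param preset preset name for [preset_spec()], or `NULL` when `spec` is
#'   given.
#' @param spec a [simulation_spec()], taking precedence over `preset`.
#' @param seed integer seed.
#' @return The [simulate_cq()] result, invisibly.
#' @export
run_simulate <- function(out_dir, preset = NULL, spec = NULL, seed = 1) {
  if (is.null(spec)) {
    if (is.null(preset)) stopf("either a preset name or a spec is required")
    spec <- preset_spec(preset, seed = seed)
  }
  sim <- simulate_cq(spec, seed = seed)
  write_sim(sim, out_dir)
  invisible(sim)
}

#' Normalize a target gene and write the expression-ratio table
#'
#' @param cq_file,assay_file input paths as in [run_rank()].
#' @param target target gene name.
#' @param refs character vector of reference genes.
#' @param control,treatment group labels.
#' @param out output TSV path.
#' @param n_perm,seed randomization-test settings.
#' @return The test result, invisibly.
#' @export
run_normalize <- function(cq_file, assay_file = NULL, target, refs,
                          control, treatment, out, n_perm = 2000, seed = 1) {
  ds <- read_cq(cq_file)
  assays <- if (!is.null(assay_file)) read_assays(assay_file) else NULL
  rt <- randomization_test(ds, assays, target, refs, control, treatment,
                           n_perm = n_perm, seed = seed)
  write_tsv(data.frame(target = target, refs = paste(refs, collapse = ","),
                       control = control, treatment = treatment,
                       ratio = rt$ratio, p = rt$p_value,
                       n_perm = n_perm, seed = seed),
            out)
  invisible(rt)
}
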