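#' Describe one simulated gene
#'
#' @param name gene name.
#' @param baseline_cq baseline Cq in cycles, in `(5, 40)`.
#' @param efficiency fractional amplification efficiency `E` of the gene's
#'   assay (default 1, perfect doubling).
#' @param group_effects named numeric vector of additive Cq shifts per
#'   group (cycles); unnamed groups get 0.
#' @param time_slope additive Cq change per timepoint step (cycles).
#' @param noise_sd per-observation Gaussian noise SD on the Cq scale
#'   (log-scale multiplicative noise on quantities).
#' @return A list describing the gene, for use in [simulation_spec()].
#' @export
sim_gene <- function(name, baseline_cq, efficiency = 1, group_effects = NULL,
                     time_slope = 0, noise_sd = 0.5) {
  if (baseline_cq <= 5 || baseline_cq >= 40) {
    stopf("genes[%s].baseline_cq must lie in (5, 40)", name)
  }
  if (noise_sd < 0) stopf("genes[%s].noise_sd must be >= 0", name)
  list(name = as.character(name), baseline_cq = baseline_cq,
       efficiency = efficiency,
       group_effects = group_effects %||% numeric(0),
       time_slope = time_slope, noise_sd = noise_sd)
}

#' Build a simulation specification for synthetic Cq data
#'
#' The generative model for sample `s` (group `g(s)`, timepoint `t(s)`) and
#' gene `j` is
#' `Cq_sj = baseline_j + group_effect_j(g) + time_slope_j * t + delta_s + eps_sj`
#' with a per-sample technical shift `delta_s ~ N(0, technical_shift_sd^2)`
#' shared by all genes of a sample — the extraction/RT/pipetting variation
#' that reference-gene normalization exists to remove — and independent
#' per-gene noise `eps_sj ~ N(0, noise_sd_j^2)`.
#'
#' A gene with zero group effects and zero time slope is stable by
#' construction; this ground truth is recorded alongside the simulated
#' dataset.
#'
#' @param genes list of [sim_gene()] descriptions.
#' @param groups character vector of group labels.
#' @param timepoints number of timepoints (indices `0 .. timepoints - 1`).
#' @param n_per_cell samples per group-by-timepoint cell (>= 1).
#' @param technical_shift_sd SD in cycles of the shared per-sample shift.
#' @param timepoint_labels optional labels, one per timepoint.
#' @param seed default RNG seed used by [simulate_cq()].
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(genes, groups, timepoints, n_per_cell = 7,
                            technical_shift_sd = 0.7, timepoint_labels = NULL,
                            seed = 1) {
  if (n_per_cell < 1) stopf("n_per_cell must be >= 1")
  if (technical_shift_sd < 0) stopf("technical_shift_sd must be >= 0")
  if (timepoints < 1) stopf("timepoints must be >= 1")
  gene_names <- vapply(genes, `[[`, character(1), "name")
  if (anyDuplicated(gene_names)) stopf("genes.name entries must be unique")
  for (g in genes) {
    unknown <- setdiff(names(g$group_effects), groups)
    if (length(unknown) > 0) {
      stopf("genes[%s].group_effects names unknown group '%s'", g$name, unknown[1])
    }
  }
  if (!is.null(timepoint_labels) && length(timepoint_labels) != timepoints) {
    stopf("timepoint_labels must have length %d", timepoints)
  }
  structure(list(genes = genes, groups = as.character(groups),
                 timepoints = as.integer(timepoints),
                 n_per_cell = as.integer(n_per_cell),
                 technical_shift_sd = technical_shift_sd,
                 timepoint_labels = timepoint_labels,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %d genes, %d groups x %d timepoints x n = %d (%d samples)\n",
              length(x$genes), length(x$groups), x$timepoints, x$n_per_cell,
              length(x$groups) * x$timepoints * x$n_per_cell))
  for (g in x$genes) {
    cat(sprintf("  %s: baseline %.1f, E %.3f, slope %.3g, noise %.2f%s\n",
                g$name, g$baseline_cq, g$efficiency, g$time_slope, g$noise_sd,
                if (length(g$group_effects) > 0)
                  paste0(", effects [", paste(sprintf("%s %+0.2f",
                         names(g$group_effects), g$group_effects),
                         collapse = ", "), "]")
                else ""))
  }
  cat(sprintf("  technical shift SD %.2f, seed %d\n", x$technical_shift_sd, x$seed))
  invisible(x)
}

#' Simulate a Cq dataset from a specification
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; defaults to the spec's seed. Identical spec
#'   and seed yield a bit-identical dataset.
#' @return An object of class `cq_sim`: a list with `dataset` (a
#'   [cq_dataset()]), `assays` (per-gene [gene_assay()] list), `truth`
#'   (data frame: `gene`, `is_stable`, `group_effect_max`, `time_slope`,
#'   `noise_sd`) and `spec`.
#' @export
simulate_cq <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  gene_names <- vapply(spec$genes, `[[`, character(1), "name")
  cells <- expand.grid(timepoint = seq_len(spec$timepoints) - 1L,
                       group = spec$groups, stringsAsFactors = FALSE)
  samples <- cells[rep(seq_len(nrow(cells)), each = spec$n_per_cell), ]
  n <- nrow(samples)
  samples$rep <- rep(seq_len(spec$n_per_cell), times = nrow(cells))
  samples$sample_id <- sprintf("%s_t%d_%02d", samples$group,
                               samples$timepoint, samples$rep)

  cq <- matrix(NA_real_, n, length(gene_names),
               dimnames = list(NULL, gene_names))
  with_seed(seed, {
    delta <- stats::rnorm(n, 0, spec$technical_shift_sd)
    for (j in seq_along(spec$genes)) {
      g <- spec$genes[[j]]
      eff <- rep(0, n)
      if (length(g$group_effects) > 0) {
        idx <- match(samples$group, names(g$group_effects))
        eff <- ifelse(is.na(idx), 0, g$group_effects[idx])
      }
      cq[, j] <- g$baseline_cq + eff + g$time_slope * samples$timepoint +
        delta + stats::rnorm(n, 0, g$noise_sd)
    }
  })

  labels <- if (!is.null(spec$timepoint_labels)) {
    spec$timepoint_labels[samples$timepoint + 1L]
  } else NULL
  ds <- cq_dataset(cq, sample_id = samples$sample_id, group = samples$group,
                   timepoint = samples$timepoint, timepoint_label = labels)
  assays <- lapply(spec$genes, function(g) gene_assay(g$name, g$efficiency))
  names(assays) <- gene_names
  truth <- data.frame(
    gene = gene_names,
    is_stable = vapply(spec$genes, function(g) {
      all(g$group_effects == 0) && g$time_slope == 0
    }, logical(1)),
    group_effect_max = vapply(spec$genes, function(g) {
      if (length(g$group_effects) == 0) 0 else max(abs(g$group_effects))
    }, numeric(1)),
    time_slope = vapply(spec$genes, `[[`, numeric(1), "time_slope"),
    noise_sd = vapply(spec$genes, `[[`, numeric(1), "noise_sd")
  )
  structure(list(dataset = ds, assays = assays, truth = truth, spec = spec),
            class = "cq_sim")
}

#' @export
print.cq_sim <- function(x, ...) {
  cat("Simulated Cq dataset\n")
  print(x$dataset)
  stable <- x$truth$gene[x$truth$is_stable]
  cat("  stable by construction:",
      if (length(stable) > 0) paste(stable, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Preset simulation specifications
#'
#' Two presets emulate the structure of hepatic reference-gene experiments
#' in female Atlantic salmon:
#'
#' `"adult_like"`: four genes over a reproductive season, 4 groups
#' (maiden/repeat spawners at 14/22 degrees C) x 6 sampling months x n = 7.
#' The Tbp-like gene (low abundance, baseline Cq 28) is stable by
#' construction; the Ef1a-like gene (high abundance, baseline 18) carries a
#' small seasonal trend (~9% of Cq variance); the Hprt1-like gene trends
#' with reproductive development (slope calibrated so sampling time
#' accounts for ~30% of its Cq variance); the beta-tubulin-like gene
#' responds to warm rearing (+2.2 cycles at 22 degrees C) with elevated
#' noise.
#'
#' `"juvenile_like"`: three genes over a 14-day estradiol implant trial,
#' 4 groups (blank/E2 implant at 14/22 degrees C) x 3 sampling days x
#' n = 7. The Ef1a-like gene is stable by construction; the Hprt1-like gene
#' shows a mild implant-by-temperature response; the Tbp-like gene responds
#' to the E2 implant (+1.7 cycles) with elevated noise.
#'
#' @param name `"adult_like"` or `"juvenile_like"`.
#' @param seed default seed carried by the returned spec.
#' @return A [simulation_spec()].
#' @export
preset_spec <- function(name = c("adult_like", "juvenile_like"), seed = 1) {
  name <- match.arg(name)
  if (name == "adult_like") {
    groups <- c("maiden-14", "maiden-22", "repeat-14", "repeat-22")
    warm <- c("maiden-22" = 2.2, "repeat-22" = 2.2)
    simulation_spec(
      genes = list(
        sim_gene("Tbp_like", baseline_cq = 28, efficiency = 0.981,
                 noise_sd = 0.35),
        sim_gene("Ef1a_like", baseline_cq = 18, efficiency = 0.969,
                 time_slope = 0.30, noise_sd = 0.5),
        sim_gene("Hprt1_like", baseline_cq = 24, efficiency = 0.963,
                 time_slope = 0.65, noise_sd = 0.5),
        sim_gene("Btub_like", baseline_cq = 24.5, efficiency = 0.975,
                 group_effects = warm, noise_sd = 1.2)
      ),
      groups = groups, timepoints = 6, n_per_cell = 7,
      technical_shift_sd = 1.0,
      timepoint_labels = c("Aug07", "Nov07", "Jan08", "Feb08", "Mar08", "Apr08"),
      seed = seed
    )
  } else {
    groups <- c("blank-14", "blank-22", "E2-14", "E2-22")
    simulation_spec(
      genes = list(
        sim_gene("Ef1a_like", baseline_cq = 18, efficiency = 0.969,
                 noise_sd = 0.2),
        sim_gene("Hprt1_like", baseline_cq = 24, efficiency = 0.963,
                 group_effects = c("E2-22" = 1.0), time_slope = 0.7,
                 noise_sd = 0.4),
        sim_gene("Tbp_like", baseline_cq = 28, efficiency = 0.981,
                 group_effects = c("E2-14" = 2.2, "E2-22" = 2.2),
                 noise_sd = 0.75)
      ),
      groups = groups, timepoints = 3, n_per_cell = 7,
      technical_shift_sd = 1.2,
      timepoint_labels = c("day03", "day07", "day14"),
      seed = seed
    )
  }
}

#' Write a simulated dataset with its ground-truth sidecar
#'
#' Writes the Cq table in the standard CSV dialect of [write_cq()], the
#' per-gene assay table, and a `gene, is_stable, group_effect_max,
#' time_slope` ground-truth table.
#'
#' @param sim a [simulate_cq()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cq_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cq_file <- file.path(dir, "cq.csv")
  write_cq(sim$dataset, cq_file)
  assay_file <- file.path(dir, "assays.csv")
  at <- data.frame(gene = names(sim$assays),
                   efficiency = vapply(sim$assays, `[[`, numeric(1), "efficiency"))
  utils::write.csv(at, assay_file, row.names = FALSE, quote = FALSE)
  truth_file <- file.path(dir, "truth.csv")
  utils::write.csv(sim$truth, truth_file, row.names = FALSE, quote = FALSE)
  invisible(c(cq = cq_file, assays = assay_file, truth = truth_file))
}
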