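#' Construct a Cq dataset
#'
#' A `cq_dataset` holds a samples-by-genes matrix of raw quantification-cycle
#' (Cq) values together with per-sample metadata: the experimental group
#' label, an integer timepoint index ordered by calendar time, and an
#' optional timepoint label and temperature. Missing Cq values are stored as
#' `NA` and propagate as missing through all downstream analyses.
#'
#' @param cq numeric matrix of Cq values (cycles), one row per sample, one
#'   column per gene. All present values must lie in `(0, 45]`.
#' @param sample_id character vector of unique sample identifiers.
#' @param group character or factor vector of experimental group labels.
#' @param timepoint integer timepoint index (>= 0), ordered by calendar time,
#'   or a vector coercible to one.
#' @param timepoint_label optional character labels for the timepoints
#'   (e.g. `"Aug07"`, `"day 14"`).
#' @param temperature optional numeric rearing temperature in degrees C.
#' @return An object of class `cq_dataset` with elements `cq` (matrix),
#'   `samples` (data.frame of metadata) and `genes` (character vector).
#' @export
#' @examples
#' cq <- matrix(c(20, 21, 22, 23, 25, 25.5, 26, 26.5), ncol = 2,
#'              dimnames = list(NULL, c("g1", "g2")))
#' ds <- cq_dataset(cq, sample_id = paste0("s", 1:4),
#'                  group = c("A", "A", "B", "B"), timepoint = c(0, 1, 0, 1))
#' ds
cq_dataset <- function(cq, sample_id, group, timepoint,
                       timepoint_label = NULL, temperature = NULL) {
  cq <- as.matrix(cq)
  if (!is.numeric(cq)) stopf("cq must be a numeric matrix")
  if (is.null(colnames(cq))) stopf("cq must have gene names as column names")
  genes <- colnames(cq)
  if (anyDuplicated(genes)) stopf("duplicate gene name: %s",
                                  genes[duplicated(genes)][1])
  n <- nrow(cq)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n) stopf("sample_id length (%d) does not match cq rows (%d)",
                                    length(sample_id), n)
  if (anyDuplicated(sample_id)) stopf("duplicate sample id: %s",
                                      sample_id[duplicated(sample_id)][1])
  if (length(group) != n) stopf("group length does not match number of samples")
  if (length(timepoint) != n) stopf("timepoint length does not match number of samples")
  tp <- as.integer(timepoint)
  if (any(is.na(tp)) || any(tp < 0)) stopf("timepoint must be a non-negative integer index")
  bad <- which(!is.na(cq) & (cq <= 0 | cq > 45), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("Cq value out of range (0, 45] at sample '%s', gene '%s'",
          sample_id[bad[1, 1]], genes[bad[1, 2]])
  }
  samples <- data.frame(
    sample_id = sample_id,
    group = as.character(group),
    timepoint = tp,
    stringsAsFactors = FALSE
  )
  if (!is.null(timepoint_label)) samples$timepoint_label <- as.character(timepoint_label)
  if (!is.null(temperature)) samples$temperature <- as.numeric(temperature)
  rownames(cq) <- sample_id
  structure(list(cq = cq, samples = samples, genes = genes),
            class = "cq_dataset")
}

#' @export
print.cq_dataset <- function(x, ...) {
  cat(sprintf("Cq dataset: %d samples x %d genes\n", nrow(x$cq), length(x$genes)))
  cat("  genes:     ", paste(x$genes, collapse = ", "), "\n")
  cat("  groups:    ", paste(unique(x$samples$group), collapse = ", "), "\n")
  cat("  timepoints:", paste(sort(unique(x$samples$timepoint)), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$cq))
  if (nmiss > 0) cat(sprintf("  missing Cq: %d\n", nmiss))
  invisible(x)
}

#' Read a wide Cq table from a delimited text file
#'
#' Reads a UTF-8 CSV/TSV file with one header row, one row per biological
#' sample. Column roles are assigned through `sample_col`, `group_col` and
#' `timepoint_col`; every remaining column (or the columns named in
#' `gene_cols`) is treated as a gene with numeric Cq values. Empty cells
#' become missing values, not zeros.
#'
#' When the timepoint column is numeric the timepoint index is assigned by
#' increasing numeric value; when it is text the index follows
#' `timepoint_levels` (or first appearance if not given), so that the index
#' is ordered by calendar time as the user intends.
#'
#' @param file path to a delimited text file.
#' @param sample_col,group_col,timepoint_col names of the metadata columns.
#' @param gene_cols optional character vector naming the gene columns; by
#'   default all non-metadata columns are genes.
#' @param timepoint_levels optional character vector giving the calendar
#'   order of text timepoint labels.
#' @param sep field separator, `","` by default (use `"\t"` for TSV).
#' @param aggregate_replicates if `TRUE`, rows sharing a sample id are
#'   treated as technical replicates and averaged arithmetically; duplicated
#'   ids are otherwise an error.
#' @return A [cq_dataset()].
#' @export
read_cq <- function(file, sample_col = "sample_id", group_col = "group",
                    timepoint_col = "timepoint", gene_cols = NULL,
                    timepoint_levels = NULL, sep = ",",
                    aggregate_replicates = FALSE) {
  raw <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, fileEncoding = "UTF-8")
  for (col in c(sample_col, group_col, timepoint_col)) {
    if (!col %in% names(raw)) stopf("schema column '%s' not found in %s", col, file)
  }
  meta_cols <- c(sample_col, group_col, timepoint_col)
  if (is.null(gene_cols)) {
    gene_cols <- setdiff(names(raw), meta_cols)
  } else {
    missing_g <- setdiff(gene_cols, names(raw))
    if (length(missing_g) > 0) stopf("gene column '%s' not found", missing_g[1])
  }
  if (length(gene_cols) == 0) stopf("no gene columns found in %s", file)

  cq <- matrix(NA_real_, nrow = nrow(raw), ncol = length(gene_cols),
               dimnames = list(NULL, gene_cols))
  for (g in gene_cols) {
    txt <- raw[[g]]
    blank <- is.na(txt) | txt == "" | toupper(txt) == "NA"
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!blank & is.na(val))
    if (length(bad) > 0) {
      stopf("non-numeric Cq value '%s' at row %d, column '%s'",
            txt[bad[1]], bad[1], g)
    }
    cq[, g] <- val
  }

  ids <- raw[[sample_col]]
  if (aggregate_replicates && anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    agg <- apply(cq, 2, function(col) {
      tapply(col, factor(ids, levels = ids[keep]), mean, na.rm = TRUE)
    })
    agg[is.nan(agg)] <- NA_real_
    cq <- matrix(agg, ncol = length(gene_cols),
                 dimnames = list(NULL, gene_cols))
    raw <- raw[keep, , drop = FALSE]
    ids <- ids[keep]
  }

  tp_txt <- raw[[timepoint_col]]
  tp_num <- suppressWarnings(as.numeric(tp_txt))
  if (!any(is.na(tp_num))) {
    levels_ord <- sort(unique(tp_num))
    tp_index <- match(tp_num, levels_ord) - 1L
    tp_label <- as.character(tp_txt)
  } else {
    levels_ord <- timepoint_levels %||% unique(tp_txt)
    if (!all(tp_txt %in% levels_ord)) {
      stopf("timepoint label '%s' not in timepoint_levels",
            setdiff(tp_txt, levels_ord)[1])
    }
    tp_index <- match(tp_txt, levels_ord) - 1L
    tp_label <- tp_txt
  }

  cq_dataset(cq, sample_id = ids, group = raw[[group_col]],
             timepoint = tp_index, timepoint_label = tp_label)
}

#' Write a Cq dataset to a CSV file
#'
#' Numeric values are written with 17 significant digits so that a
#' `write_cq()` / [read_cq()] round trip reproduces finite values
#' bit-exactly. Missing Cq values are written as empty cells.
#'
#' @param ds a [cq_dataset()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cq <- function(ds, file) {
  stopifnot(inherits(ds, "cq_dataset"))
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  header <- c("sample_id", "group", "timepoint", ds$genes)
  rows <- vapply(seq_len(nrow(ds$cq)), function(i) {
    paste(c(ds$samples$sample_id[i], ds$samples$group[i],
            as.character(ds$samples$timepoint[i]), num(ds$cq[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), file, useBytes = TRUE)
  invisible(file)
}

# Subset a cq_dataset by gene names (internal).
subset_genes <- function(ds, genes) {
  missing_g <- setdiff(genes, ds$genes)
  if (length(missing_g) > 0) stopf("gene '%s' not in dataset", missing_g[1])
  ds$cq <- ds$cq[, genes, drop = FALSE]
  ds$genes <- genes
  ds
}
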