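# Independent brute-force oracles and small fixture builders. These are
# deliberately written with explicit loops and first-principles formulas,
# not by calling the package's own code paths.

# Build a cq_dataset from a samples-by-genes matrix with minimal metadata.
make_ds <- function(cq, group = NULL, timepoint = NULL) {
  n <- nrow(cq)
  cq_dataset(cq,
             sample_id = paste0("s", seq_len(n)),
             group = group %||% rep("A", n),
             timepoint = timepoint %||% rep(0L, n))
}

# Wrap a quantity matrix as rel_quantities without going through the
# delta-Cq transform (for direct algorithm checks on known q-vectors).
make_q <- function(qmat, group = NULL, timepoint = NULL) {
  ds <- make_ds(matrix(25, nrow(qmat), ncol(qmat),
                       dimnames = dimnames(qmat)),
                group = group, timepoint = timepoint)
  q <- relative_quantities(ds)
  q$q <- qmat
  q
}

# n-1 standard deviation of log2 ratios, written out longhand.
oracle_v <- function(qj, qk) {
  r <- log2(qj / qk)
  m <- sum(r) / length(r)
  sqrt(sum((r - m)^2) / (length(r) - 1))
}

# Full-panel M and stepwise elimination by direct recomputation.
oracle_genorm <- function(qmat) {
  genes <- colnames(qmat)
  vmat <- function(cols) {
    k <- length(cols)
    v <- matrix(0, k, k, dimnames = list(cols, cols))
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b) v[a, b] <- oracle_v(qmat[, cols[a]], qmat[, cols[b]])
    }
    v
  }
  mvals <- function(cols) {
    v <- vmat(cols)
    out <- numeric(length(cols))
    for (a in seq_along(cols)) out[a] <- mean(v[a, -a])
    names(out) <- cols
    out
  }
  elim <- character(0)
  left <- genes
  while (length(left) > 2) {
    m <- mvals(left)
    worst <- which(m == max(m))
    drop <- worst[length(worst)]          # later column on ties
    elim <- c(elim, left[drop])
    left <- left[-drop]
  }
  list(M = mvals(genes), V = vmat(genes), elimination = elim, final = left)
}

# Pearson r from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Tie-corrected Kendall tau-b by exhaustive pair enumeration.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
    else if (dx == 0) tie_x <- tie_x + 1
    else if (dy == 0) tie_y <- tie_y + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Random small relative-quantity fixture (values in (0, 1], max 1 per gene).
random_qmat <- function(n_genes, n_samples) {
  qmat <- matrix(2^(-stats::runif(n_samples * n_genes, 0, 6)),
                 n_samples, n_genes,
                 dimnames = list(NULL, paste0("g", seq_len(n_genes))))
  sweep(qmat, 2, apply(qmat, 2, max), "/")
}
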