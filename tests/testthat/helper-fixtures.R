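# Fixture builders and independent oracles used across the suite.

snapshot_sample_sheet <- function() {
  data.frame(
    sample_id = paste(rep(c("F", "L"), each = 6), rep(TISSUES_ALL, 2), sep = "_"),
    line = rep(c("F", "L"), each = 6),
    tissue = rep(TISSUES_ALL, 2),
    diet = "chow",
    replicate = 1L,
    stringsAsFactors = FALSE
  )
}

TISSUES_ALL <- c("SC", "EPI", "MES", "LIV", "MUS", "KID")

# Build a snapshot study from a probes x 6-tissues matrix of desired signed
# folds: F = base * fold (fold > 0) or base (fold < 0); L symmetric.
study_from_folds <- function(folds, base = 200) {
  folds <- as.matrix(folds)
  colnames(folds) <- TISSUES_ALL[seq_len(ncol(folds))]
  if (is.null(rownames(folds))) {
    rownames(folds) <- sprintf("p%03d", seq_len(nrow(folds)))
  }
  f <- ifelse(folds >= 1, base * folds, base)
  l <- ifelse(folds >= 1, base, base * abs(folds))
  m <- cbind(f, l)
  colnames(m) <- paste(rep(c("F", "L"), each = ncol(folds)),
                       rep(colnames(folds), 2), sep = "_")
  expression_study(m, snapshot_sample_sheet(), design = "snapshot")
}

depdc6_study <- function() {
  read_expression_study(
    system.file("extdata", "depdc6_snapshot_matrix.tsv", package = "stratiq"),
    system.file("extdata", "depdc6_snapshot_samples.tsv", package = "stratiq")
  )
}

# Quantitative study from explicit per-group log2 means (one probe) or a
# probes x 4 matrix of log2 group means; noise added per chip.
quant_study_from_log2 <- function(log2_means, reps = 4, noise_sd = 0,
                                  seed = NULL) {
  log2_means <- as.matrix(log2_means)
  colnames(log2_means) <- c("FC", "FF", "LC", "LF")
  if (is.null(rownames(log2_means))) {
    rownames(log2_means) <- sprintf("p%03d", seq_len(nrow(log2_means)))
  }
  if (!is.null(seed)) set.seed(seed)
  cols <- list()
  for (g in colnames(log2_means)) {
    for (r in seq_len(reps)) {
      noise <- if (noise_sd > 0) rnorm(nrow(log2_means), 0, noise_sd) else 0
      cols[[paste(g, r, sep = "_")]] <- 2^(log2_means[, g] + noise)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(log2_means)
  samples <- data.frame(
    sample_id = colnames(m),
    line = substr(colnames(m), 1, 1),
    tissue = "SC",
    diet = ifelse(substr(colnames(m), 2, 2) == "F", "highfat", "control"),
    replicate = as.integer(sub(".*_", "", colnames(m))),
    stringsAsFactors = FALSE
  )
  expression_study(m, samples, design = "quantitative")
}

# Quantitative study with explicit per-chip log2 values for two groups only
# (FC and LC), for hand-computable t-statistics.
two_group_study <- function(g1_log2, g2_log2) {
  m <- matrix(2^c(g1_log2, g2_log2), nrow = 1)
  ids <- c(paste0("FC_", seq_along(g1_log2)), paste0("LC_", seq_along(g2_log2)))
  colnames(m) <- ids
  rownames(m) <- "p001"
  samples <- data.frame(
    sample_id = ids,
    line = substr(ids, 1, 1),
    tissue = "SC",
    diet = "control",
    replicate = as.integer(sub(".*_", "", ids)),
    stringsAsFactors = FALSE
  )
  expression_study(m, samples, design = "quantitative")
}

# --- independent oracles -------------------------------------------------

# Brute-force BH step-up: q_i = min_{j >= i} p_(j) * m / j, in input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(X >= k) by explicit combinatorial sums.
hyper_tail_brute <- function(N, K, n, k) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# Ordinary pooled two-sample t (the d0 = 0 oracle).
pooled_t <- function(x, y) {
  df <- length(x) + length(y) - 2
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  (mean(x) - mean(y)) / sqrt(s2 * (1 / length(x) + 1 / length(y)))
}

# Brute-force per-probe re-evaluation of the depot-filter predicate.
brute_depot_lists <- function(study, depot, thr, win, inclusive = FALSE,
                              epsilon = 1) {
  ids <- rownames(study$intensities)
  up_F <- character(); up_L <- character()
  col_of <- function(line, tissue) {
    which(study$samples$line == line & study$samples$tissue == tissue)
  }
  for (pid in ids) {
    sfc <- sapply(TISSUES_ALL, function(tt) {
      f <- max(study$intensities[pid, col_of("F", tt)], epsilon)
      l <- max(study$intensities[pid, col_of("L", tt)], epsilon)
      if (f >= l) f / l else -(l / f)
    })
    ok_win <- is.null(win) ||
      all(abs(sfc[c("LIV", "MUS", "KID")]) < win)
    hit <- function(v) if (inclusive) v >= thr else v > thr
    if (hit(sfc[depot]) && ok_win) up_F <- c(up_F, pid)
    if (hit(-sfc[depot]) && ok_win) up_L <- c(up_L, pid)
  }
  list(up_F = up_F, up_L = up_L)
}

# Swap the F and L columns of a snapshot study.
swap_lines <- function(study) {
  samples <- study$samples
  samples$line <- ifelse(samples$line == "F", "L", "F")
  samples$sample_id <- paste(samples$line, samples$tissue, sep = "_")
  m <- study$intensities
  colnames(m) <- samples$sample_id
  expression_study(m, samples, design = "snapshot")
}

random_snapshot_study <- function(n_probes, seed) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_probes * 12, mean = 8, sd = 1.5), n_probes, 12)
  rownames(m) <- sprintf("p%03d", seq_len(n_probes))
  colnames(m) <- snapshot_sample_sheet()$sample_id
  expression_study(m, snapshot_sample_sheet(), design = "snapshot")
}
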