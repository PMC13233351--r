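# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (per-element loops) so they cannot share bugs with the
# vectorised implementations they check.

tiny_cohort <- function(seed = 42, ...) {
  simulate_cohort(sim_config(
    n_samples = 40, malignant_fraction = 0.3, n_weak = 10, n_bins = 80,
    n_species = 30, seed = seed, ...
  ))
}

random_count_tbl <- function(n_samples, n_bins, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_bins, lambda), n_samples, n_bins)
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  colnames(m) <- sprintf("sim1:%d-%d", (seq_len(n_bins) - 1) * 10,
                         seq_len(n_bins) * 10)
  feature_tibble(m)
}

# Naive per-sample normalization oracle.
oracle_normalize <- function(m, usable) {
  out <- m
  for (i in seq_len(nrow(m))) {
    tot <- 0
    for (j in which(usable)) tot <- tot + m[i, j]
    for (j in seq_len(ncol(m))) out[i, j] <- m[i, j] / tot * 1e6
  }
  out
}

# Naive per-pair AUC oracle with explicit tie handling.
oracle_auc <- function(truth, scores) {
  pos <- which(truth == "malignant")
  neg <- which(truth != "malignant")
  total <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) total <- total + 1
      else if (scores[i] == scores[j]) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# Naive per-bin availability oracle.
oracle_available <- function(m, min_sample_fraction, min_reads) {
  keep <- integer(0)
  for (j in seq_len(ncol(m))) {
    n_avail <- 0
    for (i in seq_len(nrow(m))) {
      if (m[i, j] >= min_reads) n_avail <- n_avail + 1
    }
    if (n_avail / nrow(m) >= min_sample_fraction) keep <- c(keep, j)
  }
  keep
}

# Naive per-species prevalence oracle.
oracle_retained_species <- function(counts, species, cutoff, min_reads = 2) {
  kept <- character(0)
  for (s in seq_along(species)) {
    n_pos <- 0
    for (j in seq_len(ncol(counts))) {
      if (counts[s, j] > min_reads) n_pos <- n_pos + 1
    }
    if (n_pos / ncol(counts) >= cutoff) kept <- c(kept, species[s])
  }
  kept
}

# A two-class toy with a clean mean shift on the first `k` features.
separable_features <- function(n = 60, p = 10, k = min(p, 10), delta = 3,
                               seed = 5) {
  set.seed(seed)
  y <- rep(c("malignant", "non_malignant"), each = n / 2)
  m <- matrix(rnorm(n * p), n, p)
  m[y == "malignant", seq_len(k)] <- m[y == "malignant", seq_len(k)] + delta
  rownames(m) <- sprintf("t%03d", seq_len(n))
  colnames(m) <- paste0("f", seq_len(p))
  names(y) <- rownames(m)
  list(features = feature_tibble(m), labels = y)
}
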