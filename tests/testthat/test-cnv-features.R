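make_bins <- function(n, gc = NULL, mappability = 0.99) {
  bins <- define_bins(c(sim1 = n * 1e6))
  bins$gc <- if (is.null(gc)) seq(0.3, 0.6, length.out = n) else gc
  bins$mappability <- rep_len(mappability, n)
  bins
}
bin_ids <- function(bins) paste0(bins$chrom, ":", format(bins$start, scientific = FALSE, trim = TRUE), "-", format(bins$end, scientific = FALSE, trim = TRUE))

test_that("per-million normalization is exact and scale invariant", {
  tbl <- random_count_tbl(6, 40, seed = 1)
  m <- feature_matrix(tbl)
  norm <- feature_matrix(normalize_counts(tbl))
  expect_equal(norm, oracle_normalize(m, rep(TRUE, 40)), tolerance = 1e-12)
  expect_equal(unname(rowSums(norm)), rep(1e6, 6))

  doubled <- feature_tibble(m * 2)
  expect_equal(feature_matrix(normalize_counts(doubled)), norm,
               tolerance = 1e-12)

  uni <- feature_tibble(matrix(7, 2, 10, dimnames = list(c("a", "b"), paste0("sim1:", 0:9, "-", 1:10))))
  expect_true(all(abs(feature_matrix(normalize_counts(uni)) - 1e6 / 10) < 1e-9))
})

test_that("normalization respects the mask and flags all-zero samples", {
  tbl <- random_count_tbl(4, 20, seed = 2)
  mask <- rep(c(TRUE, FALSE), c(5, 15))
  norm <- feature_matrix(normalize_counts(tbl, mask = mask))
  expect_equal(unname(rowSums(norm[, !mask])), rep(1e6, 4))
  expect_equal(norm, oracle_normalize(feature_matrix(tbl), !mask),
               tolerance = 1e-12)

  m <- feature_matrix(tbl)
  m[2, ] <- 0
  expect_warning(out <- normalize_counts(feature_tibble(m)), "zero usable")
  expect_equal(attr(out, "excluded_samples"), "s02")
  expect_equal(nrow(out), 3)
})

test_that("GC correction is a near no-op when counts are GC independent", {
  set.seed(4)
  n <- 400
  bins <- make_bins(n)
  m <- matrix(rpois(5 * n, 2000), 5, n,
              dimnames = list(sprintf("s%d", 1:5), bin_ids(bins)))
  res <- correct_gc_mappability(feature_tibble(m), bins)
  corrected <- feature_matrix(res$corrected)
  rel <- abs(corrected - m) / m
  expect_lt(max(rel, na.rm = TRUE), 0.02)
})

test_that("an injected smooth GC effect is removed", {
  set.seed(5)
  n <- 2000
  bins <- make_bins(n, gc = runif(n, 0.3, 0.6))
  base <- 2000
  # monotone over the GC range so the raw linear correlation is visible
  effect <- exp(-6 * (bins$gc - 0.30)^2)
  m <- matrix(rpois(2 * n, rep(base * effect, each = 2)), 2, n,
              dimnames = list(c("s1", "s2"), bin_ids(bins)))
  raw_r <- abs(cor(m[1, ], bins$gc))
  res <- correct_gc_mappability(feature_tibble(m), bins, loess_span = 0.3)
  corrected <- feature_matrix(res$corrected)
  for (i in 1:2) {
    expect_lt(abs(cor(corrected[i, ], bins$gc)), 0.05)
  }
  expect_gt(raw_r, 0.3) # the injected bias was real
})

test_that("low-mappability windows are masked", {
  n <- 50
  bins <- make_bins(n)
  bins$mappability[c(3, 17)] <- 0.5
  tbl <- random_count_tbl(3, n, seed = 6, lambda = 1000)
  res <- correct_gc_mappability(tbl, bins)
  expect_true(all(res$mask[c(3, 17)]))
  expect_true(all(is.na(feature_matrix(res$corrected)[, c(3, 17)])))
  expect_false(any(res$mask[-c(3, 17)]))

  bins_few <- make_bins(12)
  bins_few$mappability <- 0.1
  expect_error(correct_gc_mappability(random_count_tbl(2, 12, seed = 1), bins_few),
               class = "cnvrisk_invalid_input")
})

test_that("log2 ratios match the elementwise definition", {
  expect_equal(compute_log2_ratio(c(4, 8), c(4, 8)), c(0, 0))
  expect_equal(compute_log2_ratio(8, 4), 1.0)
  set.seed(7)
  s <- runif(30, 0.5, 10)
  b <- runif(30, 0.5, 10)
  expect_equal(compute_log2_ratio(s, b), log2(s / b), tolerance = 1e-12)
  # zero coverage is masked, not clamped
  x <- compute_log2_ratio(c(0, 2), c(1, 1))
  expect_true(is.na(x[1]))
  expect_equal(x[2], 1)
  expect_error(compute_log2_ratio(1:3, 1:2), class = "cnvrisk_invalid_input")
})

test_that("degenerate baselines floor sigma and k = 0 disables denoising", {
  prof <- c(0.1, -0.2, 0.3, 0)
  m <- matrix(rep(prof, each = 5), 5, 4,
              dimnames = list(paste0("r", 1:5), paste0("b", 1:4)))
  suppressWarnings(base <- build_reference_baseline(m, k_components = 0))
  expect_equal(unname(base$mu), prof)
  expect_equal(unname(base$sigma), rep(1e-4, 4))

  set.seed(8)
  m2 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("r", 1:8), paste0("b", 1:5)))
  suppressWarnings(b0 <- build_reference_baseline(m2, k_components = 0))
  expect_equal(unname(b0$mu), unname(colMeans(m2)))
  expect_equal(unname(b0$sigma), unname(apply(m2, 2, sd)))
  expect_identical(pca_denoise(m2[1, ], b0), m2[1, ])

  expect_error(suppressWarnings(build_reference_baseline(m2, k_components = 8)),
               class = "cnvrisk_error")
  expect_error(build_reference_baseline(m2[1, , drop = FALSE]),
               class = "cnvrisk_error")
})

test_that("one shared factor is removed by a rank-1 denoiser", {
  set.seed(9)
  n <- 60; p <- 120
  loading <- rnorm(p)
  scores <- rnorm(n, sd = 0.5)
  noise <- matrix(rnorm(n * p, sd = 0.05), n, p)
  m <- outer(scores, loading) + noise
  dimnames(m) <- list(paste0("r", seq_len(n)), paste0("b", seq_len(p)))
  base <- build_reference_baseline(m, k_components = 1)
  raw_sd <- apply(scale(m, scale = FALSE), 2, sd)
  expect_lt(median(base$sigma / raw_sd), 0.25)

  # a fresh profile built from the component leaves only the baseline mean
  x <- base$mu + 2.5 * base$components[, 1]
  resid <- pca_denoise(x, base)
  expect_lt(max(abs(resid - base$mu)), 1e-10)

  # a fresh profile carrying the factor is decorrelated from the loading
  x2 <- base$mu + 1.5 * loading + rnorm(p, sd = 0.05)
  expect_gt(abs(cor(x2 - base$mu, loading)), 0.9)
  expect_lt(abs(cor(pca_denoise(x2, base) - base$mu, loading)), 0.1)
})

test_that("Z scoring matches the standardization formula", {
  set.seed(10)
  mu <- rnorm(20)
  sigma <- runif(20, 0.1, 2)
  base <- structure(list(mu = mu, sigma = sigma,
                         components = matrix(0, 20, 0), k = 0L,
                         sigma_floor = 1e-4), class = "cnv_baseline")
  expect_equal(compute_z(mu, base), rep(0, 20))
  expect_equal(compute_z(mu + 2 * sigma, base), rep(2, 20))
  x <- rnorm(20)
  expect_equal(compute_z(x, base), (x - mu) / sigma, tolerance = 1e-12)
  # masked windows are imputed to "no deviation"
  x[3] <- NA
  expect_equal(compute_z(x, base)[3], 0)
})

test_that("availability filtering is inclusive and matches the loop oracle", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("s", 1:4), paste0("b", 1:3)))
  m[, 1] <- 5L
  m[1, 2] <- 1L          # available in exactly 1/4 samples
  idx <- filter_available_bins(feature_tibble(m), min_sample_fraction = 0.25)
  expect_equal(idx, c(1L, 2L))

  tbl <- random_count_tbl(20, 50, seed = 11, lambda = 0.8)
  mat <- feature_matrix(tbl)
  for (frac in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(filter_available_bins(tbl, min_sample_fraction = frac),
                 oracle_available(mat, frac, 1))
  }
  # monotone in the threshold
  sizes <- vapply(c(0.1, 0.25, 0.5, 0.9), function(f) {
    length(filter_available_bins(tbl, min_sample_fraction = f))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(filter_available_bins(feature_tibble(matrix(0, 0, 0))),
               class = "cnvrisk_error")
})

test_that("the full pipeline is invariant to per-sample scaling", {
  co <- simulate_cohort(sim_config(n_samples = 30, malignant_fraction = 0.2,
                                   n_weak = 0, n_bins = 60, n_species = 2,
                                   mean_reads_per_bin = 300, seed = 12))
  ref <- co$labels$sample_id[co$labels$label == "non_malignant"][1:20]
  suppressWarnings(z1 <- cnv_feature_pipeline(co$bin_counts, co$bins, ref))
  m <- feature_matrix(co$bin_counts)
  m[5, ] <- m[5, ] * 17L
  suppressWarnings(z2 <- cnv_feature_pipeline(feature_tibble(m), co$bins, ref))
  expect_equal(feature_matrix(z1$z)[5, ], feature_matrix(z2$z)[5, ],
               tolerance = 1e-8)
})

test_that("reference samples re-scored by their frozen baseline are calibrated", {
  co <- simulate_cohort(sim_config(n_samples = 80, malignant_fraction = 0,
                                   n_weak = 0, n_bins = 120, n_species = 2,
                                   n_latent_factors = 0, seed = 14))
  ref <- co$labels$sample_id[1:60]
  feats <- cnv_feature_pipeline(co$bin_counts, co$bins, ref)
  z <- feature_matrix(feats$z)[ref, ]
  expect_lt(max(abs(colMeans(z))), 0.1)
  sds <- apply(z, 2, sd)
  expect_true(all(sds > 0.8 & sds < 1.2))
})
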