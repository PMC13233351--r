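# Window-level CNV Z-score feature derivation: normalization, GC/mappability
# correction, reference baseline with PCA denoising, Z scoring, and the
# availability filter. All stages operate on the canonical wide tibble
# (sample_id + one column per window) and compose in cnv_feature_pipeline().

#' Library-size normalization of a window count matrix
#'
#' Scales each sample so its total count over usable windows equals 1e6
#' (counts per million), making coverage profiles comparable across samples
#' regardless of sequencing depth or host-read fraction.
#'
#' @param counts Wide tibble (`sample_id` + one numeric column per window).
#' @param mask Optional logical vector, one per window; `TRUE` marks windows
#'   excluded from the per-sample total (they are still rescaled).
#' @return A wide tibble of normalized values. Samples with zero total over
#'   usable windows are dropped with a warning and listed in the
#'   `excluded_samples` attribute.
#' @export
normalize_counts <- function(counts, mask = NULL) {
  m <- feature_matrix(counts)
  if (any(m < 0, na.rm = TRUE)) abort_schema("counts must be non-negative")
  usable <- if (is.null(mask)) rep(TRUE, ncol(m)) else !mask
  totals <- rowSums(m[, usable, drop = FALSE], na.rm = TRUE)
  bad <- totals <= 0
  if (any(bad)) {
    rlang::warn(paste0(
      "excluding sample(s) with zero usable counts: ",
      paste(rownames(m)[bad], collapse = ", ")
    ))
    m <- m[!bad, , drop = FALSE]
    totals <- totals[!bad]
  }
  out <- feature_tibble(m / totals * 1e6)
  attr(out, "excluded_samples") <- names(bad)[bad]
  out
}

#' GC-bias correction and mappability masking
#'
#' Per sample, fits a smooth local-regression curve of normalized coverage
#' against window GC fraction, divides each window by the fitted value, and
#' rescales so the sample median is preserved. Windows with mappability
#' below `mappability_min` are masked: excluded from the fit and set to `NA`
#' in the output.
#'
#' @param normalized Wide tibble of normalized coverage values.
#' @param bins Window tibble with `gc` and `mappability` columns, one row
#'   per value column of `normalized`, in order.
#' @param mappability_min Windows below this mappability are masked
#'   (default 0.8).
#' @param loess_span Local-regression span (default 0.3).
#' @return A list: `corrected` (wide tibble, masked windows `NA`) and
#'   `mask` (logical vector, `TRUE` = masked window).
#' @export
correct_gc_mappability <- function(normalized, bins, mappability_min = 0.8,
                                   loess_span = 0.3) {
  m <- feature_matrix(normalized)
  if (ncol(m) != nrow(bins)) {
    abort_schema(sprintf("matrix has %d windows but `bins` has %d rows",
                         ncol(m), nrow(bins)))
  }
  mask <- !is.na(bins$mappability) & bins$mappability < mappability_min
  usable <- which(!mask)
  if (length(usable) < 10) {
    abort_invalid("fewer than 10 usable windows after mappability masking",
                  class = "cnvrisk_invalid_input")
  }
  gc <- bins$gc
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    y <- m[i, usable]
    fit <- stats::loess(y ~ g, data = data.frame(y = y, g = gc[usable]),
                        span = loess_span, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    f <- predict(fit, data.frame(g = gc[usable]))
    f[!is.finite(f) | f <= 0] <- NA_real_
    ratio <- y / f
    out[i, usable] <- ratio * median(f, na.rm = TRUE)
  }
  list(corrected = feature_tibble(out), mask = mask)
}

#' Per-window log2 ratio of a sample against the reference median
#'
#' `x_b = log2(sample_b / baseline_median_b)`; positive values indicate
#' relative copy-number gain, negative values loss. Windows where the sample
#' has zero (or masked) coverage are returned as `NA` rather than clamped.
#'
#' @param sample_values Numeric vector of corrected coverage values.
#' @param baseline_median Numeric vector of per-window reference medians
#'   (positive on usable windows).
#' @return Numeric vector of log2 ratios with `NA` at unavailable windows.
#' @export
compute_log2_ratio <- function(sample_values, baseline_median) {
  if (length(sample_values) != length(baseline_median)) {
    abort_invalid("sample and baseline lengths differ",
                  class = "cnvrisk_invalid_input")
  }
  ok <- is.finite(sample_values) & sample_values > 0 &
    is.finite(baseline_median) & baseline_median > 0
  x <- rep(NA_real_, length(sample_values))
  x[ok] <- log2(sample_values[ok] / baseline_median[ok])
  x
}

#' Build the non-malignant reference baseline with PCA denoising
#'
#' Fits principal components on the column-centered reference log2-ratio
#' matrix. The top `k` components capture shared background variation
#' (sequencing depth, batch effects); per-window mean and SD are computed
#' from the component-removed (denoised) reference profiles, with the SD
#' floored at `sigma_floor`.
#'
#' @param reference_log2 Samples-by-windows matrix (or wide tibble) of
#'   reference log2 ratios; `NA` entries are mean-imputed for the fit.
#' @param k_components Number of components to remove, or `"auto"`:
#'   permutation-calibrated selection (parallel analysis) — components whose
#'   eigenvalue exceeds the largest eigenvalue seen in column-permuted
#'   copies of the reference matrix, capped at 10. On a reference with no
#'   shared structure this keeps k near 0, so the per-window SD stays
#'   unbiased and downstream Z scores stay calibrated.
#' @param sigma_floor Lower bound on the per-window SD (default 1e-4).
#' @return A `cnv_baseline` object: `mu`, `sigma`, `components`
#'   (windows x k, orthonormal), `k`, `reference_sample_ids`, `bin_ids`.
#' @export
build_reference_baseline <- function(reference_log2, k_components = "auto",
                                     sigma_floor = 1e-4) {
  m <- if (is.data.frame(reference_log2)) feature_matrix(reference_log2)
       else as.matrix(reference_log2)
  n <- nrow(m)
  if (n < 2) abort_invalid("need at least 2 reference samples")
  if (n < 30) {
    rlang::warn(sprintf(
      "only %d reference samples; per-window SDs may be unstable below 30", n
    ))
  }
  if (!identical(k_components, "auto")) {
    check_count(k_components, "k_components")
    if (k_components >= n) {
      abort_invalid("`k_components` must be smaller than the reference size")
    }
  }
  na_idx <- which(is.na(m))
  if (length(na_idx)) {
    cm <- matrix(colMeans(m, na.rm = TRUE), n, ncol(m), byrow = TRUE)
    m[na_idx] <- cm[na_idx]
    m[is.na(m)] <- 0 # windows missing in every reference sample
  }
  mu_raw <- colMeans(m)
  xc <- sweep(m, 2, mu_raw)
  sv <- La.svd(xc, nu = 0, nv = min(n - 1, ncol(m)))
  eig <- sv$d^2 / (n - 1)
  k <- if (identical(k_components, "auto")) {
    # parallel analysis: null top eigenvalue from column permutations,
    # internally seeded so the fit is a pure function of its input
    thr <- with_seed((n * 2147 + ncol(m)) %% .Machine$integer.max, {
      max(vapply(seq_len(3), function(b) {
        perm <- apply(xc, 2, function(col) col[sample.int(n)])
        max(La.svd(sweep(perm, 2, colMeans(perm)), nu = 0, nv = 0)$d^2) / (n - 1)
      }, numeric(1)))
    })
    min(sum(eig > thr), 10L, n - 1L)
  } else {
    as.integer(k_components)
  }
  components <- if (k > 0) t(sv$vt[seq_len(k), , drop = FALSE])
                else matrix(0, ncol(m), 0)
  resid <- xc
  if (k > 0) resid <- xc - (xc %*% components) %*% t(components)
  sigma <- pmax(apply(resid, 2, sd), sigma_floor)
  structure(
    list(
      mu = mu_raw,
      sigma = sigma,
      components = components,
      k = k,
      sigma_floor = sigma_floor,
      reference_sample_ids = rownames(m),
      bin_ids = colnames(m)
    ),
    class = "cnv_baseline"
  )
}

#' Remove shared background components from a log2-ratio profile
#'
#' Projects the baseline-centered profile onto the span of the top-k
#' reference components and subtracts the projection, removing background
#' variation common to the non-malignant reference (depth, batch). With
#' `k = 0` this is the identity. Unavailable (`NA`) windows contribute 0 to
#' the projection and stay `NA` in the output.
#'
#' @param x Numeric log2-ratio vector (`NA` = unavailable window).
#' @param baseline A [build_reference_baseline()] object.
#' @return The denoised log2-ratio vector.
#' @export
pca_denoise <- function(x, baseline) {
  stopifnot(inherits(baseline, "cnv_baseline"))
  if (length(x) != length(baseline$mu)) {
    abort_invalid("profile length does not match the baseline",
                  class = "cnvrisk_invalid_input")
  }
  if (baseline$k == 0) return(x)
  xc <- x - baseline$mu
  xc[is.na(xc)] <- 0
  proj <- as.vector(baseline$components %*%
                      crossprod(baseline$components, xc))
  x - proj
}

#' Standardize a denoised profile against the reference baseline
#'
#' `Z_b = (x_b - mu_b) / sigma_b`: the number of reference SDs by which the
#' sample's window coverage deviates from the non-malignant background.
#' Unavailable windows are imputed to Z = 0 ("no deviation"), a neutral
#' value for tree-based classifiers.
#'
#' @param x Denoised log2-ratio vector (`NA` = unavailable).
#' @param baseline A [build_reference_baseline()] object.
#' @return Numeric Z-score vector, finite everywhere.
#' @export
compute_z <- function(x, baseline) {
  stopifnot(inherits(baseline, "cnv_baseline"))
  z <- (x - baseline$mu) / baseline$sigma
  z[!is.finite(z)] <- 0
  z
}

#' Filter windows by cross-sample availability
#'
#' A window is "available" in a sample when its raw count reaches
#' `min_reads`; windows available in fewer than `min_sample_fraction` of
#' samples are unstable under shallow coverage and are dropped from the
#' feature set. Both thresholds are inclusive.
#'
#' @param raw_counts Wide tibble of raw (integer) window counts.
#' @param min_sample_fraction Minimum fraction of samples in which a window
#'   must be available (default 0.25).
#' @param min_reads Minimum raw count for availability (default 1).
#' @return Sorted integer indices of retained windows.
#' @export
filter_available_bins <- function(raw_counts, min_sample_fraction = 0.25,
                                  min_reads = 1) {
  m <- feature_matrix(raw_counts)
  if (nrow(m) == 0 || ncol(m) == 0) {
    abort_invalid("empty count matrix", class = "cnvrisk_invalid_input")
  }
  frac <- colMeans(m >= min_reads)
  sort(unname(which(frac >= min_sample_fraction)))
}

#' Full window-level CNV Z-score feature pipeline
#'
#' Composes the feature-derivation stages in order: per-million
#' normalization, GC/mappability correction, reference-baseline
#' construction (per-window median, then PCA on reference log2 ratios —
#' fitted only on `reference_ids` and frozen), log2 ratio, component
#' removal, Z scoring, and the cross-sample availability filter.
#'
#' @param raw_counts Wide tibble of raw window counts for every sample
#'   (reference and test).
#' @param bins Window tibble with `gc` and `mappability`, matching the
#'   count columns.
#' @param reference_ids Sample ids of the non-malignant reference set.
#' @param k_components Components removed by the denoiser (`"auto"` or a
#'   count); see [build_reference_baseline()].
#' @param min_sample_fraction,min_reads Availability-filter settings.
#' @param mappability_min,loess_span GC/mappability-correction settings.
#' @param sigma_floor Baseline SD floor.
#' @return A `cnv_features` object: `z` (wide tibble, samples x retained
#'   windows), `baseline`, `retained_bins` (indices into `bins`),
#'   `bin_ids`, and the settings used.
#' @export
cnv_feature_pipeline <- function(raw_counts, bins, reference_ids,
                                 k_components = "auto",
                                 min_sample_fraction = 0.25, min_reads = 1,
                                 mappability_min = 0.8, loess_span = 0.3,
                                 sigma_floor = 1e-4) {
  raw_m <- feature_matrix(raw_counts)
  ids <- rownames(raw_m)
  missing_ref <- setdiff(reference_ids, ids)
  if (length(missing_ref)) {
    abort_invalid(paste0("reference ids absent from the count matrix: ",
                         paste(head(missing_ref, 5), collapse = ", ")),
                  class = "cnvrisk_invalid_input")
  }

  mask0 <- !is.na(bins$mappability) & bins$mappability < mappability_min
  norm <- normalize_counts(raw_counts, mask = mask0)
  corr <- correct_gc_mappability(norm, bins, mappability_min = mappability_min,
                                 loess_span = loess_span)
  cm <- feature_matrix(corr$corrected)

  ref_rows <- rownames(cm) %in% reference_ids
  baseline_median <- apply(cm[ref_rows, , drop = FALSE], 2, median,
                           na.rm = TRUE)
  baseline_median[!is.finite(baseline_median) | baseline_median <= 0] <- NA

  log2m <- t(apply(cm, 1, compute_log2_ratio,
                   baseline_median = baseline_median))
  dimnames(log2m) <- dimnames(cm)

  baseline <- build_reference_baseline(log2m[ref_rows, , drop = FALSE],
                                       k_components = k_components,
                                       sigma_floor = sigma_floor)

  z <- t(apply(log2m, 1, function(x) {
    compute_z(pca_denoise(x, baseline), baseline)
  }))
  dimnames(z) <- dimnames(cm)

  avail <- filter_available_bins(raw_counts,
                                 min_sample_fraction = min_sample_fraction,
                                 min_reads = min_reads)
  retained <- sort(intersect(avail,
                             which(!corr$mask & !is.na(baseline_median))))
  structure(
    list(
      z = feature_tibble(z[, retained, drop = FALSE]),
      baseline = baseline,
      retained_bins = retained,
      bin_ids = colnames(raw_m)[retained],
      bins = bins[retained, , drop = FALSE],
      settings = list(
        k_components = baseline$k,
        min_sample_fraction = min_sample_fraction,
        min_reads = min_reads,
        mappability_min = mappability_min,
        loess_span = loess_span,
        sigma_floor = sigma_floor
      ),
      reference_ids = reference_ids
    ),
    class = "cnv_features"
  )
}
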