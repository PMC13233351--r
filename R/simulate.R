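#' Expected coverage multiplier of a copy-number state under tumor admixture
#'
#' In a sample where a fraction `tumor_fraction` of host DNA derives from
#' tumor cells carrying `copy_number` copies of a region (diploid elsewhere),
#' the expected read depth of that region relative to the diploid level is
#' `(1 - tf) + tf * cn / 2`: copy-number signal is diluted linearly by the
#' non-tumor background.
#'
#' @param copy_number Integer copy number (>= 0); vectorised.
#' @param tumor_fraction Tumor DNA fraction in \[0, 1\]; vectorised.
#' @return The multiplicative depth factor (1 for diploid or zero tumor
#'   fraction).
#' @export
#' @examples
#' expected_multiplier(4, 0.5) # 1.5
expected_multiplier <- function(copy_number, tumor_fraction) {
  if (any(copy_number < 0) || any(copy_number != floor(copy_number))) {
    abort_invalid("`copy_number` must be a non-negative integer")
  }
  check_proportion(tumor_fraction, "tumor_fraction")
  (1 - tumor_fraction) + tumor_fraction * copy_number / 2
}

#' Configuration for the synthetic BALF-mNGS cohort simulator
#'
#' Collects every knob of the cohort generator with validated defaults. The
#' defaults describe a shallow-coverage setting: ~500 host reads per 1-Mb
#' window (about 0.025-0.05x for 50-bp reads), negative-binomial counts with
#' variance about twice the mean, a mild unimodal GC bias, two weak shared
#' latent batch factors, and malignant samples carrying a handful of clonal
#' gain/loss segments diluted by a per-sample tumor fraction.
#'
#' @param n_samples Number of definitively labeled samples.
#' @param malignant_fraction Fraction of labeled samples that are malignant;
#'   exactly `round(n_samples * malignant_fraction)` are malignant.
#' @param n_weak Number of additional weakly labeled samples (hidden truth
#'   stored for pseudo-label purity measurement).
#' @param n_bins Number of 1-Mb windows in the synthetic genome (one
#'   chromosome named `"sim1"`).
#' @param tumor_fraction_range `(lo, hi)` of the per-malignant-sample tumor
#'   fraction, drawn uniformly.
#' @param n_cnv_segments Copy-number segments per malignant sample.
#' @param segment_length_bins Length of each segment in windows.
#' @param copy_numbers Integer copy states sampled per segment.
#' @param fixed_segments Optional tibble (`start_bin`, `end_bin`,
#'   `copy_number`; 1-based inclusive window indices) planted identically in
#'   every malignant sample instead of random segments — useful for
#'   planted-signal recovery studies.
#' @param mean_reads_per_bin Expected reads per window at diploid state with
#'   no bias terms.
#' @param gc_bias_strength Strength of the multiplicative GC curve
#'   `exp(-s * (gc - 0.45)^2)`; 0 disables GC bias.
#' @param n_latent_factors,latent_factor_sd Rank and per-sample loading SD of
#'   the shared multiplicative batch term `exp(L %*% F)`; rank 0 disables it.
#' @param n_species Number of microbial species simulated.
#' @param species_prevalence_range `(lo, hi)` of per-species detection
#'   prevalence, drawn uniformly.
#' @param nb_dispersion Negative-binomial size parameter for all counts
#'   (`Inf` gives Poisson).
#' @param microbe_effect_size Multiplicative abundance shift of the first
#'   `n_affected_species` species in malignant samples (1 = no association).
#' @param n_affected_species Number of species carrying the shift.
#' @param weak_label_noise Fraction of weak samples whose recorded suspected
#'   label is flipped relative to the data-generating truth.
#' @param low_mappability_fraction Fraction of windows given mappability 0.5
#'   (masked downstream); all other windows get 0.99.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 300,
                       malignant_fraction = 0.3,
                       n_weak = 100,
                       n_bins = 500,
                       tumor_fraction_range = c(0.2, 0.6),
                       n_cnv_segments = 4,
                       segment_length_bins = 20,
                       copy_numbers = c(0L, 1L, 3L, 4L),
                       fixed_segments = NULL,
                       mean_reads_per_bin = 500,
                       gc_bias_strength = 1,
                       n_latent_factors = 2,
                       latent_factor_sd = 0.05,
                       n_species = 150,
                       species_prevalence_range = c(0.05, 0.9),
                       nb_dispersion = 500,
                       microbe_effect_size = 1,
                       n_affected_species = 0,
                       weak_label_noise = 0.1,
                       low_mappability_fraction = 0.02,
                       seed = 1L) {
  check_count(n_samples, "n_samples")
  check_count(n_weak, "n_weak")
  check_count(n_bins, "n_bins")
  check_count(n_cnv_segments, "n_cnv_segments")
  check_count(segment_length_bins, "segment_length_bins")
  check_count(n_species, "n_species")
  check_proportion(malignant_fraction, "malignant_fraction")
  check_proportion(weak_label_noise, "weak_label_noise")
  check_proportion(low_mappability_fraction, "low_mappability_fraction")
  check_range(tumor_fraction_range, "tumor_fraction_range")
  check_proportion(tumor_fraction_range, "tumor_fraction_range")
  check_range(species_prevalence_range, "species_prevalence_range")
  check_proportion(species_prevalence_range, "species_prevalence_range")
  if (mean_reads_per_bin <= 0) abort_invalid("`mean_reads_per_bin` must be positive")
  if (nb_dispersion <= 0) abort_invalid("`nb_dispersion` must be positive")
  if (any(copy_numbers < 0)) abort_invalid("copy numbers must be non-negative")
  structure(
    list(
      n_samples = as.integer(n_samples),
      malignant_fraction = malignant_fraction,
      n_weak = as.integer(n_weak),
      n_bins = as.integer(n_bins),
      tumor_fraction_range = tumor_fraction_range,
      n_cnv_segments = as.integer(n_cnv_segments),
      segment_length_bins = as.integer(segment_length_bins),
      copy_numbers = as.integer(copy_numbers),
      fixed_segments = fixed_segments,
      mean_reads_per_bin = mean_reads_per_bin,
      gc_bias_strength = gc_bias_strength,
      n_latent_factors = as.integer(n_latent_factors),
      latent_factor_sd = latent_factor_sd,
      n_species = as.integer(n_species),
      species_prevalence_range = species_prevalence_range,
      nb_dispersion = nb_dispersion,
      microbe_effect_size = microbe_effect_size,
      n_affected_species = as.integer(n_affected_species),
      weak_label_noise = weak_label_noise,
      low_mappability_fraction = low_mappability_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

rnb <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

#' Simulate a synthetic admixed-mNGS cohort with known copy-number truth
#'
#' Draws per-window host read counts for `n_samples` definitively labeled
#' plus `n_weak` weakly labeled samples. Counts follow a negative-binomial
#' law whose mean is `mean_reads_per_bin` modulated by a unimodal GC curve,
#' a low-rank multiplicative batch term shared across samples, and, in
#' malignant samples, the admixture-diluted copy-number multiplier of
#' [expected_multiplier()]. Microbial species counts come from
#' [simulate_microbiome()]. Weak samples are generated from a hidden truth
#' label (malignant with probability `malignant_fraction`); their recorded
#' suspected annotation is flipped with probability `weak_label_noise` so
#' pseudo-label purity is measurable against the truth.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list: `bins` (window tibble with GC and
#'   mappability), `bin_counts` (wide tibble, `sample_id` + one integer
#'   column per window), `species_counts` (tibble, `species` + one column
#'   per sample), `labels` (`sample_id`, `label`, `truth`, `suspected`),
#'   `truth_segments` (`sample_id`, `chrom`, `start_bin`, `end_bin`,
#'   `copy_number`, `tumor_fraction`), `latent_factors`, and the config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 1 || config$n_bins < 1) {
    abort_invalid("need at least one sample and one bin")
  }
  with_seed(config$seed, {
    n_total <- config$n_samples + config$n_weak
    n_mal <- as.integer(round(config$n_samples * config$malignant_fraction))

    bins <- define_bins(c(sim1 = config$n_bins * 1e6))
    bins$gc <- runif(config$n_bins, 0.3, 0.6)
    low_map <- runif(config$n_bins) < config$low_mappability_fraction
    bins$mappability <- ifelse(low_map, 0.5, 0.99)

    ids <- sprintf("S%03d", seq_len(n_total))
    label <- c(
      rep(c("malignant", "non_malignant"),
          c(n_mal, config$n_samples - n_mal)),
      rep("weak", config$n_weak)
    )
    truth <- label
    if (config$n_weak > 0) {
      weak_truth <- ifelse(runif(config$n_weak) < config$malignant_fraction,
                           "malignant", "non_malignant")
      truth[label == "weak"] <- weak_truth
    }
    suspected <- truth
    if (config$n_weak > 0 && config$weak_label_noise > 0) {
      flip <- label == "weak" & runif(n_total) < config$weak_label_noise
      suspected[flip] <- ifelse(truth[flip] == "malignant",
                                "non_malignant", "malignant")
    }
    suspected[label != "weak"] <- NA_character_

    # Copy-number multiplier matrix: 1 everywhere except planted segments in
    # (truly) malignant samples.
    mult <- matrix(1, n_total, config$n_bins)
    seg_list <- list()
    for (i in which(truth == "malignant")) {
      tf <- runif(1, config$tumor_fraction_range[1],
                  config$tumor_fraction_range[2])
      segs <- if (!is.null(config$fixed_segments)) {
        config$fixed_segments
      } else {
        len <- min(config$segment_length_bins, config$n_bins)
        tibble::tibble(
          start_bin = vapply(seq_len(config$n_cnv_segments), function(s) {
            sample.int(config$n_bins - len + 1, 1)
          }, integer(1)),
          end_bin = start_bin + len - 1,
          copy_number = sample(config$copy_numbers, config$n_cnv_segments,
                               replace = TRUE)
        )
      }
      for (s in seq_len(nrow(segs))) {
        start_bin <- segs$start_bin[s]
        end_bin <- min(segs$end_bin[s], config$n_bins)
        cn <- segs$copy_number[s]
        mult[i, start_bin:end_bin] <- expected_multiplier(cn, tf)
        seg_list[[length(seg_list) + 1]] <- tibble::tibble(
          sample_id = ids[i], chrom = "sim1",
          start_bin = start_bin, end_bin = end_bin,
          copy_number = cn, tumor_fraction = tf
        )
      }
    }
    truth_segments <- if (length(seg_list)) {
      dplyr::bind_rows(seg_list)
    } else {
      tibble::tibble(sample_id = character(), chrom = character(),
                     start_bin = integer(), end_bin = integer(),
                     copy_number = integer(), tumor_fraction = numeric())
    }

    gc_term <- exp(-config$gc_bias_strength * (bins$gc - 0.45)^2)
    latent <- matrix(0, n_total, max(config$n_latent_factors, 0))
    lf_term <- matrix(0, n_total, config$n_bins)
    if (config$n_latent_factors > 0) {
      latent <- matrix(rnorm(n_total * config$n_latent_factors,
                             sd = config$latent_factor_sd),
                       n_total, config$n_latent_factors)
      loadings <- matrix(rnorm(config$n_latent_factors * config$n_bins),
                         config$n_latent_factors, config$n_bins)
      lf_term <- latent %*% loadings
    }

    mu <- config$mean_reads_per_bin *
      sweep(mult * exp(lf_term), 2, gc_term, "*")
    counts <- matrix(
      rnb(length(mu), mu = as.vector(mu), size = config$nb_dispersion),
      n_total, config$n_bins
    )
    rownames(counts) <- ids
    colnames(counts) <- bin_ids(bins)

    species <- simulate_microbiome(config, truth = truth, sample_ids = ids)

    structure(
      list(
        bins = bins,
        bin_counts = feature_tibble(counts),
        species_counts = species,
        labels = tibble::tibble(sample_id = ids, label = label,
                                truth = truth, suspected = suspected),
        truth_segments = truth_segments,
        latent_factors = latent,
        config = config
      ),
      class = "synthetic_cohort"
    )
  })
}

#' Simulate a sparse overdispersed species-by-sample count matrix
#'
#' Each species gets a detection prevalence drawn uniformly from
#' `species_prevalence_range` and a lognormal mean abundance; present cells
#' are negative-binomial draws, absent cells exact zeros. The first
#' `n_affected_species` species are scaled by `microbe_effect_size` in
#' malignant samples, allowing power studies of label-associated microbial
#' signal; the default effect of 1 makes species counts independent of the
#' label.
#'
#' @param config A [sim_config()].
#' @param truth Optional character vector of per-sample data-generating
#'   labels (defaults to all non-malignant).
#' @param sample_ids Optional sample ids (defaults to `M001`...).
#' @return A tibble with a `species` column and one integer column per
#'   sample. Called standalone it seeds from `config$seed`.
#' @export
simulate_microbiome <- function(config, truth = NULL, sample_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  standalone <- is.null(truth) && is.null(sample_ids)
  run <- function() {
    n <- if (is.null(truth)) config$n_samples else length(truth)
    if (is.null(sample_ids)) sample_ids <- sprintf("M%03d", seq_len(n))
    if (is.null(truth)) truth <- rep("non_malignant", n)
    if (config$n_species == 0) {
      out <- tibble::tibble(species = character())
      for (id in sample_ids) out[[id]] <- integer()
      return(out)
    }
    prev <- runif(config$n_species, config$species_prevalence_range[1],
                  config$species_prevalence_range[2])
    base_mu <- exp(rnorm(config$n_species, mean = log(50), sd = 1.5))
    mal <- truth == "malignant"
    m <- matrix(0L, config$n_species, n)
    for (s in seq_len(config$n_species)) {
      present <- runif(n) < prev[s]
      mu_s <- rep(base_mu[s], n)
      if (s <= config$n_affected_species) {
        mu_s[mal] <- mu_s[mal] * config$microbe_effect_size
      }
      m[s, present] <- rnb(sum(present), mu = mu_s[present],
                           size = config$nb_dispersion)
    }
    rownames(m) <- sprintf("species_%03d", seq_len(config$n_species))
    colnames(m) <- sample_ids
    tibble::as_tibble(m, rownames = "species")
  }
  if (standalone) with_seed(config$seed, run()) else run()
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the cohort as diff-able TSV/JSON artifacts: `bin_counts.tsv`
#' (rows = samples), `species_counts.tsv` (rows = species), `labels.tsv`,
#' `bins.tsv`, `truth_segments.tsv` (BED-like, bp coordinates), and
#' `config.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$bin_counts, file.path(dir, "bin_counts.tsv"))
  readr::write_tsv(cohort$species_counts, file.path(dir, "species_counts.tsv"))
  readr::write_tsv(cohort$labels, file.path(dir, "labels.tsv"))
  readr::write_tsv(cohort$bins, file.path(dir, "bins.tsv"))
  segs <- dplyr::mutate(
    cohort$truth_segments,
    start = (.data$start_bin - 1) * 1e6,
    end = .data$end_bin * 1e6
  )
  readr::write_tsv(
    segs[, c("chrom", "start", "end", "sample_id", "copy_number",
             "tumor_fraction")],
    file.path(dir, "truth_segments.tsv")
  )
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
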