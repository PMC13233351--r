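# Species-level microbial feature construction from Kraken2-style reports:
# detection rule, prevalence filter, and diversity summaries.

#' Parse a Kraken2-style report into species-level read counts
#'
#' Reads the standard six-column report (percentage, clade reads, direct
#' reads, rank code, taxid, indented name) and keeps rows at rank `"S"`,
#' using the clade read count (which rolls up subspecies/strain rows) as
#' the species count.
#'
#' @param path Path to one report file.
#' @return A tibble with columns `species`, `taxid`, `count`.
#' @export
parse_species_report <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) {
      abort_schema(sprintf("malformed report line %d in %s: expected 6 fields, got %d",
                           i, path, length(f)))
    }
    clade_reads <- suppressWarnings(as.integer(f[2]))
    if (is.na(clade_reads)) {
      abort_schema(sprintf("malformed read count on line %d in %s", i, path))
    }
    if (f[4] == "S") {
      out[[i]] <- tibble::tibble(
        species = trimws(f[6]),
        taxid = trimws(f[5]),
        count = clade_reads
      )
    }
  }
  rows <- dplyr::bind_rows(out)
  if (nrow(rows) == 0) {
    tibble::tibble(species = character(), taxid = character(),
                   count = integer())
  } else {
    rows
  }
}

#' Read a directory of per-sample species reports into a count table
#'
#' @param paths Named character vector of report paths; names become sample
#'   ids (defaults to file names without extension).
#' @return A tibble with a `species` column and one count column per
#'   sample; species absent from a sample get 0.
#' @export
read_species_reports <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  long <- purrr::imap_dfr(paths, function(p, id) {
    dplyr::mutate(parse_species_report(p), sample_id = id)
  })
  if (nrow(long) == 0) abort_invalid("no species rows found in any report")
  wide <- tidyr::pivot_wider(long[, c("species", "sample_id", "count")],
                             names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  wide[order(wide$species), , drop = FALSE]
}

#' Species detection rule for shallow metagenomic counts
#'
#' A species counts as positively detected in a sample only when its read
#' count strictly exceeds `min_reads` (default 2), guarding against
#' background contamination, stochastic sampling and read misassignment at
#' very low counts.
#'
#' @param count Read count(s).
#' @param min_reads Strict detection threshold (default 2).
#' @return Logical vector: `TRUE` where `count > min_reads`.
#' @export
detect_positive <- function(count, min_reads = 2) {
  if (any(count < 0)) abort_invalid("counts must be non-negative")
  count > min_reads
}

#' Retain species detected in a minimum fraction of samples
#'
#' Species positively detected (per [detect_positive()]) in at least
#' `cutoff` of samples (inclusive) are retained; the feature values stay as
#' raw read counts. Rarely detected species mostly add sparsity and noise
#' at model time.
#'
#' @param table Species count tibble (`species` column + one count column
#'   per sample).
#' @param cutoff Prevalence cutoff in (0, 1] (default 0.10).
#' @param min_reads Detection threshold passed to [detect_positive()].
#' @return A `microbial_features` object: `counts` (wide sample-by-species
#'   tibble, `sample_id` first), `retained_species`, `prevalence_cutoff`,
#'   `detection_min_reads`.
#' @export
prevalence_filter <- function(table, cutoff = 0.10, min_reads = 2) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff <= 0 || cutoff > 1) {
    abort_invalid("`cutoff` must lie in (0, 1]")
  }
  if (!"species" %in% names(table)) {
    abort_schema("expected a `species` column")
  }
  sample_cols <- setdiff(names(table), c("species", "taxid"))
  if (length(sample_cols) < 1) abort_invalid("need at least one sample")
  m <- as.matrix(table[, sample_cols, drop = FALSE])
  rownames(m) <- table$species
  prev <- rowMeans(detect_positive(m, min_reads))
  keep <- prev >= cutoff
  kept <- m[keep, , drop = FALSE]
  structure(
    list(
      counts = feature_tibble(t(kept)),
      retained_species = rownames(kept),
      prevalence = prev[keep],
      prevalence_cutoff = cutoff,
      detection_min_reads = min_reads
    ),
    class = "microbial_features"
  )
}

#' Shannon diversity of a sample's species counts
#'
#' `H = -sum(p_i * log(p_i))` over species with positive counts, with
#' `p_i` the read-count proportions. Natural log by default, so values are
#' in nats.
#'
#' @param sample_counts Numeric vector of per-species read counts.
#' @param base Log base (default `exp(1)`).
#' @return The Shannon index.
#' @export
shannon_index <- function(sample_counts, base = exp(1)) {
  total <- sum(sample_counts)
  if (total <= 0) {
    abort_invalid("Shannon index undefined for an all-zero sample",
                  class = "cnvrisk_undefined_diversity")
  }
  p <- sample_counts[sample_counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Number of detected species in a sample
#'
#' @param sample_counts Numeric vector of per-species read counts.
#' @param min_reads Count a species only when its reads strictly exceed
#'   this (default 0, i.e. any nonzero count).
#' @return Integer species richness.
#' @export
species_richness <- function(sample_counts, min_reads = 0) {
  sum(sample_counts > min_reads)
}

#' Per-sample diversity summary table
#'
#' @param table Species count tibble (`species` + one column per sample).
#' @param base Log base for the Shannon index.
#' @return A tibble with `sample_id`, `shannon`, `richness`.
#' @export
diversity_summary <- function(table, base = exp(1)) {
  sample_cols <- setdiff(names(table), c("species", "taxid"))
  purrr::map_dfr(sample_cols, function(id) {
    x <- table[[id]]
    tibble::tibble(
      sample_id = id,
      shannon = if (sum(x) > 0) shannon_index(x, base = base) else NA_real_,
      richness = species_richness(x)
    )
  })
}
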