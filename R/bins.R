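#' Chromosome lengths of the GRCh37 (hs37d5) primary assembly
#'
#' Lengths in base pairs of chromosomes 1-22, X and Y of the human GRCh37
#' reference (identical in the hs37d5 build used for shallow host alignment).
#' Tiling these at 1 Mb yields the 3,113 genome-wide windows used for
#' copy-number feature extraction.
#'
#' @return A named numeric vector of 24 chromosome lengths.
#' @export
#' @examples
#' sum(ceiling(grch37_chrom_lengths() / 1e6))
grch37_chrom_lengths <- function() {
  c(
    `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566
  )
}

#' Tile chromosomes into fixed-size genomic windows
#'
#' Produces non-overlapping, BED-style (0-based, half-open) windows of
#' `bin_size` base pairs per chromosome; the last window of each chromosome
#' is truncated at the chromosome end. With the GRCh37 primary chromosomes
#' at the default 1 Mb this yields 3,113 windows.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param bin_size Window width in bp (default 1e6).
#' @param gc,mappability Optional per-bin annotation vectors recycled onto
#'   the result (fractions in \[0, 1\]); default `NA`.
#' @return A tibble with columns `chrom`, `start`, `end`, `gc`,
#'   `mappability`, sorted by (chrom, start) in the input chromosome order.
#' @export
#' @examples
#' nrow(define_bins(grch37_chrom_lengths()))
define_bins <- function(chrom_lengths, bin_size = 1e6, gc = NA_real_,
                        mappability = NA_real_) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || is.na(bin_size) ||
      bin_size <= 0) {
    abort_invalid("`bin_size` must be a positive number of base pairs")
  }
  if (length(chrom_lengths) == 0 || any(chrom_lengths <= 0)) {
    abort_invalid("chromosome lengths must be positive")
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort_invalid("`chrom_lengths` must be a named vector")
  }
  bins <- purrr::map2_dfr(
    names(chrom_lengths), unname(chrom_lengths),
    function(chrom, len) {
      n <- ceiling(len / bin_size)
      start <- (seq_len(n) - 1) * bin_size
      tibble::tibble(chrom = chrom, start = start,
                     end = pmin(start + bin_size, len))
    }
  )
  bins$gc <- rep_len(gc, nrow(bins))
  bins$mappability <- rep_len(mappability, nrow(bins))
  bins
}

#' Sample-level quality control for shallow host coverage
#'
#' A sample is usable for copy-number feature extraction only with at least
#' 5 Mb of host-derived sequence and an effective host-genome coverage of
#' at least 0.05-fold; both thresholds are inclusive.
#'
#' @param host_bases Host-derived bases sequenced (bp); vectorised.
#' @param effective_coverage Effective host-genome fold coverage; vectorised.
#' @param min_host_bases,min_coverage Inclusive thresholds (defaults 5e6 bp
#'   and 0.05x).
#' @return A tibble with columns `host_bases`, `effective_coverage`, `pass`
#'   and a `reasons` list-column naming the failed checks.
#' @export
qc_sample <- function(host_bases, effective_coverage,
                      min_host_bases = 5e6, min_coverage = 0.05) {
  if (any(host_bases < 0) || any(effective_coverage < 0)) {
    abort_invalid("QC inputs must be non-negative")
  }
  low_bases <- host_bases < min_host_bases
  low_cov <- effective_coverage < min_coverage
  tibble::tibble(
    host_bases = host_bases,
    effective_coverage = effective_coverage,
    pass = !low_bases & !low_cov,
    reasons = purrr::map2(low_bases, low_cov, function(b, cv) {
      c(if (b) "low_host_bases", if (cv) "low_coverage")
    })
  )
}

#' Count aligned reads per genomic window
#'
#' Assigns each usable alignment record to exactly one window by its
#' leftmost (0-based) coordinate under half-open window boundaries.
#' Secondary, supplementary, unmapped and duplicate records are skipped;
#' records on contigs absent from `bins` are tallied as unassigned.
#'
#' @param records A data frame of alignment records with columns `chrom`
#'   and `pos` (0-based leftmost position) and optional logical columns
#'   `unmapped`, `secondary`, `supplementary`, `duplicate`. See
#'   [read_alignments()] for building one from a SAM/BAM file.
#' @param bins A window tibble from [define_bins()], sorted by
#'   (chrom, start).
#' @return A list with `counts` (integer vector, one per window, named by
#'   window id) and `unassigned` (count of skipped-by-contig records).
#' @export
count_reads_in_bins <- function(records, bins) {
  if (is.unsorted(bins$start[bins$chrom == bins$chrom[1]]) ||
      any(unlist(tapply(bins$start, factor(bins$chrom, unique(bins$chrom)),
                        is.unsorted)))) {
    rlang::abort("`bins` must be sorted by (chrom, start)",
                 class = c("cnvrisk_invalid_state", "cnvrisk_error"))
  }
  counts <- integer(nrow(bins))
  names(counts) <- bin_ids(bins)
  unassigned <- 0L
  if (nrow(records) > 0) {
    keep <- rep(TRUE, nrow(records))
    for (flag in c("unmapped", "secondary", "supplementary", "duplicate")) {
      if (flag %in% names(records)) keep <- keep & !records[[flag]]
    }
    records <- records[keep, , drop = FALSE]
    for (chrom in unique(records$chrom)) {
      idx <- which(bins$chrom == chrom)
      pos <- records$pos[records$chrom == chrom]
      if (length(idx) == 0) {
        unassigned <- unassigned + length(pos)
        next
      }
      # findInterval on half-open starts; positions beyond the last bin end
      # fall off the chromosome and are unassigned.
      j <- findInterval(pos, bins$start[idx])
      off <- j == 0 | pos >= bins$end[idx][pmax(j, 1)]
      unassigned <- unassigned + sum(off)
      tab <- tabulate(j[!off], nbins = length(idx))
      counts[idx] <- counts[idx] + tab
    }
  }
  list(counts = counts, unassigned = unassigned)
}

#' Read alignment records from a SAM/BAM file
#'
#' Thin wrapper over Rsamtools producing the record tibble consumed by
#' [count_reads_in_bins()]. Positions are converted to 0-based.
#'
#' @param path Path to a SAM or BAM file.
#' @return A tibble with columns `chrom`, `pos` (0-based), `unmapped`,
#'   `secondary`, `supplementary`, `duplicate`.
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort_invalid("reading SAM/BAM requires the Rsamtools package")
  }
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "flag"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  tibble::tibble(
    chrom = as.character(x$rname),
    pos = x$pos - 1L,
    unmapped = bitwAnd(flag, 4L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L
  )
}
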