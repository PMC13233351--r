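# Internal helpers shared across modules.

abort_invalid <- function(msg, class = "cnvrisk_invalid_parameter", ...) {
  rlang::abort(msg, class = c(class, "cnvrisk_error"), ...)
}

abort_schema <- function(msg, ...) {
  abort_invalid(msg, class = "cnvrisk_schema_error", ...)
}

abort_leakage <- function(msg, ...) {
  abort_invalid(msg, class = "cnvrisk_leakage_error", ...)
}

#' Convert a sample-by-feature tibble to a numeric matrix
#'
#' Wide tibbles with a `sample_id` first column are the canonical tabular
#' form throughout the package; model fitting and linear algebra use the
#' matrix form produced here.
#'
#' @param tbl A tibble whose first column is `sample_id` and whose remaining
#'   columns are numeric features.
#' @return A numeric matrix with sample ids as row names.
#' @export
feature_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  if (!"sample_id" %in% names(tbl)) {
    abort_schema("expected a `sample_id` column in the feature table")
  }
  ids <- as.character(tbl$sample_id)
  if (anyDuplicated(ids)) {
    abort_schema(paste0(
      "duplicate sample ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  if (!is.numeric(m) && ncol(m) > 0) {
    abort_schema("feature columns must be numeric")
  }
  rownames(m) <- ids
  m
}

#' Convert a numeric matrix back to the canonical wide tibble
#'
#' @param m A numeric matrix with sample ids as row names.
#' @return A tibble with a `sample_id` first column.
#' @export
feature_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never clobber it.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort_invalid(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

check_count <- function(x, name, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) &&
    (x > 0 || (!positive && x >= 0))
  if (!ok) {
    abort_invalid(sprintf(
      "`%s` must be a %s integer", name, if (positive) "positive" else "non-negative"
    ))
  }
  invisible(as.integer(x))
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] > x[2]) {
    abort_invalid(sprintf("`%s` must be a (lo, hi) pair with lo <= hi", name))
  }
  invisible(x)
}

# Format bin ids as "chrom:start-end" (0-based half-open, BED-style).
bin_ids <- function(bins) {
  paste0(bins$chrom, ":", format(bins$start, scientific = FALSE, trim = TRUE),
         "-", format(bins$end, scientific = FALSE, trim = TRUE))
}

parse_bin_ids <- function(ids) {
  m <- stringr::str_match(ids, "^(.+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    abort_schema(paste0(
      "bin ids must look like 'chrom:start-end'; offending: ",
      paste(head(ids[is.na(m[, 1])], 3), collapse = ", ")
    ))
  }
  tibble::tibble(
    feature_id = ids,
    chrom = m[, 2],
    start = as.numeric(m[, 3]),
    end = as.numeric(m[, 4])
  )
}
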