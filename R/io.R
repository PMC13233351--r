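# Tabular I/O (TSV as the canonical dialect), the baseline flat-file
# bundle, and the end-to-end three-stage pipeline.

#' Read a count matrix TSV
#'
#' Tab-separated with a header row; the first column holds row ids
#' (samples or species). Values must be non-negative and ids unique;
#' violations raise schema errors naming the location.
#'
#' @param path Path to the TSV.
#' @param id_column Name to give the id column (default taken from the
#'   file header).
#' @param allow_negative Permit negative values (used for derived feature
#'   matrices such as Z scores; raw counts must be non-negative).
#' @return A wide tibble (id column first, numeric columns after).
#' @export
read_count_matrix <- function(path, id_column = NULL,
                              allow_negative = FALSE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) {
    abort_invalid(sprintf("%s contains no data rows", path),
                  class = "cnvrisk_invalid_input")
  }
  if (!is.null(id_column)) names(tbl)[1] <- id_column
  ids <- tbl[[1]]
  if (anyDuplicated(ids)) {
    abort_schema(sprintf("duplicate row id '%s' in %s",
                         ids[duplicated(ids)][1], path))
  }
  for (j in seq(2, length.out = ncol(tbl) - 1)) {
    v <- tbl[[j]]
    if (!is.numeric(v)) {
      abort_schema(sprintf("non-numeric column '%s' in %s", names(tbl)[j], path))
    }
    bad <- which(v < 0)
    if (length(bad) && !allow_negative) {
      abort_schema(sprintf("negative value at row '%s', column '%s' in %s",
                           ids[bad[1]], names(tbl)[j], path))
    }
  }
  tbl
}

#' Read a derived feature matrix TSV (negatives permitted)
#'
#' Same layout as [read_count_matrix()] but for derived features such as
#' Z scores, which may be negative.
#'
#' @inheritParams read_count_matrix
#' @return A wide tibble with a `sample_id` first column.
#' @export
read_feature_matrix <- function(path) {
  read_count_matrix(path, id_column = "sample_id", allow_negative = TRUE)
}

#' Write a count matrix TSV
#'
#' Integer matrices round-trip bit-exactly through
#' [read_count_matrix()].
#'
#' @param tbl Wide tibble (id column first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a sample label table
#'
#' @param path TSV with at least `sample_id` and `label` columns.
#' @return A tibble.
#' @export
read_labels <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(tbl))) {
    abort_schema(sprintf("%s must have `sample_id` and `label` columns", path))
  }
  tbl
}

#' Read chromosome lengths from a two-column TSV or FASTA index
#'
#' Accepts either a headerless two-column (name, length) TSV or a
#' `samtools faidx` `.fai` file (first two columns used).
#'
#' @param path Input path.
#' @return A named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tbl) < 2 || !is.numeric(tbl[[2]])) {
    abort_schema(sprintf("%s: expected columns (chrom, length)", path))
  }
  setNames(as.numeric(tbl[[2]]), as.character(tbl[[1]]))
}

#' Read a window annotation table
#'
#' @param path TSV with columns `chrom`, `start`, `end` and optionally
#'   `gc`, `mappability`.
#' @return A window tibble as produced by [define_bins()].
#' @export
read_bins <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tbl))) {
    abort_schema(sprintf("%s must have chrom/start/end columns", path))
  }
  if (!"gc" %in% names(tbl)) tbl$gc <- NA_real_
  if (!"mappability" %in% names(tbl)) tbl$mappability <- NA_real_
  tbl[, c("chrom", "start", "end", "gc", "mappability")]
}

#' Write the reference baseline as a flat-file bundle
#'
#' Emits `baseline.tsv` (window id, mu, sigma), `components.tsv` (window id
#' plus one column per retained component) and `meta.json` (k, sigma floor,
#' reference sample ids). [read_baseline()] round-trips the bundle.
#'
#' @param baseline A [build_reference_baseline()] object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_baseline <- function(baseline, dir) {
  stopifnot(inherits(baseline, "cnv_baseline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- baseline$bin_ids %||% as.character(seq_along(baseline$mu))
  readr::write_tsv(
    tibble::tibble(bin_id = ids, mu = baseline$mu, sigma = baseline$sigma),
    file.path(dir, "baseline.tsv")
  )
  comp <- tibble::as_tibble(baseline$components,
                            .name_repair = ~ paste0("PC", seq_along(.x)))
  comp <- dplyr::bind_cols(tibble::tibble(bin_id = ids), comp)
  readr::write_tsv(comp, file.path(dir, "components.tsv"))
  jsonlite::write_json(
    list(k = baseline$k, sigma_floor = baseline$sigma_floor,
         reference_sample_ids = baseline$reference_sample_ids),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a reference baseline bundle written by [write_baseline()]
#'
#' @param dir Bundle directory.
#' @return A `cnv_baseline` object.
#' @export
read_baseline <- function(dir) {
  ms <- readr::read_tsv(file.path(dir, "baseline.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  comp <- readr::read_tsv(file.path(dir, "components.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cm <- as.matrix(comp[, setdiff(names(comp), "bin_id"), drop = FALSE])
  structure(
    list(mu = ms$mu, sigma = ms$sigma,
         components = matrix(cm, nrow(ms), meta$k),
         k = meta$k, sigma_floor = meta$sigma_floor,
         reference_sample_ids = meta$reference_sample_ids,
         bin_ids = ms$bin_id),
    class = "cnv_baseline"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Settings for the end-to-end pipeline
#'
#' Defaults mirror the method's stated settings where one exists (1-Mb
#' windows, 25% availability, detection above 2 reads, 10% prevalence,
#' pseudo-label threshold 0.8, 5 CV folds, decision threshold 0.5) and
#' documented package choices otherwise.
#'
#' @param eval_fraction Fraction of the definitively labeled samples held
#'   out (stratified) as the independent evaluation set.
#' @param reference_size Non-malignant training samples used for the
#'   reference baseline (capped at availability).
#' @param k_components,min_sample_fraction,min_reads,mappability_min,loess_span,sigma_floor
#'   CNV-feature settings; see [cnv_feature_pipeline()].
#' @param prevalence_cutoff,detection_min_reads Microbial-feature settings.
#' @param methods Classifier methods to compare.
#' @param cv_folds Cross-validation folds for baseline development.
#' @param pseudo_threshold Confidence threshold for pseudo-positives.
#' @param decision_threshold Probability cut for confusion metrics.
#' @param n_boot Bootstrap replicates for CIs.
#' @param seed Master seed for partitioning, folds and fitting.
#' @return A `run_config` list.
#' @export
run_config <- function(eval_fraction = 0.25, reference_size = 200,
                       k_components = "auto", min_sample_fraction = 0.25,
                       min_reads = 1, mappability_min = 0.8,
                       loess_span = 0.3, sigma_floor = 1e-4,
                       prevalence_cutoff = 0.10, detection_min_reads = 2,
                       methods = c("xgb", "rf", "glm"), cv_folds = 5,
                       pseudo_threshold = 0.8, decision_threshold = 0.5,
                       n_boot = 500, seed = 1L) {
  check_proportion(eval_fraction, "eval_fraction")
  structure(
    list(eval_fraction = eval_fraction, reference_size = reference_size,
         k_components = k_components,
         min_sample_fraction = min_sample_fraction, min_reads = min_reads,
         mappability_min = mappability_min, loess_span = loess_span,
         sigma_floor = sigma_floor, prevalence_cutoff = prevalence_cutoff,
         detection_min_reads = detection_min_reads, methods = methods,
         cv_folds = cv_folds, pseudo_threshold = pseudo_threshold,
         decision_threshold = decision_threshold, n_boot = n_boot,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full three-stage analysis on a cohort
#'
#' Stage 1: derive CNV, microbial and combined features; split the
#' definitively labeled samples (stratified) into a training set and an
#' independent evaluation set; train every method on every feature type
#' with cross-validated tuning. Stage 2: score the weakly labeled samples
#' with the default baseline model (gradient-boosted trees on CNV
#' features), select high-confidence pseudo-positives once, and refit
#' every method/feature combination on the extended set with fixed
#' parameters. Stage 3: evaluate all baseline and extended models on the
#' held-out evaluation samples in a unified table; training/evaluation
#' overlap is a fatal error.
#'
#' @param cohort A [simulate_cohort()] result, or a list with the same
#'   elements (`bin_counts`, `species_counts`, `labels`, `bins`) built
#'   from files.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, features, the metrics
#'   table, the pseudo-label audit and a config snapshot are written there.
#' @return A list: `comparison` (the 18-row metrics tibble for the default
#'   three methods), `models`, `selection`, `audit`, `features`, `splits`,
#'   `config`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  labels <- cohort$labels
  strong <- labels[labels$label != "weak", ]
  weak <- labels[labels$label == "weak", ]

  splits <- with_seed(config$seed, {
    eval_ids <- unlist(lapply(split(strong$sample_id, strong$label),
                              function(ids) {
                                n <- max(1L, round(length(ids) * config$eval_fraction))
                                sample(ids, n)
                              }), use.names = FALSE)
    train_ids <- setdiff(strong$sample_id, eval_ids)
    ref_pool <- intersect(train_ids,
                          strong$sample_id[strong$label == "non_malignant"])
    list(train = train_ids, eval = eval_ids, weak = weak$sample_id,
         reference = head(ref_pool, config$reference_size))
  })

  # Stage 1a: features over the full cohort, baseline frozen on the
  # non-malignant training reference.
  cnv <- cnv_feature_pipeline(
    cohort$bin_counts, cohort$bins, reference_ids = splits$reference,
    k_components = config$k_components,
    min_sample_fraction = config$min_sample_fraction,
    min_reads = config$min_reads, mappability_min = config$mappability_min,
    loess_span = config$loess_span, sigma_floor = config$sigma_floor
  )
  micro <- prevalence_filter(cohort$species_counts,
                             cutoff = config$prevalence_cutoff,
                             min_reads = config$detection_min_reads)
  feats <- list(
    cnv = cnv$z,
    micro = micro$counts,
    combined = combine_features(cnv, micro)
  )
  take <- function(tbl, ids) tbl[match(ids, tbl$sample_id), , drop = FALSE]
  train_labels <- strong[strong$sample_id %in% splits$train,
                         c("sample_id", "label")]
  eval_labels <- strong[strong$sample_id %in% splits$eval,
                        c("sample_id", "label")]

  # Stage 1b: cross-validated baseline models.
  models <- list()
  for (method in config$methods) {
    for (ft in names(feats)) {
      spec <- model_spec(method, mode = "cv_tuned", seed = config$seed)
      models[[paste(method, ft, "baseline", sep = ".")]] <- list(
        model = train_cv(take(feats[[ft]], splits$train), train_labels,
                         spec, n_folds = config$cv_folds),
        feature = ft, strategy = "Set A"
      )
    }
  }

  # Stage 2: one pseudo-label selection by the default baseline model
  # (gradient-boosted trees on CNV features when available), shared by all
  # extended refits.
  scorer_key <- if ("xgb" %in% config$methods) "xgb.cnv.baseline"
                else paste(config$methods[1], "cnv.baseline", sep = ".")
  scorer <- models[[scorer_key]]$model
  weak_probs <- predict_proba(scorer, take(feats$cnv, splits$weak))
  selection <- select_pseudo_positives(weak_probs,
                                       threshold = config$pseudo_threshold)
  audit <- NULL
  for (method in config$methods) {
    for (ft in names(feats)) {
      spec <- model_spec(method, mode = "fixed", seed = config$seed)
      ext <- extend_and_retrain(take(feats[[ft]], splits$train), train_labels,
                                take(feats[[ft]], splits$weak), selection,
                                spec = spec)
      models[[paste(method, ft, "extended", sep = ".")]] <- list(
        model = ext$model, feature = ft, strategy = "Set A + pseudo"
      )
      audit <- ext$audit
    }
  }

  # Stage 3: unified evaluation on the held-out samples.
  eval_feats <- lapply(feats, take, ids = splits$eval)
  comparison <- compare_experiments(models, eval_feats, eval_labels,
                                    decision_threshold = config$decision_threshold,
                                    n_boot = config$n_boot,
                                    seed = config$seed)

  out <- list(comparison = comparison, models = models,
              selection = selection, audit = audit, features = feats,
              splits = splits, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(comparison, file.path(out_dir, "comparison.tsv"))
    for (ft in names(feats)) {
      write_count_matrix(feats[[ft]], file.path(out_dir, paste0(ft, "_features.tsv")))
    }
    jsonlite::write_json(
      list(threshold = audit$threshold, n_weak_scored = audit$n_weak_scored,
           n_selected = audit$n_selected, selected_ids = audit$selected_ids),
      file.path(out_dir, "pseudo_audit.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_baseline(cnv$baseline, file.path(out_dir, "baseline"))
  }
  out
}
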