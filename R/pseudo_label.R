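# Pseudo-label extension training: score weakly labeled samples with the
# baseline model, promote high-confidence predicted-malignant cases, and
# retrain with fixed parameters. Only positive pseudo-labels are ever
# assigned, and only one self-training round is performed.

#' Select high-confidence pseudo-positive samples
#'
#' Keeps exactly the samples whose predicted malignancy probability is
#' strictly greater than `threshold`; the boundary is excluded. Predicted
#' non-malignant samples are discarded, never added as negatives.
#'
#' @param probs Tibble from [predict_proba()] (`sample_id`, `probability`)
#'   or a named probability vector.
#' @param threshold Strict selection threshold in \[0, 1) (default 0.8).
#' @return A `pseudo_selection` object: `selected_ids`, `probabilities`
#'   (all scored samples), `threshold`, `assigned_label = "malignant"`.
#' @export
select_pseudo_positives <- function(probs, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold >= 1) {
    abort_invalid("`threshold` must lie in [0, 1)")
  }
  if (is.data.frame(probs)) {
    p <- setNames(probs$probability, probs$sample_id)
  } else {
    p <- probs
  }
  if (any(p < 0 | p > 1)) abort_invalid("probabilities must lie in [0, 1]")
  structure(
    list(
      selected_ids = names(p)[p > threshold],
      probabilities = p,
      threshold = threshold,
      assigned_label = "malignant"
    ),
    class = "pseudo_selection"
  )
}

#' Extend the training set with pseudo-positives and refit
#'
#' Builds the extended training set as the high-quality labeled set plus
#' the selected weak samples labeled malignant, and refits the model with
#' fixed hyperparameters (no repeated cross-validation). High-quality
#' labels are never modified.
#'
#' @param setA_features,setA_labels High-quality labeled training data.
#' @param weak_features Feature tibble covering the weak samples (at least
#'   the selected ids).
#' @param selection A [select_pseudo_positives()] result.
#' @param spec A [model_spec()]; refit via [refit_fixed()].
#' @return A list: `model` (the refitted `risk_model`) and `audit`
#'   (threshold, `n_weak_scored`, `n_selected`, selected ids, probability
#'   summary of the scored weak set).
#' @export
extend_and_retrain <- function(setA_features, setA_labels, weak_features,
                               selection, spec = model_spec(mode = "fixed")) {
  stopifnot(inherits(selection, "pseudo_selection"))
  xa <- feature_matrix(setA_features)
  xw <- feature_matrix(weak_features)
  overlap <- intersect(rownames(xa), rownames(xw))
  if (length(overlap)) {
    abort_invalid(paste0("sample(s) present in both Set A and the weak set: ",
                         paste(head(overlap, 5), collapse = ", ")),
                  class = "cnvrisk_invalid_input")
  }
  sel <- selection$selected_ids
  missing <- setdiff(sel, rownames(xw))
  if (length(missing)) {
    abort_invalid(paste0("selected id(s) absent from weak features: ",
                         paste(head(missing, 5), collapse = ", ")),
                  class = "cnvrisk_invalid_input")
  }
  ya <- align_labels(setA_labels, rownames(xa))
  common <- intersect(colnames(xa), colnames(xw))
  if (length(common) < ncol(xa)) {
    abort_invalid("weak features must cover all Set A feature columns",
                  class = "cnvrisk_invalid_input")
  }
  x_ext <- rbind(xa, xw[sel, colnames(xa), drop = FALSE])
  y_ext <- c(as.character(ya), rep(selection$assigned_label, length(sel)))
  names(y_ext) <- rownames(x_ext)
  model <- refit_fixed(feature_tibble(x_ext), y_ext, spec = spec)
  list(
    model = model,
    audit = list(
      threshold = selection$threshold,
      n_weak_scored = length(selection$probabilities),
      n_selected = length(sel),
      selected_ids = sel,
      probability_summary = summary(unname(selection$probabilities))
    )
  )
}

#' Sensitivity of extension training to the confidence threshold
#'
#' For each threshold: select pseudo-positives from the weak set with the
#' baseline model, retrain with fixed parameters, and evaluate on the
#' held-out evaluation set. The evaluation set must be disjoint from all
#' training data.
#'
#' @param baseline_model Baseline `risk_model` trained on the high-quality
#'   set.
#' @param setA_features,setA_labels The high-quality labeled training data.
#' @param weak_features Features of the weakly labeled samples.
#' @param eval_features,eval_labels Independent evaluation data.
#' @param thresholds Probability thresholds to compare (default
#'   `c(0.7, 0.8, 0.9)`).
#' @param spec [model_spec()] used for each refit.
#' @param decision_threshold Probability cut for confusion metrics.
#' @return A tibble with one metrics row per threshold (plus `n_selected`).
#' @export
threshold_sensitivity <- function(baseline_model, setA_features, setA_labels,
                                  weak_features, eval_features, eval_labels,
                                  thresholds = c(0.7, 0.8, 0.9),
                                  spec = model_spec(mode = "fixed"),
                                  decision_threshold = 0.5) {
  eval_ids <- eval_features$sample_id
  tainted <- intersect(eval_ids,
                       c(setA_features$sample_id, weak_features$sample_id))
  if (length(tainted)) {
    abort_leakage(paste0("evaluation sample(s) appear in training data: ",
                         paste(head(tainted, 5), collapse = ", ")))
  }
  weak_probs <- predict_proba(baseline_model, weak_features)
  purrr::map_dfr(thresholds, function(th) {
    sel <- select_pseudo_positives(weak_probs, threshold = th)
    ext <- extend_and_retrain(setA_features, setA_labels, weak_features,
                              sel, spec = spec)
    scores <- predict_proba(ext$model, eval_features,
                            decision_threshold = decision_threshold)
    res <- evaluate_predictions(eval_labels, scores,
                                decision_threshold = decision_threshold)
    dplyr::mutate(res, threshold = th, n_selected = ext$audit$n_selected,
                  .before = 1)
  })
}
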