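# Performance metrics with bootstrap confidence intervals, the unified
# model-comparison table, and mapping of top model features to genomic
# intervals.

#' Confusion-matrix metrics at a fixed decision threshold
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/N, Youden index = sensitivity + specificity - 1 (the identity
#' holds exactly for the emitted values).
#'
#' @param truth,predicted Character/factor vectors of
#'   `"malignant"`/`"non_malignant"` labels.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `youden`, `n_pos`, `n_neg`.
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  pos <- truth == "malignant"
  if (!any(pos) || all(pos)) {
    abort_invalid("both classes must be present in `truth`",
                  class = "cnvrisk_undefined_metric")
  }
  tp <- sum(pos & predicted == "malignant")
  fn <- sum(pos & predicted != "malignant")
  tn <- sum(!pos & predicted != "malignant")
  fp <- sum(!pos & predicted == "malignant")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    sensitivity = sens,
    specificity = spec,
    accuracy = (tp + tn) / length(truth),
    youden = sens + spec - 1,
    n_pos = sum(pos),
    n_neg = sum(!pos)
  )
}

#' Area under the ROC curve (tie-aware Mann-Whitney)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)`,
#' computed from midranks; invariant to strictly monotone transforms of
#' the scores.
#'
#' @param truth Labels (`"malignant"` positive) or a logical/0-1 vector.
#' @param scores Numeric scores, higher = more malignant.
#' @return The AUC in \[0, 1\]; constant scores give 0.5 with a warning.
#' @export
roc_auc <- function(truth, scores) {
  pos <- if (is.logical(truth) || is.numeric(truth)) as.logical(truth)
         else as.character(truth) == "malignant"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort_invalid("both classes must be present",
                  class = "cnvrisk_undefined_metric")
  }
  if (length(unique(scores)) == 1) {
    rlang::warn("constant scores: AUC is 0.5 by convention")
    return(0.5)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble of operating points (`threshold`, `fpr`, `tpr`),
#'   ordered from the most to the least stringent threshold.
#' @export
roc_points <- function(truth, scores) {
  pos <- as.character(truth) == "malignant"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  purrr::map_dfr(thr, function(t) {
    call <- scores >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(call & !pos) / sum(!pos),
      tpr = sum(call & pos) / sum(pos)
    )
  })
}

#' Stratified bootstrap confidence interval for a classification metric
#'
#' Resamples positives and negatives separately (so every resample keeps
#' both classes) and returns the percentile interval. Deterministic for a
#' fixed seed.
#'
#' @param truth True labels.
#' @param predicted_or_scores Predicted labels (for threshold metrics) or
#'   numeric scores (for `"auc"`).
#' @param metric One of `"sensitivity"`, `"specificity"`, `"accuracy"`,
#'   `"youden"`, `"auc"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return A named numeric vector `c(lo, hi)`.
#' @export
metric_ci <- function(truth, predicted_or_scores, metric, level = 0.95,
                      n_boot = 2000, seed = 1L) {
  truth <- as.character(truth)
  if (length(truth) < 10) {
    abort_invalid("need at least 10 samples for a bootstrap interval",
                  class = "cnvrisk_invalid_input")
  }
  pos_idx <- which(truth == "malignant")
  neg_idx <- which(truth != "malignant")
  stat <- function(idx) {
    t2 <- truth[idx]
    v2 <- predicted_or_scores[idx]
    if (metric == "auc") {
      suppressWarnings(roc_auc(t2, v2))
    } else {
      confusion_metrics(t2, v2)[[metric]]
    }
  }
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos_idx, replace = TRUE),
               sample(neg_idx, replace = TRUE))
      stat(idx)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- unname(quantile(vals, c(alpha, 1 - alpha), type = 7, na.rm = TRUE))
  c(lo = q[1], hi = q[2])
}

#' Evaluate scored predictions against true labels
#'
#' One-stop evaluation: confusion metrics at the decision threshold, AUC,
#' and stratified-bootstrap 95% intervals for sensitivity, specificity and
#' accuracy.
#'
#' @param truth Label table (`sample_id`, `label`) or vector aligned with
#'   `scores`.
#' @param scores Tibble from [predict_proba()] or a named probability
#'   vector.
#' @param decision_threshold Probability above which a sample is called
#'   malignant (default 0.5).
#' @param n_boot,ci_level,seed Bootstrap settings for [metric_ci()].
#' @return A one-row tibble with all metrics and CI bounds.
#' @export
evaluate_predictions <- function(truth, scores, decision_threshold = 0.5,
                                 n_boot = 2000, ci_level = 0.95, seed = 1L) {
  if (is.data.frame(scores)) {
    p <- setNames(scores$probability, scores$sample_id)
  } else {
    p <- scores
  }
  if (is.data.frame(truth)) {
    truth <- setNames(as.character(truth$label), truth$sample_id)
  }
  if (!is.null(names(truth)) && !is.null(names(p))) {
    missing <- setdiff(names(p), names(truth))
    if (length(missing)) {
      abort_invalid(paste0("no truth label for: ",
                           paste(head(missing, 5), collapse = ", ")),
                    class = "cnvrisk_invalid_input")
    }
    truth <- truth[names(p)]
  }
  predicted <- ifelse(p > decision_threshold, "malignant", "non_malignant")
  cm <- confusion_metrics(truth, predicted)
  auc <- suppressWarnings(roc_auc(truth, p))
  cis <- list(
    sensitivity = metric_ci(truth, predicted, "sensitivity",
                            level = ci_level, n_boot = n_boot, seed = seed),
    specificity = metric_ci(truth, predicted, "specificity",
                            level = ci_level, n_boot = n_boot, seed = seed),
    accuracy = metric_ci(truth, predicted, "accuracy",
                         level = ci_level, n_boot = n_boot, seed = seed)
  )
  dplyr::mutate(
    cm,
    auc = auc,
    ci_sensitivity_lo = cis$sensitivity["lo"],
    ci_sensitivity_hi = cis$sensitivity["hi"],
    ci_specificity_lo = cis$specificity["lo"],
    ci_specificity_hi = cis$specificity["hi"],
    ci_accuracy_lo = cis$accuracy["lo"],
    ci_accuracy_hi = cis$accuracy["hi"],
    threshold = decision_threshold
  )
}

#' Unified comparison of models on an independent evaluation set
#'
#' Produces one metrics row per registered model (method x feature type x
#' training strategy), evaluating every model on the same held-out samples.
#' Any overlap between a model's training ids and the evaluation ids is a
#' fatal leakage error.
#'
#' @param models A list of entries, each a list with elements `model` (a
#'   `risk_model`), `feature` (name into `eval_features_by_type`), and
#'   `strategy` (free-text label, e.g. `"Set A"` / `"Set A + pseudo"`).
#' @param eval_features_by_type Named list of wide evaluation feature
#'   tibbles, one per feature type.
#' @param eval_labels Label table for the evaluation samples.
#' @param decision_threshold,n_boot,ci_level,seed Passed to
#'   [evaluate_predictions()].
#' @return A long-format tibble: `method`, `feature`, `strategy`, all
#'   metrics and CI bounds.
#' @export
compare_experiments <- function(models, eval_features_by_type, eval_labels,
                                decision_threshold = 0.5, n_boot = 2000,
                                ci_level = 0.95, seed = 1L) {
  purrr::map_dfr(models, function(entry) {
    feats <- eval_features_by_type[[entry$feature]]
    if (is.null(feats)) {
      abort_invalid(sprintf("no evaluation features of type '%s'",
                            entry$feature),
                    class = "cnvrisk_invalid_input")
    }
    leaked <- intersect(entry$model$training_sample_ids, feats$sample_id)
    if (length(leaked)) {
      abort_leakage(paste0(
        "evaluation sample(s) were in the training data of a ",
        entry$model$method, "/", entry$feature, " model: ",
        paste(head(leaked, 5), collapse = ", ")
      ))
    }
    scores <- predict_proba(entry$model, feats,
                            decision_threshold = decision_threshold)
    res <- evaluate_predictions(eval_labels, scores,
                                decision_threshold = decision_threshold,
                                n_boot = n_boot, ci_level = ci_level,
                                seed = seed)
    dplyr::mutate(res,
                  method = entry$model$method,
                  feature = entry$feature,
                  strategy = entry$strategy,
                  .before = 1)
  })
}

#' Map the most important model features to genomic intervals
#'
#' Ranks features by the fitted model's native importance (tree gain,
#' impurity decrease, or absolute coefficient) and resolves window features
#' (`chrom:start-end` ids, optionally `cnv:`-prefixed) to coordinates;
#' microbial features are reported without coordinates.
#'
#' @param model A fitted `risk_model`.
#' @param top_k Number of top features to report (default 10).
#' @return A tibble: `feature_id`, `chrom`, `start`, `end`, `importance`.
#'   All-zero importances give an empty table with a warning.
#' @export
rank_feature_regions <- function(model, top_k = 10) {
  check_count(top_k, "top_k")
  imp <- tidy(model)
  if (nrow(imp) == 0 || all(imp$importance == 0)) {
    rlang::warn("no informative features: importance is zero everywhere")
    return(tibble::tibble(feature_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          importance = numeric()))
  }
  if (top_k > nrow(imp)) {
    rlang::warn(sprintf("top_k = %d exceeds the %d available features; truncating",
                        top_k, nrow(imp)))
    top_k <- nrow(imp)
  }
  top <- imp[seq_len(top_k), , drop = FALSE]
  bare <- sub("^cnv:", "", top$feature_id)
  parsed <- stringr::str_match(bare, "^(.+):(\\d+)-(\\d+)$")
  tibble::tibble(
    feature_id = top$feature_id,
    chrom = parsed[, 2],
    start = as.numeric(parsed[, 3]),
    end = as.numeric(parsed[, 4]),
    importance = top$importance
  )
}
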