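# Malignancy classifier harness: gradient-boosted trees (default engine),
# random forest and a logistic GLM behind one interface, with stratified
# five-fold CV for baseline development and deterministic fixed-parameter
# refits for extension training.

#' Describe a classifier to train
#'
#' @param method One of `"xgb"` (gradient-boosted trees, the default
#'   implementation), `"rf"` (random forest), `"glm"` (binomial logistic
#'   regression).
#' @param mode `"cv_tuned"` (grid search by mean out-of-fold AUROC) or
#'   `"fixed"` (deterministic refit with fixed hyperparameters).
#' @param hyperparameters Named list overriding the method defaults (fixed
#'   mode) or replacing the tuning grid (cv mode, as a data frame).
#' @param seed Integer seed governing folds and any stochastic fitting.
#' @return A `model_spec` list.
#' @export
model_spec <- function(method = c("xgb", "rf", "glm"),
                       mode = c("cv_tuned", "fixed"),
                       hyperparameters = list(), seed = 1L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  structure(
    list(method = method, mode = mode, hyperparameters = hyperparameters,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

# Fixed-refit hyperparameter defaults per method.
fixed_defaults <- function(method, p) {
  switch(method,
    xgb = list(nrounds = 100, max_depth = 6, eta = 0.3, gamma = 0,
               colsample_bytree = 1.0, min_child_weight = 1, subsample = 1.0),
    rf = list(ntree = 500, mtry = max(1L, as.integer(floor(sqrt(p))))),
    glm = list()
  )
}

# Small documented CV grids (cv_tuned mode).
default_grid <- function(method, p) {
  switch(method,
    xgb = expand.grid(nrounds = c(50, 100), max_depth = c(3, 6), eta = 0.3,
                      gamma = 0, colsample_bytree = 1.0, min_child_weight = 1,
                      subsample = 1.0),
    rf = {
      base <- max(1L, floor(sqrt(p)))
      data.frame(ntree = 500,
                 mtry = unique(pmin(p, pmax(1L, c(base %/% 2L, base, 2L * base)))))
    },
    glm = data.frame(dummy = 0)
  )
}

# Normalize labels to a factor with levels (non_malignant, malignant),
# aligned to the rows of the feature matrix.
align_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "label") %in% names(labels))) {
      abort_schema("label table needs `sample_id` and `label` columns")
    }
    missing <- setdiff(sample_ids, labels$sample_id)
    if (length(missing)) {
      abort_invalid(paste0("no label for sample(s): ",
                           paste(head(missing, 5), collapse = ", ")),
                    class = "cnvrisk_invalid_input")
    }
    labels <- labels$label[match(sample_ids, labels$sample_id)]
  }
  if (!is.null(names(labels))) labels <- labels[sample_ids]
  lv <- unique(as.character(labels))
  if (!all(lv %in% c("malignant", "non_malignant"))) {
    abort_invalid(paste0("labels must be 'malignant'/'non_malignant'; saw: ",
                         paste(setdiff(lv, c("malignant", "non_malignant")),
                               collapse = ", ")),
                  class = "cnvrisk_invalid_input")
  }
  factor(as.character(labels), levels = c("non_malignant", "malignant"))
}

fit_engine <- function(method, x, y01, hp, seed) {
  with_seed(seed, switch(method,
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, gamma = hp$gamma,
                    colsample_bytree = hp$colsample_bytree,
                    min_child_weight = hp$min_child_weight,
                    subsample = hp$subsample, nthread = 1,
                    seed = seed %% .Machine$integer.max),
      data = xgboost::xgb.DMatrix(x, label = y01, nthread = 1),
      nrounds = hp$nrounds, verbose = 0
    ),
    rf = randomForest::randomForest(
      x = x, y = factor(y01, levels = c(0, 1)),
      ntree = hp$ntree, mtry = min(hp$mtry, ncol(x))
    ),
    glm = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, x), y01,
                       family = stats::binomial())
      )
      beta <- coef(fit)
      if (anyNA(beta)) {
        rlang::warn(sprintf(
          "logistic fit is rank-deficient (%d aliased coefficients dropped); p >> n makes this GLM unstable",
          sum(is.na(beta))
        ))
        beta[is.na(beta)] <- 0
      }
      list(coefficients = beta)
    }
  ))
}

predict_engine <- function(method, fit, x) {
  switch(method,
    xgb = as.numeric(predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))),
    rf = as.numeric(predict(fit, x, type = "prob")[, "1"]),
    glm = {
      eta <- drop(cbind(1, x) %*% fit$coefficients)
      1 / (1 + exp(-eta))
    }
  )
}

# Seeded stratified fold assignment: per class, shuffle then deal round-robin.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Train a classifier with stratified cross-validated tuning
#'
#' Splits the samples into `n_folds` stratified folds, evaluates each grid
#' setting by mean out-of-fold AUROC, refits the winning setting on all
#' training data, and stores the per-fold AUROCs of the winner.
#'
#' @param features Wide feature tibble (`sample_id` + numeric columns).
#' @param labels Label table (`sample_id`, `label`) or vector;
#'   `"malignant"` is the positive class.
#' @param spec A [model_spec()].
#' @param n_folds Number of folds (default 5).
#' @return A `risk_model` object.
#' @export
train_cv <- function(features, labels, spec = model_spec(), n_folds = 5) {
  x <- feature_matrix(features)
  y <- align_labels(labels, rownames(x))
  if (nlevels(droplevels(y)) < 2) {
    abort_invalid("both classes must be present to train",
                  class = "cnvrisk_invalid_input")
  }
  if (min(table(y)) < n_folds) {
    abort_invalid(sprintf("need >= %d samples per class for %d folds",
                          n_folds, n_folds),
                  class = "cnvrisk_invalid_input")
  }
  y01 <- as.integer(y == "malignant")
  grid <- if (is.data.frame(spec$hyperparameters) &&
              nrow(spec$hyperparameters) > 0) {
    spec$hyperparameters
  } else {
    default_grid(spec$method, ncol(x))
  }
  folds <- stratified_folds(y, n_folds, spec$seed)
  cv <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    hp <- as.list(grid[g, , drop = FALSE])
    purrr::map_dfr(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- fit_engine(spec$method, x[tr, , drop = FALSE], y01[tr], hp,
                        seed = spec$seed + f)
      p <- predict_engine(spec$method, fit, x[!tr, , drop = FALSE])
      tibble::tibble(setting = g, fold = f,
                     auroc = suppressWarnings(roc_auc(y[!tr], p)))
    })
  })
  means <- tapply(cv$auroc, cv$setting, mean)
  best <- as.integer(names(means)[which.max(means)])
  hp <- as.list(grid[best, , drop = FALSE])
  fit <- fit_engine(spec$method, x, y01, hp, seed = spec$seed)
  structure(
    list(
      spec = spec,
      method = spec$method,
      mode = "cv_tuned",
      hyperparameters = hp,
      feature_ids = colnames(x),
      training_sample_ids = rownames(x),
      fit = fit,
      cv_summary = cv,
      cv_auroc = unname(means[as.character(best)]),
      n_folds = n_folds
    ),
    class = "risk_model"
  )
}

#' Refit a classifier with fixed hyperparameters
#'
#' Deterministic single fit used for extension training: gradient-boosted
#' trees with 100 rounds, depth 6, learning rate 0.3, gamma 0, all
#' subsampling disabled; random forest with 500 trees and
#' `mtry = floor(sqrt(p))`; or a plain binomial GLM.
#'
#' @inheritParams train_cv
#' @return A `risk_model` object (no CV summary).
#' @export
refit_fixed <- function(features, labels, spec = model_spec(mode = "fixed")) {
  x <- feature_matrix(features)
  if (ncol(x) == 0) {
    abort_invalid("no features to fit", class = "cnvrisk_invalid_input")
  }
  y <- align_labels(labels, rownames(x))
  y01 <- as.integer(y == "malignant")
  hp <- utils::modifyList(fixed_defaults(spec$method, ncol(x)),
                          as.list(spec$hyperparameters))
  fit <- fit_engine(spec$method, x, y01, hp, seed = spec$seed)
  structure(
    list(
      spec = spec,
      method = spec$method,
      mode = "fixed",
      hyperparameters = hp,
      feature_ids = colnames(x),
      training_sample_ids = rownames(x),
      fit = fit,
      cv_summary = NULL,
      cv_auroc = NA_real_,
      n_folds = NA_integer_
    ),
    class = "risk_model"
  )
}

#' Predict malignancy probabilities
#'
#' @param model A `risk_model`.
#' @param features Wide feature tibble whose columns cover the model's
#'   `feature_ids` (extra columns are ignored; order is fixed by the model).
#' @param decision_threshold Probability above which the predicted label is
#'   malignant (default 0.5).
#' @return A tibble with `sample_id`, `probability`, and `predicted`
#'   (malignant iff probability > 0.5).
#' @export
predict_proba <- function(model, features, decision_threshold = 0.5) {
  stopifnot(inherits(model, "risk_model"))
  x <- feature_matrix(features)
  missing <- setdiff(model$feature_ids, colnames(x))
  if (length(missing)) {
    abort_schema(paste0("feature column(s) missing from input: ",
                        paste(head(missing, 5), collapse = ", ")))
  }
  x <- x[, model$feature_ids, drop = FALSE]
  p <- predict_engine(model$method, model$fit, x)
  tibble::tibble(
    sample_id = rownames(x),
    probability = p,
    predicted = ifelse(p > decision_threshold, "malignant", "non_malignant")
  )
}

#' Concatenate CNV and microbial feature tables
#'
#' Namespaces the columns (`cnv:`, `micro:`) and joins on the shared sample
#' set, CNV columns first. No rescaling is applied: the tree-based engines
#' are scale-free and feature values keep their native units.
#'
#' @param cnv CNV Z-score features (a `cnv_features` object or wide tibble).
#' @param micro Microbial counts (a `microbial_features` object or wide
#'   tibble).
#' @return A wide tibble with namespaced feature columns.
#' @export
combine_features <- function(cnv, micro) {
  ctbl <- if (inherits(cnv, "cnv_features")) cnv$z else cnv
  mtbl <- if (inherits(micro, "microbial_features")) micro$counts else micro
  cm <- feature_matrix(ctbl)
  mm <- feature_matrix(mtbl)
  if (ncol(mm) == 0 || nrow(mm) == 0) {
    out <- cm
    colnames(out) <- paste0("cnv:", colnames(out))
    return(feature_tibble(out))
  }
  if (!setequal(rownames(cm), rownames(mm))) {
    off <- c(setdiff(rownames(cm), rownames(mm)),
             setdiff(rownames(mm), rownames(cm)))
    abort_invalid(paste0("sample sets differ between feature tables: ",
                         paste(head(off, 5), collapse = ", ")),
                  class = "cnvrisk_invalid_input")
  }
  mm <- mm[rownames(cm), , drop = FALSE]
  colnames(cm) <- paste0("cnv:", colnames(cm))
  colnames(mm) <- paste0("micro:", colnames(mm))
  feature_tibble(cbind(cm, mm))
}

#' Split a combined feature table back into its namespaces
#'
#' Inverse of [combine_features()].
#'
#' @param combined A wide tibble with `cnv:`/`micro:` prefixed columns.
#' @return A list with elements `cnv` and `micro` (wide tibbles, prefixes
#'   stripped).
#' @export
split_features <- function(combined) {
  m <- feature_matrix(combined)
  is_cnv <- startsWith(colnames(m), "cnv:")
  is_micro <- startsWith(colnames(m), "micro:")
  cnv <- m[, is_cnv, drop = FALSE]
  micro <- m[, is_micro, drop = FALSE]
  colnames(cnv) <- sub("^cnv:", "", colnames(cnv))
  colnames(micro) <- sub("^micro:", "", colnames(micro))
  list(cnv = feature_tibble(cnv), micro = feature_tibble(micro))
}

#' Feature importances of a fitted risk model
#'
#' Gain for gradient-boosted trees, mean decrease in Gini impurity for
#' random forests, absolute coefficient for the logistic GLM. Features the
#' model never used get importance 0.
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble with `feature_id` and `importance`, sorted decreasing.
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  imp <- setNames(numeric(length(x$feature_ids)), x$feature_ids)
  if (x$method == "xgb") {
    tab <- xgboost::xgb.importance(model = x$fit)
    imp[tab$Feature] <- tab$Gain
  } else if (x$method == "rf") {
    gi <- randomForest::importance(x$fit)[, "MeanDecreaseGini"]
    imp[names(gi)] <- gi
  } else {
    beta <- x$fit$coefficients
    beta <- beta[setdiff(names(beta), "(Intercept)")]
    imp[names(beta)] <- abs(beta)
  }
  out <- tibble::tibble(feature_id = names(imp), importance = unname(imp))
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' One-row model summary
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble with method, mode, feature and sample counts, and mean
#'   CV AUROC (NA for fixed refits).
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    mode = x$mode,
    n_features = length(x$feature_ids),
    n_samples = length(x$training_sample_ids),
    cv_auroc = x$cv_auroc
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (%s): %d features, %d training samples",
              x$method, x$mode, length(x$feature_ids),
              length(x$training_sample_ids)))
  if (!is.na(x$cv_auroc)) cat(sprintf(", mean CV AUROC %.3f", x$cv_auroc))
  cat("\n")
  invisible(x)
}
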