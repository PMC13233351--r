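test_that("cross-validated models separate a strong multivariate shift", {
  # 10 informative features at 1.5 sd each: jointly ~3 sd of separation,
  # so no single split is perfect but the ensemble should be near-perfect
  toy <- separable_features(n = 100, p = 20, k = 10, delta = 1.5, seed = 40)
  for (method in c("xgb", "rf")) {
    m <- train_cv(toy$features, toy$labels, model_spec(method, seed = 1))
    expect_gt(m$cv_auroc, 0.95)
    expect_equal(nrow(m$cv_summary) %% 5, 0) # 5 folds per grid setting
  }
})

test_that("permuted labels give chance-level cross-validation AUROC", {
  set.seed(41)
  n <- 200
  m <- matrix(rnorm(n * 15), n, 15,
              dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:15)))
  y <- sample(rep(c("malignant", "non_malignant"), each = n / 2))
  names(y) <- rownames(m)
  for (method in c("xgb", "rf", "glm")) {
    fit <- suppressWarnings(
      train_cv(feature_tibble(m), y, model_spec(method, seed = 2))
    )
    expect_gt(fit$cv_auroc, 0.4)
    expect_lt(fit$cv_auroc, 0.6)
  }
})

test_that("constant features degrade to chance without crashing", {
  m <- matrix(1, 30, 4, dimnames = list(sprintf("s%02d", 1:30), paste0("f", 1:4)))
  y <- rep(c("malignant", "non_malignant"), 15)
  names(y) <- rownames(m)
  fit <- suppressWarnings(train_cv(feature_tibble(m), y, model_spec("xgb")))
  expect_true(abs(fit$cv_auroc - 0.5) < 1e-9)
})

test_that("training contract errors are raised", {
  toy <- separable_features(n = 20, seed = 42)
  one_class <- setNames(rep("malignant", 20), names(toy$labels))
  expect_error(train_cv(toy$features, one_class),
               class = "cnvrisk_invalid_input")
  expect_error(refit_fixed(toy$features[, 1, drop = FALSE], toy$labels),
               class = "cnvrisk_invalid_input")
  bad <- setNames(rep(c("tumour", "normal"), 10), names(toy$labels))
  expect_error(train_cv(toy$features, bad), class = "cnvrisk_invalid_input")
})

test_that("fixed refits are deterministic for every method", {
  toy <- separable_features(n = 40, p = 8, delta = 1, seed = 43)
  for (method in c("xgb", "rf", "glm")) {
    f1 <- suppressWarnings(refit_fixed(toy$features, toy$labels,
                                       model_spec(method, mode = "fixed", seed = 9)))
    f2 <- suppressWarnings(refit_fixed(toy$features, toy$labels,
                                       model_spec(method, mode = "fixed", seed = 9)))
    expect_identical(predict_proba(f1, toy$features)$probability,
                     predict_proba(f2, toy$features)$probability)
  }
})

test_that("random forest default mtry is floor(sqrt(p))", {
  set.seed(44)
  p <- 2523
  m <- matrix(rnorm(40 * p), 40, p,
              dimnames = list(sprintf("s%02d", 1:40), paste0("f", seq_len(p))))
  y <- rep(c("malignant", "non_malignant"), 20)
  names(y) <- rownames(m)
  fit <- refit_fixed(feature_tibble(m), y, model_spec("rf", mode = "fixed"))
  expect_equal(fit$hyperparameters$mtry, 50)
  expect_equal(fit$hyperparameters$ntree, 500)
  # gradient-boosted defaults for extension training
  fx <- refit_fixed(feature_tibble(m[, 1:5]), y,
                    model_spec("xgb", mode = "fixed"))
  expect_equal(fx$hyperparameters[c("nrounds", "max_depth", "eta", "gamma")],
               list(nrounds = 100, max_depth = 6, eta = 0.3, gamma = 0))
})

test_that("logistic refit orients probabilities along the discriminant", {
  set.seed(45)
  n <- 80
  x1 <- rnorm(n)
  y <- ifelse(x1 + rnorm(n, sd = 0.3) > 0, "malignant", "non_malignant")
  m <- cbind(f1 = x1, f2 = rnorm(n))
  rownames(m) <- sprintf("s%02d", 1:n)
  names(y) <- rownames(m)
  fit <- suppressWarnings(refit_fixed(feature_tibble(m), y,
                                      model_spec("glm", mode = "fixed")))
  p <- predict_proba(fit, feature_tibble(m))$probability
  expect_gt(cor(p, x1, method = "spearman"), 0.9)
})

test_that("probability predictions respect their contracts", {
  toy <- separable_features(n = 40, p = 6, delta = 2, seed = 46)
  fit <- refit_fixed(toy$features, toy$labels, model_spec("xgb", mode = "fixed"))
  pp <- predict_proba(fit, toy$features)
  expect_true(all(pp$probability >= 0 & pp$probability <= 1))
  mal <- toy$labels[pp$sample_id] == "malignant"
  expect_gt(mean(pp$probability[mal]), mean(pp$probability[!mal]))
  expect_equal(pp$predicted, ifelse(pp$probability > 0.5, "malignant",
                                    "non_malignant"))
  # a duplicated row predicts identically
  m <- feature_matrix(toy$features)
  dup <- rbind(m, dup1 = m[1, ])
  rownames(dup)[nrow(dup)] <- "dup1"
  p2 <- predict_proba(fit, feature_tibble(dup))
  expect_equal(p2$probability[p2$sample_id == "dup1"],
               p2$probability[p2$sample_id == rownames(m)[1]])
  # missing feature columns are schema errors naming the column
  expect_error(predict_proba(fit, toy$features[, 1:3]), "f4",
               class = "cnvrisk_schema_error")
})

test_that("tree methods are invariant to monotone feature transforms", {
  toy <- separable_features(n = 40, p = 5, delta = 1.5, seed = 47)
  m <- feature_matrix(toy$features)
  warped <- feature_tibble(exp(m / 2) + 1)
  # gradient boosting splits on value order only: exact invariance
  f1 <- refit_fixed(toy$features, toy$labels,
                    model_spec("xgb", mode = "fixed", seed = 3))
  f2 <- refit_fixed(warped, toy$labels,
                    model_spec("xgb", mode = "fixed", seed = 3))
  expect_equal(predict_proba(f1, toy$features)$probability,
               predict_proba(f2, warped)$probability, tolerance = 1e-12)
  # the forest engine breaks exact gain ties on raw values, so invariance
  # is statistical: rankings and discrimination are preserved
  r1 <- refit_fixed(toy$features, toy$labels,
                    model_spec("rf", mode = "fixed", seed = 3))
  r2 <- refit_fixed(warped, toy$labels,
                    model_spec("rf", mode = "fixed", seed = 3))
  p1 <- predict_proba(r1, toy$features)$probability
  p2 <- predict_proba(r2, warped)$probability
  expect_gt(cor(p1, p2, method = "spearman"), 0.98)
  expect_lt(abs(roc_auc(toy$labels, p1) - roc_auc(toy$labels, p2)), 0.02)
})

test_that("feature combination namespaces columns and round-trips", {
  cnv <- feature_tibble(matrix(1:10, 5, 2,
                               dimnames = list(paste0("s", 1:5),
                                               c("sim1:0-10", "sim1:10-20"))))
  micro <- feature_tibble(matrix(11:25, 5, 3,
                                 dimnames = list(paste0("s", 1:5),
                                                 c("spA", "spB", "spC"))))
  comb <- combine_features(cnv, micro)
  expect_equal(names(comb),
               c("sample_id", "cnv:sim1:0-10", "cnv:sim1:10-20",
                 "micro:spA", "micro:spB", "micro:spC"))
  back <- split_features(comb)
  expect_equal(feature_matrix(back$cnv), feature_matrix(cnv))
  expect_equal(feature_matrix(back$micro), feature_matrix(micro))

  empty <- feature_tibble(matrix(numeric(0), 5, 0,
                                 dimnames = list(paste0("s", 1:5), NULL)))
  only_cnv <- combine_features(cnv, empty)
  expect_equal(unname(feature_matrix(only_cnv)), unname(feature_matrix(cnv)))

  mismatched <- feature_tibble(matrix(1:6, 3, 2,
                                      dimnames = list(paste0("x", 1:3),
                                                      c("spA", "spB"))))
  expect_error(combine_features(cnv, mismatched), "differ",
               class = "cnvrisk_invalid_input")
})

test_that("tidy and glance summarise fitted models", {
  toy <- separable_features(n = 40, p = 6, k = 2, delta = 3, seed = 48)
  fit <- train_cv(toy$features, toy$labels, model_spec("xgb", seed = 4))
  td <- tidy(fit)
  expect_setequal(td$feature_id, paste0("f", 1:6))
  # the two informative features dominate the importance ranking
  expect_true(all(td$feature_id[1:2] %in% c("f1", "f2")))
  gl <- glance(fit)
  expect_equal(gl$method, "xgb")
  expect_equal(gl$n_features, 6)
  expect_false(is.na(gl$cv_auroc))
})
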