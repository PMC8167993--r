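# Metric formulas, ROC/AUC, operating points, and the cross-validation
# drivers.

test_that("confusion metrics reproduce the closed-form cases", {
  perfect <- confusion_metrics(tp = 50, fn = 0, tn = 50, fp = 0)
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1))
  chance <- confusion_metrics(tp = 25, fn = 25, tn = 25, fp = 25)
  expect_equal(chance$ACC, 0.5)
  expect_equal(chance$MCC, 0)
  m <- confusion_metrics(tp = 90, fn = 10, tn = 80, fp = 20)
  expect_equal(m$ACC, 0.85)
  expect_equal(m$SN, 0.9)
  expect_equal(m$SP, 0.8)
  expect_equal(m$MCC, (90 * 80 - 20 * 10) /
                 sqrt(100 * 100 * 110 * 90), tolerance = 1e-12)
  expect_equal(m$MCC, 0.7035, tolerance = 1e-4)
  # degenerate margin: MCC defined as 0
  expect_equal(confusion_metrics(tp = 10, fn = 0, tn = 0, fp = 10)$MCC, 0)
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("AUC is 1 for perfect separation, 0.5 for constant scores, null-centered otherwise", {
  y <- c(rep(1L, 5), rep(-1L, 5))
  expect_equal(roc_auc(c(6:10, 1:5), y)$auc, 1)
  expect_equal(roc_auc(rep(3, 10), y)$auc, 0.5)
  set.seed(80)
  y_big <- sample(c(1L, -1L), 2000, replace = TRUE)
  s_big <- rnorm(2000)                      # independent of labels
  auc0 <- roc_auc(s_big, y_big)$auc
  expect_gt(auc0, 0.45)
  expect_lt(auc0, 0.55)
  expect_error(roc_auc(1:5, rep(1L, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(81)
  y <- balanced_labels(60)
  s <- rnorm(60) + 0.8 * y
  a1 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_auc(2 * s - 7, y)$auc, a1, tolerance = 1e-12)
})

test_that("midrank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  y <- balanced_labels(100)
  s <- rnorm(100) + 0.6 * y
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y),
                                        predictor = s, quiet = TRUE,
                                        direction = "<", levels = c("-1", "1"))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("sensitivity at fixed specificity matches a threshold-scan oracle", {
  sens_oracle <- function(s, y, target) {
    best <- -Inf
    for (t in c(Inf, sort(unique(s), decreasing = TRUE))) {
      sp <- sum(s < t & y == -1L) / sum(y == -1L)
      sn <- sum(s >= t & y == 1L) / sum(y == 1L)
      if (sp >= target && sn > best) best <- sn
    }
    best
  }
  y <- c(rep(1L, 5), rep(-1L, 5))
  expect_equal(sensitivity_at_specificity(c(6:10, 1:5), y, 0.5), 1)
  expect_equal(sensitivity_at_specificity(c(6:10, 1:5), y, 0.99), 1)
  # all-equal scores: only the all-negative point satisfies spec >= 0.5
  expect_equal(sensitivity_at_specificity(rep(2, 10), y, 0.5), 0)
  set.seed(83)
  for (i in 1:10) {
    y2 <- balanced_labels(40)
    s2 <- rnorm(40) + 0.7 * y2
    for (target in c(0.3, 0.5, 0.9)) {
      expect_equal(sensitivity_at_specificity(s2, y2, target),
                   sens_oracle(s2, y2, target))
    }
  }
  expect_error(sensitivity_at_specificity(1:4, c(1L, 1L, -1L, -1L), 1.5),
               "unreachable")
})

test_that("stratified folds balance classes and respect the seed", {
  y <- rep(c(1L, -1L), each = 20)
  f1 <- stratified_folds(y, 5, seed = 9)
  f2 <- stratified_folds(y, 5, seed = 9)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_equal(sum(f1 == k & y == 1L), 4L)
    expect_equal(sum(f1 == k & y == -1L), 4L)
  }
  expect_error(stratified_folds(y, 25, seed = 1), "class")
})

test_that("pooled report metrics equal a brute-force recount of the decisions", {
  d <- make_fixture_dataset(12, 12, c(60, 90), 0.8, seed = 31)
  rep5 <- kfold_cv(d, dbp_config(), k = 4, seed = 2)
  dec <- rep5$decisions
  tp <- sum(dec$pred == 1 & dec$label == 1)
  fn <- sum(dec$pred == -1 & dec$label == 1)
  tn <- sum(dec$pred == -1 & dec$label == -1)
  fp <- sum(dec$pred == 1 & dec$label == -1)
  expect_equal(rep5$counts, list(tp = tp, fn = fn, tn = tn, fp = fp))
  expect_equal(rep5$metrics[, c("ACC", "SN", "SP", "MCC")],
               confusion_metrics(tp, fn, tn, fp))
  expect_equal(nrow(dec), 24L)
  expect_setequal(dec$id, d$records$id)
})

test_that("LOOCV recovers strong signal and finds none in null data", {
  strong <- make_fixture_dataset(20, 20, c(60, 80), 1.0, seed = 5)
  rep_strong <- loocv(strong, dbp_config())
  expect_gte(rep_strong$metrics$ACC, 0.9)
  null <- make_fixture_dataset(20, 20, c(60, 80), 0.0, seed = 5)
  # LOOCV on balanced null data is anti-learning-biased: the held-out
  # sample's class is always the training minority, so a no-signal
  # classifier votes with the majority and lands BELOW chance. The upper
  # bound is the meaningful "no spurious signal" check here; the
  # two-sided near-chance band is asserted on balanced 5-fold splits.
  rep_null <- loocv(null, dbp_config())
  expect_lte(rep_null$metrics$ACC, 0.8)
  rep_null5 <- kfold_cv(null, dbp_config(), k = 5)
  expect_gte(rep_null5$metrics$ACC, 0.2)
  expect_lte(rep_null5$metrics$ACC, 0.8)
})

test_that("k-fold with k = N has the leave-one-out fold structure", {
  d <- make_fixture_dataset(6, 6, c(60, 70), 0.9, seed = 6)
  cfg <- dbp_config()
  rep_loo <- loocv(d, cfg)
  rep_kn <- kfold_cv(d, cfg, k = nrow(d$records))
  expect_equal(sort(unique(rep_kn$decisions$fold)), 1:12)
  expect_equal(table(rep_kn$decisions$fold), table(rep_loo$decisions$fold))
  expect_equal(dplyr::arrange(rep_kn$decisions, id),
               dplyr::arrange(rep_loo$decisions, id))
})

test_that("independent test keeps train/test separation and rejects overlap", {
  train <- make_fixture_dataset(15, 15, c(60, 90), 1.0, seed = 11)
  test <- make_fixture_dataset(10, 10, c(60, 90), 1.0, seed = 12)
  test$records$id <- sub("fx", "te", test$records$id)
  names(test$profiles) <- test$records$id
  rep_it <- independent_test(train, test, dbp_config())
  expect_gte(rep_it$metrics$ACC, 0.9)
  expect_equal(nrow(rep_it$decisions), 20L)
  # resubstitution via the override equals direct training-set metrics
  rep_self <- independent_test(train, train, dbp_config(),
                               allow_overlap = TRUE)
  model <- dbp_train(train, dbp_config())
  pr <- dbp_predict(model, train)
  expect_equal(rep_self$metrics$ACC, mean(pr$pred == train$records$label))
  expect_error(independent_test(train, train, dbp_config()), "overlap")
  empty <- train
  empty$records <- empty$records[0, ]
  expect_error(independent_test(train, empty, dbp_config()), "empty")
})

test_that("per-fold kernel weights ignore held-out samples entirely", {
  d <- make_fixture_dataset(10, 10, c(60, 80), 0.8, seed = 21)
  cfg <- dbp_config()
  feats <- extract_features(d, cfg)
  y <- d$records$label
  fold_id <- stratified_folds(y, 4, seed = cfg$seed)
  base <- kfold_cv(d, cfg, k = 4, features = feats)
  # corrupt the features of every sample in fold 1 and rerun
  perturbed <- lapply(feats, function(X) {
    X[fold_id == 1L, ] <- X[fold_id == 1L, ] + 1000
    X
  })
  pert <- kfold_cv(d, cfg, k = 4, features = perturbed)
  expect_equal(base$fold_weights[["1"]], pert$fold_weights[["1"]],
               tolerance = 1e-10)
})

test_that("evaluation reports expose tidy/glance/autoplot interfaces", {
  d <- make_fixture_dataset(8, 8, c(60, 70), 0.9, seed = 41)
  rep4 <- kfold_cv(d, dbp_config(), k = 4)
  td <- tidy(rep4)
  expect_setequal(td$metric, c("ACC", "SN", "SP", "MCC", "AUC"))
  gl <- glance(rep4)
  expect_equal(gl$n, 16L)
  p <- autoplot(rep4)
  expect_s3_class(p, "ggplot")
})
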