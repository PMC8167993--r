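# Metrics and cross-validation drivers.

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity, specificity and Matthews correlation
#' coefficient from the four confusion counts. When the MCC denominator
#' is zero (a degenerate margin) MCC is reported as 0.
#'
#' @param tp,fn,tn,fp nonnegative integer counts.
#' @return One-row tibble with `ACC`, `SN`, `SP`, `MCC`.
#' @export
#' @examples
#' confusion_metrics(tp = 90, fn = 10, tn = 80, fp = 20)
confusion_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total <= 0) stop("empty confusion matrix")
  denom <- sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tp + fp)) * sqrt((tn + fn))
  tibble::tibble(
    ACC = (tp + tn) / total,
    SN = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    SP = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    MCC = if (denom == 0) 0 else (tp * tn - fp * fn) / denom)
}

count_confusion <- function(pred, label) {
  list(tp = sum(pred == 1L & label == 1L),
       fn = sum(pred == -1L & label == 1L),
       tn = sum(pred == -1L & label == -1L),
       fp = sum(pred == 1L & label == -1L))
}

#' ROC curve and AUC
#'
#' AUC by the rank (Wilcoxon--Mann--Whitney) statistic with midranks for
#' tied scores, which equals the trapezoidal area under the empirical ROC
#' curve. ROC points are returned for plotting.
#'
#' @param scores real-valued decision scores (larger = more positive).
#' @param labels labels in \{+1, -1\}; both classes required.
#' @return List with `auc` and a tibble `roc` (`threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  check_labels(labels, length(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for ROC")
  r <- rank(scores)                            # midranks for ties
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                 numeric(1)),
    fpr = vapply(thr, function(t) sum(scores >= t & labels == -1L) / n_neg,
                 numeric(1)))
  list(auc = auc, roc = roc)
}

#' Sensitivity at a fixed specificity
#'
#' Scans every achievable operating point (predict positive when the
#' score is at or above a threshold, including the all-negative point)
#' and returns the highest sensitivity among points whose specificity is
#' at least `spec_target` -- a conservative convention: the constraint is
#' met, never merely approached.
#'
#' @inheritParams roc_auc
#' @param spec_target required specificity (default 0.5).
#' @return Scalar sensitivity.
#' @export
sensitivity_at_specificity <- function(scores, labels, spec_target = 0.5) {
  check_labels(labels, length(scores))
  if (spec_target > 1) stop("specificity target above 1 is unreachable")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- -Inf
  for (t in thr) {
    sp <- sum(scores < t & labels == -1L) / n_neg
    if (sp >= spec_target) {
      sn <- sum(scores >= t & labels == 1L) / n_pos
      if (sn > best) best <- sn
    }
  }
  if (!is.finite(best)) stop("specificity target unreachable")
  best
}

#' Stratified fold assignment
#'
#' @param y labels in \{+1, -1\}.
#' @param k fold count; must not exceed either class size.
#' @param seed assignment seed.
#' @return Integer fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  check_labels(y)
  if (k > min(sum(y == 1L), sum(y == -1L))) {
    stop("fold count exceeds the size of a class")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  fold_id <- integer(length(y))
  for (cls in c(1L, -1L)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold_id
}

# One cross-validation pass: per fold, fit scalers on the training rows,
# build kernels, estimate weights on training kernels only, train the SVM
# and score the held-out rows. `features` may be supplied precomputed
# (encoders are per-record, so this is leakage-free).
run_cv_folds <- function(dataset, config, fold_id, features = NULL) {
  y <- dataset$records$label
  if (anyNA(y)) stop("all records need labels for cross-validation")
  check_labels(y)
  if (is.null(features)) features <- extract_features(dataset, config)
  gammas <- config$gammas
  decisions <- vector("list", length(unique(fold_id)))
  fold_weights <- list()
  global_beta <- NULL
  if (isTRUE(config$global_weights)) {
    scaled_all <- lapply(features, function(X) apply_scaler(fit_scaler(X), X))
    k_all <- build_kernel_set(scaled_all, gammas,
                              kernel_fun = config$kernel_fun)
    global_beta <- kernel_weights(k_all, y, config)
  }
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    scalers <- lapply(features, function(X) fit_scaler(X[tr, , drop = FALSE]))
    tr_sc <- lapply(names(features), function(nm) {
      apply_scaler(scalers[[nm]], features[[nm]][tr, , drop = FALSE])
    })
    te_sc <- lapply(names(features), function(nm) {
      apply_scaler(scalers[[nm]], features[[nm]][!tr, , drop = FALSE])
    })
    names(tr_sc) <- names(te_sc) <- names(features)
    k_train <- build_kernel_set(tr_sc, gammas, kernel_fun = config$kernel_fun)
    k_test <- build_kernel_set(te_sc, gammas, features_cols = tr_sc,
                               kernel_fun = config$kernel_fun)
    beta <- global_beta %||% kernel_weights(k_train, y[tr], config)
    fold_weights[[as.character(f)]] <- beta
    model <- train_svm(combine_kernels(k_train, beta), y[tr], C = config$C)
    pr <- predict(model, combine_kernels(k_test, beta))
    pr$label <- y[!tr]
    pr$fold <- f
    decisions[[f]] <- pr
  }
  list(decisions = dplyr::bind_rows(decisions), fold_weights = fold_weights)
}

make_eval_report <- function(decisions, name, seed, config,
                             fold_weights = NULL) {
  cc <- count_confusion(decisions$pred, decisions$label)
  roc <- roc_auc(decisions$decision, decisions$label)
  metrics <- confusion_metrics(cc$tp, cc$fn, cc$tn, cc$fp)
  metrics$AUC <- roc$auc
  structure(list(metrics = metrics, counts = cc, decisions = decisions,
                 roc = roc$roc, fold_weights = fold_weights,
                 name = name, seed = seed, strategy = config$strategy),
            class = "dbp_eval")
}

#' @export
print.dbp_eval <- function(x, ...) {
  cat("<dbp_eval> ", x$name, " (strategy: ", x$strategy, ")\n", sep = "")
  print(as.data.frame(round(x$metrics, 4)), row.names = FALSE)
  invisible(x)
}

#' k-fold cross-validation of the full pipeline
#'
#' Stratified folds; within each fold, feature scaling, kernel-weight
#' estimation and SVM training see only the training portion. Held-out
#' decisions from all folds are pooled into a single confusion matrix and
#' ROC curve.
#'
#' @param dataset labelled `dbp_dataset`.
#' @param config a [dbp_config()].
#' @param k fold count (default 5).
#' @param seed fold-assignment seed (defaults to the config seed).
#' @param features optional precomputed feature list (mainly for
#'   instrumentation and repeated runs).
#' @return A `dbp_eval` report.
#' @export
kfold_cv <- function(dataset, config = dbp_config(), k = 5L,
                     seed = config$seed, features = NULL) {
  y <- dataset$records$label
  # k = N is leave-one-out: every sample is its own fold
  fold_id <- if (k == length(y)) seq_along(y) else
    stratified_folds(y, k, seed)
  run <- run_cv_folds(dataset, config, fold_id, features)
  make_eval_report(run$decisions, paste0(dataset$name, " ", k, "-fold CV"),
                   seed, config, run$fold_weights)
}

#' Leave-one-out cross-validation
#'
#' The k = N limit of [kfold_cv()]: every sample is held out once and the
#' N held-out decisions form one pooled report.
#'
#' @inheritParams kfold_cv
#' @return A `dbp_eval` report.
#' @export
loocv <- function(dataset, config = dbp_config(), features = NULL) {
  n <- nrow(dataset$records)
  run <- run_cv_folds(dataset, config, seq_len(n), features)
  make_eval_report(run$decisions, paste0(dataset$name, " LOOCV"),
                   config$seed, config, run$fold_weights)
}

#' Train on one dataset, evaluate on another
#'
#' All scalers and kernel weights are fitted on the training set only.
#'
#' @param train_dataset,test_dataset labelled `dbp_dataset`s with
#'   disjoint ids.
#' @param config a [dbp_config()].
#' @param allow_overlap permit overlapping ids (e.g. deliberate
#'   resubstitution checks).
#' @return A `dbp_eval` report.
#' @export
independent_test <- function(train_dataset, test_dataset,
                             config = dbp_config(), allow_overlap = FALSE) {
  if (nrow(test_dataset$records) == 0L) stop("empty test set")
  overlap <- intersect(train_dataset$records$id, test_dataset$records$id)
  if (length(overlap) > 0L && !allow_overlap) {
    stop("train/test ids overlap: ", paste(head(overlap, 5), collapse = ", "))
  }
  model <- dbp_train(train_dataset, config)
  pr <- dbp_predict(model, test_dataset)
  pr$label <- test_dataset$records$label
  pr$fold <- 1L
  make_eval_report(pr, paste0(train_dataset$name, " -> ",
                              test_dataset$name),
                   config$seed, config,
                   list(train = model$beta))
}
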