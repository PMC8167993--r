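#' Run configuration
#'
#' Bundles every tunable of the pipeline with the tuned defaults: feature
#' parameters (`lg_max` 30, `lag_max` 10, `n_blocks` 20, db4 wavelet at 4
#' levels), the per-kernel RBF bandwidths, the weight-smoothing strength
#' `lambda` = 0.8, the SVM cost `C` = 2 and the weighting strategy.
#'
#' @param lg_max NMBAC maximum lag.
#' @param lag_max PsePSSM maximum lag.
#' @param n_blocks PSSM-AB block count.
#' @param wavelet,levels PSSM-DWT wavelet name and depth.
#' @param gammas named per-feature RBF bandwidths.
#' @param lambda Laplacian smoothing strength (>= 0).
#' @param C SVM box constraint.
#' @param strategy `"cka"`, `"mean"` or `"single:<feature>"`.
#' @param kernel_fun kernel family (`"rbf"`, `"linear"`, `"polynomial"`,
#'   `"sigmoid"`).
#' @param sequence_only use only the three profile-free descriptors.
#' @param centered_w compute the smoothing similarity from centered
#'   kernels.
#' @param global_weights estimate kernel weights once on the full dataset
#'   instead of per fold (reproduces the non-nested reading of the
#'   protocol; the default per-fold estimation is leakage-free).
#' @param seed default seed for fold assignment.
#' @return List of class `dbp_config`.
#' @export
dbp_config <- function(lg_max = 30L, lag_max = 10L, n_blocks = 20L,
                       wavelet = "db4", levels = 4L,
                       gammas = default_gammas(), lambda = 0.8, C = 2,
                       strategy = "cka", kernel_fun = "rbf",
                       sequence_only = FALSE, centered_w = FALSE,
                       global_weights = FALSE, seed = 1L) {
  stopifnot(lg_max >= 1L, lag_max >= 1L, n_blocks >= 1L, levels >= 1L,
            lambda >= 0, C > 0, all(gammas > 0))
  ok <- strategy %in% c("cka", "mean") || startsWith(strategy, "single:")
  if (!ok) stop("invalid strategy '", strategy, "'")
  structure(list(lg_max = lg_max, lag_max = lag_max, n_blocks = n_blocks,
                 wavelet = wavelet, levels = levels, gammas = gammas,
                 lambda = lambda, C = C, strategy = strategy,
                 kernel_fun = kernel_fun, sequence_only = sequence_only,
                 centered_w = centered_w, global_weights = global_weights,
                 seed = as.integer(seed)),
            class = "dbp_config")
}

#' Train the full multiple-kernel predictor
#'
#' Extracts the configured features, min-max-scales them, builds the
#' kernel set, estimates kernel weights by the configured strategy,
#' combines the kernels and trains the precomputed-kernel SVM. The
#' returned model carries everything prediction needs (scalers, scaled
#' training features, weights, SVM coefficients).
#'
#' @param dataset labelled `dbp_dataset`.
#' @param config a [dbp_config()].
#' @return Object of class `dbp_model`.
#' @export
dbp_train <- function(dataset, config = dbp_config()) {
  y <- dataset$records$label
  if (anyNA(y)) stop("all training records need labels")
  features <- extract_features(dataset, config)
  scalers <- lapply(features, fit_scaler)
  scaled <- lapply(names(features), function(nm) {
    apply_scaler(scalers[[nm]], features[[nm]])
  })
  names(scaled) <- names(features)
  kernels <- build_kernel_set(scaled, config$gammas,
                              kernel_fun = config$kernel_fun)
  beta <- kernel_weights(kernels, y, config)
  svm <- train_svm(combine_kernels(kernels, beta), y, C = config$C)
  structure(list(svm = svm, beta = beta, scalers = scalers,
                 train_features = scaled, train_ids = dataset$records$id,
                 config = config),
            class = "dbp_model")
}

#' @export
print.dbp_model <- function(x, ...) {
  cat("<dbp_model> trained on", length(x$train_ids), "samples; strategy",
      x$config$strategy, "\n  kernel weights:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Score new records with a trained model
#'
#' Features for the new records are scaled with the training scalers,
#' rectangular test-by-train kernels are built and combined with the
#' trained weights, and the SVM decision function is applied.
#'
#' @param model a `dbp_model`.
#' @param dataset `dbp_dataset` of records to score (labels ignored).
#' @return Tibble with `id`, `decision` and `pred` (+1 = DNA-binding).
#' @export
dbp_predict <- function(model, dataset) {
  config <- model$config
  features <- extract_features(dataset, config)
  scaled <- lapply(names(features), function(nm) {
    apply_scaler(model$scalers[[nm]], features[[nm]])
  })
  names(scaled) <- names(features)
  k_test <- build_kernel_set(scaled, config$gammas,
                             features_cols = model$train_features,
                             kernel_fun = config$kernel_fun)
  predict(model$svm, combine_kernels(k_test, model$beta))
}

#' Serialize / restore a trained model
#'
#' The model is written as a single JSON archive (coefficients, bias,
#' weights, scaler parameters, scaled training features and config), so
#' prediction needs only the archive plus the new FASTA/PSSM inputs.
#'
#' @param model a `dbp_model`.
#' @param path output file.
#' @return `path` (writer) or the restored model (reader).
#' @export
save_model <- function(model, path) {
  cfg <- unclass(model$config)
  cfg$gammas <- as.list(cfg$gammas)   # keep names through JSON
  payload <- list(
    alpha_y = model$svm$alpha_y, b = model$svm$b, C = model$svm$C,
    support = model$svm$support, y = model$svm$y,
    train_ids = model$train_ids, beta = as.list(model$beta),
    scalers = lapply(model$scalers, function(s) s[c("min", "range", "d")]),
    train_features = lapply(model$train_features, function(m) {
      list(ids = rownames(m), values = unname(m))
    }),
    config = cfg)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- p$config
  config <- dbp_config(lg_max = cfg$lg_max, lag_max = cfg$lag_max,
                       n_blocks = cfg$n_blocks, wavelet = cfg$wavelet,
                       levels = cfg$levels, gammas = unlist(cfg$gammas),
                       lambda = cfg$lambda, C = cfg$C,
                       strategy = cfg$strategy, kernel_fun = cfg$kernel_fun,
                       sequence_only = cfg$sequence_only,
                       centered_w = cfg$centered_w,
                       global_weights = cfg$global_weights, seed = cfg$seed)
  scalers <- lapply(p$scalers, function(s) {
    structure(list(min = s$min, range = s$range, d = s$d),
              class = "dbp_scaler")
  })
  feats <- lapply(p$train_features, function(f) {
    m <- as.matrix(f$values)
    rownames(m) <- f$ids
    m
  })
  svm <- structure(list(alpha_y = p$alpha_y, b = p$b, C = p$C,
                        support = p$support, train_ids = p$train_ids,
                        y = p$y),
                   class = "dbp_svm")
  structure(list(svm = svm, beta = unlist(p$beta), scalers = scalers,
                 train_features = feats, train_ids = p$train_ids,
                 config = config),
            class = "dbp_model")
}
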