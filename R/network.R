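#' @include encoders.R
NULL

#' Configuration of the CNN+BLSTM advanced-feature extractor
#'
#' Defaults follow the method's protocol: three convolution blocks with 16,
#' 32 and 64 filters of length 8, max-pooling of 2 after every block, five
#' training epochs, and a bidirectional LSTM whose two directions are
#' concatenated before a fully connected ReLU layer and a sigmoid output.
#' `profile = "fast"` is a documented reduced profile (filters 4/8/16,
#' smaller recurrent and dense layers) for large simulation studies; the
#' architecture family is identical.
#'
#' @param n_conv_layers number of conv blocks (the depth sweep of the method
#'   supports 2-7).
#' @param nb_filter integer vector of output channels, one per conv block.
#' @param filter_length integer vector of kernel lengths, one per block.
#' @param pool_size max-pool window (= stride).
#' @param lstm_units hidden units per LSTM direction.
#' @param dense_units units of the fully connected layer.
#' @param dropout dropout rate on the flattened recurrent output.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs (default 5).
#' @param seed integer seed for weight init, shuffling and dropout.
#' @param profile `"default"` or `"fast"`.
#' @return a list of class `mc4_network_config`.
#' @export
network_config <- function(n_conv_layers = 3L,
                           nb_filter = c(16L, 32L, 64L),
                           filter_length = rep(8L, n_conv_layers),
                           pool_size = 2L,
                           lstm_units = 32L,
                           dense_units = 16L,
                           dropout = 0.2,
                           learning_rate = 0.001,
                           batch_size = 64L,
                           epochs = 5L,
                           seed = 1L,
                           profile = c("default", "fast")) {
  profile <- match.arg(profile)
  if (profile == "fast" && missing(nb_filter)) {
    nb_filter <- c(4L, 8L, 16L)[seq_len(n_conv_layers)]
    if (missing(lstm_units)) lstm_units <- 12L
    if (missing(dense_units)) dense_units <- 8L
  }
  cfg <- list(n_conv_layers = as.integer(n_conv_layers),
              nb_filter = as.integer(nb_filter),
              filter_length = as.integer(filter_length),
              pool_size = as.integer(pool_size),
              lstm_units = as.integer(lstm_units),
              dense_units = as.integer(dense_units),
              dropout = dropout, learning_rate = learning_rate,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              seed = as.integer(seed), profile = profile)
  validate_network_config(cfg)
  structure(cfg, class = "mc4_network_config")
}

validate_network_config <- function(cfg) {
  if (length(cfg$nb_filter) != cfg$n_conv_layers ||
      length(cfg$filter_length) != cfg$n_conv_layers) {
    stop("nb_filter and filter_length must each list one value per conv layer (",
         cfg$n_conv_layers, ")", call. = FALSE)
  }
  stopifnot(cfg$epochs >= 1L, cfg$pool_size >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1)
  invisible(cfg)
}

#' Smallest input length a conv stack can consume
#' @param config an [network_config()] object.
#' @return integer minimal feature-vector length.
#' @export
min_input_length <- function(config) .cbi_min_input(config)

# Cap the conv depth to the deepest stack the input length admits; short
# encodings (e.g. the 10-dim KNN features) cannot pass three conv blocks of
# length 8 with pooling 2, so the leading blocks of the configured stack are
# kept and the rest dropped.
adapt_depth <- function(config, input_length) {
  d <- config$n_conv_layers
  while (d >= 1L) {
    cand <- config
    cand$n_conv_layers <- d
    cand$nb_filter <- config$nb_filter[seq_len(d)]
    cand$filter_length <- config$filter_length[seq_len(d)]
    if (input_length >= .cbi_min_input(cand)) {
      attr(cand, "depth_capped") <- d < config$n_conv_layers
      return(cand)
    }
    d <- d - 1L
  }
  stop("input length ", input_length, " too short for even one conv block",
       call. = FALSE)
}

#' Build an (untrained) extractor network
#'
#' Instantiates the `[Conv -> ReLU -> MaxPool] x n` -> bidirectional LSTM ->
#' flatten -> dense -> sigmoid architecture for a given input length,
#' erroring (and reporting the minimal admissible length) when the input is
#' too short for the configured stack.
#'
#' @param config an [network_config()] object.
#' @param input_length feature-vector length the network will consume.
#' @return a list of class `mc4_cbi_model` with seeded initial weights and a
#'   shape table (`timesteps` after each block, `channels`).
#' @export
build_network <- function(config, input_length) {
  validate_network_config(config)
  m <- .cbi_min_input(config)
  if (input_length < m) {
    stop("input length ", input_length, " too short for the conv stack; ",
         "minimal length is ", m, call. = FALSE)
  }
  structure(list(config = config, input_length = as.integer(input_length),
                 weights = .cbi_init(config, input_length, config$seed),
                 timesteps = .cbi_shapes(config, input_length),
                 channels = config$nb_filter,
                 trained = FALSE),
            class = "mc4_cbi_model")
}

#' @export
print.mc4_cbi_model <- function(x, ...) {
  cat("<mc4_cbi_model> input 1x", x$input_length, "x1; conv channels ",
      paste(x$channels, collapse = ","), "; timesteps after blocks ",
      paste(x$timesteps, collapse = ","), "; BLSTM ", x$config$lstm_units,
      "x2; ", if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Forward pass of an extractor network
#' @param object an `mc4_cbi_model`.
#' @param newdata numeric matrix (n x input_length).
#' @param ... unused.
#' @return sigmoid probabilities in \[0, 1\].
#' @export
predict.mc4_cbi_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_length) {
    stop("input width ", ncol(newdata), " does not match the network's ",
         object$input_length, call. = FALSE)
  }
  as.vector(.cbi_predict(object$weights, newdata, object$config))
}

#' Train one extractor with k-fold cross-validation
#'
#' For every fold, a network is trained on the remaining folds and predicts
#' the held-out fold, so each row's out-of-fold probability comes from a
#' model that never saw that row's fold. Deterministic for a fixed config
#' seed.
#'
#' @param encoded_matrix numeric matrix (n x d), one encoding of the dataset.
#' @param labels binary labels (anything [confusion()] accepts).
#' @param folds an [stratified_folds()] assignment covering all rows.
#' @param config an [network_config()]; the conv depth is assumed feasible
#'   for `ncol(encoded_matrix)` (see [build_network()]).
#' @return list with `oof_probs` (out-of-fold probabilities), `fold_models`
#'   (one `mc4_cbi_model` per fold), `train_ids` (row indices each fold
#'   model was trained on), `history` (per-fold epoch losses).
#' @export
train_extractor <- function(encoded_matrix, labels, folds, config) {
  X <- as.matrix(encoded_matrix)
  y <- as_binary_label(labels)
  stopifnot(nrow(X) == length(y), length(folds) == nrow(X))
  validate_network_config(config)
  ks <- sort(unique(as.integer(folds)))
  oof <- rep(NA_real_, nrow(X))
  fold_models <- list()
  train_ids <- list()
  history <- list()
  for (f in ks) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[tr])) < 2L) {
      stop("training split for fold ", f, " contains a single class", call. = FALSE)
    }
    fit <- .cbi_train(X[tr, , drop = FALSE], y[tr], config,
                      seed = config$seed + f)
    model <- structure(list(config = config, input_length = ncol(X),
                            weights = fit$weights,
                            timesteps = .cbi_shapes(config, ncol(X)),
                            channels = config$nb_filter, trained = TRUE),
                       class = "mc4_cbi_model")
    oof[te] <- predict(model, X[te, , drop = FALSE])
    key <- as.character(f)
    fold_models[[key]] <- model
    train_ids[[key]] <- tr
    history[[key]] <- as.vector(fit$history)
  }
  stopifnot(!anyNA(oof))
  list(oof_probs = oof, fold_models = fold_models, train_ids = train_ids,
       history = history)
}

#' Train the eight advanced-feature extractors
#'
#' Encodes the dataset under every scheme, trains one CNN+BLSTM extractor
#' per scheme with out-of-fold cross-validation, and refits a final model
#' per scheme on all rows for predicting new samples. The returned advanced
#' feature matrix holds the *out-of-fold* sigmoid probabilities — one column
#' per scheme, entries in \[0, 1\] — which downstream stages train on.
#'
#' @param samples an `mc4_samples` table.
#' @param folds an [stratified_folds()] assignment.
#' @param config an [network_config()]; depth is capped per scheme when an
#'   encoding is too short for the full stack.
#' @param params optional encoder parameter overrides.
#' @param schemes encoding subset (default all eight, canonical order).
#' @param verbose print per-scheme progress.
#' @return a list of class `mc4_bundle`: `advanced` (n x 8 matrix, class
#'   `mc4_advanced`), `extractors` (per scheme: used config, fold models,
#'   train ids, refit model, history), `folds`, `reference_samples` (for
#'   KNN encoding of new data), `encoder_params`.
#' @export
train_advanced_features <- function(samples, folds, config = network_config(),
                                    params = NULL, schemes = mc4_schemes,
                                    verbose = TRUE) {
  stopifnot(inherits(samples, "mc4_samples"))
  y <- as_binary_label(samples$label)
  adv <- matrix(NA_real_, nrow(samples), length(schemes),
                dimnames = list(samples$id, schemes))
  extractors <- list()
  for (sc in schemes) {
    t0 <- Sys.time()
    M <- encode_dataset(samples, sc, fold_assignment = folds, params = params)
    cfg <- adapt_depth(config, ncol(M))
    fit <- train_extractor(M, y, folds, cfg)
    adv[, sc] <- fit$oof_probs
    refit <- .cbi_train(unclass(M)[, , drop = FALSE], y, cfg, seed = cfg$seed)
    refit_model <- structure(list(config = cfg, input_length = ncol(M),
                                  weights = refit$weights,
                                  timesteps = .cbi_shapes(cfg, ncol(M)),
                                  channels = cfg$nb_filter, trained = TRUE),
                             class = "mc4_cbi_model")
    extractors[[sc]] <- list(config = cfg, fold_models = fit$fold_models,
                             train_ids = fit$train_ids, refit = refit_model,
                             history = fit$history)
    if (verbose) {
      message(sprintf("advanced[%s]: d=%d, depth=%d, oof AUC=%.3f (%.1fs)",
                      sc, ncol(M), cfg$n_conv_layers,
                      auc_rank(fit$oof_probs, y),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  structure(list(advanced = structure(adv, class = c("mc4_advanced", class(adv))),
                 extractors = extractors, folds = folds,
                 reference_samples = samples,
                 encoder_params = merge_params(params)),
            class = "mc4_bundle")
}

#' Advanced feature matrix for new samples
#'
#' Encodes `samples` under every scheme held by the bundle and applies the
#' per-scheme refit extractors, yielding one sigmoid probability per scheme
#' (n x 8). KNN encoding uses the bundle's training samples as references.
#'
#' @param samples an `mc4_samples` table of new windows.
#' @param trained_bundle an `mc4_bundle` from [train_advanced_features()].
#' @param schemes schemes to extract (default: all in canonical order); any
#'   scheme missing from the bundle is an error naming it.
#' @return an `mc4_advanced` matrix, one column per scheme, entries in \[0, 1\].
#' @export
extract_advanced <- function(samples, trained_bundle, schemes = mc4_schemes) {
  stopifnot(inherits(trained_bundle, "mc4_bundle"))
  missing_sc <- setdiff(schemes, names(trained_bundle$extractors))
  if (length(missing_sc)) {
    stop("bundle has no extractor for scheme: ",
         paste(missing_sc, collapse = ", "), call. = FALSE)
  }
  n <- nrow(samples)
  adv <- matrix(NA_real_, n, length(schemes),
                dimnames = list(samples$id, schemes))
  if (n == 0L) return(structure(adv, class = c("mc4_advanced", class(adv))))
  p <- trained_bundle$encoder_params
  for (sc in schemes) {
    if (sc == "KNN") {
      refs <- trained_bundle$reference_samples
      M <- t(vapply(samples$sequence,
                    function(sq) encode_knn(sq, refs, p$knn_fractions),
                    numeric(length(p$knn_fractions)), USE.NAMES = FALSE))
    } else {
      M <- t(vapply(samples$sequence, function(sq) encode(sq, sc, p),
                    numeric(feature_length(sc, nchar(samples$sequence[1]), p)),
                    USE.NAMES = FALSE))
    }
    adv[, sc] <- predict(trained_bundle$extractors[[sc]]$refit, M)
  }
  structure(adv, class = c("mc4_advanced", class(adv)))
}
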