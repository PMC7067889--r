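#' @include stacking.R
NULL

#' Configuration of the final fully connected classifier
#'
#' A small feed-forward network on the enriched feature matrix: 2-4 hidden
#' layers with ReLU activations and a sigmoid output unit. Defaults: two
#' hidden layers of 32 and 16 units, Adam, 50 epochs with early stopping on
#' a held-back validation split (patience 5).
#'
#' @param hidden_layers number of hidden layers (2-4).
#' @param hidden_units integer vector, one entry per hidden layer.
#' @param threshold decision threshold on the output probability (in (0,1)).
#' @param epochs,batch_size,learning_rate training settings.
#' @param val_fraction fraction held back for early stopping.
#' @param patience epochs without validation improvement before stopping
#'   (0 disables early stopping).
#' @param seed integer seed.
#' @return a list of class `mc4_final_config`.
#' @export
final_net_config <- function(hidden_layers = 2L, hidden_units = c(32L, 16L),
                             threshold = 0.5, epochs = 50L, batch_size = 32L,
                             learning_rate = 0.001, val_fraction = 0.1,
                             patience = 5L, seed = 1L) {
  if (hidden_layers < 2L || hidden_layers > 4L) {
    stop("hidden_layers must be between 2 and 4", call. = FALSE)
  }
  if (length(hidden_units) != hidden_layers) {
    stop("hidden_units must list one size per hidden layer (", hidden_layers,
         ")", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)", call. = FALSE)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 threshold = threshold, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "mc4_final_config")
}

#' Train the final classifier on an enriched feature matrix
#'
#' @param enriched_matrix numeric matrix (n x d), typically an
#'   `mc4_enriched` matrix.
#' @param labels binary labels (both classes must be present).
#' @param config an [final_net_config()].
#' @return a list of class `mc4_final_model` with the trained weights,
#'   training/validation loss history and the expected input width.
#' @export
train_final <- function(enriched_matrix, labels, config = final_net_config()) {
  stopifnot(inherits(config, "mc4_final_config"))
  X <- as.matrix(enriched_matrix)
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2L) stop("labels are degenerate (single class)", call. = FALSE)
  # a tiny validation split makes the early-stopping point noise-driven;
  # below 50 held-back samples we train the full epoch budget instead
  patience <- config$patience
  if (floor(config$val_fraction * nrow(X)) < 50) patience <- 0L
  fit <- .mlp_train(X, y, config$hidden_units, config$learning_rate,
                    config$batch_size, config$epochs, config$val_fraction,
                    patience, config$seed)
  structure(list(weights = fit$weights, history = as.vector(fit$history),
                 val_history = as.vector(fit$val_history),
                 width = ncol(X), config = config),
            class = "mc4_final_model")
}

#' Predict 4mC-site probabilities and labels with the final classifier
#'
#' Labels follow the `probability >= threshold` convention (the boundary
#' value is called positive).
#'
#' @param model an `mc4_final_model`.
#' @param enriched_matrix matrix with the width the model was trained on.
#' @param threshold decision threshold (default: the model's configured one).
#' @return list with `probabilities` and integer `labels` (0/1).
#' @export
predict_final <- function(model, enriched_matrix,
                          threshold = model$config$threshold) {
  stopifnot(inherits(model, "mc4_final_model"))
  X <- as.matrix(enriched_matrix)
  if (nrow(X) == 0L) return(list(probabilities = numeric(0), labels = integer(0)))
  if (ncol(X) != model$width) {
    stop("matrix width ", ncol(X), " does not match the trained width ",
         model$width, call. = FALSE)
  }
  p <- as.vector(.mlp_predict(model$weights, X))
  list(probabilities = p, labels = as.integer(p >= threshold))
}

#' @export
predict.mc4_final_model <- function(object, newdata, ...) {
  predict_final(object, newdata)
}
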