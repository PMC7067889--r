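# Shared fixtures, built in code at test time.

# A minimal extractor config: one tiny conv block, fast to train.
tiny_net <- function(epochs = 2L, seed = 7L) {
  network_config(n_conv_layers = 1L, nb_filter = 4L, filter_length = 5L,
                 pool_size = 2L, lstm_units = 6L, dense_units = 6L,
                 dropout = 0, learning_rate = 0.01, batch_size = 32L,
                 epochs = epochs, seed = seed)
}

# Hand-built sample table (valid 41-bp windows with central C).
make_samples <- function(seqs, labels, ids = sprintf("s%02d", seq_along(seqs)),
                         modqv = NA_real_) {
  df <- data.frame(id = ids, sequence = seqs, label = labels,
                   modqv = as.numeric(modqv), stringsAsFactors = FALSE)
  class(df) <- c("mc4_samples", "data.frame")
  df
}

# Random valid window with central C.
random_window <- function(L = 41L) {
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  s[(L + 1L) %/% 2L] <- "C"
  paste0(s, collapse = "")
}

# Synthetic "advanced-like" probability matrix: 8 columns correlated with
# the label at varying strengths, plus noise. Used where only the stacking
# stage is under test.
fake_advanced <- function(n, seed = 1L, strength = seq(0.4, 1.8, length.out = 8)) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  z <- ifelse(y == 1L, 1, -1)
  M <- vapply(strength, function(a) stats::plogis(a * z + stats::rnorm(n)),
              numeric(n))
  colnames(M) <- mc4_schemes
  list(M = M, y = y)
}
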