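test_that("default architecture matches the protocol shape conventions", {
  cfg <- network_config()
  m <- build_network(cfg, 500L)
  expect_equal(m$channels, c(16L, 32L, 64L))     # final conv stage: 64 channels
  expect_equal(m$config$filter_length, rep(8L, 3))
  expect_equal(m$config$pool_size, 2L)
  expect_equal(m$config$epochs, 5L)
  # valid padding + pool 2: 500 -> 246 -> 119 -> 56 timesteps
  expect_equal(m$timesteps, c(246L, 119L, 56L))

  # forward pass of an all-zeros input is a finite probability
  p <- predict(m, matrix(0, 3, 500))
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
})

test_that("config invariants and minimal input length are enforced", {
  expect_error(network_config(n_conv_layers = 4L, nb_filter = c(16L, 32L, 64L)),
               "one value per conv layer")
  cfg <- network_config()
  expect_equal(min_input_length(cfg), 57L)
  expect_error(build_network(cfg, 56L), "minimal length is 57")
  expect_silent(build_network(cfg, 57L))
})

test_that("sigmoid outputs stay in [0,1] for arbitrary finite inputs", {
  set.seed(41)
  cfg <- tiny_net()
  m <- build_network(cfg, 30L)
  X <- matrix(rnorm(50 * 30, sd = 25), 50, 30)
  p <- predict(m, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(p)))
})

test_that("cross-validated extractor separates a strong synthetic signal", {
  set.seed(42)
  n <- 600
  y <- rep(c(1, 0), n / 2)
  X <- matrix(rnorm(n * 60), n, 60)
  X[y == 1, 15:25] <- X[y == 1, 15:25] + 1.2
  folds <- stratified_folds(ifelse(y == 1, "pos", "neg"), k = 3, seed = 1)
  fit <- train_extractor(X, y, folds, tiny_net(epochs = 5L))
  expect_gt(auc_rank(fit$oof_probs, y), 0.9)

  # permutation null: shuffled labels give chance-level AUC
  yperm <- sample(y)
  foldsp <- stratified_folds(ifelse(yperm == 1, "pos", "neg"), k = 3, seed = 1)
  fitp <- train_extractor(X, yperm, foldsp, tiny_net(epochs = 5L))
  aucp <- auc_rank(fitp$oof_probs, yperm)
  expect_gt(aucp, 0.4); expect_lt(aucp, 0.6)
})

test_that("extractor training is deterministic given the seed", {
  set.seed(43)
  X <- matrix(rnorm(60 * 20), 60, 20)
  y <- rep(c(1, 0), 30)
  folds <- stratified_folds(ifelse(y == 1, "pos", "neg"), k = 3, seed = 2)
  a <- train_extractor(X, y, folds, tiny_net(epochs = 2L, seed = 9L))
  b <- train_extractor(X, y, folds, tiny_net(epochs = 2L, seed = 9L))
  expect_identical(a$oof_probs, b$oof_probs)
  expect_identical(a$history, b$history)
  expect_equal(lengths(a$history), c(`0` = 2L, `1` = 2L, `2` = 2L))
})

test_that("training loss is (loosely) non-increasing across epochs", {
  set.seed(44)
  n <- 300
  y <- rep(c(1, 0), n / 2)
  X <- matrix(rnorm(n * 60), n, 60)
  X[y == 1, 10:30] <- X[y == 1, 10:30] + 1
  fit <- mc4deep:::.cbi_train(X, y, tiny_net(epochs = 5L), 3L)
  drops <- diff(as.vector(fit$history)) <= 1e-6
  expect_gte(sum(drops), 3)
  expect_lt(fit$history[5], fit$history[1])
})

test_that("single-class training splits are rejected", {
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- c(rep(1, 20), rep(0, 10))
  folds <- c(rep(0:2, length.out = 20), rep(0L, 10))  # all negatives in fold 0
  expect_error(train_extractor(X, y, folds, tiny_net()), "single class")
})

test_that("conv depth is capped per encoding but never below one block", {
  cfg <- network_config()
  expect_equal(mc4deep:::adapt_depth(cfg, 500L)$n_conv_layers, 3L)
  expect_equal(mc4deep:::adapt_depth(cfg, 30L)$n_conv_layers, 2L)
  a <- mc4deep:::adapt_depth(cfg, 10L)
  expect_equal(a$n_conv_layers, 1L)
  expect_equal(a$nb_filter, 16L)     # leading blocks of the configured stack
  expect_error(mc4deep:::adapt_depth(cfg, 5L), "too short")
})

test_that("advanced feature extraction yields one bounded column per scheme", {
  set.seed(45)
  cfg <- generator_config(n_pos = 30, n_neg = 30, effect = 0.9, seed = 3)
  s <- generate_samples(cfg)
  folds <- stratified_folds(s, k = 3, seed = 4)
  bundle <- train_advanced_features(s, folds, tiny_net(epochs = 1L),
                                    verbose = FALSE)
  adv <- bundle$advanced
  expect_equal(dim(adv), c(60L, 8L))
  expect_equal(colnames(adv), mc4_schemes)
  expect_true(all(adv >= 0 & adv <= 1))

  new_s <- generate_samples(generator_config(n_pos = 3, n_neg = 2, seed = 8))
  out <- extract_advanced(new_s, bundle)
  expect_equal(dim(out), c(5L, 8L))
  expect_true(all(out >= 0 & out <= 1))

  # inference is pure: duplicated rows give identical outputs
  dup <- new_s[c(1, 1, 2), ]
  out2 <- extract_advanced(dup, bundle)
  expect_equal(unname(out2[1, ]), unname(out2[2, ]))

  # empty input keeps the 8-column contract
  expect_equal(dim(extract_advanced(new_s[0, ], bundle)), c(0L, 8L))

  # a missing scheme is reported by name
  partial <- bundle
  partial$extractors$KNN <- NULL
  expect_error(extract_advanced(new_s, partial), "KNN")
})
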