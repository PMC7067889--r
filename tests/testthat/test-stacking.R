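test_that("a perfectly informative column yields cv accuracy 1", {
  set.seed(51)
  n <- 60
  y <- rep(c(1, 0), n / 2)
  M <- cbind(label_copy = y, matrix(runif(n * 7), n, 7))
  folds <- stratified_folds(ifelse(y == 1, "pos", "neg"), k = 3, seed = 1)
  it <- run_iteration(M, y, folds)
  expect_equal(it$cv_accuracy, 1)
  expect_true(all(it$probs[y == 1] >= 0.5))
  expect_true(all(it$probs[y == 0] < 0.5))
})

test_that("exact accuracy ties go to the first learner in the fixed order", {
  set.seed(52)
  n <- 30
  y <- rep(c(1, 0), n / 2)
  M <- matrix(runif(n * 2), n, 2)
  folds <- stratified_folds(ifelse(y == 1, "pos", "neg"), k = 3, seed = 1)
  constant <- function(id) {
    list(id = id, fit = function(X, y, seed) NULL,
         prob = function(m, X) rep(0.6, nrow(X)))
  }
  mock <- structure(list(a = constant("a"), b = constant("b")),
                    class = "mc4_learners")
  it <- run_iteration(M, y, folds, learners = mock)
  expect_equal(it$winner, "a")
})

test_that("winner accuracy equals an independent per-fold refit evaluation", {
  set.seed(53)
  fx <- fake_advanced(90, seed = 6)
  folds <- stratified_folds(ifelse(fx$y == 1, "pos", "neg"), k = 3, seed = 2)
  learners <- learner_set()
  it <- run_iteration(fx$M, fx$y, folds, learners, seed = 5L)
  # oracle: recompute each learner's out-of-fold accuracy with its own loop
  oracle_acc <- vapply(learners, function(l) {
    p <- rep(NA_real_, nrow(fx$M))
    for (f in 0:2) {
      tr <- which(folds != f); te <- which(folds == f)
      m <- l$fit(fx$M[tr, , drop = FALSE], fx$y[tr], 5L + f)
      p[te] <- l$prob(m, fx$M[te, , drop = FALSE])
    }
    mean((p >= 0.5) == fx$y)
  }, 0)
  expect_equal(it$cv_accuracy, max(oracle_acc))
  expect_equal(it$winner, names(oracle_acc)[which.max(oracle_acc)])
  expect_equal(it$accuracies, oracle_acc)
})

test_that("degenerate labels are rejected", {
  M <- matrix(runif(20 * 8), 20, 8)
  expect_error(run_iteration(M, rep(1, 20), rep(0:1, 10)), "single class")
})

test_that("each stacking iteration appends exactly one bounded column", {
  set.seed(54)
  fx <- fake_advanced(90, seed = 7)
  folds <- stratified_folds(ifelse(fx$y == 1, "pos", "neg"), k = 3, seed = 3)

  none <- stack_iterate(fx$M, fx$y, folds, max_iter = 0, verbose = FALSE)
  expect_equal(ncol(none), 8L)
  expect_equal(unclass(none), fx$M, ignore_attr = TRUE)

  enr <- stack_iterate(fx$M, fx$y, folds, max_iter = 3, tol = 0,
                       seed = 4, verbose = FALSE)
  expect_equal(ncol(enr), 11L)
  expect_equal(colnames(enr)[9:11], c("f9", "f10", "f11"))
  # original 8 columns never modified
  expect_equal(unclass(enr)[, 1:8], fx$M, ignore_attr = TRUE)
  expect_true(all(enr[, 9:11] >= 0 & enr[, 9:11] <= 1))
  prov <- attr(enr, "provenance")
  expect_length(prov, 3L)
  expect_equal(vapply(prov, `[[`, 0L, "iteration"), 1:3)
  expect_length(attr(enr, "history"), 3L)
})

test_that("appended columns are out-of-fold (leakage instrumentation)", {
  set.seed(55)
  fx <- fake_advanced(90, seed = 8)
  folds <- stratified_folds(ifelse(fx$y == 1, "pos", "neg"), k = 3, seed = 5)
  enr <- stack_iterate(fx$M, fx$y, folds, max_iter = 2, tol = 0,
                       seed = 6, verbose = FALSE)
  for (t in seq_along(attr(enr, "train_ids"))) {
    ids <- attr(enr, "train_ids")[[t]]
    for (f in names(ids)) {
      own_fold_rows <- which(folds == as.integer(f))
      expect_length(intersect(ids[[f]], own_fold_rows), 0L)
      expect_setequal(ids[[f]], which(folds != as.integer(f)))
    }
  }
})

test_that("accuracy history rises or the stop reason records convergence", {
  set.seed(56)
  fx <- fake_advanced(120, seed = 9)
  folds <- stratified_folds(ifelse(fx$y == 1, "pos", "neg"), k = 3, seed = 6)
  enr <- stack_iterate(fx$M, fx$y, folds, max_iter = 6, tol = 1e-4,
                       seed = 7, verbose = FALSE)
  h <- attr(enr, "history")
  expect_true(attr(enr, "stop_reason") %in% c("converged", "max_iter"))
  if (length(h) >= 2 && attr(enr, "stop_reason") == "converged") {
    expect_lt(abs(h[length(h)] - h[length(h) - 1]), 1e-4)
  }
  expect_equal(ncol(enr), 8L + length(h))
})

test_that("the fitted winner sequence transfers to new samples", {
  set.seed(57)
  fx <- fake_advanced(90, seed = 10)
  folds <- stratified_folds(ifelse(fx$y == 1, "pos", "neg"), k = 3, seed = 7)
  enr <- stack_iterate(fx$M, fx$y, folds, max_iter = 2, tol = 0,
                       seed = 8, verbose = FALSE)
  newM <- fake_advanced(20, seed = 11)$M
  out <- stack_apply(enr, newM)
  expect_equal(ncol(out), ncol(enr))
  expect_true(all(out[, 9:10] >= 0 & out[, 9:10] <= 1))
  expect_error(stack_apply(enr, newM[, 1:5]), "expected 8")
})
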