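#' @include network.R
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' The six stacking learners
#'
#' K-nearest neighbours (k = 5), L2 logistic regression, an RBF support
#' vector machine with probability outputs, Gaussian naive Bayes, a decision
#' tree and a 100-tree random forest — each able to emit class-1
#' probabilities. Hyperparameters are fixed here (the method specifies the
#' algorithm families, not their settings) and overridable via arguments.
#'
#' @param knn_k neighbours for the KNN learner.
#' @param svm_cost,svm_gamma RBF-SVM cost and kernel width (`NULL` = 1/d).
#' @param rf_trees random-forest size.
#' @param tree_cp rpart complexity parameter.
#' @return a named list of learner specs (class `mc4_learners`), each with
#'   `fit(X, y, seed)` and `prob(model, X)` closures.
#' @export
learner_set <- function(knn_k = 5L, svm_cost = 1, svm_gamma = NULL,
                        rf_trees = 100L, tree_cp = 0.01) {
  mk <- function(id, fit, prob) list(id = id, fit = fit, prob = prob)
  learners <- list(
    knn = mk("knn",
      fit = function(X, y, seed) list(X = X, y = y, k = knn_k, seed = seed),
      prob = function(m, X) {
        with_seed(m$seed, {
          pr <- class::knn(m$X, X, factor(m$y, levels = c(0, 1)),
                           k = min(m$k, nrow(m$X)), prob = TRUE, use.all = TRUE)
          p <- attr(pr, "prob")
          ifelse(pr == "1", p, 1 - p)
        })
      }),
    logistic = mk("logistic",
      fit = function(X, y, seed) {
        df <- data.frame(y = y, X)
        suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      },
      prob = function(m, X) {
        suppressWarnings(as.vector(stats::predict(m, newdata = data.frame(X),
                                                  type = "response")))
      }),
    svm = mk("svm",
      fit = function(X, y, seed) {
        with_seed(seed, e1071::svm(X, factor(y, levels = c(0, 1)),
                                   kernel = "radial", cost = svm_cost,
                                   gamma = if (is.null(svm_gamma)) 1 / ncol(X) else svm_gamma,
                                   probability = TRUE, scale = FALSE))
      },
      prob = function(m, X) {
        pr <- stats::predict(m, X, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }),
    nb = mk("nb",
      fit = function(X, y, seed) e1071::naiveBayes(X, factor(y, levels = c(0, 1))),
      prob = function(m, X) stats::predict(m, X, type = "raw")[, "1"]),
    tree = mk("tree",
      fit = function(X, y, seed) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), X)
        with_seed(seed, rpart::rpart(y ~ ., data = df, method = "class",
                                     cp = tree_cp))
      },
      prob = function(m, X) stats::predict(m, data.frame(X), type = "prob")[, "1"]),
    rf = mk("rf",
      fit = function(X, y, seed) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), X)
        ranger::ranger(y ~ ., data = df, num.trees = rf_trees,
                       probability = TRUE, seed = seed, num.threads = 1L)
      },
      prob = function(m, X) stats::predict(m, data.frame(X),
                                           num.threads = 1L)$predictions[, "1"])
  )
  structure(learners, class = "mc4_learners")
}

oof_probs_learner <- function(learner, X, y, folds, seed) {
  p <- rep(NA_real_, nrow(X))
  train_ids <- list()
  for (f in sort(unique(as.integer(folds)))) {
    tr <- which(folds != f); te <- which(folds == f)
    m <- learner$fit(X[tr, , drop = FALSE], y[tr], seed + f)
    p[te] <- learner$prob(m, X[te, , drop = FALSE])
    train_ids[[as.character(f)]] <- tr
  }
  list(probs = pmin(pmax(p, 0), 1), train_ids = train_ids)
}

#' One round of the integrated (probability-stacking) algorithm
#'
#' Evaluates all six learners by out-of-fold accuracy on the current feature
#' matrix; the winner (ties go to the first learner in the fixed order) hands
#' back its out-of-fold class-1 probability column.
#'
#' @param matrix numeric feature matrix (n x d).
#' @param labels binary labels.
#' @param folds an [stratified_folds()] assignment.
#' @param learners an [learner_set()].
#' @param seed integer seed for the seeded learners.
#' @return list with `winner`, `probs` (out-of-fold column), `cv_accuracy`,
#'   `accuracies` (all six), and `train_ids` (per-fold training rows, for
#'   leakage instrumentation).
#' @export
run_iteration <- function(matrix, labels, folds, learners = learner_set(),
                          seed = 1L) {
  X <- as.matrix(matrix)
  y <- as_binary_label(labels)
  stopifnot(nrow(X) == length(y), length(folds) == length(y))
  if (length(unique(y)) < 2L) stop("labels are degenerate (single class)", call. = FALSE)
  res <- lapply(learners, function(l) oof_probs_learner(l, X, y, folds, seed))
  acc <- vapply(res, function(r) mean((r$probs >= 0.5) == y), 0)
  win <- which.max(acc)   # ties: first in fixed order
  list(winner = names(learners)[win], probs = res[[win]]$probs,
       cv_accuracy = unname(acc[win]), accuracies = acc,
       train_ids = res[[win]]$train_ids)
}

#' Iterative probability stacking over the advanced feature matrix
#'
#' Starting from the 8-column advanced feature matrix, each iteration runs
#' the six learners, appends the winner's out-of-fold probability column and
#' feeds the widened matrix into the next round, until the winner's
#' cross-validated accuracy changes by less than `tol` or `max_iter`
#' iterations have completed. Appended columns are out-of-fold to keep later
#' iterations (and the final classifier) leakage-free; for predicting new
#' samples each round's winner is refit on the full matrix and the refits
#' are applied in sequence ([stack_apply()]).
#'
#' @param matrix the advanced feature matrix (n x 8).
#' @param labels binary labels.
#' @param folds an [stratified_folds()] assignment.
#' @param learners an [learner_set()].
#' @param max_iter maximum iterations (default 10; the method converges in
#'   fewer).
#' @param tol absolute accuracy-change convergence tolerance (default 1e-4).
#' @param seed integer seed.
#' @param verbose print per-iteration winners.
#' @return an `mc4_enriched` matrix (n x (8+t)) with attributes `provenance`
#'   (per iteration: index, winner, cv_accuracy), `history` (accuracy per
#'   iteration), `stop_reason`, `refits` (per-iteration full-data winner
#'   refits), `base_cols`, and `train_ids` per iteration.
#' @export
stack_iterate <- function(matrix, labels, folds, learners = learner_set(),
                          max_iter = 10L, tol = 1e-4, seed = 1L,
                          verbose = TRUE) {
  stopifnot(max_iter >= 0L, tol >= 0)
  X <- as.matrix(matrix)
  base_cols <- ncol(X)
  y <- as_binary_label(labels)
  provenance <- list(); refits <- list(); history <- numeric(0)
  train_ids <- list()
  stop_reason <- if (max_iter == 0L) "max_iter" else NA_character_
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    it <- run_iteration(X, y, folds, learners, seed = seed + 97L * t)
    X <- cbind(X, it$probs)
    colnames(X)[ncol(X)] <- paste0("f", ncol(X))
    provenance[[t]] <- list(iteration = t, winner = it$winner,
                            cv_accuracy = it$cv_accuracy)
    history[t] <- it$cv_accuracy
    train_ids[[t]] <- it$train_ids
    refits[[t]] <- list(winner = it$winner,
                        model = learners[[it$winner]]$fit(
                          X[, -ncol(X), drop = FALSE], y, seed + 97L * t))
    if (verbose) {
      message(sprintf("stack iter %d: winner=%s, cv ACC=%.4f", t, it$winner,
                      it$cv_accuracy))
    }
    if (t >= 2L && abs(history[t] - history[t - 1L]) < tol) {
      stop_reason <- "converged"
      break
    }
    if (t == max_iter) stop_reason <- "max_iter"
  }
  structure(X, provenance = provenance, history = history,
            stop_reason = stop_reason, refits = refits,
            base_cols = base_cols, train_ids = train_ids,
            learners = learners,
            class = c("mc4_enriched", class(X)))
}

#' Apply a fitted stacking sequence to new samples
#'
#' Grows a new advanced matrix by the same winner sequence, using each
#' iteration's full-data refit model.
#'
#' @param enriched an `mc4_enriched` matrix from [stack_iterate()].
#' @param advanced_new advanced feature matrix of the new samples (n x 8).
#' @return matrix with `ncol(enriched)` columns.
#' @export
stack_apply <- function(enriched, advanced_new) {
  stopifnot(inherits(enriched, "mc4_enriched"))
  refits <- attr(enriched, "refits")
  learners <- attr(enriched, "learners")
  X <- as.matrix(advanced_new)
  if (ncol(X) != attr(enriched, "base_cols")) {
    stop("new matrix has ", ncol(X), " columns; expected ",
         attr(enriched, "base_cols"), call. = FALSE)
  }
  for (r in refits) {
    p <- learners[[r$winner]]$prob(r$model, X)
    X <- cbind(X, pmin(pmax(p, 0), 1))
    colnames(X)[ncol(X)] <- paste0("f", ncol(X))
  }
  X
}
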