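#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives for a pair of binary label
#' vectors. Labels may be given as 0/1, logicals, or factors/characters in
#' `{"pos","neg","positive","negative","1","0"}`.
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @return An object of class `mc4_confusion`: a list with integer fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(truth, pred) {
  truth <- as_binary_label(truth)
  pred <- as_binary_label(pred)
  if (length(truth) != length(pred)) {
    stop("`truth` has ", length(truth), " labels but `pred` has ",
         length(pred), call. = FALSE)
  }
  out <- list(
    TP = sum(truth == 1L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L)
  )
  structure(lapply(out, as.integer), class = "mc4_confusion")
}

#' @export
print.mc4_confusion <- function(x, ...) {
  cat("confusion counts: TP=", x$TP, " TN=", x$TN,
      " FP=", x$FP, " FN=", x$FN, "\n", sep = "")
  invisible(x)
}

# Normalize assorted binary label representations to integer 0/1.
as_binary_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    map <- c(pos = 1L, positive = 1L, "1" = 1L, neg = 0L, negative = 0L, "0" = 0L)
    y <- map[tolower(x)]
    if (anyNA(y)) stop("unrecognized label(s): ",
                       paste(unique(x[is.na(y)]), collapse = ", "), call. = FALSE)
    return(unname(y))
  }
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L))) stop("labels must be binary (0/1)", call. = FALSE)
  x
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Tied scores contribute 1/2, which makes this identical to the exhaustive
#' pairwise-comparison estimator.
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth true binary labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, truth) {
  truth <- as_binary_label(truth)
  stopifnot(length(scores) == length(truth))
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full binary-classification metric report
#'
#' Computes sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP),
#' accuracy ACC = (TP+TN)/n, the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)), and the
#' rank-statistic AUC. An MCC whose denominator is zero is reported as 0;
#' SN/SP with an empty class are reported as NA.
#'
#' @param counts an `mc4_confusion` object, or `NULL` to derive counts from
#'   `scores >= threshold`.
#' @param scores class-1 probabilities (needed for AUC; may be `NULL` to skip
#'   AUC).
#' @param truth true labels (needed when `counts` or AUC must be computed).
#' @param threshold decision threshold used when deriving counts from scores.
#' @return An object of class `mc4_metrics`: list with `SN`, `SP`, `ACC`,
#'   `MCC`, `AUC` and the underlying `counts`.
#' @examples
#' p <- c(.9, .8, .3, .1); y <- c(1, 1, 0, 0)
#' metric_report(scores = p, truth = y)
#' @export
metric_report <- function(counts = NULL, scores = NULL, truth = NULL,
                          threshold = 0.5) {
  if (is.null(counts)) {
    if (is.null(scores) || is.null(truth)) {
      stop("either `counts` or both `scores` and `truth` are required",
           call. = FALSE)
    }
    counts <- confusion(truth, as.integer(scores >= threshold))
  }
  stopifnot(inherits(counts, "mc4_confusion"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  n <- tp + tn + fp + fn
  if (n == 0L) stop("empty input: no samples to evaluate", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  den <- prod(sqrt(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  auc <- if (!is.null(scores) && !is.null(truth)) auc_rank(scores, truth) else NA_real_
  structure(list(SN = sn, SP = sp, ACC = acc, MCC = mcc, AUC = auc,
                 counts = counts),
            class = "mc4_metrics")
}

#' @export
print.mc4_metrics <- function(x, digits = 4, ...) {
  v <- unlist(x[c("SN", "SP", "ACC", "MCC", "AUC")])
  cat(paste(names(v), formatC(v, digits = digits, format = "f"),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}
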