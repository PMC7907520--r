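#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive scores
#' above a randomly chosen negative, counting ties as one half (the
#' Mann-Whitney pair statistic). Invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels 0/1 labels (1 = positive = EGFR-mutant).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores,labels As in [auc_score()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, from (1, 1)
#'   down to (0, 0) as the threshold sweeps the score range.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  th <- c(-Inf, sort(unique(scores)), Inf)
  out <- lapply(th, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = sum(pred & labels == 0L) / n_neg,
               tpr = sum(pred & labels == 1L) / n_pos)
  })
  do.call(rbind, out)
}

#' Threshold (hard-label) classification metrics
#'
#' Dichotomizes scores at `threshold` and reports accuracy, recall
#' (sensitivity for the positive class), precision, F-score and the 2x2
#' confusion matrix (rows = actual negative/positive, columns = predicted
#' negative/positive). If no positive predictions are made, precision (and
#' the F-score) is reported as 0 with `precision_undefined = TRUE` rather
#' than NaN, so reports remain comparable.
#'
#' @param scores,labels As in [auc_score()].
#' @param threshold Decision threshold on the scores (default 0.5, for
#'   probability outputs).
#' @return List with `accuracy`, `recall`, `precision`, `f_score`,
#'   `confusion` (2x2 integer matrix), `threshold`,
#'   `precision_undefined`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(scores) < 1) stop("empty input")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
                      dimnames = list(actual = c("neg", "pos"),
                                      predicted = c("neg", "pos")))
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision_undefined <- (tp + fp) == 0
  precision <- if (precision_undefined) 0 else tp / (tp + fp)
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  if (precision_undefined) {
    warning("no positive predictions at threshold ", threshold,
            "; precision reported as 0")
  }
  list(accuracy = (tp + tn) / length(labels), recall = recall,
       precision = precision, f_score = f_score, confusion = confusion,
       threshold = threshold, precision_undefined = precision_undefined)
}

#' Per-feature two-sample t-tests between classes
#'
#' Classical independent two-sample t-test (equal-variance/pooled by
#' default, Welch optionally) for each feature, comparing EGFR-mutant vs
#' wild-type patients; two-sided p-values with significance flags at 0.05
#' and 0.001. The t statistic is signed as (mean of class 1) minus (mean of
#' class 0), so swapping the groups negates t and preserves p.
#'
#' @param table A [feature_table()] or numeric matrix (patients x features).
#' @param labels 0/1 vector or label data.frame aligned with the rows.
#' @param var_equal Pooled-variance (Student) test if TRUE (default), Welch
#'   otherwise.
#' @return data.frame with columns `feature`, `t`, `p`, `sig_05`,
#'   `sig_001`.
#' @export
two_sample_t <- function(table, labels, var_equal = TRUE) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  y <- if (is.data.frame(labels)) labels$egfr else labels
  if (length(y) != nrow(x)) stop("labels not aligned with table")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2) stop("need >= 2 samples per class")
  x1 <- x[y == 1, , drop = FALSE]
  x0 <- x[y == 0, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(x0^2) - n0 * m0^2) / (n0 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    if (any(sp2 < 1e-300)) stop("degenerate (zero) variance in feature(s)")
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    if (any(se < 1e-150)) stop("degenerate (zero) variance in feature(s)")
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(feature = colnames(x), t = unname(t), p = unname(p),
             sig_05 = unname(p < 0.05), sig_001 = unname(p < 0.001),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble an evaluation report for one model on one cohort
#'
#' Computes AUC, hard-label metrics at the stated threshold, the ROC curve
#' and the confusion matrix from a vector of scores, packaging them with
#' model and cohort identifiers.
#'
#' @param scores Model scores (probabilities or decision values), higher =
#'   more likely mutant.
#' @param labels 0/1 labels (or data.frame) aligned with scores.
#' @param model_id,cohort_id Identifier strings recorded in the report.
#' @param threshold Hard-label threshold (default 0.5).
#' @return An object of class `eval_report`: list with `model`, `cohort`,
#'   `n`, `accuracy`, `auc`, `recall`, `precision`, `f_score`,
#'   `roc_points`, `confusion`, `threshold`, `precision_undefined`.
#' @export
make_report <- function(scores, labels, model_id = "model",
                        cohort_id = "cohort", threshold = 0.5) {
  y <- if (is.data.frame(labels)) labels$egfr else labels
  tm <- threshold_metrics(scores, y, threshold)
  structure(
    list(model = model_id, cohort = cohort_id, n = length(y),
         accuracy = tm$accuracy, auc = auc_score(scores, y),
         recall = tm$recall, precision = tm$precision,
         f_score = tm$f_score, roc_points = roc_points(scores, y),
         confusion = tm$confusion, threshold = threshold,
         precision_undefined = tm$precision_undefined),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s on %s (n=%d)\n  accuracy %.3f | AUC %.3f | recall %.3f | precision %.3f | F %.3f\n",
    x$model, x$cohort, x$n, x$accuracy, x$auc, x$recall, x$precision,
    x$f_score))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An [make_report()] result.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- unclass(report)
  out$confusion <- list(tn = out$confusion[1, 1], fp = out$confusion[1, 2],
                        fn = out$confusion[2, 1], tp = out$confusion[2, 2])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
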