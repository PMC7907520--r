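#' Random-forest mean-decrease-impurity feature importance
#'
#' Scores every feature by the Gini mean decrease impurity (MDI) of a random
#' forest grown on the supplied cohort, normalized to sum to 1, and returns
#' the features in descending-score order with ties broken by ascending
#' feature name. This is the selection step that feeds both the 2D feature
#' mapping (top 784) and the classical ML baselines (top 50).
#'
#' Importance must be computed on the development (train + validation)
#' cohort only, never on held-out test patients; pass the table and labels
#' already restricted to that split (e.g. via [align_cohort()] /
#' [split_cohort()]).
#'
#' Columns are internally reordered by feature name before the forest is
#' grown, so the scores are invariant to the column order of the input
#' table.
#'
#' @param table A [feature_table()], rows restricted to the development
#'   split.
#' @param labels Label data.frame aligned with `table` (or a 0/1 vector).
#' @param n_trees Number of trees. Many trees (default 500) stabilize the
#'   importance estimates.
#' @param seed Integer seed for the forest.
#' @return An object of class `importance_ranking`: a data.frame with
#'   columns `feature`, `score` (normalized, sums to 1) and `rank` (1 =
#'   highest score), sorted by rank.
#' @export
rf_importance <- function(table, labels, n_trees = 500, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  y <- if (is.data.frame(labels)) labels$egfr else labels
  if (length(y) != nrow(table$values)) stop("labels not aligned with table")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (n_trees < 1) stop("n_trees must be >= 1")
  x <- table$values[, order(colnames(table$values)), drop = FALSE]
  fit <- ranger::ranger(
    x = x, y = factor(y, levels = c(0, 1)),
    num.trees = as.integer(n_trees),
    importance = "impurity",
    seed = as.integer(seed),
    num.threads = 1
  )
  score <- fit$variable.importance
  total <- sum(score)
  if (total > 0) score <- score / total
  ord <- order(-score, names(score))
  out <- data.frame(
    feature = names(score)[ord],
    score = unname(score[ord]),
    rank = seq_along(score),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("importance_ranking", "data.frame"))
}

#' Select the top-k features of an importance ranking
#'
#' @param ranking An `importance_ranking` from [rf_importance()].
#' @param k Number of features to keep, `1 <= k <=` number of features.
#' @return An object of class `selected_features`: list with `names`
#'   (rank-ordered, element 1 = highest score) and `k`.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "importance_ranking"))
  k <- as.integer(k)
  if (k < 1 || k > nrow(ranking)) {
    stop("k must be between 1 and ", nrow(ranking))
  }
  structure(
    list(names = ranking$feature[seq_len(k)], k = k),
    class = "selected_features"
  )
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features> top %d features; head: %s\n",
              x$k, paste(utils::head(x$names, 3), collapse = ", ")))
  invisible(x)
}

#' Group and channel composition of a feature selection
#'
#' Summarizes how many selected features fall in each feature group (shape,
#' firstorder, glcm, gldm, glrlm, glszm) and each image channel, with
#' percentages — the usual way a selection is reported (e.g. "614 of 784
#' selected features are texture features").
#'
#' @param selected A [select_top_k()] result or a character vector of
#'   feature names.
#' @return List of two data.frames `by_group` and `by_channel`, each with
#'   columns `level`, `count`, `percent`; counts sum to k, percents to 100.
#' @export
group_composition <- function(selected) {
  names <- if (inherits(selected, "selected_features")) selected$names else selected
  desc <- parse_feature_names(names)
  k <- length(names)
  tab_of <- function(values, levels) {
    counts <- table(factor(values, levels = levels))
    data.frame(
      level = names(counts), count = as.integer(counts),
      percent = 100 * as.integer(counts) / k,
      stringsAsFactors = FALSE
    )
  }
  list(
    by_group = tab_of(desc$group, .FEATURE_GROUPS),
    by_channel = tab_of(desc$channel, .FEATURE_CHANNELS)
  )
}

#' Persist / load an importance ranking as CSV
#'
#' @param ranking An `importance_ranking`.
#' @param path File path.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "importance_ranking"))
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "score", "rank") %in% names(df)))
  structure(df[order(df$rank), ], class = c("importance_ranking", "data.frame"))
}
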