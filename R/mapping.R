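#' Fit a per-feature z-score normalizer on the training split
#'
#' Radiomics features live on wildly different scales (voxel volumes vs.
#' entropies), so each selected feature is standardized to zero mean and
#' unit SD before being placed in the mapping. Statistics are estimated on
#' the training split only and then applied unchanged to validation and test
#' patients, so no test-set information leaks into the transform.
#'
#' @param table A [feature_table()].
#' @param feature_names Features to retain (e.g. `selected$names`).
#' @param train_ids Patient ids of the training split (default: all rows).
#' @return An object of class `feature_normalizer`: data.frame with columns
#'   `feature`, `mean`, `sd` in the order of `feature_names`.
#' @export
fit_normalizer <- function(table, feature_names, train_ids = rownames(table$values)) {
  stopifnot(inherits(table, "feature_table"))
  if (length(train_ids) == 0) stop("empty training split")
  missing_ids <- setdiff(train_ids, rownames(table$values))
  if (length(missing_ids) > 0) stop("unknown train ids: ", missing_ids[1], " ...")
  missing_f <- setdiff(feature_names, colnames(table$values))
  if (length(missing_f) > 0) stop("unknown feature(s): ", missing_f[1], " ...")
  x <- table$values[train_ids, feature_names, drop = FALSE]
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  if (any(sd < 1e-12)) {
    stop("zero-variance feature(s) in training split: ",
         paste(utils::head(feature_names[sd < 1e-12], 3), collapse = ", "))
  }
  structure(
    data.frame(feature = feature_names, mean = unname(mu), sd = unname(sd),
               stringsAsFactors = FALSE),
    class = c("feature_normalizer", "data.frame")
  )
}

#' Apply a fitted normalizer
#'
#' @param table A [feature_table()].
#' @param normalizer A [fit_normalizer()] result.
#' @return Numeric matrix, patients x normalizer features, z-scored with the
#'   stored (training) statistics.
#' @export
normalize_features <- function(table, normalizer) {
  stopifnot(inherits(table, "feature_table"), inherits(normalizer, "feature_normalizer"))
  x <- table$values[, normalizer$feature, drop = FALSE]
  sweep(sweep(x, 2, normalizer$mean, "-"), 2, normalizer$sd, "/")
}

#' Center-out counterclockwise spiral layout
#'
#' Assigns importance ranks to cells of a side x side grid so that rank 0
#' (the most important feature) sits at the center and ranks grow outward
#' ring by ring: the Chebyshev distance from the start cell never decreases
#' with rank. The walk starts at 0-based cell `(side/2 - 1, side/2 - 1)` for
#' even side and the exact center for odd side, first steps right (col + 1),
#' and turns counterclockwise (right, up, left, down) with run lengths
#' 1, 1, 2, 2, 3, 3, ...; cells falling outside the grid are skipped. The
#' layout is a pure function of `side` and is persisted alongside trained
#' models so mappings are reproducible.
#'
#' @param side Grid side, >= 1.
#' @return An object of class `spiral_layout`: data.frame with columns
#'   `rank` (0-based), `row`, `col` (0-based), one row per cell, ordered by
#'   rank; attribute `side`.
#' @export
#' @examples
#' spiral_layout(3)
spiral_layout <- function(side) {
  side <- as.integer(side)
  if (is.na(side) || side < 1) stop("side must be >= 1")
  start <- if (side %% 2 == 0) side %/% 2 - 1L else (side - 1L) %/% 2
  # direction order: right, up, left, down (counterclockwise)
  dr <- c(0L, -1L, 0L, 1L)
  dc <- c(1L, 0L, -1L, 0L)
  n_cells <- side * side
  rows <- integer(n_cells); cols <- integer(n_cells)
  r <- start; c <- start
  filled <- 0L
  in_grid <- function(r, c) r >= 0L && r < side && c >= 0L && c < side
  if (in_grid(r, c)) { filled <- 1L; rows[1] <- r; cols[1] <- c }
  dir <- 1L; run <- 1L; leg <- 0L
  while (filled < n_cells) {
    for (step in seq_len(run)) {
      r <- r + dr[dir]; c <- c + dc[dir]
      if (in_grid(r, c)) {
        filled <- filled + 1L
        rows[filled] <- r; cols[filled] <- c
        if (filled == n_cells) break
      }
    }
    leg <- leg + 1L
    dir <- dir %% 4L + 1L
    if (leg %% 2L == 0L) run <- run + 1L
  }
  structure(
    data.frame(rank = 0:(n_cells - 1L), row = rows, col = cols),
    side = side,
    class = c("spiral_layout", "data.frame")
  )
}

#' @export
print.spiral_layout <- function(x, ...) {
  side <- attr(x, "side")
  cat(sprintf("<spiral_layout> side %d (%d cells), start cell (%d, %d)\n",
              side, nrow(x), x$row[1], x$col[1]))
  invisible(x)
}

#' Render a spiral layout as a rank matrix
#'
#' @param layout A [spiral_layout()].
#' @return side x side integer matrix whose `[row+1, col+1]` entry is the
#'   rank placed in that cell.
#' @export
layout_matrix <- function(layout) {
  side <- attr(layout, "side")
  m <- matrix(NA_integer_, side, side)
  m[cbind(layout$row + 1L, layout$col + 1L)] <- layout$rank
  m
}

#' Build per-patient feature mappings
#'
#' Places the normalized value of the rank-r selected feature into the
#' spiral cell of rank r, producing one side x side image per patient — the
#' CNN input. Requires `side^2 == k` (alternative sides such as 24 or 32 are
#' alternative selections of k, not padding).
#'
#' @param table A [feature_table()] containing all selected features.
#' @param selected A [select_top_k()] result (rank-ordered names).
#' @param normalizer A [fit_normalizer()] over exactly the selected features.
#' @param layout A [spiral_layout()] with `side^2 == selected$k`.
#' @return An object of class `feature_map_set`: list with `values` (array
#'   side x side x n_patients), `side`, `patient_ids`, `feature_names`
#'   (rank-ordered), `layout`, `normalizer`.
#' @export
build_feature_maps <- function(table, selected, normalizer, layout) {
  stopifnot(inherits(selected, "selected_features"),
            inherits(layout, "spiral_layout"))
  side <- attr(layout, "side")
  if (side * side != selected$k) {
    stop("side^2 (", side * side, ") must equal k (", selected$k, ")")
  }
  if (!identical(normalizer$feature, selected$names)) {
    stop("normalizer must cover exactly the selected features, in rank order")
  }
  z <- normalize_features(table, normalizer)  # n x k, columns in rank order
  n <- nrow(z)
  pos <- layout$col * side + layout$row + 1L  # linear cell index per rank
  values <- array(0, dim = c(side, side, n))
  offs <- (seq_len(n) - 1L) * side * side
  for (i in seq_len(n)) values[pos + offs[i]] <- z[i, ]
  structure(
    list(values = values, side = side,
         patient_ids = rownames(z), feature_names = selected$names,
         layout = layout, normalizer = normalizer),
    class = "feature_map_set"
  )
}

#' @export
print.feature_map_set <- function(x, ...) {
  cat(sprintf("<feature_map_set> %d mappings of %dx%d (%d features)\n",
              length(x$patient_ids), x$side, x$side, length(x$feature_names)))
  invisible(x)
}

#' Invert feature mappings back to a feature matrix
#'
#' The rank-to-cell layout is a bijection, so a mapping can be unmapped
#' exactly: returns the normalized feature matrix (patients x features in
#' rank order) that produced it.
#'
#' @param maps A [build_feature_maps()] result.
#' @return Numeric matrix n_patients x k with rank-ordered feature columns.
#' @export
unmap_features <- function(maps) {
  stopifnot(inherits(maps, "feature_map_set"))
  side <- maps$side
  pos <- maps$layout$col * side + maps$layout$row + 1L
  n <- length(maps$patient_ids)
  out <- matrix(0, n, side * side,
                dimnames = list(maps$patient_ids, maps$feature_names))
  offs <- (seq_len(n) - 1L) * side * side
  for (i in seq_len(n)) out[i, ] <- maps$values[pos + offs[i]]
  out
}

#' Which feature sits in a given cell
#'
#' @param maps A [build_feature_maps()] result.
#' @param row,col 0-based cell coordinates.
#' @return The feature name mapped to that cell.
#' @export
cell_feature <- function(maps, row, col) {
  stopifnot(inherits(maps, "feature_map_set"))
  hit <- maps$layout$rank[maps$layout$row == row & maps$layout$col == col]
  if (length(hit) != 1) stop("cell (", row, ", ", col, ") outside the grid")
  maps$feature_names[hit + 1L]
}

#' Persist a layout (rank, row, col, feature name) as CSV
#'
#' @param layout A [spiral_layout()].
#' @param feature_names Optional rank-ordered feature names to include.
#' @param path File path.
#' @export
write_layout <- function(layout, path, feature_names = NULL) {
  df <- as.data.frame(layout)
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == nrow(df))
    df$feature_name <- feature_names
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
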