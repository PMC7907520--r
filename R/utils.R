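#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps every stochastic step reproducible from an explicit seed without
# clobbering the user's random stream.
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Stratified train/validation split
#'
#' Splits indices into two disjoint sets, preserving the label proportions
#' (per-class rounding) and seeded for reproducibility.
#'
#' @param labels 0/1 vector.
#' @param fraction Fraction assigned to the second (validation/test) set.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
stratified_split <- function(labels, fraction, seed) {
  stopifnot(fraction > 0, fraction < 1)
  idx <- seq_along(labels)
  with_rng_seed(seed, {
    val <- integer(0)
    for (cl in sort(unique(labels))) {
      cl_idx <- idx[labels == cl]
      n_val <- max(1L, round(length(cl_idx) * fraction))
      val <- c(val, sample(cl_idx, n_val))
    }
    val <- sort(val)
    list(train = setdiff(idx, val), val = val)
  })
}

#' Split a cohort into development and held-out test sets
#'
#' Mirrors the usual radiogenomics protocol: a development cohort (used for
#' feature selection and model fitting, internally re-split into train and
#' validation) and a held-out internal test cohort.
#'
#' @param patient_ids Character vector of patient ids.
#' @param labels 0/1 vector aligned with `patient_ids`.
#' @param n_test Number of patients held out for testing (alternatively a
#'   fraction in (0,1)).
#' @param seed Integer seed.
#' @param stratify Preserve class balance across the two sets.
#' @return List with character vectors `dev_ids` and `test_ids`.
#' @export
split_cohort <- function(patient_ids, labels, n_test, seed, stratify = TRUE) {
  stopifnot(length(patient_ids) == length(labels))
  n <- length(patient_ids)
  if (n_test > 0 && n_test < 1) n_test <- round(n * n_test)
  n_test <- as.integer(n_test)
  stopifnot(n_test >= 1, n_test < n)
  fraction <- n_test / n
  if (stratify) {
    sp <- stratified_split(labels, fraction, seed)
    test_idx <- sp$val
  } else {
    test_idx <- with_rng_seed(seed, sort(sample(n, n_test)))
  }
  list(
    dev_ids = patient_ids[setdiff(seq_len(n), test_idx)],
    test_ids = patient_ids[test_idx]
  )
}
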