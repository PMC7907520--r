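#' Configuration for a synthetic radiogenomic cohort
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' large table of correlated, mostly uninformative Gaussian features in which
#' a minority of features carry a class-conditional mean shift. Defaults
#' mirror a mid-size single-center cohort: 700 patients, 1000 features of
#' which 30 are informative with a standardized shift of 1.5 SD, features
#' correlated in equicorrelated blocks of 10 with correlation 0.5, and
#' balanced classes.
#'
#' @param n_patients Number of patients.
#' @param n_features Number of radiomics features (must not exceed the
#'   catalog size for the given roster).
#' @param n_informative Number of features given a class-mean shift.
#' @param effect_size Standardized mean difference d between classes on each
#'   informative feature (in units of the pooled within-class SD).
#' @param block_size Size of the equicorrelated feature blocks.
#' @param block_rho Within-block correlation, in `[0, 1)`.
#' @param class_balance P(label = 1), in (0, 1).
#' @param male_prob_pos,male_prob_neg P(male) given label 1 / label 0; the
#'   defaults reproduce a male-skewed mutant class. Set both equal for
#'   uninformative gender.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 700, n_features = 1000,
                       n_informative = 30, effect_size = 1.5,
                       block_size = 10, block_rho = 0.5,
                       class_balance = 0.5,
                       male_prob_pos = 0.577, male_prob_neg = 0.324,
                       seed = 1) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_features = as.integer(n_features),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    block_size = as.integer(block_size), block_rho = block_rho,
    class_balance = class_balance,
    male_prob_pos = male_prob_pos, male_prob_neg = male_prob_neg,
    seed = as.integer(seed)
  )
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (cfg$n_features < 1) stop("n_features must be >= 1")
  if (cfg$n_informative > cfg$n_features) stop("n_informative > n_features")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) stop("block_rho must be in [0, 1)")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1) {
    stop("class_balance must be in (0, 1)")
  }
  if (cfg$block_size < 1) stop("block_size must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic cohort
#'
#' Draws labels Bernoulli(`class_balance`); features are unit-variance
#' Gaussians in equicorrelated blocks (correlation `block_rho` within each
#' block of `block_size` consecutive features). A seeded random subset of
#' `n_informative` features receives a class-conditional mean shift of
#' `effect_size` pooled SDs (+d/2 for class 1, -d/2 for class 0), so the
#' informative set is spread across feature groups and image channels.
#' Feature names are drawn from the catalog convention, so the full selection
#' -> mapping -> classification pipeline runs on the output unchanged.
#' Clinical covariates: age is Gaussian (class means 60.2 / 58.6, SD 10,
#' floored at 18); gender is Bernoulli with a class-dependent male
#' probability; subtype is sampled from the 8 adenocarcinoma growth-pattern
#' categories with class-dependent frequencies.
#'
#' @param config A [sim_config()].
#' @param metrics Metric roster passed to [feature_catalog()].
#' @return List with elements `table` (a [feature_table()]), `labels`
#'   (data.frame `patient_id`, `egfr`), `clinical` (data.frame), and
#'   `informative` (character vector of the planted feature names).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 40, n_features = 50,
#'                                      n_informative = 5, seed = 7))
#' dim(cohort$table)
simulate_cohort <- function(config = sim_config(),
                            metrics = default_metric_roster()) {
  stopifnot(inherits(config, "sim_config"))
  cat_df <- feature_catalog(metrics)
  if (config$n_features > nrow(cat_df)) {
    stop("n_features exceeds catalog size (", nrow(cat_df), ")")
  }
  n <- config$n_patients
  p <- config$n_features
  with_rng_seed(config$seed, {
    feat_names <- sort(sample(cat_df$name, p))
    informative <- sort(sample(feat_names, config$n_informative))
    labels <- stats::rbinom(n, 1L, config$class_balance)

    # Equicorrelated blocks: x = sqrt(rho) * g_block + sqrt(1-rho) * e,
    # unit marginal variance, correlation rho within a block.
    n_blocks <- ceiling(p / config$block_size)
    block_of <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(p)]
    g <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    e <- matrix(stats::rnorm(n * p), n, p)
    x <- sqrt(config$block_rho) * g[, block_of, drop = FALSE] +
      sqrt(1 - config$block_rho) * e
    colnames(x) <- feat_names
    shift <- ifelse(labels == 1L, config$effect_size / 2, -config$effect_size / 2)
    inf_idx <- match(informative, feat_names)
    x[, inf_idx] <- x[, inf_idx] + shift

    ids <- sprintf("P%04d", seq_len(n))
    rownames(x) <- ids

    age <- pmax(18, stats::rnorm(n, mean = ifelse(labels == 1L, 60.2, 58.6), sd = 10))
    male_p <- ifelse(labels == 1L, config$male_prob_pos, config$male_prob_neg)
    gender <- ifelse(stats::runif(n) < male_p, "male", "female")
    # Subtype frequencies patterned on a LADC cohort: APA dominant, mutant
    # class enriched for LPA/APA, wild-type for SPA/PPA.
    subtype_p_pos <- c(AIS = 5, MIA = 27, LPA = 63, APA = 208, PPA = 51,
                       MPA = 15, SPA = 8, IMA = 5)
    subtype_p_neg <- c(AIS = 17, MIA = 45, LPA = 15, APA = 96, PPA = 66,
                       MPA = 21, SPA = 49, IMA = 18)
    subtype <- character(n)
    is_pos <- labels == 1L
    subtype[is_pos] <- sample(names(subtype_p_pos), sum(is_pos), replace = TRUE,
                              prob = subtype_p_pos)
    subtype[!is_pos] <- sample(names(subtype_p_neg), sum(!is_pos), replace = TRUE,
                               prob = subtype_p_neg)

    list(
      table = feature_table(x),
      labels = data.frame(patient_id = ids, egfr = as.integer(labels),
                          stringsAsFactors = FALSE),
      clinical = data.frame(patient_id = ids, age = age, gender = gender,
                            subtype = subtype, stringsAsFactors = FALSE),
      informative = informative
    )
  })
}
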