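#' Encode clinical covariates as a numeric feature matrix
#'
#' Gender is a fixed bit (male = 1, female = 0); age is z-scored with
#' statistics estimated on a reference (training) set; the histopathological
#' subtype is one-hot encoded over the 8 adenocarcinoma growth-pattern
#' categories (AIS, MIA, LPA, APA, PPA, MPA, SPA, IMA). A cohort lacking
#' subtype annotation entirely gets all-zero subtype columns, so internal
#' and external cohorts share one encoding.
#'
#' @param clinical Clinical data.frame (`patient_id`, `age`, `gender`,
#'   optional `subtype`).
#' @param age_stats Optional list with `mean` and `sd` for the age z-score
#'   (pass the training-set values when encoding a test set); default:
#'   estimated from `clinical`.
#' @return List with `x` (numeric matrix, rownames = patient ids) and
#'   `age_stats` (the statistics used).
#' @export
encode_clinical <- function(clinical, age_stats = NULL) {
  validate_clinical(clinical)
  if (is.null(age_stats)) {
    age_stats <- list(mean = mean(clinical$age), sd = stats::sd(clinical$age))
  }
  if (age_stats$sd < 1e-12) stop("degenerate age variance")
  gender <- as.numeric(clinical$gender == "male")
  age_z <- (clinical$age - age_stats$mean) / age_stats$sd
  sub_mat <- matrix(0, nrow(clinical), length(.LADC_SUBTYPES),
                    dimnames = list(NULL, paste0("subtype_", .LADC_SUBTYPES)))
  if ("subtype" %in% names(clinical)) {
    known <- !is.na(clinical$subtype)
    sub_mat[cbind(which(known),
                  match(clinical$subtype[known], .LADC_SUBTYPES))] <- 1
  }
  x <- cbind(gender_male = gender, age = age_z, sub_mat)
  rownames(x) <- clinical$patient_id
  list(x = x, age_stats = age_stats)
}

#' Classical machine-learning baseline specification
#'
#' The comparator models: SVM (RBF kernel, C = 3, gamma = 1), random forest
#' with 4 trees, and an MLP with two hidden layers of 10 and 5 ReLU units
#' trained with Adam — each on the radiomics feature set (top-50 selected
#' features, z-scored), the clinical covariates, or both concatenated.
#'
#' @param classifier `"svm"`, `"rf"` or `"mlp"`.
#' @param feature_set `"radiomics"`, `"clinical"` or `"combined"`.
#' @param hyperparameters Named list overriding the defaults
#'   (`svm`: `cost = 3`, `gamma = 1`; `rf`: `ntree = 4`;
#'   `mlp`: `hidden = c(10, 5)`, `learning_rate = 0.001`,
#'   `batch_size = 50`, `max_epochs = 200`, `tol = 1e-4`,
#'   `n_iter_no_change = 10`).
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(classifier = c("svm", "rf", "mlp"),
                          feature_set = c("radiomics", "clinical", "combined"),
                          hyperparameters = list()) {
  classifier <- match.arg(classifier)
  feature_set <- match.arg(feature_set)
  defaults <- switch(classifier,
    svm = list(cost = 3, gamma = 1),
    rf = list(ntree = 4),
    mlp = list(hidden = c(10, 5), learning_rate = 0.001, batch_size = 50,
               max_epochs = 200, tol = 1e-4, n_iter_no_change = 10)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(classifier = classifier, feature_set = feature_set,
                 hyperparameters = hp),
            class = "baseline_spec")
}

#' Fit a baseline classifier
#'
#' Trains the classifier named by `spec` on a numeric feature matrix and
#' returns an object whose `predict` method yields scores usable for ROC
#' analysis (higher = more likely EGFR-mutant). The SVM score is the signed
#' decision value oriented toward the positive class (rank-equivalent to
#' any calibrated probability, which is all AUC needs); the RF score is the
#' positive-class vote fraction; the MLP outputs a sigmoid probability.
#'
#' @param spec A [baseline_spec()].
#' @param x Numeric matrix, patients x features (already encoded/z-scored).
#' @param labels 0/1 vector or label data.frame aligned with `x`.
#' @param seed Integer seed (rf and mlp are stochastic).
#' @return An object of class `baseline_model`.
#' @export
fit_baseline <- function(spec, x, labels, seed = 1) {
  stopifnot(inherits(spec, "baseline_spec"))
  x <- as.matrix(x)
  y <- if (is.data.frame(labels)) labels$egfr else labels
  if (length(y) != nrow(x)) stop("feature/label length mismatch")
  if (length(unique(y)) < 2) stop("both classes must be present")
  hp <- spec$hyperparameters
  fit <- switch(spec$classifier,
    svm = {
      m <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", cost = hp$cost, gamma = hp$gamma,
                      scale = FALSE)
      dv <- attr(stats::predict(m, x, decision.values = TRUE),
                 "decision.values")[, 1]
      # orient the decision value so larger means class 1
      flip <- if (auc_score(dv, y) < 0.5) -1 else 1
      list(model = m, flip = flip)
    },
    rf = {
      m <- with_rng_seed(seed,
        randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                   ntree = hp$ntree))
      list(model = m)
    },
    mlp = {
      list(model = fit_mlp(x, y, hp, seed))
    }
  )
  structure(list(spec = spec, fit = fit, feature_names = colnames(x)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  scores <- switch(object$spec$classifier,
    svm = {
      dv <- attr(stats::predict(object$fit$model, x, decision.values = TRUE),
                 "decision.values")[, 1]
      object$fit$flip * dv
    },
    rf = stats::predict(object$fit$model, x, type = "prob")[, "1"],
    mlp = predict_mlp(object$fit$model, x)
  )
  names(scores) <- rownames(x)
  scores
}

# Two-hidden-layer ReLU MLP with a sigmoid output, trained by minibatch
# Adam on mean BCE with sklearn-style stopping (train loss improvement
# below tol for n_iter_no_change consecutive epochs).
fit_mlp <- function(x, y, hp, seed) {
  d <- ncol(x)
  h1 <- hp$hidden[1]; h2 <- hp$hidden[2]
  with_rng_seed(seed, {
    params <- list(
      W1 = matrix(stats::rnorm(h1 * d, sd = sqrt(2 / d)), h1, d),
      b1 = numeric(h1),
      W2 = matrix(stats::rnorm(h2 * h1, sd = sqrt(2 / h1)), h2, h1),
      b2 = numeric(h2),
      W3 = matrix(stats::rnorm(h2, sd = sqrt(1 / h2)), 1, h2),
      b3 = 0
    )
    state <- adam_init(params)
    n <- nrow(x)
    xt <- t(x)
    best <- Inf
    stall <- 0L
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[start:min(start + hp$batch_size - 1L, n)]
        xb <- xt[, idx, drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        a1p <- params$W1 %*% xb + params$b1; a1 <- pmax(a1p, 0)
        a2p <- params$W2 %*% a1 + params$b2; a2 <- pmax(a2p, 0)
        pr <- as.vector(sigmoid(params$W3 %*% a2 + params$b3))
        ep_loss <- ep_loss + bce_loss(pr, yb, reduce = "sum")
        dlog <- matrix((pr - yb) / nb, 1, nb)
        g <- list()
        g$W3 <- tcrossprod(dlog, a2); g$b3 <- sum(dlog)
        da2 <- crossprod(params$W3, dlog) * (a2p > 0)
        g$W2 <- tcrossprod(da2, a1); g$b2 <- rowSums(da2)
        da1 <- crossprod(params$W2, da2) * (a1p > 0)
        g$W1 <- tcrossprod(da1, xb); g$b1 <- rowSums(da1)
        upd <- adam_step(params, g, state, hp$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      ep_loss <- ep_loss / n
      if (ep_loss < best - hp$tol) {
        best <- ep_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= hp$n_iter_no_change) break
      }
    }
    list(params = params)
  })
}

predict_mlp <- function(model, x) {
  p <- model$params
  a1 <- pmax(p$W1 %*% t(x) + p$b1, 0)
  a2 <- pmax(p$W2 %*% a1 + p$b2, 0)
  as.vector(sigmoid(p$W3 %*% a2 + p$b3))
}
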