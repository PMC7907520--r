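#' Default end-to-end pipeline configuration
#'
#' A nested list mirroring the stages: `data` (either `simulate` = args for
#' [sim_config()], or `paths` with `features`/`labels`/`clinical` CSVs),
#' `split` (held-out test size and seed), `selection` (k, n_trees, seed;
#' `k` must be a perfect square — it is the mapping side squared),
#' `model` (kind and [train_config()] args), `baselines` (enable flag and
#' the smaller k used for the classical models), and `threshold`.
#'
#' @return Nested named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    data = list(simulate = list()),
    split = list(n_test = 71, seed = 11),
    selection = list(k = 784, n_trees = 500, seed = 21),
    model = list(kind = "secnn", init_seed = 31,
                 train = list(seed = 41)),
    baselines = list(enabled = FALSE, k = 50, seed = 51),
    threshold = 0.5
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Executes the workflow end to end: obtain a cohort (simulated or loaded
#' from CSV), hold out a test set, rank features by random-forest impurity
#' importance on the development cohort only, select the top k, fit the
#' z-score normalizer on the development cohort, build the spiral feature
#' mappings, train the chosen deep model with early stopping, and evaluate
#' on the held-out test set (plus the classical baselines if enabled). All
#' artifacts are written under `output_dir` with a manifest recording the
#' config hash and seeds; a rerun with an identical config reproduces
#' identical reports.
#'
#' @param config Nested list (see [default_pipeline_config()]; partial
#'   configs are merged over the defaults) or the path to a YAML file with
#'   the same structure.
#' @param output_dir Directory for artifacts; created if missing. `NULL`
#'   (default) skips writing.
#' @return List with the cohort split, ranking, selection composition,
#'   trained model, test predictions and `eval_report`s, invisibly.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)

  k <- cfg$selection$k
  side <- as.integer(round(sqrt(k)))
  if (side * side != k) {
    stop("validation error: selection k (", k, ") must be a perfect square")
  }

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$data$paths)) {
    table <- read_feature_table(cfg$data$paths$features)
    labels <- read_label_table(cfg$data$paths$labels)
    clinical <- if (!is.null(cfg$data$paths$clinical)) {
      read_clinical_table(cfg$data$paths$clinical)
    }
    cohort <- align_cohort(table, labels, clinical)
  } else {
    sim <- simulate_cohort(do.call(sim_config, cfg$data$simulate))
    cohort <- list(table = sim$table, labels = sim$labels,
                   clinical = sim$clinical)
  }
  ids <- rownames(cohort$table$values)
  y <- cohort$labels$egfr

  # --- split --------------------------------------------------------------
  sp <- split_cohort(ids, y, cfg$split$n_test, cfg$split$seed)
  dev_idx <- match(sp$dev_ids, ids)
  test_idx <- match(sp$test_ids, ids)
  dev_table <- feature_table(cohort$table$values[dev_idx, , drop = FALSE])

  # --- selection (development cohort only) --------------------------------
  ranking <- rf_importance(dev_table, y[dev_idx],
                           n_trees = cfg$selection$n_trees,
                           seed = cfg$selection$seed)
  selected <- select_top_k(ranking, k)
  composition <- group_composition(selected)

  # --- mapping ------------------------------------------------------------
  normalizer <- fit_normalizer(cohort$table, selected$names,
                               train_ids = sp$dev_ids)
  layout <- spiral_layout(side)
  maps <- build_feature_maps(cohort$table, selected, normalizer, layout)

  # --- deep model ---------------------------------------------------------
  model <- build_model(cfg$model$kind,
                       config = conv_stack_config_for(cfg$model, side),
                       seed = cfg$model$init_seed)
  tc <- do.call(train_config, cfg$model$train)
  inner <- stratified_split(y[dev_idx], tc$validation_fraction, tc$seed)
  split <- list(train = dev_idx[inner$train], val = dev_idx[inner$val])
  trained <- train_model(model, maps, y, tc, split = split)

  test_scores <- predict(trained, maps)[test_idx]
  reports <- list(
    test = make_report(test_scores, y[test_idx],
                       model_id = cfg$model$kind, cohort_id = "internal_test",
                       threshold = cfg$threshold)
  )

  # --- baselines ----------------------------------------------------------
  baseline_models <- NULL
  if (isTRUE(cfg$baselines$enabled)) {
    kb <- cfg$baselines$k
    sel_b <- select_top_k(ranking, kb)
    norm_b <- fit_normalizer(cohort$table, sel_b$names, train_ids = sp$dev_ids)
    xb <- normalize_features(cohort$table, norm_b)
    enc <- encode_clinical(cohort$clinical[dev_idx, , drop = FALSE])
    enc_all <- encode_clinical(cohort$clinical, age_stats = enc$age_stats)
    sets <- list(radiomics = xb, clinical = enc_all$x,
                 combined = cbind(xb, enc_all$x))
    specs <- list(
      list(classifier = "svm", feature_set = "radiomics"),
      list(classifier = "rf", feature_set = "radiomics"),
      list(classifier = "mlp", feature_set = "radiomics"),
      list(classifier = "svm", feature_set = "clinical"),
      list(classifier = "svm", feature_set = "combined")
    )
    baseline_models <- list()
    for (s in specs) {
      spec <- baseline_spec(s$classifier, s$feature_set)
      xs <- sets[[s$feature_set]]
      fit <- fit_baseline(spec, xs[dev_idx, , drop = FALSE], y[dev_idx],
                          seed = cfg$baselines$seed)
      sc <- predict(fit, xs[test_idx, , drop = FALSE])
      id <- paste(s$feature_set, s$classifier, sep = "_")
      baseline_models[[id]] <- fit
      reports[[id]] <- make_report(sc, y[test_idx], model_id = id,
                                   cohort_id = "internal_test",
                                   threshold = if (s$classifier == "svm") 0
                                               else cfg$threshold)
    }
  }

  result <- list(config = cfg, split = sp, ranking = ranking,
                 selected = selected, composition = composition,
                 normalizer = normalizer, layout = layout, maps = maps,
                 model = trained, test_scores = test_scores,
                 reports = reports, baselines = baseline_models)

  if (!is.null(output_dir)) {
    write_pipeline_artifacts(result, output_dir)
  }
  invisible(result)
}

conv_stack_config_for <- function(model_cfg, side) {
  args <- model_cfg$conv_stack
  if (is.null(args)) args <- list()
  args$input_side <- side
  if (model_cfg$kind == "cnn1d") {
    defaults <- list(filters = c(16, 32), kernel_size = 9, pool_size = 4,
                     pool_kinds = c("max", "avg"), use_se = FALSE)
    args <- merge_config(defaults, args)
  } else if (model_cfg$kind == "cnn") {
    args$use_se <- FALSE
  }
  do.call(conv_stack_config, args)
}

write_pipeline_artifacts <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(output_dir, ...)
  write_ranking(result$ranking, fp("ranking.csv"))
  write_layout(result$layout, fp("layout.csv"),
               feature_names = result$selected$names)
  utils::write.csv(as.data.frame(result$normalizer), fp("normalizer.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$model$history, fp("history.csv"), row.names = FALSE)
  for (nm in names(result$reports)) {
    write_report(result$reports[[nm]], fp(paste0("report_", nm, ".json")))
  }
  summary <- list(
    model = result$config$model$kind,
    n_dev = length(result$split$dev_ids),
    n_test = length(result$split$test_ids),
    k = result$selected$k,
    side = attr(result$layout, "side"),
    stopped_epoch = result$model$stopped_epoch,
    best_epoch = result$model$best_epoch,
    composition_by_group = result$composition$by_group,
    metrics = lapply(result$reports, function(r) {
      list(accuracy = r$accuracy, auc = r$auc, recall = r$recall,
           precision = r$precision, f_score = r$f_score)
    })
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  manifest <- list(
    package = "radiomap",
    version = as.character(utils::packageVersion("radiomap")),
    config_hash = config_hash(result$config),
    seeds = list(split = result$config$split$seed,
                 selection = result$config$selection$seed,
                 model_init = result$config$model$init_seed,
                 train = result$config$model$train$seed),
    artifacts = c("ranking.csv", "layout.csv", "normalizer.csv",
                  "history.csv", "summary.json")
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(output_dir)
}

#' Write a simulated cohort to CSV files
#'
#' Convenience front-end for the generator: writes `features.csv`,
#' `labels.csv` and `clinical.csv` under `output_dir`.
#'
#' @param config A [sim_config()].
#' @param output_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulated_cohort <- function(config = sim_config(), output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  paths <- c(
    features = file.path(output_dir, "features.csv"),
    labels = file.path(output_dir, "labels.csv"),
    clinical = file.path(output_dir, "clinical.csv")
  )
  write_feature_table(sim$table, paths["features"])
  utils::write.csv(sim$labels, paths["labels"], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$clinical, paths["clinical"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
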