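test_that("importance scores are normalized, deterministic and column-order invariant", {
  fx <- make_separable_table(n = 120, p = 30, seed = 4)
  rk <- rf_importance(fx$table, fx$labels, n_trees = 100, seed = 9)
  expect_equal(sum(rk$score), 1, tolerance = 1e-9)
  expect_true(all(rk$score >= 0))
  expect_identical(rk, rf_importance(fx$table, fx$labels, n_trees = 100, seed = 9))

  # permuting the feature columns permutes scores identically
  perm <- sample(ncol(fx$table$values))
  tab_perm <- feature_table(fx$table$values[, perm])
  rk_perm <- rf_importance(tab_perm, fx$labels, n_trees = 100, seed = 9)
  expect_identical(rk, rk_perm)

  expect_error(rf_importance(fx$table, rep(1L, 120), n_trees = 10), "both classes")
  expect_error(rf_importance(fx$table, fx$labels, n_trees = 0), "n_trees")
})

test_that("a perfectly separating feature wins rank 1 across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    fx <- make_separable_table(n = 200, p = 50, seed = seed)
    rk <- rf_importance(fx$table, fx$labels, n_trees = 100, seed = seed)
    hits <- hits + (rk$feature[1] == fx$separating)
  }
  expect_gte(hits, 19L)
})

test_that("permuting labels dethrones the separating feature", {
  fx <- make_separable_table(n = 200, p = 50, seed = 1)
  dethroned <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    y_perm <- sample(fx$labels)
    rk <- rf_importance(fx$table, y_perm, n_trees = 100, seed = rep)
    dethroned <- dethroned + (rk$feature[1] != fx$separating)
  }
  expect_gt(dethroned, 10L)
})

test_that("select_top_k honors ranking order, bounds and alphabetic tie-break", {
  fx <- make_separable_table(n = 60, p = 20, seed = 2)
  rk <- rf_importance(fx$table, fx$labels, n_trees = 50, seed = 3)
  all_sel <- select_top_k(rk, nrow(rk))
  expect_equal(all_sel$names, rk$feature)
  top5 <- select_top_k(rk, 5)
  expect_equal(top5$names, rk$feature[1:5])
  expect_equal(top5$k, 5L)
  expect_error(select_top_k(rk, 0), "between")
  expect_error(select_top_k(rk, 21), "between")

  # tie-break: equal scores sort by ascending name (same rule rf_importance uses)
  score <- c("glcm_Id" = 0.35, "glcm_Contrast" = 0.35, "gldm_GrayLevelVariance" = 0.3)
  ord <- order(-score, names(score))
  expect_equal(names(score)[ord][1:2], c("glcm_Contrast", "glcm_Id"))
})

test_that("selection power for planted features grows with effect size", {
  prob_in_topk <- vapply(c(0, 0.5, 1.5), function(d) {
    hit <- 0
    for (rep in 1:10) {
      cohort <- simulate_cohort(sim_config(
        n_patients = 150, n_features = 60, n_informative = 6,
        effect_size = d, seed = 1000 * d + rep))
      rk <- rf_importance(cohort$table, cohort$labels$egfr,
                          n_trees = 100, seed = rep)
      top <- select_top_k(rk, 10)$names
      hit <- hit + mean(cohort$informative %in% top)
    }
    hit / 10
  }, numeric(1))
  expect_true(all(diff(prob_in_topk) > 0))
  expect_gt(prob_in_topk[3], 0.8)
})

test_that("group composition partitions the selection and matches a plant", {
  nms <- c("original_glcm_Contrast", "wavelet-LLL_glcm_Id",
           "original_shape_MeshVolume", "log-sigma-1_firstorder_Mean",
           "wavelet-LLL_glszm_ZoneEntropy")
  comp <- group_composition(nms)
  expect_equal(sum(comp$by_group$count), 5L)
  expect_equal(sum(comp$by_channel$count), 5L)
  expect_equal(sum(comp$by_group$percent), 100, tolerance = 0.1)
  gc <- setNames(comp$by_group$count, comp$by_group$level)
  expect_equal(gc[["glcm"]], 2L)
  expect_equal(gc[["shape"]], 1L)
  expect_equal(gc[["firstorder"]], 1L)
  expect_equal(gc[["glszm"]], 1L)
  cc <- setNames(comp$by_channel$count, comp$by_channel$level)
  expect_equal(cc[["wavelet-LLL"]], 2L)
  expect_equal(cc[["original"]], 2L)

  all_fo <- paste0("original_firstorder_F", 1:7)
  comp_fo <- group_composition(all_fo)
  expect_equal(setNames(comp_fo$by_group$count, comp_fo$by_group$level)[["firstorder"]], 7L)
  expect_equal(max(comp_fo$by_group$percent), 100)

  expect_error(group_composition("garbage"), "cannot parse")
})

test_that("rankings persist to CSV and back", {
  fx <- make_separable_table(n = 60, p = 10, seed = 8)
  rk <- rf_importance(fx$table, fx$labels, n_trees = 50, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranking(rk, path)
  back <- read_ranking(path)
  expect_equal(back$feature, rk$feature)
  expect_equal(back$score, rk$score, tolerance = 1e-12)
})
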