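test_that("catalog enumerates the channel x group taxonomy deterministically", {
  cat_df <- feature_catalog()
  expect_equal(length(unique(cat_df$channel)), 12)
  expect_equal(sum(grepl("^wavelet-", unique(cat_df$channel))), 8)
  expect_equal(sum(grepl("^log-sigma-", unique(cat_df$channel))), 3)
  expect_equal(sort(unique(cat_df$group)),
               sort(c("shape", "firstorder", "glcm", "gldm", "glrlm", "glszm")))
  # shape only on the original channel
  expect_true(all(cat_df$channel[cat_df$group == "shape"] == "original"))
  # determinism
  expect_identical(cat_df, feature_catalog())

  # one metric per group: 1 shape + 5 groups x 12 channels
  one <- lapply(default_metric_roster(), function(m) m[1])
  expect_equal(nrow(feature_catalog(one)), 1 + 5 * 12)

  bad <- default_metric_roster()
  bad$shape <- character(0)
  expect_error(feature_catalog(bad), "empty metric list")
  dup <- default_metric_roster()
  dup$glcm <- c("Contrast", "Contrast")
  expect_error(feature_catalog(dup), "duplicate metric")
})

test_that("feature names parse and format as inverses", {
  cat_df <- feature_catalog()
  parsed <- parse_feature_names(cat_df$name)
  expect_equal(parsed$channel, cat_df$channel)
  expect_equal(parsed$group, cat_df$group)
  expect_equal(parsed$metric, cat_df$metric)
  expect_equal(format_feature_name(parsed$channel, parsed$group, parsed$metric),
               cat_df$name)

  # original channel may be omitted on read
  p <- parse_feature_names("glcm_Contrast")
  expect_equal(p$channel, "original")
  expect_equal(p$metric, "Contrast")
  p2 <- parse_feature_names("wavelet-HLL_glcm_MaximumProbability")
  expect_equal(p2$channel, "wavelet-HLL")
  expect_equal(p2$group, "glcm")

  expect_error(parse_feature_names("nonsense"), "cannot parse")
  expect_error(parse_feature_names("wavelet-HLL_shape_MeshVolume"),
               "original-channel only")
  expect_error(format_feature_name("wavelet-HLL", "shape", "MeshVolume"),
               "original")
})

test_that("feature tables validate, round-trip through CSV, and reject bad input", {
  x <- matrix(c(1.5, 2.25, -3, 4e6, 0.001, 7), 2, 3,
              dimnames = list(c("a", "b"),
                              c("glcm_Contrast", "shape_MeshVolume",
                                "wavelet-LLL_firstorder_Mean")))
  tab <- feature_table(x)
  expect_equal(dim(tab), c(2L, 3L))

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_identical(back$features, tab$features)
  # header column count = id + features
  expect_equal(length(strsplit(readLines(path, n = 1), ",")[[1]]), 4)

  x_na <- x; x_na[1, 2] <- NA
  expect_error(feature_table(x_na), "missing")
  x_inf <- x; x_inf[1, 2] <- Inf
  expect_error(feature_table(x_inf), "non-finite")
  expect_error(feature_table(x, patient_ids = c("a", "a")), "duplicate patient")
  expect_error(feature_table(x[0, , drop = FALSE], patient_ids = character(0)),
               "empty")

  # header-only CSV
  writeLines("patient_id,glcm_Contrast", path)
  expect_error(read_feature_table(path), "empty table")
  # non-numeric cell
  writeLines(c("patient_id,glcm_Contrast", "a,oops"), path)
  expect_error(read_feature_table(path), "non-numeric")
})

test_that("align_cohort restricts to the id intersection in table order", {
  x <- matrix(rnorm(12), 4, 3,
              dimnames = list(c("p1", "p2", "p3", "p4"),
                              c("glcm_Contrast", "glcm_Id", "gldm_GrayLevelVariance")))
  tab <- feature_table(x)
  labels <- data.frame(patient_id = c("p4", "p2", "p1", "p3"),
                       egfr = c(1L, 0L, 1L, 0L))
  clin <- data.frame(patient_id = c("p3", "p1", "p2", "p4"),
                     age = c(60, 55, 70, 48),
                     gender = c("male", "female", "male", "female"))

  al <- align_cohort(tab, labels, clin)
  expect_equal(rownames(al$table$values), c("p1", "p2", "p3", "p4"))
  expect_equal(al$labels$patient_id, rownames(al$table$values))
  expect_equal(al$clinical$patient_id, rownames(al$table$values))
  expect_equal(al$labels$egfr, c(1L, 0L, 0L, 1L))

  # strict subset of labels
  al2 <- align_cohort(tab, labels[1:2, ])
  expect_equal(nrow(al2$table$values), 2)

  labels_disjoint <- data.frame(patient_id = c("q1", "q2"), egfr = c(0L, 1L))
  expect_error(align_cohort(tab, labels_disjoint), "empty")
})
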