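#' Radiomics feature catalog and name conventions
#'
#' Radiomics features are identified by a name of the form
#' `"<channel>_<group>_<Metric>"`, e.g.
#' `"wavelet-HLL_glcm_MaximumProbability"`. The channel is the image the
#' feature was computed on: the original CT image, one of the eight wavelet
#' decompositions (low/high pass along each of three axes: LLL ... HHH), or a
#' Laplacian-of-Gaussian filtered image at sigma 1, 2 or 3. The group is one
#' of six feature families: lesion shape, first-order intensity statistics,
#' and four texture-matrix families (GLCM, GLDM, GLRLM, GLSZM). Shape
#' features are geometric and therefore exist only for the original channel.
#'
#' On reading, a name without a recognized channel prefix is taken to be an
#' `original`-channel feature (`"glcm_Contrast"` ==
#' `"original_glcm_Contrast"`); names are always written with the channel
#' explicit.
#'
#' @name feature-names
NULL

.FEATURE_CHANNELS <- c(
  "original",
  "wavelet-LLL", "wavelet-LLH", "wavelet-LHL", "wavelet-LHH",
  "wavelet-HLL", "wavelet-HLH", "wavelet-HHL", "wavelet-HHH",
  "log-sigma-1", "log-sigma-2", "log-sigma-3"
)

.FEATURE_GROUPS <- c("shape", "firstorder", "glcm", "gldm", "glrlm", "glszm")

#' Default per-group metric roster
#'
#' A conventional roster of base metrics per feature group, patterned on the
#' usual radiomics extractor output (the exact roster is extractor-version
#' dependent and is configurable; the taxonomy, not the count, is fixed).
#'
#' @return Named list mapping each of the six groups to a character vector of
#'   metric names.
#' @export
default_metric_roster <- function() {
  list(
    shape = c(
      "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
      "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
      "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
      "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
      "VoxelVolume"
    ),
    firstorder = c(
      "10Percentile", "90Percentile", "Energy", "Entropy",
      "InterquartileRange", "Kurtosis", "Maximum", "Mean",
      "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
      "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
      "TotalEnergy", "Uniformity", "Variance"
    ),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
      "SumEntropy", "SumSquares"
    ),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"
    ),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"
    ),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"
    )
  )
}

#' Enumerate the radiomics feature catalog
#'
#' Builds the full descriptor table for a per-group metric roster: shape
#' metrics on the original channel only, every other group crossed with all
#' 12 image channels (original + 8 wavelet + 3 LoG). Order is deterministic:
#' channel, then group, then metric, each in canonical order.
#'
#' @param metrics Named list, one character vector of metric names per group
#'   (see [default_metric_roster()]). Every group must have at least one
#'   metric.
#' @return A data.frame with columns `name`, `channel`, `group`, `metric`.
#' @export
#' @examples
#' cat_df <- feature_catalog()
#' nrow(cat_df)
#' table(cat_df$group)
feature_catalog <- function(metrics = default_metric_roster()) {
  missing_groups <- setdiff(.FEATURE_GROUPS, names(metrics))
  if (length(missing_groups) > 0) {
    stop("metric roster missing group(s): ", paste(missing_groups, collapse = ", "))
  }
  for (g in .FEATURE_GROUPS) {
    m <- metrics[[g]]
    if (length(m) < 1) stop("group '", g, "' has an empty metric list")
    if (anyDuplicated(m)) stop("duplicate metric name within group '", g, "'")
  }
  rows <- list()
  for (ch in .FEATURE_CHANNELS) {
    groups_here <- if (ch == "original") .FEATURE_GROUPS else setdiff(.FEATURE_GROUPS, "shape")
    for (g in groups_here) {
      m <- sort(metrics[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, group = g, metric = m, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$name <- format_feature_name(out$channel, out$group, out$metric)
  rownames(out) <- NULL
  out[, c("name", "channel", "group", "metric")]
}

#' Compose a feature name from its parts
#'
#' @param channel,group,metric Character vectors (recycled to a common
#'   length).
#' @return Character vector of names `"<channel>_<group>_<Metric>"`.
#' @export
format_feature_name <- function(channel, group, metric) {
  ok_ch <- channel %in% .FEATURE_CHANNELS
  if (!all(ok_ch)) stop("unknown channel: ", paste(unique(channel[!ok_ch]), collapse = ", "))
  ok_g <- group %in% .FEATURE_GROUPS
  if (!all(ok_g)) stop("unknown group: ", paste(unique(group[!ok_g]), collapse = ", "))
  if (any(group == "shape" & channel != "original")) {
    stop("shape features exist only on the original channel")
  }
  paste(channel, group, metric, sep = "_")
}

#' Parse feature names into (channel, group, metric)
#'
#' Accepts names with or without the `original` channel prefix. Unknown base
#' metrics are tolerated; the channel and group must parse.
#'
#' @param names Character vector of feature names.
#' @return A data.frame with columns `name`, `channel`, `group`, `metric`.
#' @export
parse_feature_names <- function(names) {
  if (anyNA(names) || any(!nzchar(names))) stop("empty feature name")
  parts <- strsplit(names, "_", fixed = TRUE)
  parse_one <- function(nm, p) {
    if (p[1] %in% .FEATURE_CHANNELS) {
      channel <- p[1]
      p <- p[-1]
    } else {
      channel <- "original"
    }
    if (length(p) < 2 || !(p[1] %in% .FEATURE_GROUPS)) {
      stop("cannot parse feature name '", nm, "': no recognizable group")
    }
    group <- p[1]
    if (group == "shape" && channel != "original") {
      stop("invalid feature name '", nm, "': shape is original-channel only")
    }
    c(channel, group, paste(p[-1], collapse = "_"))
  }
  mat <- t(mapply(parse_one, names, parts, USE.NAMES = FALSE))
  data.frame(
    name = names, channel = mat[, 1], group = mat[, 2], metric = mat[, 3],
    stringsAsFactors = FALSE
  )
}

#' Construct a feature table
#'
#' A feature table is the pipeline's universal currency: a numeric matrix of
#' patients (rows) by named radiomics features (columns), with no missing and
#' no non-finite values. Patients for whom features could not be extracted
#' are expected to be excluded upstream; a table with missing cells is
#' rejected, never imputed.
#'
#' @param values Numeric matrix, rows = patients, columns = features.
#' @param patient_ids Character vector of unique patient ids (defaults to
#'   `rownames(values)`).
#' @param feature_names Character vector of unique feature names (defaults to
#'   `colnames(values)`).
#' @return An object of class `feature_table` with elements `values`
#'   (the named matrix) and `features` (descriptor data.frame from
#'   [parse_feature_names()]).
#' @export
feature_table <- function(values, patient_ids = rownames(values),
                          feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(patient_ids)) stop("patient ids are required")
  if (is.null(feature_names)) stop("feature names are required")
  if (nrow(values) == 0) stop("empty table: no patients")
  if (ncol(values) == 0) stop("empty table: no features")
  patient_ids <- as.character(patient_ids)
  feature_names <- as.character(feature_names)
  if (length(patient_ids) != nrow(values)) stop("patient_ids length mismatch")
  if (length(feature_names) != ncol(values)) stop("feature_names length mismatch")
  if (anyDuplicated(patient_ids)) stop("duplicate patient id")
  if (anyDuplicated(feature_names)) stop("duplicate feature name")
  if (!is.numeric(values)) stop("non-numeric feature values")
  if (anyNA(values)) stop("missing feature values are not allowed (no imputation)")
  if (any(!is.finite(values))) stop("non-finite feature values")
  dimnames(values) <- list(patient_ids, feature_names)
  structure(
    list(values = values, features = parse_feature_names(feature_names)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d patients x %d features (%d channels, %d groups)\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$features$channel)), length(unique(x$features$group))
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read / write a feature table as CSV
#'
#' The on-disk format is UTF-8 CSV with a header row; the first column is
#' `patient_id`, remaining columns are feature names. Values are written with
#' 17 significant digits so a write/read round trip reproduces the matrix to
#' well below 1e-12.
#'
#' @param path File path.
#' @return For `read_feature_table`, a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table: file has a header but no rows")
  if (ncol(df) < 2) stop("empty table: no feature columns")
  if (names(df)[1] != "patient_id") {
    stop("first column must be 'patient_id', got '", names(df)[1], "'")
  }
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      stop("non-numeric cell(s) in feature column '", names(vals)[j], "'")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  feature_table(m)
}

#' @param table A [feature_table()].
#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(
    patient_id = rownames(table$values),
    signif(table$values, 17),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write label and clinical tables
#'
#' Labels are a CSV with columns `patient_id` and `egfr` (1 = mutant /
#' EGFR(+), 0 = wild type / EGFR(-)). Clinical covariates are a CSV with
#' columns `patient_id`, `age` (years), `gender` (`male`/`female`) and
#' optionally `subtype` (one of the 8 adenocarcinoma growth-pattern
#' subtypes, possibly absent for a whole cohort).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_labels(df)
  df
}

#' @rdname read_label_table
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
  df
}

.LADC_SUBTYPES <- c("AIS", "MIA", "LPA", "APA", "PPA", "MPA", "SPA", "IMA")

validate_labels <- function(labels) {
  if (!all(c("patient_id", "egfr") %in% names(labels))) {
    stop("label table needs columns patient_id, egfr")
  }
  if (anyDuplicated(labels$patient_id)) stop("duplicate patient id in labels")
  if (!all(labels$egfr %in% c(0L, 1L))) stop("egfr labels must be 0/1")
  invisible(labels)
}

validate_clinical <- function(clinical) {
  need <- c("patient_id", "age", "gender")
  if (!all(need %in% names(clinical))) {
    stop("clinical table needs columns patient_id, age, gender")
  }
  if (anyDuplicated(clinical$patient_id)) stop("duplicate patient id in clinical table")
  if (!is.numeric(clinical$age) || any(clinical$age <= 0)) stop("age must be positive")
  if (!all(clinical$gender %in% c("male", "female"))) {
    stop("gender must be 'male' or 'female'")
  }
  if ("subtype" %in% names(clinical)) {
    st <- clinical$subtype[!is.na(clinical$subtype)]
    if (!all(st %in% .LADC_SUBTYPES)) {
      stop("unknown subtype value(s): ",
           paste(setdiff(unique(st), .LADC_SUBTYPES), collapse = ", "))
    }
  }
  invisible(clinical)
}

#' Align a feature table with labels (and clinical covariates)
#'
#' Restricts all inputs to the intersection of their patient ids and puts
#' them in the same (feature-table) order, so that row i refers to the same
#' patient everywhere downstream.
#'
#' @param table A [feature_table()].
#' @param labels Label data.frame (`patient_id`, `egfr`).
#' @param clinical Optional clinical data.frame.
#' @return List with elements `table`, `labels` and (if given) `clinical`,
#'   all row-aligned.
#' @export
align_cohort <- function(table, labels, clinical = NULL) {
  stopifnot(inherits(table, "feature_table"))
  validate_labels(labels)
  ids <- intersect(rownames(table$values), labels$patient_id)
  if (!is.null(clinical)) {
    validate_clinical(clinical)
    ids <- intersect(ids, clinical$patient_id)
  }
  if (length(ids) == 0) stop("empty patient id intersection")
  ids <- rownames(table$values)[rownames(table$values) %in% ids]
  out <- list(
    table = feature_table(table$values[ids, , drop = FALSE]),
    labels = labels[match(ids, labels$patient_id), , drop = FALSE]
  )
  rownames(out$labels) <- NULL
  if (!is.null(clinical)) {
    out$clinical <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
    rownames(out$clinical) <- NULL
  }
  out
}
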