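#' Construct a SpiralFeatures cohort container
#'
#' @param values numeric matrix, samples x features, with feature names as
#'   column names (a features x samples matrix is also accepted when
#'   `byRow = FALSE`).
#' @param labels per-sample class labels (`"ET"` / `"CONTROL"` /
#'   `"UNKNOWN"`).
#' @param subjectIds per-sample identifiers (defaults to `s1`, `s2`, ...).
#' @param byRow `TRUE` (default) when `values` rows are samples.
#' @return a [SpiralFeatures-class].
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(NULL, paste0("F", 1:5)))
#' sf <- SpiralFeatures(m, labels = c("ET", "ET", "CONTROL", "CONTROL"))
#' featureMatrix(sf)
#' @export
SpiralFeatures <- function(values, labels, subjectIds = NULL, byRow = TRUE) {
  values <- as.matrix(values)
  if (byRow) values <- t(values)
  nSamples <- ncol(values)
  if (length(labels) != nSamples)
    stop("labels must have one entry per sample")
  if (is.null(subjectIds)) subjectIds <- paste0("s", seq_len(nSamples))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  colnames(values) <- subjectIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    colData = S4Vectors::DataFrame(subject_id = as.character(subjectIds),
                                   label = as.character(labels)))
  new("SpiralFeatures", se)
}

#' Feature matrix of a cohort (samples x features)
#'
#' @param x a [SpiralFeatures-class].
#' @return numeric matrix with samples in rows and named feature columns.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "SpiralFeatures"))
  t(SummarizedExperiment::assay(x, "features"))
}

#' Per-sample class labels of a cohort
#'
#' @param x a [SpiralFeatures-class].
#' @return character vector of labels.
#' @export
sampleLabels <- function(x) {
  stopifnot(is(x, "SpiralFeatures"))
  as.character(SummarizedExperiment::colData(x)$label)
}

#' Per-sample identifiers of a cohort
#'
#' @param x a [SpiralFeatures-class].
#' @return character vector of subject ids.
#' @export
subjectIds <- function(x) {
  stopifnot(is(x, "SpiralFeatures"))
  as.character(SummarizedExperiment::colData(x)$subject_id)
}

#' Subset a cohort to named features
#'
#' @param x a [SpiralFeatures-class].
#' @param features character vector of feature (row) names, kept in the
#'   given order.
#' @return a [SpiralFeatures-class] restricted to those features.
#' @export
selectFeatures <- function(x, features) {
  stopifnot(is(x, "SpiralFeatures"))
  missing <- setdiff(features, rownames(x))
  if (length(missing))
    stop("unknown features: ", paste(missing, collapse = ", "))
  x[features, ]
}

#' Write a cohort feature matrix as CSV
#'
#' One row per sample with `subject_id`, `label` and the named feature
#' columns, 10 significant digits.
#'
#' @param x a [SpiralFeatures-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureCsv <- function(x, path) {
  fm <- featureMatrix(x)
  df <- data.frame(subject_id = subjectIds(x), label = sampleLabels(x),
                   signif(fm, 10), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort feature matrix from CSV
#'
#' Inverse of [writeFeatureCsv()].
#'
#' @param path CSV path with `subject_id`, `label` and feature columns.
#' @return a [SpiralFeatures-class].
#' @export
readFeatureCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "label") %in% colnames(df)))
  featCols <- setdiff(colnames(df), c("subject_id", "label"))
  SpiralFeatures(as.matrix(df[, featCols, drop = FALSE]),
                 labels = df$label, subjectIds = df$subject_id)
}

setMethod("show", "SpiralFeatures", function(object) {
  lab <- sampleLabels(object)
  cat(sprintf("SpiralFeatures: %d features x %d samples (%d ET, %d CONTROL)\n",
              nrow(object), ncol(object), sum(lab == "ET"),
              sum(lab == "CONTROL")))
  cat("features:", paste(utils::head(rownames(object), 8), collapse = ", "),
      if (nrow(object) > 8) "...", "\n")
})
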