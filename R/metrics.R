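#' Construct a confusion matrix from counts
#'
#' @param TP,FN,FP,TN non-negative counts; essential tremor (ET) is the
#'   positive class, so TP = ET predicted ET and TN = control predicted
#'   control.
#' @return a [ConfusionMatrix-class].
#' @examples
#' cm <- confusionMatrix(TP = 21, FN = 0, FP = 1, TN = 27)
#' accuracy(cm)     # 97.959...
#' sensitivity(cm)  # 100
#' specificity(cm)  # 96.428...
#' @export
confusionMatrix <- function(TP, FN, FP, TN) {
  new("ConfusionMatrix", TP = as.integer(TP), FN = as.integer(FN),
      FP = as.integer(FP), TN = as.integer(TN))
}

#' Tally a confusion matrix from labels
#'
#' @param truth,predicted equal-length label vectors using `"ET"` /
#'   `"CONTROL"`.
#' @return a [ConfusionMatrix-class] with ET as the positive class.
#' @export
confusionFromPredictions <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), c("ET", "CONTROL"))
  if (length(bad))
    stop("labels must be ET or CONTROL; found: ", paste(bad, collapse = ", "))
  confusionMatrix(TP = sum(truth == "ET" & predicted == "ET"),
                  FN = sum(truth == "ET" & predicted == "CONTROL"),
                  FP = sum(truth == "CONTROL" & predicted == "ET"),
                  TN = sum(truth == "CONTROL" & predicted == "CONTROL"))
}

#' @describeIn sensitivity 100 * TP / (TP + FN); errors when no actual
#'   positives exist.
#' @export
setMethod("sensitivity", "ConfusionMatrix", function(x) {
  if (x@TP + x@FN == 0) stop("sensitivity undefined: no actual positives")
  100 * x@TP / (x@TP + x@FN)
})

#' @describeIn specificity 100 * TN / (TN + FP); errors when no actual
#'   negatives exist.
#' @export
setMethod("specificity", "ConfusionMatrix", function(x) {
  if (x@TN + x@FP == 0) stop("specificity undefined: no actual negatives")
  100 * x@TN / (x@TN + x@FP)
})

#' @describeIn accuracy 100 * (TP + TN) / total.
#' @export
setMethod("accuracy", "ConfusionMatrix", function(x) {
  total <- x@TP + x@FN + x@FP + x@TN
  100 * (x@TP + x@TN) / total
})

#' @describeIn sensitivity of the tallied predictions.
#' @export
setMethod("sensitivity", "CVResult", function(x) sensitivity(x@confusion))

#' @describeIn specificity of the tallied predictions.
#' @export
setMethod("specificity", "CVResult", function(x) specificity(x@confusion))

#' @describeIn accuracy of the tallied predictions.
#' @export
setMethod("accuracy", "CVResult", function(x) x@accuracy)

#' Confusion matrix of a CV result
#'
#' @param x a [CVResult-class].
#' @return the [ConfusionMatrix-class] tallied from its predictions.
#' @export
confusion <- function(x) {
  stopifnot(is(x, "CVResult"))
  x@confusion
}

#' JSON-ready metrics report
#'
#' @param cm a [ConfusionMatrix-class] or [CVResult-class].
#' @param config optional configuration list to embed.
#' @return a list with TP, FN, FP, TN, accuracy, sensitivity, specificity
#'   and config, suitable for `jsonlite::write_json()`.
#' @export
metricsReport <- function(cm, config = list()) {
  if (is(cm, "CVResult")) {
    if (!length(config)) config <- cm@config
    cm <- cm@confusion
  }
  stopifnot(is(cm, "ConfusionMatrix"))
  list(TP = cm@TP, FN = cm@FN, FP = cm@FP, TN = cm@TN,
       accuracy = accuracy(cm), sensitivity = sensitivity(cm),
       specificity = specificity(cm), config = config)
}
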