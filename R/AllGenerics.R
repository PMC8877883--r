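#' @rdname GrayImage-class
#' @param x,object a package object.
#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))

#' @rdname BinaryMask-class
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname GrayHistogram-class
#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))

#' @rdname GrayHistogram-class
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("tStar", function(x) standardGeneric("tStar"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("objectiveCurve", function(x) standardGeneric("objectiveCurve"))

#' @rdname MCETConfig-class
#' @export
setGeneric("configId", function(x) standardGeneric("configId"))

#' Average of the segmentation scores present
#'
#' The unweighted arithmetic mean of the scores that are available:
#' the three unsupervised scores always, plus the three supervised scores
#' when a ground-truth mask was supplied.
#'
#' @param x an [EvaluationReport-class], or a numeric vector of scores in
#'   which \code{NA} marks an absent score.
#' @return a single number in \code{[0, 1]}.
#' @examples
#' averageScore(c(0.6, 0.75, 0.7, NA, NA, NA))
#' @export
setGeneric("averageScore", function(x) standardGeneric("averageScore"))

#' Mean of a histogram mode under a chosen estimator
#'
#' Dispatches to the filter named by an [EstimatorSpec-class]: classical,
#' geometric, harmonic, contra-harmonic (order \code{Q}) or alpha-trimmed
#' (trim \code{dHalf} per tail).
#'
#' @param region a [ModeRegion-class].
#' @param spec an [EstimatorSpec-class].
#' @return the mean on the shifted index scale, or \code{NA} when the mean
#'   is undefined (empty region).
#' @seealso [classicalMean()], [geometricMean()], [harmonicMean()],
#'   [contraharmonicMean()], [alphaTrimMean()]
#' @export
setGeneric("regionMean", function(region, spec) standardGeneric("regionMean"))

## ---- accessors ----

#' @rdname GrayImage-class
#' @export
setMethod("pixelMatrix", "GrayImage", function(x) x@pixels)

#' @rdname BinaryMask-class
#' @export
setMethod("maskMatrix", "BinaryMask", function(x) x@labels)

#' @rdname GrayHistogram-class
#' @export
setMethod("histCounts", "GrayHistogram", function(x) {
    stats::setNames(x@counts, 0:255)
})

#' @rdname GrayHistogram-class
#' @export
setMethod("nPixels", "GrayHistogram", function(x) x@nPixels)

#' @rdname ThresholdResult-class
#' @export
setMethod("tStar", "ThresholdResult", function(x) x@tStar)

#' @rdname ThresholdResult-class
#' @export
setMethod("objectiveValue", "ThresholdResult", function(x) x@objective)

#' @rdname ThresholdResult-class
#' @export
setMethod("objectiveCurve", "ThresholdResult", function(x) x@objectiveCurve)

#' @rdname MCETConfig-class
#' @export
setMethod("configId", "MCETConfig", function(x) x@configId)

#' @rdname ThresholdResult-class
#' @export
setMethod("configId", "ThresholdResult", function(x) x@config@configId)

#' @rdname EvaluationReport-class
#' @export
setMethod("configId", "EvaluationReport", function(x) x@configId)

#' @rdname EvaluationReport-class
#' @export
setMethod("tStar", "EvaluationReport", function(x) x@tStar)

#' @rdname averageScore
#' @export
setMethod("averageScore", "EvaluationReport", function(x) x@average)

#' @rdname averageScore
#' @export
setMethod("averageScore", "numeric", function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("no scores present to average")
    mean(x)
})

#' Scores of an evaluation report
#'
#' @param x an [EvaluationReport-class].
#' @return named numeric vector (\code{iu}, \code{rc}, \code{disparity},
#'   \code{jaccard}, \code{fscore}, \code{accuracy}); supervised entries are
#'   \code{NA} when no ground truth was supplied.
#' @export
reportScores <- function(x) {
    stopifnot(is(x, "EvaluationReport"))
    x@scores
}

## ---- show methods ----

setMethod("show", "GrayImage", function(object) {
    p <- object@pixels
    cat(sprintf("GrayImage %d x %d, gray range [%d, %d]\n",
                nrow(p), ncol(p), min(p), max(p)))
})

setMethod("show", "BinaryMask", function(object) {
    l <- object@labels
    cat(sprintf("BinaryMask %d x %d, foreground %d / %d pixels\n",
                nrow(l), ncol(l), sum(l == 1L), length(l)))
})

setMethod("show", "GrayHistogram", function(object) {
    occ <- which(object@counts > 0) - 1L
    cat(sprintf(
        "GrayHistogram: %g pixels, %d occupied levels in [%d, %d]\n",
        object@nPixels, length(occ),
        if (length(occ)) min(occ) else NA_integer_,
        if (length(occ)) max(occ) else NA_integer_))
})

setMethod("show", "EstimatorSpec", function(object) {
    cat(estimatorLabel(object), "\n")
})

setMethod("show", "MCETConfig", function(object) {
    cat(sprintf("MCETConfig %d: mu1 = %s | mu2 = %s\n", object@configId,
                estimatorLabel(object@mu1Spec),
                estimatorLabel(object@mu2Spec)))
})

setMethod("show", "ThresholdResult", function(object) {
    cat(sprintf(
        "ThresholdResult: t* = %d (config %d), mu1 = %.3f, mu2 = %.3f, objective = %.6g\n",
        object@tStar, object@config@configId, object@mu1, object@mu2,
        object@objective))
})

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: TP=%g FP=%g FN=%g TN=%g\n",
                object@TP, object@FP, object@FN, object@TN))
})

setMethod("show", "EvaluationReport", function(object) {
    s <- object@scores
    fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.4f", v))
    cat(sprintf(
        "EvaluationReport (config %d, t* = %d): IU=%s RC=%s D=%s J=%s F=%s Acc=%s | avg=%.4f\n",
        object@configId, object@tStar, fmt(s["iu"]), fmt(s["rc"]),
        fmt(s["disparity"]), fmt(s["jaccard"]), fmt(s["fscore"]),
        fmt(s["accuracy"]), object@average))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec %dx%d %s fg, muBg=%g muFg=%g sigma=%g salt=%g pepper=%g seed=%d\n",
        object@height, object@width, object@geometry, object@muBg,
        object@muFg, object@sigma, object@saltDensity,
        object@pepperDensity, object@seed))
})
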