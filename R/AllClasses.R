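#' @import methods
NULL

#' GrayImage: an 8-bit grayscale image
#'
#' A minimal container for a 2-D grayscale raster with integer intensities
#' in \code{[0, 255]}. Rows index image height, columns index width.
#'
#' @slot pixels integer matrix of gray values in \code{[0, 255]}.
#'
#' @seealso [readGrayImage()], [computeHistogram()], [applyThreshold()]
#' @exportClass GrayImage
setClass("GrayImage", representation(pixels = "matrix"))

setValidity("GrayImage", function(object) {
    p <- object@pixels
    if (length(dim(p)) != 2L || nrow(p) < 1L || ncol(p) < 1L)
        return("'pixels' must be a matrix with at least one row and column")
    if (anyNA(p))
        return("'pixels' contains NA")
    if (any(p != as.integer(p)))
        return("'pixels' must hold integer gray values")
    if (min(p) < 0 || max(p) > 255)
        return("gray values must lie in [0, 255]")
    TRUE
})

#' BinaryMask: a two-label segmentation mask
#'
#' Pixel labels are 0 (background) and 1 (foreground), stored as an integer
#' matrix with the same shape as the image it segments.
#'
#' @slot labels integer matrix over \{0, 1\}.
#'
#' @seealso [applyThreshold()], [readMask()], [writeMask()]
#' @exportClass BinaryMask
setClass("BinaryMask", representation(labels = "matrix"))

setValidity("BinaryMask", function(object) {
    l <- object@labels
    if (length(dim(l)) != 2L || nrow(l) < 1L || ncol(l) < 1L)
        return("'labels' must be a matrix with at least one row and column")
    if (anyNA(l) || !all(l %in% c(0L, 1L)))
        return("'labels' must contain only 0 and 1")
    TRUE
})

#' GrayHistogram: 256-bin gray-level histogram
#'
#' Bin \code{i} of \code{counts} holds the number of pixels with gray value
#' \code{g = i - 1}; all mean-filter and cross-entropy computations run on
#' this shifted index \code{i = g + 1} in \code{[1, 256]}, which keeps
#' logarithms and geometric/harmonic means defined at gray level zero.
#' Thresholds are reported back on the 0--255 gray scale.
#'
#' @slot counts numeric vector of 256 non-negative bin counts.
#' @slot nPixels total pixel count (equals \code{sum(counts)}).
#'
#' @seealso [computeHistogram()], [findThreshold()]
#' @exportClass GrayHistogram
setClass("GrayHistogram",
    representation(counts = "numeric", nPixels = "numeric"))

setValidity("GrayHistogram", function(object) {
    if (length(object@counts) != 256L)
        return("'counts' must have exactly 256 bins")
    if (anyNA(object@counts) || any(object@counts < 0))
        return("'counts' must be non-negative")
    if (!isTRUE(all.equal(sum(object@counts), object@nPixels)))
        return("sum(counts) must equal nPixels")
    TRUE
})

#' ModeRegion: one histogram mode as a sorted pixel multiset
#'
#' A contiguous slice \code{[lo, hi]} of the shifted-index histogram,
#' interpreted as the sorted multiset in which intensity level \code{i}
#' appears \code{counts[i - lo + 1]} times. All mean filters evaluate on
#' this weighted representation, which is mathematically identical to the
#' expanded per-pixel vector.
#'
#' @slot lo,hi inclusive slice bounds on the shifted index scale
#'   \code{[1, 256]}.
#' @slot counts bin counts restricted to \code{lo:hi}.
#'
#' @seealso [modeRegion()], [classicalMean()], [regionMean()]
#' @exportClass ModeRegion
setClass("ModeRegion",
    representation(lo = "integer", hi = "integer", counts = "numeric"))

setValidity("ModeRegion", function(object) {
    if (object@lo < 1L || object@hi > 256L || object@lo > object@hi)
        return("bounds must satisfy 1 <= lo <= hi <= 256")
    if (length(object@counts) != object@hi - object@lo + 1L)
        return("'counts' length must match the slice [lo, hi]")
    if (anyNA(object@counts) || any(object@counts < 0))
        return("'counts' must be non-negative")
    TRUE
})

#' EstimatorSpec: one mean-filter approach with its parameter
#'
#' @slot approach one of \code{"classical"}, \code{"geometric"},
#'   \code{"harmonic"}, \code{"contraharmonic"}, \code{"alphatrim"}.
#' @slot Q real order of the contra-harmonic filter (\code{NA} otherwise).
#' @slot dHalf pixels trimmed from each tail by the alpha-trimmed filter,
#'   the usual d/2 (\code{NA} otherwise).
#'
#' @seealso [estimatorSpec()], [regionMean()]
#' @exportClass EstimatorSpec
setClass("EstimatorSpec",
    representation(approach = "character", Q = "numeric", dHalf = "integer"))

.approaches <- c("classical", "geometric", "harmonic",
                 "contraharmonic", "alphatrim")

setValidity("EstimatorSpec", function(object) {
    if (length(object@approach) != 1L || !object@approach %in% .approaches)
        return(paste0("'approach' must be one of: ",
                      paste(.approaches, collapse = ", ")))
    if (object@approach == "contraharmonic" && is.na(object@Q))
        return("contra-harmonic estimator requires an order Q")
    if (object@approach == "alphatrim" &&
        (is.na(object@dHalf) || object@dHalf < 0L))
        return("alpha-trim estimator requires dHalf >= 0")
    TRUE
})

#' MCETConfig: a pair of mean estimators for the two histogram modes
#'
#' @slot mu1Spec estimator for the lower mode (levels at or below the
#'   candidate threshold).
#' @slot mu2Spec estimator for the upper mode.
#' @slot configId integer row index in the configuration table
#'   (0 = classical baseline, 1--32 = heterogeneous rows).
#'
#' @seealso [heterogeneousConfigs()], [homogeneousConfigs()],
#'   [findThreshold()]
#' @exportClass MCETConfig
setClass("MCETConfig",
    representation(mu1Spec = "EstimatorSpec", mu2Spec = "EstimatorSpec",
                   configId = "integer"))

#' ThresholdResult: the outcome of one MCET threshold search
#'
#' @slot tStar optimal threshold on the 0--255 gray scale (smallest
#'   minimizer on plateaus).
#' @slot mu1,mu2 estimated region means at \code{tStar}, on the shifted
#'   index scale.
#' @slot objective the minimized cross-entropy objective value.
#' @slot objectiveCurve the objective at every candidate split
#'   \code{t = 1, ..., 255} of the shifted index scale; \code{Inf} marks
#'   candidates with an empty mode or an undefined mean.
#' @slot config the [MCETConfig-class] that produced the result.
#'
#' @seealso [findThreshold()], [sweepConfigs()]
#' @exportClass ThresholdResult
setClass("ThresholdResult",
    representation(tStar = "integer", mu1 = "numeric", mu2 = "numeric",
                   objective = "numeric", objectiveCurve = "numeric",
                   config = "MCETConfig"))

setValidity("ThresholdResult", function(object) {
    if (length(object@objectiveCurve) != 255L)
        return("'objectiveCurve' must have 255 entries")
    if (object@tStar < 0L || object@tStar > 254L)
        return("'tStar' must lie in [0, 254] on the gray scale")
    TRUE
})

#' ConfusionCounts: pixelwise confusion table of two binary masks
#'
#' @slot TP,FP,FN,TN non-negative pixel counts.
#'
#' @seealso [confusionCounts()], [jaccardIndex()], [fScore()],
#'   [pixelAccuracy()]
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
    representation(TP = "numeric", FP = "numeric",
                   FN = "numeric", TN = "numeric"))

setValidity("ConfusionCounts", function(object) {
    v <- c(object@TP, object@FP, object@FN, object@TN)
    if (anyNA(v) || any(v < 0)) return("counts must be non-negative")
    TRUE
})

#' EvaluationReport: scores of one thresholded segmentation
#'
#' Holds the three unsupervised scores (image uniformity, region contrast,
#' inter-region disparity), the three supervised scores (Jaccard, F-score,
#' accuracy; \code{NA} when no ground truth was supplied), and their
#' unweighted mean over the scores present.
#'
#' @slot configId configuration row the scored threshold came from.
#' @slot tStar the scored threshold (0--255 gray scale).
#' @slot scores named numeric vector with elements \code{iu}, \code{rc},
#'   \code{disparity}, \code{jaccard}, \code{fscore}, \code{accuracy}.
#' @slot average mean of the non-\code{NA} scores.
#'
#' @seealso [evaluateThreshold()], [selectBestThreshold()]
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(configId = "integer", tStar = "integer",
                   scores = "numeric", average = "numeric"))

.scoreNames <- c("iu", "rc", "disparity", "jaccard", "fscore", "accuracy")

setValidity("EvaluationReport", function(object) {
    if (!identical(names(object@scores), .scoreNames))
        return(paste0("'scores' must be named: ",
                      paste(.scoreNames, collapse = ", ")))
    s <- object@scores[!is.na(object@scores)]
    if (length(s) && (min(s) < -1e-12 || max(s) > 1 + 1e-12))
        return("all present scores must lie in [0, 1]")
    TRUE
})

#' PhantomSpec: parameters of a bimodal synthetic phantom
#'
#' Describes a two-region test image: a geometric foreground on a flat
#' background, each region drawn from a Gaussian around its mean gray
#' value, optionally contaminated with impulse (salt/pepper) noise placed
#' uniformly over the whole canvas.
#'
#' @slot height,width canvas size in pixels.
#' @slot geometry \code{"disk"}, \code{"ellipse"} or \code{"rectangle"}.
#' @slot center foreground center \code{c(row, col)}.
#' @slot radii half-extents \code{c(row, col)}; a disk uses \code{radii[1]}.
#' @slot muBg,muFg mean gray values of background and foreground.
#' @slot sigma Gaussian noise standard deviation (gray levels).
#' @slot saltDensity,pepperDensity fractions of pixels forced to 255 / 0.
#' @slot seed RNG seed making generation bit-reproducible.
#'
#' @seealso [phantomSpec()], [generatePhantom()], [bayesThreshold()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(height = "integer", width = "integer",
                   geometry = "character", center = "numeric",
                   radii = "numeric", muBg = "numeric", muFg = "numeric",
                   sigma = "numeric", saltDensity = "numeric",
                   pepperDensity = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (object@height < 1L || object@width < 1L)
        return("canvas must be at least 1x1")
    if (!object@geometry %in% c("disk", "ellipse", "rectangle"))
        return("'geometry' must be disk, ellipse or rectangle")
    if (object@muBg < 0 || object@muBg > 255 ||
        object@muFg < 0 || object@muFg > 255)
        return("region means must lie in [0, 255]")
    if (object@muBg == object@muFg)
        return("'muBg' and 'muFg' must differ")
    if (object@sigma < 0) return("'sigma' must be non-negative")
    if (object@saltDensity < 0 || object@pepperDensity < 0 ||
        object@saltDensity + object@pepperDensity >= 1)
        return("impulse densities must be >= 0 and sum below 1")
    TRUE
})
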