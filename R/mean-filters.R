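## Histogram-domain mean estimators for one mode of a bilevel split.
##
## Each filter evaluates on the mode's sorted pixel multiset: level i
## (shifted index scale, so i >= 1 and logs/reciprocals are defined)
## appears counts[i] times. The histogram-weighted forms below are exact
## equivalents of filtering the expanded pixel vector.

#' Construct a ModeRegion
#'
#' @param counts bin counts of the slice, one entry per level in
#'   \code{lo:hi}.
#' @param lo lower slice bound on the shifted index scale \code{[1, 256]}.
#' @param hi upper bound; defaults to \code{lo + length(counts) - 1}.
#' @return a [ModeRegion-class].
#' @examples
#' ## the multiset {5, 5, 5, 7}
#' modeRegion(c(3, 0, 1), lo = 5)
#' @export
modeRegion <- function(counts, lo = 1L, hi = lo + length(counts) - 1L) {
    new("ModeRegion", lo = as.integer(lo), hi = as.integer(hi),
        counts = as.numeric(counts))
}

#' Split a histogram into its two modes at a candidate threshold
#'
#' @param hist a [GrayHistogram-class].
#' @param t candidate split on the shifted index scale: the lower mode is
#'   \code{[1, t]}, the upper mode \code{[t + 1, 256]}.
#' @return list with elements \code{a} and \code{b}, both
#'   [ModeRegion-class].
#' @export
histModes <- function(hist, t) {
    stopifnot(is(hist, "GrayHistogram"))
    t <- as.integer(t)
    if (t < 1L || t > 255L)
        stop("split index must lie in [1, 255]")
    list(a = modeRegion(hist@counts[1:t], lo = 1L),
         b = modeRegion(hist@counts[(t + 1L):256L], lo = t + 1L))
}

#' @rdname ModeRegion-class
#' @param x a \code{ModeRegion}.
#' @export
regionLength <- function(x) {
    stopifnot(is(x, "ModeRegion"))
    sum(x@counts)
}

setMethod("show", "ModeRegion", function(object) {
    cat(sprintf("ModeRegion [%d, %d], %g pixels\n",
                object@lo, object@hi, sum(object@counts)))
})

.regionLevels <- function(region) seq.int(region@lo, region@hi)

#' Classical (arithmetic) mean of a mode
#'
#' @param region a [ModeRegion-class].
#' @return the arithmetic mean of the mode's pixel multiset, or \code{NA}
#'   if the mode is empty.
#' @examples
#' classicalMean(modeRegion(c(1, 1, 1), lo = 1))  # multiset {1,2,3} -> 2
#' @export
classicalMean <- function(region) {
    stopifnot(is(region, "ModeRegion"))
    n <- sum(region@counts)
    if (n == 0) return(NA_real_)
    sum(.regionLevels(region) * region@counts) / n
}

#' Geometric mean of a mode
#'
#' Computed in log space; well-defined because all levels are >= 1 on the
#' shifted index scale.
#'
#' @inheritParams classicalMean
#' @return the geometric mean, or \code{NA} if the mode is empty.
#' @export
geometricMean <- function(region) {
    stopifnot(is(region, "ModeRegion"))
    n <- sum(region@counts)
    if (n == 0) return(NA_real_)
    exp(sum(region@counts * log(.regionLevels(region))) / n)
}

#' Harmonic mean of a mode
#'
#' Downweights high outliers, which makes it robust to salt impulses in
#' the mode but not to pepper.
#'
#' @inheritParams classicalMean
#' @return the harmonic mean, or \code{NA} if the mode is empty.
#' @export
harmonicMean <- function(region) {
    stopifnot(is(region, "ModeRegion"))
    n <- sum(region@counts)
    if (n == 0) return(NA_real_)
    n / sum(region@counts / .regionLevels(region))
}

#' Contra-harmonic mean of a mode
#'
#' \eqn{\sum c_i i^{Q+1} / \sum c_i i^{Q}}. Positive orders suppress low
#' outliers (pepper), negative orders suppress high outliers (salt);
#' \code{Q = 0} reduces to the classical mean and \code{Q = -1} to the
#' harmonic mean.
#'
#' @inheritParams classicalMean
#' @param Q real order of the filter.
#' @return the contra-harmonic mean, or \code{NA} if the mode is empty or
#'   the denominator vanishes.
#' @export
contraharmonicMean <- function(region, Q) {
    stopifnot(is(region, "ModeRegion"), is.numeric(Q), length(Q) == 1L)
    if (sum(region@counts) == 0) return(NA_real_)
    i <- .regionLevels(region)
    den <- sum(region@counts * i^Q)
    if (!is.finite(den) || den == 0) return(NA_real_)
    num <- sum(region@counts * i^(Q + 1))
    if (!is.finite(num)) return(NA_real_)
    num / den
}

#' Alpha-trimmed mean of a mode
#'
#' Arithmetic mean of the sorted pixel multiset after discarding the
#' \code{dHalf} smallest and \code{dHalf} largest pixels (the usual trim
#' parameter d equals \code{2 * dHalf}). When the mode holds no more than
#' \code{2 * dHalf} pixels, the untrimmed classical mean is returned, so a
#' full threshold scan never aborts near the histogram tails.
#'
#' @inheritParams classicalMean
#' @param dHalf non-negative integer count of pixels trimmed per tail.
#' @return the trimmed mean, or \code{NA} if the mode is empty.
#' @examples
#' alphaTrimMean(modeRegion(c(1, 0, 0, 0, 3, 0, 0, 0, 1), lo = 1), 1)
#' @export
alphaTrimMean <- function(region, dHalf) {
    stopifnot(is(region, "ModeRegion"))
    if (!is.numeric(dHalf) || length(dHalf) != 1L || is.na(dHalf) ||
        dHalf < 0 || dHalf != as.integer(dHalf))
        stop("'dHalf' must be a single non-negative integer")
    dHalf <- as.integer(dHalf)
    n <- sum(region@counts)
    if (n == 0) return(NA_real_)
    if (n <= 2 * dHalf) return(classicalMean(region))
    cnt <- region@counts
    ## remove dHalf pixels from the low tail, then from the high tail
    rem <- dHalf
    for (k in seq_along(cnt)) {
        if (rem <= 0) break
        take <- min(cnt[k], rem)
        cnt[k] <- cnt[k] - take
        rem <- rem - take
    }
    rem <- dHalf
    for (k in rev(seq_along(cnt))) {
        if (rem <= 0) break
        take <- min(cnt[k], rem)
        cnt[k] <- cnt[k] - take
        rem <- rem - take
    }
    sum(.regionLevels(region) * cnt) / (n - 2 * dHalf)
}

#' Construct an EstimatorSpec
#'
#' @param approach filter name: \code{"classical"}, \code{"geometric"},
#'   \code{"harmonic"}, \code{"contraharmonic"} or \code{"alphatrim"}.
#' @param Q contra-harmonic order (required for that approach).
#' @param dHalf alpha-trim count per tail (required for that approach).
#' @return an [EstimatorSpec-class].
#' @examples
#' estimatorSpec("contraharmonic", Q = 0.5)
#' estimatorSpec("alphatrim", dHalf = 55)
#' @export
estimatorSpec <- function(approach, Q = NA_real_, dHalf = NA_integer_) {
    new("EstimatorSpec", approach = approach, Q = as.numeric(Q),
        dHalf = as.integer(dHalf))
}

#' @rdname regionMean
#' @export
setMethod("regionMean", signature("ModeRegion", "EstimatorSpec"),
    function(region, spec) {
        switch(spec@approach,
            classical      = classicalMean(region),
            geometric      = geometricMean(region),
            harmonic       = harmonicMean(region),
            contraharmonic = contraharmonicMean(region, spec@Q),
            alphatrim      = alphaTrimMean(region, spec@dHalf))
    })

#' Compact textual label of an estimator
#'
#' The serialization used in configuration listings and the command line,
#' e.g. \code{"classical"}, \code{"c-harmonic:+0.5"}, \code{"alpha-trim:55"}.
#'
#' @param spec an [EstimatorSpec-class].
#' @return a single string.
#' @export
estimatorLabel <- function(spec) {
    stopifnot(is(spec, "EstimatorSpec"))
    switch(spec@approach,
        classical = "classical",
        geometric = "geometric",
        harmonic  = "harmonic",
        contraharmonic = sprintf("c-harmonic:%+g", spec@Q),
        alphatrim = sprintf("alpha-trim:%d", spec@dHalf))
}

#' Parse an estimator label
#'
#' Inverse of [estimatorLabel()].
#'
#' @param label a string such as \code{"harmonic"},
#'   \code{"c-harmonic:-1.5"} or \code{"alpha-trim:55"}.
#' @return an [EstimatorSpec-class].
#' @export
parseEstimator <- function(label) {
    stopifnot(is.character(label), length(label) == 1L)
    parts <- strsplit(trimws(label), ":", fixed = TRUE)[[1L]]
    name <- parts[1L]
    if (name %in% c("classical", "geometric", "harmonic")) {
        if (length(parts) > 1L)
            stop("estimator '", name, "' takes no parameter")
        return(estimatorSpec(name))
    }
    if (name %in% c("c-harmonic", "contraharmonic")) {
        if (length(parts) != 2L)
            stop("contra-harmonic estimator needs an order, e.g. 'c-harmonic:+0.5'")
        return(estimatorSpec("contraharmonic", Q = as.numeric(parts[2L])))
    }
    if (name %in% c("alpha-trim", "alphatrim")) {
        if (length(parts) != 2L)
            stop("alpha-trim estimator needs a trim count, e.g. 'alpha-trim:55'")
        return(estimatorSpec("alphatrim", dHalf = as.integer(parts[2L])))
    }
    stop("unknown estimator label: ", label)
}
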