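## Independent brute-force oracles: every quantity is recomputed from the
## expanded per-pixel representation with straight-line code, never through
## the package's histogram-weighted paths.

## expand a ModeRegion (or a counts vector with offset lo) to its sorted
## pixel vector on the shifted index scale
expandRegion <- function(region) {
    rep(seq.int(region@lo, region@hi), times = region@counts)
}

## expand a GrayHistogram to the sorted pixel vector on the shifted scale
expandHistogram <- function(hist) {
    rep(1:256, times = hist@counts)
}

## a region from an explicit pixel multiset (shifted-scale values >= 1)
regionFromPixels <- function(values) {
    lo <- min(values); hi <- max(values)
    modeRegion(tabulate(values - lo + 1L, nbins = hi - lo + 1L), lo = lo)
}

## direct filter definitions on an expanded pixel vector
oracleMean <- function(v, spec) {
    if (!length(v)) return(NA_real_)
    switch(spec@approach,
        classical = mean(v),
        geometric = exp(mean(log(v))),
        harmonic = length(v) / sum(1 / v),
        contraharmonic = {
            den <- sum(v^spec@Q)
            if (den == 0) NA_real_ else sum(v^(spec@Q + 1)) / den
        },
        alphatrim = {
            d <- spec@dHalf
            if (length(v) <= 2 * d) mean(v)
            else mean(sort(v)[(d + 1L):(length(v) - d)])
        })
}

## straight-line re-scan of the cross-entropy objective: for every split t
## compute both means from expanded pixel lists and
## n(t) = -sum(mode_a) log(mu1) - sum(mode_b) log(mu2);
## returns the smallest minimizer on the 0-255 gray scale
oracleFindThreshold <- function(hist, config) {
    v <- expandHistogram(hist)
    best <- Inf
    bestT <- NA_integer_
    for (t in 1:255) {
        va <- v[v <= t]
        vb <- v[v > t]
        if (!length(va) || !length(vb)) next
        m1 <- oracleMean(va, config@mu1Spec)
        m2 <- oracleMean(vb, config@mu2Spec)
        if (is.na(m1) || is.na(m2) || m1 <= 0 || m2 <= 0) next
        nt <- -sum(va) * log(m1) - sum(vb) * log(m2)
        if (nt < best) { best <- nt; bestT <- t }
    }
    list(tStar = bestT - 1L, objective = best)
}

## random histogram with k distinct occupied gray levels
randomHistogram <- function(k = 16L, maxCount = 30L, grayMax = 255L) {
    levels <- sort(sample.int(grayMax + 1L, k) - 1L)
    counts <- numeric(256L)
    counts[levels + 1L] <- sample.int(maxCount, k, replace = TRUE)
    grayHistogram(counts)
}

## random small mode region (shifted scale)
randomRegion <- function(maxLevels = 8L, maxCount = 20L) {
    lo <- sample.int(250L, 1L)
    k <- sample.int(maxLevels, 1L)
    hi <- lo + k - 1L
    counts <- sample.int(maxCount, k, replace = TRUE) - 1L
    if (sum(counts) == 0) counts[sample.int(k, 1L)] <- 1L
    modeRegion(counts, lo = lo)
}

allEstimatorSpecs <- function() list(
    estimatorSpec("classical"),
    estimatorSpec("geometric"),
    estimatorSpec("harmonic"),
    estimatorSpec("contraharmonic", Q = 1.5),
    estimatorSpec("contraharmonic", Q = -0.5),
    estimatorSpec("alphatrim", dHalf = 3L),
    estimatorSpec("alphatrim", dHalf = 55L))

## the two-delta histogram used across the threshold tests:
## 100 pixels at gray 50 and 100 at gray 200
twoDeltaHistogram <- function() {
    grayHistogram(`[<-`(numeric(256), c(51L, 201L), 100))
}

twoDeltaImage <- function() {
    grayImage(matrix(rep(c(50L, 200L), each = 100L), 10L, 20L))
}
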