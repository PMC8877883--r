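## Minimum cross entropy thresholding with pluggable mode-mean estimators.
##
## The objective for a candidate split t of the shifted index scale is
##   n(t) = - sum_{i<=t} i h(i) log(mu1(t)) - sum_{i>t} i h(i) log(mu2(t))
## (natural log; any base rescales n(t) by a positive constant and leaves
## the argmin unchanged). The optimal threshold minimizes n(t) over all
## splits leaving both modes non-empty.

#' Construct an MCETConfig
#'
#' @param mu1Spec estimator for the lower mode ([EstimatorSpec-class] or a
#'   label accepted by [parseEstimator()]).
#' @param mu2Spec estimator for the upper mode.
#' @param configId integer row identifier (0 = classical baseline;
#'   defaults to \code{-1} for ad-hoc configurations).
#' @return an [MCETConfig-class].
#' @examples
#' mcetConfig("harmonic", "c-harmonic:-0.5")
#' @export
mcetConfig <- function(mu1Spec, mu2Spec, configId = -1L) {
    if (is.character(mu1Spec)) mu1Spec <- parseEstimator(mu1Spec)
    if (is.character(mu2Spec)) mu2Spec <- parseEstimator(mu2Spec)
    new("MCETConfig", mu1Spec = mu1Spec, mu2Spec = mu2Spec,
        configId = as.integer(configId))
}

#' Cross-entropy objective at one candidate threshold
#'
#' @param hist a [GrayHistogram-class].
#' @param t candidate split on the shifted index scale \code{[1, 255]}:
#'   the lower mode spans levels \code{[1, t]}, the upper mode
#'   \code{[t + 1, 256]}.
#' @param mu1,mu2 the two region means (shifted index scale). Candidates
#'   with a non-positive or undefined mean get \code{Inf}, the sentinel
#'   that drops them from the scan.
#' @return the objective value (natural log).
#' @export
crossEntropyObjective <- function(hist, t, mu1, mu2) {
    stopifnot(is(hist, "GrayHistogram"))
    t <- as.integer(t)
    if (t < 1L || t > 255L)
        stop("candidate split must lie in [1, 255] on the shifted scale")
    if (is.na(mu1) || is.na(mu2) || mu1 <= 0 || mu2 <= 0)
        return(Inf)
    i <- 1:256
    ih <- i * hist@counts
    -sum(ih[1:t]) * log(mu1) - sum(ih[(t + 1L):256L]) * log(mu2)
}

#' Find the MCET-optimal threshold for one estimator configuration
#'
#' Exhaustively scans every split of the shifted index scale that leaves
#' both modes non-empty, estimates the two mode means with the
#' configuration's filters, and returns the smallest minimizer of the
#' cross-entropy objective (deterministic tie-break on plateaus).
#' Candidates where either mean is undefined are skipped via an
#' \code{Inf} sentinel.
#'
#' @param hist a [GrayHistogram-class] with at least two occupied levels.
#' @param config an [MCETConfig-class].
#' @return a [ThresholdResult-class]; its \code{tStar} is on the 0--255
#'   gray scale, so \code{applyThreshold(img, tStar(res))} selects the
#'   upper mode as foreground.
#' @examples
#' h <- grayHistogram(`[<-`(numeric(256), c(51, 201), 100))
#' findThreshold(h, mcetConfig("classical", "classical", 0L))
#' @export
findThreshold <- function(hist, config) {
    stopifnot(is(hist, "GrayHistogram"), is(config, "MCETConfig"))
    occupied <- which(hist@counts > 0)
    if (length(occupied) < 2L)
        stop("degenerate histogram: only occupied gray level is ",
             if (length(occupied)) occupied[1L] - 1L else "none")
    ih <- (1:256) * hist@counts
    cumCnt <- cumsum(hist@counts)
    cumIH <- cumsum(ih)
    total <- cumCnt[256L]
    totalIH <- cumIH[256L]
    curve <- rep(Inf, 255L)
    mu1s <- mu2s <- rep(NA_real_, 255L)
    for (t in 1:255) {
        if (cumCnt[t] == 0 || cumCnt[t] == total) next
        modes <- histModes(hist, t)
        m1 <- regionMean(modes$a, config@mu1Spec)
        m2 <- regionMean(modes$b, config@mu2Spec)
        if (is.na(m1) || is.na(m2) || m1 <= 0 || m2 <= 0) next
        mu1s[t] <- m1
        mu2s[t] <- m2
        curve[t] <- -cumIH[t] * log(m1) - (totalIH - cumIH[t]) * log(m2)
    }
    if (!any(is.finite(curve)))
        stop("no valid threshold candidate for this configuration")
    tI <- which.min(curve)  # smallest index among ties
    new("ThresholdResult", tStar = tI - 1L, mu1 = mu1s[tI], mu2 = mu2s[tI],
        objective = curve[tI], objectiveCurve = curve, config = config)
}

.chQ1 <- c(1.5, 0.5)    # positive orders, lower-mode estimation
.chQ2 <- c(-1.5, -0.5)  # negative orders, upper-mode estimation
.atD <- 55L             # alpha-trim d/2 retained from the homogeneous study

.hetPool1 <- function() list(
    estimatorSpec("classical"),
    estimatorSpec("geometric"),
    estimatorSpec("harmonic"),
    estimatorSpec("contraharmonic", Q = 1.5),
    estimatorSpec("contraharmonic", Q = 0.5),
    estimatorSpec("alphatrim", dHalf = .atD))

.hetPool2 <- function() list(
    estimatorSpec("classical"),
    estimatorSpec("geometric"),
    estimatorSpec("harmonic"),
    estimatorSpec("contraharmonic", Q = -1.5),
    estimatorSpec("contraharmonic", Q = -0.5),
    estimatorSpec("alphatrim", dHalf = .atD))

#' Enumerate the 32 heterogeneous estimator configurations
#'
#' Every pairing of a lower-mode estimator from \{classical, geometric,
#' harmonic, contra-harmonic Q = +1.5, Q = +0.5, alpha-trim d/2 = 55\}
#' with an upper-mode estimator from the complementary pool \{classical,
#' geometric, harmonic, contra-harmonic Q = -1.5, Q = -0.5, alpha-trim
#' d/2 = 55\}, excluding same-approach pairs except the sign-opposed
#' contra-harmonic combinations. Positive orders suppress pepper in the
#' dark mode, negative orders suppress salt in the bright mode.
#'
#' @return ordered list of 32 [MCETConfig-class] objects with
#'   \code{configId} 1--32.
#' @export
heterogeneousConfigs <- function() {
    p1 <- .hetPool1()
    p2 <- .hetPool2()
    out <- vector("list", 32L)
    id <- 0L
    for (s1 in p1) {
        for (s2 in p2) {
            if (s1@approach == s2@approach &&
                s1@approach != "contraharmonic") next
            id <- id + 1L
            out[[id]] <- mcetConfig(s1, s2, configId = id)
        }
    }
    out
}

#' Enumerate the 21 homogeneous baseline configurations
#'
#' The same estimator on both modes: classical, harmonic, geometric,
#' contra-harmonic with Q in \{-3.0, -1.5, -0.5, +0.5, +1.5\}, and
#' alpha-trim with d/2 in \{10, 20, 30, 40, 50, 55, 60, 65, 70, 80, 90,
#' 100, 110\}. Row 0 (classical/classical) is the original MCET.
#'
#' @return ordered list of 21 [MCETConfig-class] objects with
#'   \code{configId} 0--20.
#' @export
homogeneousConfigs <- function() {
    specs <- c(
        list(estimatorSpec("classical"),
             estimatorSpec("harmonic"),
             estimatorSpec("geometric")),
        lapply(c(-3.0, -1.5, -0.5, 0.5, 1.5),
               function(q) estimatorSpec("contraharmonic", Q = q)),
        lapply(c(10L, 20L, 30L, 40L, 50L, 55L, 60L, 65L, 70L, 80L, 90L,
                 100L, 110L),
               function(d) estimatorSpec("alphatrim", dHalf = d)))
    mapply(function(s, id) mcetConfig(s, s, configId = id),
           specs, seq_along(specs) - 1L)
}

#' Look up a configuration by its table row
#'
#' @param id 0 for the classical baseline, 1--32 for the heterogeneous
#'   rows.
#' @return an [MCETConfig-class].
#' @export
configById <- function(id) {
    id <- as.integer(id)
    if (id == 0L)
        return(mcetConfig(estimatorSpec("classical"),
                          estimatorSpec("classical"), configId = 0L))
    het <- heterogeneousConfigs()
    if (id >= 1L && id <= length(het)) return(het[[id]])
    stop("no configuration row ", id, " (valid rows: 0-", length(het), ")")
}

#' Run the threshold search over many configurations
#'
#' One [findThreshold()] call per configuration. With \code{workers > 1}
#' the scans run through \code{parallel::mclapply}; results are assembled
#' in configuration order, so the output is identical for any degree of
#' parallelism.
#'
#' @param hist a [GrayHistogram-class].
#' @param configs non-empty list of [MCETConfig-class] objects.
#' @param workers parallelism degree (forked processes; 1 = sequential).
#' @return list of [ThresholdResult-class], one per configuration, in
#'   input order.
#' @export
sweepConfigs <- function(hist, configs, workers = 1L) {
    stopifnot(is(hist, "GrayHistogram"), is.list(configs),
              length(configs) >= 1L)
    run <- function(cfg) findThreshold(hist, cfg)
    if (workers > 1L && .Platform$OS.type == "unix") {
        res <- parallel::mclapply(configs, run, mc.cores = workers)
        bad <- vapply(res, inherits, logical(1L), "try-error")
        if (any(bad)) stop(attr(res[[which(bad)[1L]]], "condition"))
        res
    } else {
        lapply(configs, run)
    }
}
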