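## Segmentation quality: three unsupervised measures (uniformity, region
## contrast, inter-region disparity), three supervised measures (Jaccard,
## F-score, accuracy), their average, and best-threshold selection.

#' Image uniformity of a bilevel split
#'
#' \eqn{1 - (\sigma_1^2 + \sigma_2^2)/Z} with \eqn{Z = (I_{max} -
#' I_{min})^2 / 2} over the whole image and \eqn{\sigma_k^2} the
#' population variance of each threshold-induced region. Clipped to
#' \code{[0, 1]}; a constant image (Z = 0) is perfectly uniform and
#' scores 1.
#'
#' @param img a [GrayImage-class].
#' @param t threshold on the 0--255 gray scale; region 1 holds pixels
#'   \code{<= t}, region 2 pixels \code{> t}.
#' @return uniformity score in \code{[0, 1]}.
#' @export
imageUniformity <- function(img, t) {
    stopifnot(is(img, "GrayImage"))
    p <- as.numeric(img@pixels)
    Z <- (max(p) - min(p))^2 / 2
    if (Z == 0) return(1)
    lo <- p[p <= t]
    hi <- p[p > t]
    if (!length(lo) || !length(hi))
        stop("threshold ", t, " leaves one region empty")
    popvar <- function(v) mean((v - mean(v))^2)
    min(max(1 - (popvar(lo) + popvar(hi)) / Z, 0), 1)
}

#' Region contrast between the two mode means
#'
#' \eqn{|\mu_1 - \mu_2| / (\mu_1 + \mu_2)}: 0 for identical means, 1 when
#' one mean vanishes.
#'
#' @param mu1,mu2 non-negative region means.
#' @return contrast in \code{[0, 1]}; defined as 0 when both means are 0.
#' @export
regionContrast <- function(mu1, mu2) {
    stopifnot(is.numeric(mu1), is.numeric(mu2), mu1 >= 0, mu2 >= 0)
    if (mu1 + mu2 == 0) return(0)
    abs(mu1 - mu2) / (mu1 + mu2)
}

## Per-pixel max contrast to 8-neighbors inside / outside the pixel's
## region, via eight shifted-overlap passes (no per-pixel loops).
.neighborContrasts <- function(p, l) {
    h <- nrow(p); w <- ncol(p)
    ci <- matrix(0, h, w)       # max contrast to same-label neighbors
    ce <- matrix(0, h, w)       # max contrast to other-label neighbors
    hasOut <- matrix(FALSE, h, w)
    for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r1 <- max(1L, 1L - dr); r2 <- min(h, h - dr)
        c1 <- max(1L, 1L - dc); c2 <- min(w, w - dc)
        if (r1 > r2 || c1 > c2) next
        rs <- r1:r2; cs <- c1:c2
        rt <- rs + dr; ct <- cs + dc
        cc <- abs(p[rs, cs, drop = FALSE] - p[rt, ct, drop = FALSE]) / 255
        same <- l[rs, cs, drop = FALSE] == l[rt, ct, drop = FALSE]
        ci[rs, cs] <- pmax(ci[rs, cs, drop = FALSE], ifelse(same, cc, 0))
        ce[rs, cs] <- pmax(ce[rs, cs, drop = FALSE], ifelse(same, 0, cc))
        hasOut[rs, cs] <- hasOut[rs, cs, drop = FALSE] | !same
    }
    list(ci = ci, ce = ce, hasOut = hasOut)
}

#' Inter-region disparity of a segmentation
#'
#' For each region, the interior contrast is the mean over region pixels
#' of the largest normalized intensity difference \eqn{|I(s) - I(t)|/(L-1)}
#' to an 8-neighbor inside the region; the exterior contrast is the mean
#' over border pixels (region pixels with at least one neighbor outside)
#' of the largest difference to a neighbor outside. A region scores
#' \eqn{1 - CI/CE} when \eqn{0 < CI < CE}, \eqn{CE} when \eqn{CI = 0},
#' and 0 otherwise; the image score is the area-weighted mean of the two
#' region scores.
#'
#' @param img a [GrayImage-class].
#' @param mask a [BinaryMask-class] of the same shape with both labels
#'   present.
#' @return disparity score in \code{[0, 1]}; 1 indicates sharp boundaries
#'   with flat region interiors.
#' @export
interRegionDisparity <- function(img, mask) {
    stopifnot(is(img, "GrayImage"), is(mask, "BinaryMask"))
    p <- img@pixels
    l <- mask@labels
    if (!identical(dim(p), dim(l)))
        stop("image and mask shapes differ")
    if (length(unique(as.vector(l))) < 2L)
        stop("mask must contain both labels (a one-region mask has no border)")
    storage.mode(p) <- "double"
    nb <- .neighborContrasts(p, l)
    total <- length(l)
    score <- 0
    for (lab in c(0L, 1L)) {
        inR <- l == lab
        A <- sum(inR)
        CI <- sum(nb$ci[inR]) / A
        border <- inR & nb$hasOut
        CE <- sum(nb$ce[border]) / sum(border)
        cR <- if (CI == 0) CE
              else if (CI < CE) 1 - CI / CE
              else 0
        score <- score + (A / total) * cR
    }
    score
}

#' Confusion counts between a predicted and a ground-truth mask
#'
#' @param pred,gt [BinaryMask-class] objects of identical shape.
#' @return a [ConfusionCounts-class].
#' @examples
#' p <- binaryMask(matrix(c(1, 1, 0, 0, 1), 1))
#' g <- binaryMask(matrix(c(1, 0, 0, 1, 1), 1))
#' confusionCounts(p, g)
#' @export
confusionCounts <- function(pred, gt) {
    stopifnot(is(pred, "BinaryMask"), is(gt, "BinaryMask"))
    if (!identical(dim(pred@labels), dim(gt@labels)))
        stop("mask shapes differ")
    p <- pred@labels == 1L
    g <- gt@labels == 1L
    new("ConfusionCounts",
        TP = sum(p & g), FP = sum(p & !g),
        FN = sum(!p & g), TN = sum(!p & !g))
}

#' Jaccard index (intersection over union)
#'
#' @param cc a [ConfusionCounts-class].
#' @return \code{TP / (TP + FP + FN)}; 1 when both masks are empty.
#' @export
jaccardIndex <- function(cc) {
    stopifnot(is(cc, "ConfusionCounts"))
    den <- cc@TP + cc@FP + cc@FN
    if (den == 0) return(1)
    cc@TP / den
}

#' F-score (Dice) of a segmentation
#'
#' Harmonic mean of precision \code{TP/(TP+FP)} and recall
#' \code{TP/(TP+FN)}.
#'
#' @inheritParams jaccardIndex
#' @return F-score in \code{[0, 1]}; 0 when TP = 0 with any
#'   disagreement, 1 when both masks are empty.
#' @export
fScore <- function(cc) {
    stopifnot(is(cc, "ConfusionCounts"))
    if (cc@TP + cc@FP + cc@FN == 0) return(1)
    if (cc@TP == 0) return(0)
    prec <- cc@TP / (cc@TP + cc@FP)
    rec <- cc@TP / (cc@TP + cc@FN)
    2 * prec * rec / (prec + rec)
}

#' Pixel accuracy of a segmentation
#'
#' @inheritParams jaccardIndex
#' @return \code{(TP + TN) / (TP + TN + FP + FN)}.
#' @export
pixelAccuracy <- function(cc) {
    stopifnot(is(cc, "ConfusionCounts"))
    total <- cc@TP + cc@FP + cc@FN + cc@TN
    if (total == 0) stop("empty confusion table")
    (cc@TP + cc@TN) / total
}

#' Score one threshold result against an image (and optional ground truth)
#'
#' Computes the three unsupervised measures from the image at the
#' result's threshold and, when a ground-truth mask is supplied, the
#' three supervised measures of the induced mask, then averages all
#' present scores. Region contrast is evaluated on the actual arithmetic
#' means of the two threshold-induced regions (shifted index scale), not
#' on the estimator outputs stored in the result, so the evaluation is a
#' property of the segmentation alone and identical thresholds score
#' identically regardless of which estimator pair found them.
#'
#' @param img the segmented [GrayImage-class].
#' @param result a [ThresholdResult-class].
#' @param gt optional ground-truth [BinaryMask-class].
#' @param invert passed to [applyThreshold()] when building the mask.
#' @return an [EvaluationReport-class].
#' @export
evaluateThreshold <- function(img, result, gt = NULL, invert = FALSE) {
    stopifnot(is(img, "GrayImage"), is(result, "ThresholdResult"))
    mask <- applyThreshold(img, result@tStar, invert = invert)
    modes <- histModes(computeHistogram(img), result@tStar + 1L)
    scores <- c(iu = imageUniformity(img, result@tStar),
                rc = regionContrast(classicalMean(modes$a),
                                    classicalMean(modes$b)),
                disparity = interRegionDisparity(img, mask),
                jaccard = NA_real_, fscore = NA_real_,
                accuracy = NA_real_)
    if (!is.null(gt)) {
        cc <- confusionCounts(mask, gt)
        scores["jaccard"] <- jaccardIndex(cc)
        scores["fscore"] <- fScore(cc)
        scores["accuracy"] <- pixelAccuracy(cc)
    }
    new("EvaluationReport", configId = result@config@configId,
        tStar = result@tStar, scores = scores,
        average = averageScore(scores))
}

#' Select the best threshold across configurations
#'
#' Scores every result with [evaluateThreshold()] and returns the one
#' whose average score is maximal; ties break on the smaller
#' configuration id, then the smaller threshold. A result whose metrics
#' fail a precondition (e.g. a mask collapsing to one label) is scored 0
#' and reported with a warning rather than aborting the selection.
#'
#' @inheritParams evaluateThreshold
#' @param results non-empty list of [ThresholdResult-class].
#' @return list with elements \code{best} (the winning
#'   [ThresholdResult-class]) and \code{reports} (one
#'   [EvaluationReport-class] per input result, in input order).
#' @export
selectBestThreshold <- function(img, results, gt = NULL, invert = FALSE) {
    stopifnot(is.list(results), length(results) >= 1L)
    reports <- lapply(results, function(res) {
        tryCatch(evaluateThreshold(img, res, gt = gt, invert = invert),
            error = function(e) {
                warning("configuration ", res@config@configId,
                        " could not be scored (", conditionMessage(e),
                        "); assigned average 0", call. = FALSE)
                new("EvaluationReport", configId = res@config@configId,
                    tStar = res@tStar,
                    scores = stats::setNames(rep(NA_real_, 6L), .scoreNames),
                    average = 0)
            })
    })
    avg <- vapply(reports, function(r) r@average, numeric(1L))
    ids <- vapply(results, function(r) r@config@configId, integer(1L))
    ts <- vapply(results, function(r) r@tStar, integer(1L))
    best <- order(-avg, ids, ts)[1L]
    list(best = results[[best]], reports = reports)
}
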