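test_that("image uniformity handles zero-variance and mixed regions", {
    ## two-delta image split between the deltas: both variances vanish
    expect_equal(imageUniformity(twoDeltaImage(), 125), 1)
    expect_equal(imageUniformity(grayImage(matrix(7L, 3L, 3L)), 100), 1)
    ## direct-variance oracle on a 4-pixel image
    img <- grayImage(matrix(c(0L, 0L, 2L, 255L), 1L, 4L))
    popvar <- function(v) mean((v - mean(v))^2)
    want <- 1 - (popvar(c(0, 0, 2)) + popvar(255)) / (255^2 / 2)
    expect_equal(imageUniformity(img, 100), want)
    expect_error(imageUniformity(img, 255), "empty")
})

test_that("region contrast normalizes the mean difference by the mean sum", {
    expect_equal(regionContrast(10, 10), 0)
    expect_equal(regionContrast(51, 201), 150 / 252)
    expect_equal(regionContrast(10, 0), 1)
    expect_equal(regionContrast(0, 0), 0)
})

test_that("inter-region disparity matches a hand neighborhood scan", {
    ## 4x4 image of two flat halves (50 | 200), mask on the true boundary:
    ## interior contrast 0 in both regions, exterior contrast 150/255
    px <- matrix(rep(c(50L, 200L), each = 8L), 4L, 4L)
    mask <- binaryMask(matrix(rep(c(0L, 1L), each = 8L), 4L, 4L))
    expect_equal(interRegionDisparity(grayImage(px), mask), 150 / 255)
    ## same mask on a uniform image: CI = CE = 0, "otherwise" branch
    expect_equal(interRegionDisparity(grayImage(matrix(80L, 4L, 4L)), mask),
                 0)
    ## score stays in [0, 1] on random inputs with both labels present
    set.seed(42)
    for (k in 1:20) {
        img <- grayImage(matrix(sample.int(256L, 36L, TRUE) - 1L, 6L, 6L))
        m <- matrix(rbinom(36L, 1L, 0.5), 6L, 6L)
        if (length(unique(as.vector(m))) < 2L) m[1L] <- 1L - m[1L]
        d <- interRegionDisparity(img, binaryMask(m))
        expect_true(d >= 0 && d <= 1)
    }
    expect_error(interRegionDisparity(grayImage(px),
                                      binaryMask(matrix(1L, 4L, 4L))),
                 "border")
})

test_that("confusion counts and supervised scores match hand tallies", {
    p <- binaryMask(matrix(c(1L, 1L, 0L, 0L, 1L), 1L))
    g <- binaryMask(matrix(c(1L, 0L, 0L, 1L, 1L), 1L))
    cc <- confusionCounts(p, g)
    expect_equal(c(cc@TP, cc@FP, cc@FN, cc@TN), c(2, 1, 1, 1))
    expect_error(confusionCounts(p, binaryMask(matrix(1L, 2L, 2L))),
                 "shapes")

    cc2 <- new("ConfusionCounts", TP = 3, FP = 1, FN = 1, TN = 0)
    expect_equal(jaccardIndex(cc2), 0.6)
    expect_equal(fScore(cc2), 0.75)
    expect_equal(pixelAccuracy(new("ConfusionCounts", TP = 3, FP = 1,
                                   FN = 2, TN = 4)), 0.7)

    ## identical masks: perfect scores; disjoint: zero overlap
    ccEq <- confusionCounts(p, p)
    expect_equal(c(jaccardIndex(ccEq), fScore(ccEq), pixelAccuracy(ccEq)),
                 c(1, 1, 1))
    comp <- binaryMask(1L - maskMatrix(p))
    ccC <- confusionCounts(p, comp)
    expect_equal(c(jaccardIndex(ccC), fScore(ccC), pixelAccuracy(ccC)),
                 c(0, 0, 0))
    ## both masks empty
    e <- binaryMask(matrix(0L, 2L, 2L))
    expect_equal(jaccardIndex(confusionCounts(e, e)), 1)
    expect_equal(fScore(confusionCounts(e, e)), 1)
})

test_that("Dice-Jaccard identity holds for every confusion table", {
    set.seed(7)
    for (k in 1:50) {
        cc <- new("ConfusionCounts", TP = sample(0:20, 1L),
                  FP = sample(0:20, 1L), FN = sample(0:20, 1L),
                  TN = sample(0:20, 1L))
        if (cc@TP + cc@FP + cc@FN == 0) next
        J <- jaccardIndex(cc)
        expect_equal(fScore(cc), 2 * J / (1 + J), tolerance = 1e-15)
    }
})

test_that("label swap in both masks maps TP<->TN and keeps accuracy", {
    set.seed(13)
    for (k in 1:10) {
        p <- binaryMask(matrix(rbinom(24L, 1L, 0.5), 4L, 6L))
        g <- binaryMask(matrix(rbinom(24L, 1L, 0.5), 4L, 6L))
        cc <- confusionCounts(p, g)
        sw <- confusionCounts(binaryMask(1L - maskMatrix(p)),
                              binaryMask(1L - maskMatrix(g)))
        expect_equal(c(sw@TP, sw@FP, sw@FN, sw@TN),
                     c(cc@TN, cc@FN, cc@FP, cc@TP))
        expect_equal(pixelAccuracy(sw), pixelAccuracy(cc))
    }
})

test_that("averageScore averages exactly the scores present", {
    expect_equal(averageScore(rep(1, 6L)), 1)
    expect_equal(averageScore(c(0.6, 0.75, 0.7, NA, NA, NA)),
                 mean(c(0.6, 0.75, 0.7)))
    s <- c(0.2, 0.9, 0.5, 0.7, NA, 0.1)
    expect_equal(averageScore(s), averageScore(sample(s)))
    expect_error(averageScore(c(NA_real_, NA_real_)), "no scores")
})

test_that("evaluateThreshold assembles the report from its parts", {
    ph <- generatePhantom(phantomSpec(seed = 5L))
    h <- computeHistogram(ph$image)
    res <- findThreshold(h, configById(0L))
    repU <- evaluateThreshold(ph$image, res)               # unsupervised only
    repS <- evaluateThreshold(ph$image, res, gt = ph$mask) # with ground truth
    su <- reportScores(repU)
    expect_true(all(is.na(su[c("jaccard", "fscore", "accuracy")])))
    expect_equal(averageScore(repU),
                 mean(su[c("iu", "rc", "disparity")]))
    ss <- reportScores(repS)
    expect_false(anyNA(ss))
    expect_equal(averageScore(repS), mean(ss))
    ## the unsupervised components agree with their direct recomputation
    mask <- applyThreshold(ph$image, tStar(res))
    expect_equal(unname(ss["iu"]), imageUniformity(ph$image, tStar(res)))
    ## region contrast uses the actual mode means of the image at t*,
    ## not the estimator outputs
    modes <- histModes(computeHistogram(ph$image), tStar(res) + 1L)
    expect_equal(unname(ss["rc"]),
                 regionContrast(classicalMean(modes$a),
                                classicalMean(modes$b)))
    expect_equal(unname(ss["disparity"]),
                 interRegionDisparity(ph$image, mask))
    cc <- confusionCounts(mask, ph$mask)
    expect_equal(unname(ss["jaccard"]), jaccardIndex(cc))
})

test_that("selectBestThreshold maximizes the recomputed average", {
    ph <- generatePhantom(phantomSpec(saltDensity = 0.03,
                                      pepperDensity = 0.03, seed = 8L))
    h <- computeHistogram(ph$image)
    cfgs <- c(list(configById(0L)), heterogeneousConfigs()[c(2L, 6L, 19L)])
    results <- sweepConfigs(h, cfgs)
    sel <- selectBestThreshold(ph$image, results, gt = ph$mask)
    avgs <- vapply(sel$reports, averageScore, numeric(1L))
    indep <- vapply(results, function(r)
        averageScore(evaluateThreshold(ph$image, r, gt = ph$mask)),
        numeric(1L))
    expect_equal(avgs, indep)
    expect_equal(averageScore(sel$reports[[
        which(vapply(results, configId, integer(1L)) ==
              configId(sel$best))[1L]]]), max(avgs))
    ## singleton list returns its only element
    one <- selectBestThreshold(ph$image, results[2L], gt = ph$mask)
    expect_identical(tStar(one$best), tStar(results[[2L]]))
})
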