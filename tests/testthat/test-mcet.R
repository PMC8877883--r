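test_that("cross-entropy objective matches closed forms", {
    h <- twoDeltaHistogram()
    expect_equal(crossEntropyObjective(h, 51L, 1, 1), 0)
    ## mass concentrated at one level below the split: single-term form
    h1 <- grayHistogram(`[<-`(numeric(256), 40L, 7))  # level i = 40
    expect_equal(crossEntropyObjective(h1, 100L, 3, 2), -40 * 7 * log(3))
    ## the two-delta histogram at its separating split
    expect_equal(crossEntropyObjective(h, 51L, 51, 201),
                 -51 * 100 * log(51) - 201 * 100 * log(201))
    expect_identical(crossEntropyObjective(h, 51L, 0, 5), Inf)
    expect_identical(crossEntropyObjective(h, 51L, NA_real_, 5), Inf)
    expect_error(crossEntropyObjective(h, 0L, 1, 1), "\\[1, 255\\]")
})

test_that("two-delta histogram yields the smallest plateau minimizer", {
    h <- twoDeltaHistogram()
    res <- findThreshold(h, mcetConfig("classical", "classical", 0L))
    expect_identical(tStar(res), 50L)
    expect_equal(res@mu1, 51)
    expect_equal(res@mu2, 201)
    ## the objective is flat over the separating plateau
    curve <- objectiveCurve(res)
    expect_true(all(abs(curve[51:200] - objectiveValue(res)) < 1e-9))
    ## every heterogeneous config separates the deltas
    for (cfg in heterogeneousConfigs()) {
        t <- tStar(findThreshold(h, cfg))
        expect_true(t >= 50L && t <= 199L, info = configId(cfg))
    }
    ## the induced mask isolates the upper delta
    img <- twoDeltaImage()
    mask <- applyThreshold(img, tStar(res))
    gt <- binaryMask(matrix(as.integer(pixelMatrix(img) == 200L),
                            nrow(pixelMatrix(img))))
    expect_equal(jaccardIndex(confusionCounts(mask, gt)), 1)
})

test_that("findThreshold agrees with the brute-force expanded-pixel oracle", {
    set.seed(101)
    configs <- c(list(configById(0L)), heterogeneousConfigs())
    for (k in 1:10) {
        h <- randomHistogram(k = 16L)
        for (cfg in configs[sample.int(length(configs), 6L)]) {
            got <- findThreshold(h, cfg)
            want <- oracleFindThreshold(h, cfg)
            expect_identical(tStar(got), want$tStar,
                             info = sprintf("hist %d config %d", k,
                                            configId(cfg)))
            expect_equal(objectiveValue(got), want$objective,
                         tolerance = 1e-9)
        }
    }
})

test_that("t* is invariant under uniform count scaling and pixel permutation", {
    set.seed(202)
    cfg <- mcetConfig("harmonic", "c-harmonic:-0.5")
    for (k in 1:5) {
        h <- randomHistogram(k = 12L)
        t1 <- tStar(findThreshold(h, cfg))
        h3 <- grayHistogram(unname(histCounts(h)) * 3)
        expect_identical(tStar(findThreshold(h3, cfg)), t1)
        ## histogram sufficiency: any spatial arrangement gives the same t*
        v <- rep(0:255, times = histCounts(h))
        img1 <- grayImage(matrix(v, 1L))
        img2 <- grayImage(matrix(sample(v), 1L))
        expect_identical(tStar(findThreshold(computeHistogram(img1), cfg)),
                         tStar(findThreshold(computeHistogram(img2), cfg)))
    }
})

test_that("single-level histograms are rejected as degenerate", {
    h <- grayHistogram(`[<-`(numeric(256), 31L, 50))
    expect_error(findThreshold(h, configById(0L)), "degenerate")
})

test_that("heterogeneous enumeration reproduces the 32-row table", {
    het <- heterogeneousConfigs()
    expect_length(het, 32L)
    expect_identical(vapply(het, configId, integer(1L)), 1:32)
    ## row 25: contra-harmonic +0.5 over contra-harmonic -1.5
    expect_equal(estimatorLabel(het[[25]]@mu1Spec), "c-harmonic:+0.5")
    expect_equal(estimatorLabel(het[[25]]@mu2Spec), "c-harmonic:-1.5")
    ## heterogeneity rule: approaches differ except sign-opposed
    ## contra-harmonic pairs
    for (cfg in het) {
        s1 <- cfg@mu1Spec; s2 <- cfg@mu2Spec
        if (s1@approach == s2@approach) {
            expect_equal(s1@approach, "contraharmonic")
            expect_true(s1@Q > 0 && s2@Q < 0)
        }
    }
    ## lower-mode contra-harmonic orders positive, upper-mode negative
    for (cfg in het) {
        if (cfg@mu1Spec@approach == "contraharmonic")
            expect_true(cfg@mu1Spec@Q %in% c(0.5, 1.5))
        if (cfg@mu2Spec@approach == "contraharmonic")
            expect_true(cfg@mu2Spec@Q %in% c(-0.5, -1.5))
    }
})

test_that("homogeneous enumeration reproduces the 21-row baseline table", {
    hom <- homogeneousConfigs()
    expect_length(hom, 21L)
    expect_identical(vapply(hom, configId, integer(1L)), 0:20)
    expect_equal(estimatorLabel(hom[[1]]@mu1Spec), "classical")
    expect_equal(estimatorLabel(hom[[1]]@mu2Spec), "classical")
    for (cfg in hom)
        expect_identical(estimatorLabel(cfg@mu1Spec),
                         estimatorLabel(cfg@mu2Spec))
})

test_that("classical baseline equals the original single-estimator MCET", {
    ## with classical/classical the searched threshold must equal the
    ## textbook MCET computed from prefix sums alone (an independent
    ## algorithmic route: no mode objects, no estimator dispatch)
    textbookMCET <- function(counts) {
        A <- cumsum(counts)
        B <- cumsum((1:256) * counts)
        best <- Inf; bt <- NA_integer_
        for (t in 1:255) {
            if (A[t] == 0 || A[t] == A[256]) next
            mu1 <- B[t] / A[t]
            mu2 <- (B[256] - B[t]) / (A[256] - A[t])
            v <- -B[t] * log(mu1) - (B[256] - B[t]) * log(mu2)
            if (v < best) { best <- v; bt <- t }
        }
        bt - 1L
    }
    set.seed(303)
    for (k in 1:5) {
        h <- randomHistogram(k = 10L)
        expect_identical(tStar(findThreshold(h, configById(0L))),
                         textbookMCET(unname(histCounts(h))))
    }
})

test_that("sweepConfigs is deterministic and order-preserving across workers", {
    h <- computeHistogram(generatePhantom(phantomSpec(seed = 9L))$image)
    cfgs <- heterogeneousConfigs()[c(3L, 17L, 32L)]
    seq1 <- sweepConfigs(h, cfgs, workers = 1L)
    par4 <- sweepConfigs(h, cfgs, workers = 4L)
    expect_equal(lapply(seq1, tStar), lapply(par4, tStar))
    expect_equal(lapply(seq1, objectiveValue), lapply(par4, objectiveValue))
    single <- sweepConfigs(h, cfgs[2L])
    expect_equal(tStar(single[[1L]]), tStar(findThreshold(h, cfgs[[2L]])))
    expect_error(sweepConfigs(h, list()))
})

test_that("configById resolves table rows and rejects unknown rows", {
    expect_equal(configId(configById(0L)), 0L)
    expect_equal(estimatorLabel(configById(5L)@mu2Spec), "alpha-trim:55")
    expect_error(configById(33L), "no configuration row")
})
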