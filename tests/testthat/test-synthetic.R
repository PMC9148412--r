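cfg <- generatorConfig()

test_that("calibratedTransitionMatrix hits its stationary targets", {
    P <- calibratedTransitionMatrix(cfg)
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
    mask <- defaultAllowedMask(TRUE)
    expect_true(all(P[!mask] == 0))
    # independent power-iteration oracle for the stationary vector
    v <- rep(0.2, 5)
    for (i in 1:200000) {
        v2 <- as.vector(v %*% P)
        if (max(abs(v2 - v)) < 1e-14) break
        v <- v2
    }
    expect_equal(v2, unname(occupancyTargets(cfg)), tolerance = 1e-6)
    # expected shift probability per epoch matches the configured rate
    qEpoch <- sum(v2 * (1 - diag(P)))
    expect_equal(qEpoch * 3600 / 30, 1.6, tolerance = 1e-9)
})

test_that("symmetric masks yield symmetric Metropolis-Hastings chains", {
    full <- matrix(TRUE, 5, 5,
                   dimnames = list(postureLabels(TRUE),
                                   postureLabels(TRUE)))
    cfgU <- generatorConfig(occupancyTargets = stats::setNames(
        rep(0.2, 5), postureLabels(TRUE)))
    P <- calibratedTransitionMatrix(cfgU, full)
    expect_equal(P, t(P), tolerance = 1e-12)
    v <- rep(1, 5) / 5
    for (i in 1:10000) v <- as.vector(v %*% P)
    expect_equal(v, rep(0.2, 5), tolerance = 1e-9)
})

test_that("shift rate scales the off-diagonal mass toward the identity", {
    tiny <- generatorConfig(shiftRatePerHour = 1e-6)
    P <- calibratedTransitionMatrix(tiny)
    expect_equal(unname(diag(P)), rep(1, 5), tolerance = 1e-6)
})

test_that("infeasible calibrations are rejected", {
    bad <- generatorConfig(occupancyTargets = c(
        SUPINE = 0.988, PRONE = 0, LLR = 0.005, RLR = 0.005,
        OFFBED = 0.002))
    expect_error(calibratedTransitionMatrix(bad), "infeasible")
    # prone mass too large for the laterals under equal bout lengths
    lop <- generatorConfig(occupancyTargets = c(
        SUPINE = 0.1, PRONE = 0.7, LLR = 0.05, RLR = 0.05,
        OFFBED = 0.1))
    expect_error(calibratedTransitionMatrix(lop), "infeasible")
})

test_that("simulateSequence is reproducible and respects the support", {
    P <- calibratedTransitionMatrix(cfg)
    s1 <- simulateSequence(P, 5000, seed = 9)
    s2 <- simulateSequence(P, 5000, seed = 9)
    expect_identical(epochLabels(s1), epochLabels(s2))
    expect_equal(epochLabels(s1)[1], "SUPINE")
    # no forbidden transition ever appears
    mask <- defaultAllowedMask(TRUE)
    lab <- epochLabels(s1)
    pairs <- cbind(lab[-length(lab)], lab[-1])
    expect_true(all(mask[pairs]))
    # identity matrix freezes the chain
    I5 <- diag(5); dimnames(I5) <- dimnames(P)
    expect_equal(unique(epochLabels(simulateSequence(I5, 100, seed = 1,
                                                     initial = "PRONE"))),
                 "PRONE")
    bad <- P; bad[1, 1] <- bad[1, 1] + 0.1
    expect_error(simulateSequence(bad, 10, seed = 1), "invalid")
})

test_that("posture image templates have the documented geometry", {
    cfg0 <- generatorConfig(imageNoiseSd = 0)
    imgs <- lapply(postureLabels(TRUE), renderPostureImage, cfg = cfg0,
                   seed = 1)
    names(imgs) <- postureLabels(TRUE)
    # noiseless render equals the template: repeated calls identical
    expect_identical(pixels(imgs$SUPINE),
                     pixels(renderPostureImage("SUPINE", cfg0, seed = 99)))
    # LLR and RLR are exact horizontal mirrors
    expect_equal(pixels(imgs$LLR), pixels(imgs$RLR)[, 64:1])
    # lateral centroids sit on the expected side of the midline
    colCentroid <- function(img) {
        p <- pixels(img)
        sum(col(p) * p) / sum(p)
    }
    expect_lt(colCentroid(imgs$LLR), 32.5)
    expect_gt(colCentroid(imgs$RLR), 32.5)
    expect_equal(sum(pixels(imgs$OFFBED)), 0)
    # all classes distinct, values in [0, 1]
    for (im in imgs) {
        expect_true(all(pixels(im) >= 0 & pixels(im) <= 1))
    }
    expect_gt(max(abs(pixels(imgs$SUPINE) - pixels(imgs$PRONE))), 0.3)
    # noisy render is reproducible per (label, seed) and non-negative
    n1 <- renderPostureImage("LLR", cfg, seed = 5)
    n2 <- renderPostureImage("LLR", cfg, seed = 5)
    expect_identical(pixels(n1), pixels(n2))
    expect_true(all(pixels(n1) >= 0))
})

test_that("simulateHeartbeat draws truncated Normal bpm traces", {
    cfg0 <- generatorConfig(hbrSd = 0)
    t0 <- simulateHeartbeat("PRONE", 10, cfg0, seed = 1)
    expect_equal(t0$bpm, rep(56, 10))
    tr <- simulateHeartbeat("RLR", 10000, cfg, seed = 2)
    se <- cfg@hbrSd / sqrt(10000)
    expect_lt(abs(mean(tr$bpm) - 68), 3 * se)
    expect_true(all(tr$bpm >= 30 & tr$bpm <= 200))
    expect_identical(simulateHeartbeat("LLR", 5, cfg, seed = 3)$bpm,
                     simulateHeartbeat("LLR", 5, cfg, seed = 3)$bpm)
})

test_that("separated heartbeat means support a likelihood-ratio classifier", {
    set.seed(72)
    n <- 2000
    means <- cfg@hbrMeans[c("LLR", "RLR")]
    bpmL <- simulateHeartbeat("LLR", n, cfg, seed = 10)$bpm
    bpmR <- simulateHeartbeat("RLR", n, cfg, seed = 11)$bpm
    predL <- abs(bpmL - means["LLR"]) < abs(bpmL - means["RLR"])
    predR <- abs(bpmR - means["RLR"]) < abs(bpmR - means["LLR"])
    acc <- (sum(predL) + sum(predR)) / (2 * n)
    expect_gt(acc, 0.6)   # well above chance for 4-bpm separation
})

test_that("makeDataset assembles a reproducible end-to-end dataset", {
    ds <- makeDataset(cfg, nEpochs = 10, seed = 12)
    expect_identical(ds$labels, epochLabels(ds$sequence))
    expect_length(ds$images, 10)
    expect_equal(nrow(ds$heartbeats), 10 * 30)
    ds2 <- makeDataset(cfg, nEpochs = 10, seed = 12)
    expect_identical(ds$manifest, ds2$manifest)
    expect_identical(lapply(ds$images, pixels),
                     lapply(ds2$images, pixels))
    expect_identical(ds$heartbeats$bpm, ds2$heartbeats$bpm)
    # perfect oracle classifier on the generated truth gives accuracy 1
    ev <- evaluatePredictions(ds$labels, ds$labels)
    expect_equal(ev$accuracy, 1)
})

test_that("empirical occupancy and shift rate match the calibration", {
    P <- calibratedTransitionMatrix(cfg)
    s <- simulateSequence(P, 200000, seed = 13)
    occ <- estimateOccupancy(s)
    # Monte-Carlo standard errors from batch means (correlated chain)
    lab <- epochLabels(s)
    batch <- function(x) {
        b <- matrix(x[1:(2000 * floor(length(x) / 2000))],
                    nrow = 2000)
        colMeans(b)
    }
    for (stt in postureLabels(TRUE)) {
        bm <- batch(as.numeric(lab == stt))
        se <- stats::sd(bm) / sqrt(length(bm))
        expect_lt(abs(occ[[stt]] - occupancyTargets(cfg)[[stt]]),
                  3.5 * se + 1e-12)
    }
    sh <- shiftsPerHour(s)
    shifts <- as.numeric(lab[-1] != lab[-length(lab)])
    bm <- batch(shifts)
    seShift <- stats::sd(bm) / sqrt(length(bm)) * 120
    expect_lt(abs(sh - 1.6), 3.5 * seShift)
})
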