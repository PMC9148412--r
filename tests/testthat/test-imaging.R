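test_that("standardizeImage min-max scales and handles degenerate input", {
    # hand min-max computation: [[0,10],[5,10]] -> [[0,1],[0.5,1]]
    raw <- matrix(c(0, 10, 5, 10), 2, 2, byrow = TRUE)
    out <- standardizeImage(raw, 2, 2)
    expect_equal(pixels(out), matrix(c(0, 1, 0.5, 1), 2, 2, byrow = TRUE))
    # constant input maps to all zeros (max = min convention)
    expect_equal(pixels(standardizeImage(matrix(7, 3, 5), 3, 5)),
                 matrix(0, 3, 5))
    expect_error(standardizeImage(matrix(numeric(0), 0, 0)), "empty")
    expect_error(standardizeImage(matrix(1:4, 2), -2, 2), "at least 2")
})

test_that("standardizeImage downsampling is area averaging", {
    checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
    out <- standardizeImage(checker, 2, 2)
    expect_equal(pixels(out), matrix(0.5, 2, 2))
    # brute-force block average oracle on a random 6x6 -> 3x3 case
    set.seed(11)
    m <- matrix(runif(36), 6, 6)
    mm <- (m - min(m)) / diff(range(m))
    oracle <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
        oracle[i, j] <- mean(mm[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    expect_equal(pixels(standardizeImage(m, 3, 3)), oracle,
                 tolerance = 1e-12)
})

test_that("pulseThreshold is total intensity over nonzero count", {
    img <- PulseImage(matrix(c(4, 0, 2, 6), 2, 2, byrow = TRUE))
    # explicit-loop oracle
    p <- pixels(img); s <- 0; nz <- 0L
    for (v in as.vector(p)) { s <- s + v; if (v > 0) nz <- nz + 1L }
    expect_equal(pulseThreshold(img), s / nz)
    expect_equal(pulseThreshold(img), 4)
    expect_equal(pulseThreshold(PulseImage(matrix(3.2, 5, 5))), 3.2)
    expect_error(pulseThreshold(PulseImage(matrix(0, 3, 3))),
                 "degenerate")
})

test_that("thresholdFilter applies the cutoff in both modes", {
    img <- PulseImage(matrix(c(4, 0, 2, 6), 2, 2, byrow = TRUE))
    expect_equal(pixels(thresholdFilter(img, 4, "keep_low")),
                 matrix(c(4, 0, 2, 0), 2, 2, byrow = TRUE))
    expect_equal(pixels(thresholdFilter(img, 4, "keep_high")),
                 matrix(c(4, 0, 0, 6), 2, 2, byrow = TRUE))
    # threshold at the max keeps everything in keep_low mode
    expect_equal(pixels(thresholdFilter(img, 6, "keep_low")), pixels(img))
    # no positive value is <= 0
    pos <- PulseImage(matrix(1:9, 3))
    expect_equal(pixels(thresholdFilter(pos, 0, "keep_low")),
                 matrix(0, 3, 3))
    expect_error(thresholdFilter(img, -1), "non-negative")
})

test_that("thresholdFilter is idempotent and subsets the input values", {
    set.seed(21)
    img <- PulseImage(matrix(rexp(400), 20, 20))
    for (mode in c("keep_low", "keep_high")) {
        thr <- pulseThreshold(img)
        once <- thresholdFilter(img, thr, mode)
        twice <- thresholdFilter(once, thr, mode)
        expect_identical(pixels(once), pixels(twice))
        expect_true(all(pixels(once) %in% c(0, pixels(img))))
    }
})

test_that("gaussianKernel has the closed-form shape and normalization", {
    k <- kernelWeights(gaussianKernel(5, 1))
    expect_equal(sum(k), 1, tolerance = 1e-12)
    # center / corner ratio = exp((4 + 4) / 2) = e^4
    expect_equal(k[3, 3] / k[1, 1], exp(4), tolerance = 1e-12)
    expect_equal(k[3, 3], max(k))
    # symmetric under flips and 90-degree rotation
    expect_equal(k, k[5:1, ]); expect_equal(k, k[, 5:1])
    expect_equal(k, t(k))
    # flat-kernel limit
    kf <- kernelWeights(gaussianKernel(7, 1e6))
    expect_equal(as.vector(kf), rep(1 / 49, 49), tolerance = 1e-9)
    expect_error(gaussianKernel(4, 1), "odd")
    expect_error(gaussianKernel(5, 0), "positive")
})

test_that("gaussianFilter matches the nested-loop convolution oracle", {
    set.seed(31)
    k <- gaussianKernel(5, 1)
    for (rep in 1:5) {
        m <- matrix(runif(256), 16, 16)
        out <- pixels(gaussianFilter(PulseImage(m), k))
        expect_equal(out, ocConvolve(m, kernelWeights(k)),
                     tolerance = 1e-10)
    }
    # constant image is a fixed point; impulse reproduces the kernel
    expect_equal(pixels(gaussianFilter(PulseImage(matrix(2.5, 9, 9)), k)),
                 matrix(2.5, 9, 9), tolerance = 1e-12)
    imp <- matrix(0, 15, 15); imp[8, 8] <- 1
    out <- pixels(gaussianFilter(PulseImage(imp), k))
    expect_equal(out[6:10, 6:10], kernelWeights(k), tolerance = 1e-12)
    expect_error(gaussianFilter(PulseImage(matrix(1, 3, 3)), k), "larger")
})

test_that("gaussianFilter preserves interior-supported total intensity", {
    m <- matrix(0, 20, 20)
    m[8:13, 8:13] <- matrix(runif(36, 0.5, 1), 6, 6)
    sm <- gaussianFilter(PulseImage(m), gaussianKernel(5, 1))
    expect_equal(sum(pixels(sm)), sum(m), tolerance = 1e-9)
})

test_that("alignPrincipalAxis recovers blob orientation", {
    # already-vertical ellipse: angle ~ 0
    a0 <- alignPrincipalAxis(PulseImage(ocRotatedBlob(deg = 0)), 0.2)
    expect_lt(abs(a0@angle), 0.5)
    expect_false(a0@degenerate)
    # rotated by 30 degrees CCW: recovered within 1 degree
    a30 <- alignPrincipalAxis(PulseImage(ocRotatedBlob(deg = 30)), 0.2)
    expect_lt(abs(a30@angle - 30), 1)
    am <- alignPrincipalAxis(PulseImage(ocRotatedBlob(deg = -40)), 0.2)
    expect_lt(abs(am@angle + 40), 1)
    # rotated output has the same dimensions and a unit principal axis
    expect_equal(dim(a30@rotated), c(64L, 64L))
    expect_equal(sum(a30@principalAxis^2), 1, tolerance = 1e-9)
})

test_that("alignPrincipalAxis is self-consistent and flags isotropy", {
    a30 <- alignPrincipalAxis(PulseImage(ocRotatedBlob(deg = 30)), 0.2)
    again <- alignPrincipalAxis(a30@rotated, 0.2)
    expect_lt(abs(again@angle), 1)
    iso <- alignPrincipalAxis(
        PulseImage(ocRotatedBlob(deg = 0, sLong = 6, sShort = 6)), 0.2)
    expect_true(iso@degenerate)
    expect_equal(iso@angle, 0)
    tiny <- matrix(0, 8, 8); tiny[4, 4] <- 1
    expect_error(alignPrincipalAxis(PulseImage(tiny), 0.5),
                 "degenerate")
})
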