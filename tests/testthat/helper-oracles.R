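# Independent brute-force oracles used to cross-check the package's
# vectorized implementations.

# nested-loop 2-D convolution with reflect padding (no shared code with
# gaussianFilter)
ocConvolve <- function(img, kern) {
    n <- nrow(img); k <- ncol(img)
    r <- (nrow(kern) - 1L) %/% 2L
    reflect <- function(i, len) {
        while (i < 1L || i > len) {
            if (i < 1L) i <- 2L - i
            if (i > len) i <- 2L * len - i
        }
        i
    }
    out <- matrix(0, n, k)
    for (a in seq_len(n)) for (b in seq_len(k)) {
        acc <- 0
        for (da in -r:r) for (db in -r:r) {
            acc <- acc + kern[da + r + 1L, db + r + 1L] *
                img[reflect(a + da, n), reflect(b + db, k)]
        }
        out[a, b] <- acc
    }
    out
}

# closed-form eigendecomposition of a symmetric 2x2 matrix
ocEigen2 <- function(C) {
    a <- C[1L, 1L]; b <- C[1L, 2L]; d <- C[2L, 2L]
    tr <- a + d
    disc <- sqrt((a - d)^2 / 4 + b^2)
    vals <- c(tr / 2 + disc, tr / 2 - disc)
    vecOf <- function(l) {
        v <- if (abs(b) > 1e-14) c(b, l - a) else if (a >= d) c(1, 0)
             else c(0, 1)
        v / sqrt(sum(v^2))
    }
    list(values = vals, vectors = cbind(vecOf(vals[1L]), vecOf(vals[2L])))
}

# eigenvalues of a symmetric 3x3 matrix via polyroot of the
# characteristic polynomial
ocEigvals3 <- function(C) {
    p <- c(-det(C),
           C[1, 1] * C[2, 2] + C[1, 1] * C[3, 3] + C[2, 2] * C[3, 3] -
               C[1, 2]^2 - C[1, 3]^2 - C[2, 3]^2,
           -sum(diag(C)), 1)
    sort(Re(polyroot(p)), decreasing = TRUE)
}

# anisotropic Gaussian blob whose long axis is rotated `deg` CCW from
# vertical, used to exercise the principal-axis estimator
ocRotatedBlob <- function(size = 64L, deg = 0, sLong = 14, sShort = 4) {
    mid <- (size + 1) / 2
    th <- deg * pi / 180
    g <- expand.grid(r = seq_len(size), c = seq_len(size))
    x <- g$c - mid; y <- -(g$r - mid)
    # coordinates in the blob frame (long axis = y')
    xp <- cos(th) * x + sin(th) * y
    yp <- -sin(th) * x + cos(th) * y
    v <- exp(-(xp^2 / (2 * sShort^2) + yp^2 / (2 * sLong^2)))
    matrix(v, size, size)
}

# enumerate all label paths of a given length from a start state and
# return the most probable one under an order-1 transition matrix
ocMaxProbPath <- function(P, start, len) {
    st <- rownames(P)
    paths <- list(c(start))
    for (step in seq_len(len - 1L)) {
        paths <- unlist(lapply(paths, function(p)
            lapply(st, function(s) c(p, s))), recursive = FALSE)
    }
    probs <- vapply(paths, function(p) {
        pr <- 1
        for (i in seq_len(length(p) - 1L))
            pr <- pr * P[p[i], p[i + 1L]]
        pr
    }, numeric(1L))
    paths[[which.max(probs)]]
}

expect_postureFeatures <- function(f) {
    expect_s4_class(f, "PostureFeatures")
    expect_true(all(hogDescriptor(f) >= 0))
}
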