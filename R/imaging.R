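#' Standardize a raw intensity grid to a [0, 1] pulse image
#'
#' Min-max scales a raw non-negative intensity grid to [0, 1] and
#' resamples it to the target resolution by area averaging (each output
#' pixel is the overlap-weighted mean of the source pixels it covers, so
#' downsampling a block-constant image averages the blocks exactly).
#' Scaling happens before resampling; a constant input maps to the
#' all-zero image by convention (max = min leaves the scale undefined).
#'
#' @param raw numeric matrix of raw intensities.
#' @param targetHeight,targetWidth output dimensions; default 32 x 32.
#' @return A [PulseImage-class] with values in [0, 1].
#' @examples
#' raw <- matrix(c(0, 5, 10, 10), 2, 2)
#' pixels(standardizeImage(raw, 2, 2))
#' @export
standardizeImage <- function(raw, targetHeight = 32L, targetWidth = 32L) {
    raw <- as.matrix(raw)
    if (length(raw) == 0L) stop("input grid is empty")
    if (anyNA(raw) || any(!is.finite(raw))) stop("input grid must be finite")
    if (targetHeight < 2 || targetWidth < 2)
        stop("target dimensions must be at least 2")
    rng <- range(raw)
    scaled <- if (rng[2L] > rng[1L]) (raw - rng[1L]) / (rng[2L] - rng[1L])
              else array(0, dim(raw))
    PulseImage(.resampleArea(scaled, as.integer(targetHeight),
                             as.integer(targetWidth)))
}

# Area-average resampling: output pixel (I, J) covers the source box
# [(I-1)*h/H, I*h/H) x [(J-1)*w/W, J*w/W); its value is the mean of the
# source image over that box. Separable, so done with two 1-D overlap
# weight matrices.
.resampleArea <- function(m, H, W) {
    if (nrow(m) == H && ncol(m) == W) return(m)
    Wr <- .overlapWeights(nrow(m), H)
    Wc <- .overlapWeights(ncol(m), W)
    Wr %*% m %*% t(Wc)
}

# n source cells of unit length -> k target cells of length n/k; entry
# (i, j) is the fraction of target cell i covered by source cell j.
.overlapWeights <- function(n, k) {
    lo <- (seq_len(k) - 1L) * n / k
    hi <- seq_len(k) * n / k
    w <- matrix(0, k, n)
    for (j in seq_len(n)) {
        ov <- pmax(0, pmin(hi, j) - pmax(lo, j - 1L))
        w[, j] <- ov
    }
    w / (n / k)
}

#' Pulse-intensity threshold of an image
#'
#' The adaptive threshold used by the pulse-point filter: total image
#' intensity divided by the number of non-void (nonzero) pulse points.
#'
#' @param img a [PulseImage-class].
#' @return Positive scalar threshold in intensity units.
#' @examples
#' pulseThreshold(PulseImage(matrix(c(4, 0, 2, 6), 2, 2))) # 12 / 3
#' @export
pulseThreshold <- function(img) {
    stopifnot(is(img, "PulseImage"))
    p <- pixels(img)
    nz <- sum(p > 0)
    if (nz == 0L)
        stop("degenerate image: all pulse points are void, ",
             "threshold undefined")
    sum(p) / nz
}

#' Threshold filtering of a pulse image
#'
#' Keeps pixels on one side of the threshold and voids (zeros) the rest.
#' The default `keep_low` mode retains values less than or equal to the
#' threshold; `keep_high` reverses the inequality (the usual denoising
#' direction). The operation is idempotent and never introduces values
#' not already present in the image.
#'
#' @param img a [PulseImage-class].
#' @param threshold non-negative cutoff; defaults to [pulseThreshold()]
#'   of the image.
#' @param mode `"keep_low"` or `"keep_high"`.
#' @return Filtered [PulseImage-class] of the same dimensions.
#' @examples
#' img <- PulseImage(matrix(c(4, 0, 2, 6), 2, 2))
#' pixels(thresholdFilter(img, 4))
#' @export
thresholdFilter <- function(img, threshold = pulseThreshold(img),
                            mode = c("keep_low", "keep_high")) {
    stopifnot(is(img, "PulseImage"))
    mode <- match.arg(mode)
    if (threshold < 0) stop("threshold must be non-negative")
    p <- pixels(img)
    keep <- if (mode == "keep_low") p <= threshold else p >= threshold
    PulseImage(ifelse(keep, p, 0))
}

#' Normalized discrete 2-D Gaussian kernel
#'
#' Weights proportional to exp(-(x^2 + y^2) / (2 sigma^2)) on the
#' integer grid centered at 0, renormalized to sum to exactly 1.
#'
#' @param size odd kernel side length >= 3; default 5.
#' @param sigma positive standard deviation in pixels; default 1.
#' @return A [GaussianKernel-class].
#' @examples
#' k <- gaussianKernel(5, 1)
#' sum(kernelWeights(k)) # 1
#' @export
gaussianKernel <- function(size = 5L, sigma = 1) {
    size <- as.integer(size)
    if (size %% 2L == 0L || size < 3L)
        stop("kernel size must be odd and at least 3")
    if (sigma <= 0) stop("sigma must be positive")
    r <- (size - 1L) %/% 2L
    g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    w <- outer(g, g)
    new("GaussianKernel", weights = w / sum(w), sigma = sigma)
}

#' @describeIn gaussianKernel extract the weight matrix.
#' @param kernel a GaussianKernel.
#' @export
kernelWeights <- function(kernel) {
    stopifnot(is(kernel, "GaussianKernel"))
    kernel@weights
}

#' Gaussian smoothing of a pulse image
#'
#' 2-D convolution of the image with a normalized Gaussian kernel, using
#' reflect border padding (the image is mirrored across each edge, which
#' preserves the local mean at borders). Because the kernel sums to 1,
#' constant images are fixed points.
#'
#' @param img a [PulseImage-class].
#' @param kernel a [GaussianKernel-class]; default 5 x 5, sigma 1.
#' @return Smoothed [PulseImage-class] of the same dimensions.
#' @export
gaussianFilter <- function(img, kernel = gaussianKernel()) {
    stopifnot(is(img, "PulseImage"), is(kernel, "GaussianKernel"))
    p <- pixels(img)
    w <- kernel@weights
    r <- (nrow(w) - 1L) %/% 2L
    if (nrow(w) > nrow(p) || ncol(w) > ncol(p))
        stop("kernel larger than image")
    pad <- .padReflect(p, r)
    out <- matrix(0, nrow(p), ncol(p))
    for (di in seq_len(nrow(w))) {
        for (dj in seq_len(ncol(w))) {
            out <- out + w[di, dj] *
                pad[(di - 1L) + seq_len(nrow(p)),
                    (dj - 1L) + seq_len(ncol(p))]
        }
    }
    PulseImage(pmax(out, 0))
}

# mirror the border rows/columns (without repeating the edge pixel)
.padReflect <- function(m, r) {
    n <- nrow(m); k <- ncol(m)
    ri <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    ci <- c(rev(seq_len(r) + 1L), seq_len(k), k - seq_len(r))
    m[ri, ci, drop = FALSE]
}

#' Rotation-PCA alignment of a pulse image
#'
#' Treats the coordinates of above-threshold pixels, weighted by their
#' intensity, as a point cloud; the orientation of the leading
#' eigenvector of the weighted coordinate covariance gives the principal
#' axis of the body silhouette. The image is then resampled (bilinear
#' interpolation, 0 outside the support) so that axis is vertical.
#'
#' Angles are counter-clockwise positive, reported in (-90, 90]. The
#' eigenvector sign ambiguity is resolved by forcing a non-negative
#' vertical component. If the cloud is isotropic (relative eigenvalue
#' gap below 1e-9) the angle defaults to 0 and `degenerate` is set.
#'
#' @param img a [PulseImage-class], typically standardized to [0, 1].
#' @param intensityThreshold foreground cutoff; default 0.5725 on
#'   standardized images.
#' @return An [AlignmentResult-class].
#' @export
alignPrincipalAxis <- function(img, intensityThreshold = 0.5725) {
    stopifnot(is(img, "PulseImage"))
    p <- pixels(img)
    fg <- which(p > intensityThreshold, arr.ind = TRUE)
    if (nrow(fg) < 3L)
        stop("degenerate image: fewer than 3 pixels above the ",
             "intensity threshold")
    wt <- p[fg]
    # mathematical coordinates: x right (columns), y up (negated rows)
    x <- fg[, 2L]; y <- -fg[, 1L]
    mx <- sum(wt * x) / sum(wt); my <- sum(wt * y) / sum(wt)
    cx <- x - mx; cy <- y - my
    cov <- matrix(c(sum(wt * cx * cx), sum(wt * cx * cy),
                    sum(wt * cx * cy), sum(wt * cy * cy)), 2L) / sum(wt)
    eg <- eigen(cov, symmetric = TRUE)
    gap <- (eg$values[1L] - eg$values[2L]) /
        max(eg$values[1L], .Machine$double.eps)
    degenerate <- gap < 1e-9
    if (degenerate) {
        axis <- c(0, 1)
        angle <- 0
    } else {
        axis <- eg$vectors[, 1L]
        if (axis[2L] < 0) axis <- -axis
        if (axis[2L] == 0 && axis[1L] < 0) axis <- -axis
        # CCW angle that carried the vertical axis onto the eigenvector
        angle <- -atan2(axis[1L], axis[2L]) * 180 / pi
        if (angle <= -90) angle <- angle + 180
        if (angle > 90) angle <- angle - 180
    }
    rotated <- .rotateBilinear(p, -angle)
    new("AlignmentResult", rotated = PulseImage(rotated), angle = angle,
        principalAxis = axis / sqrt(sum(axis^2)), degenerate = degenerate)
}

# rotate image by `deg` CCW about its center; bilinear, 0 outside
.rotateBilinear <- function(m, deg) {
    n <- nrow(m); k <- ncol(m)
    th <- deg * pi / 180
    cs <- cos(th); sn <- sin(th)
    cx <- (k + 1) / 2; cy <- (n + 1) / 2
    out <- matrix(0, n, k)
    cols <- rep(seq_len(k), each = n)
    rows <- rep(seq_len(n), times = k)
    # inverse map output pixel -> source location (math coords, y up)
    xo <- cols - cx; yo <- -(rows - cy)
    xs <- cs * xo + sn * yo
    ys <- -sn * xo + cs * yo
    sc <- xs + cx          # source column (fractional)
    sr <- -ys + cy         # source row (fractional)
    c0 <- floor(sc); r0 <- floor(sr)
    fc <- sc - c0; fr <- sr - r0
    val <- numeric(length(cols))
    for (dd in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        rr <- r0 + dd[1L]; cc <- c0 + dd[2L]
        wgt <- (if (dd[1L] == 0) 1 - fr else fr) *
               (if (dd[2L] == 0) 1 - fc else fc)
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= k
        idx <- which(ok)
        val[idx] <- val[idx] + wgt[idx] * m[cbind(rr[idx], cc[idx])]
    }
    matrix(val, n, k)
}
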