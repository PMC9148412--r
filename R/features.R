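#' Histogram of oriented gradients descriptor
#'
#' Computes a HOG descriptor of a pulse image: gradients by central
#' differences (replicated borders, so a constant image has zero
#' gradient everywhere), unsigned orientation binned into `nBins` bins
#' over [0, 180) degrees with gradient-magnitude votes, magnitudes
#' summed per cell, then blocks of `blockCells` x `blockCells` cells
#' (stride one cell) L2-normalized with guard epsilon 1e-6. Descriptor
#' length is nBlocksY * nBlocksX * blockCells^2 * nBins.
#'
#' @param img a [PulseImage-class].
#' @param cellSize cell side in pixels; default 8.
#' @param blockCells block side in cells; default 2.
#' @param nBins unsigned orientation bins; default 9.
#' @return Numeric non-negative descriptor vector.
#' @examples
#' img <- PulseImage(matrix(runif(64 * 64), 64, 64))
#' length(computeHOG(img)) # 7 * 7 * 2 * 2 * 9 = 1764
#' @export
computeHOG <- function(img, cellSize = 8L, blockCells = 2L, nBins = 9L) {
    stopifnot(is(img, "PulseImage"))
    p <- pixels(img)
    cellSize <- as.integer(cellSize)
    blockCells <- as.integer(blockCells)
    nBins <- as.integer(nBins)
    ny <- nrow(p) %/% cellSize
    nx <- ncol(p) %/% cellSize
    if (ny < blockCells || nx < blockCells)
        stop("image too small: needs at least one ",
             blockCells * cellSize, "-pixel block")
    p <- p[seq_len(ny * cellSize), seq_len(nx * cellSize), drop = FALSE]
    n <- nrow(p); k <- ncol(p)
    # central differences with replicated borders
    gx <- (p[, pmin(seq_len(k) + 1L, k)] - p[, pmax(seq_len(k) - 1L, 1L)]) / 2
    gy <- (p[pmin(seq_len(n) + 1L, n), ] - p[pmax(seq_len(n) - 1L, 1L), ]) / 2
    mag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx) * 180 / pi          # (-180, 180]
    ang <- ang %% 180                        # unsigned, [0, 180)
    bin <- pmin(floor(ang / (180 / nBins)), nBins - 1L) + 1L
    cellRow <- (seq_len(n) - 1L) %/% cellSize + 1L
    cellCol <- (seq_len(k) - 1L) %/% cellSize + 1L
    # accumulate magnitude votes into (cellRow, cellCol, bin)
    idx <- cellRow[row(p)] +
        (cellCol[col(p)] - 1L) * ny +
        (bin - 1L) * (ny * nx)
    hist3 <- array(0, c(ny, nx, nBins))
    acc <- rowsum(as.vector(mag), group = as.vector(idx))
    hist3[as.integer(rownames(acc))] <- acc
    # block normalization, stride one cell
    nby <- ny - blockCells + 1L
    nbx <- nx - blockCells + 1L
    out <- numeric(nby * nbx * blockCells^2 * nBins)
    blockLen <- blockCells^2 * nBins
    pos <- 0L
    for (bx in seq_len(nbx)) {
        for (by in seq_len(nby)) {
            v <- as.vector(hist3[by + seq_len(blockCells) - 1L,
                                 bx + seq_len(blockCells) - 1L, ])
            out[pos + seq_len(blockLen)] <- v / sqrt(sum(v^2) + 1e-6^2)
            pos <- pos + blockLen
        }
    }
    out
}

#' Pressure-weight normalization and scale factor
#'
#' Normalizes a vector of non-negative pressure-point readings to
#' weights summing to 1 (w_i = p_i / sum p) and computes the scale
#' factor sqrt(w_n / w_1) from the last and first weights.
#'
#' @param pressurePoints numeric vector of non-negative readings, at
#'   least one positive.
#' @return A list with components `weights` and `scaleFactor`.
#' @examples
#' pressureWeights(c(2, 6)) # weights 0.25/0.75, scale factor sqrt(3)
#' @export
pressureWeights <- function(pressurePoints) {
    p <- as.numeric(pressurePoints)
    if (any(p < 0)) stop("pressure points must be non-negative")
    s <- sum(p)
    if (s == 0) stop("degenerate input: all pressure points are zero")
    w <- p / s
    if (w[1L] == 0)
        stop("scale factor undefined: first pressure weight is zero")
    list(weights = w, scaleFactor = sqrt(w[length(w)] / w[1L]))
}

#' Extract a full feature vector from a pulse image
#'
#' Runs [computeHOG()] and [pressureWeights()] (pressure points are the
#' per-cell intensity sums, in column-major cell order) and assembles a
#' [PostureFeatures-class]. Deterministic for fixed input and
#' configuration. A blank image yields a zero HOG descriptor and falls
#' back to uniform pressure weights with a warning (scale factor 1), so
#' batch pipelines do not abort on empty frames.
#'
#' @param img a [PulseImage-class] standardized to [0, 1].
#' @param cellSize,blockCells,nBins HOG geometry, see [computeHOG()].
#' @return A [PostureFeatures-class].
#' @export
extractFeatures <- function(img, cellSize = 8L, blockCells = 2L,
                            nBins = 9L) {
    stopifnot(is(img, "PulseImage"))
    hog <- computeHOG(img, cellSize, blockCells, nBins)
    p <- pixels(img)
    ny <- nrow(p) %/% cellSize
    nx <- ncol(p) %/% cellSize
    p <- p[seq_len(ny * cellSize), seq_len(nx * cellSize), drop = FALSE]
    cellRow <- (seq_len(nrow(p)) - 1L) %/% cellSize + 1L
    cellCol <- (seq_len(ncol(p)) - 1L) %/% cellSize + 1L
    cellIdx <- cellRow[row(p)] + (cellCol[col(p)] - 1L) * ny
    sums <- rowsum(as.vector(p), group = as.vector(cellIdx))
    pts <- numeric(ny * nx)
    pts[as.integer(rownames(sums))] <- sums
    if (sum(pts) == 0) {
        warning("blank image: falling back to uniform pressure weights")
        wts <- rep(1 / length(pts), length(pts))
        sf <- 1
    } else if (pts[1L] == 0) {
        warning("first pressure cell is void: scale factor undefined, ",
                "set to 1")
        wts <- pts / sum(pts)
        sf <- 1
    } else {
        pw <- pressureWeights(pts)
        wts <- pw$weights
        sf <- pw$scaleFactor
    }
    new("PostureFeatures", hog = hog, weights = wts, scaleFactor = sf)
}
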