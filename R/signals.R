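#' Slow-time moving-average smoothing
#'
#' Replaces each entry X(i, j) by the mean of the slow-time window
#' j - R ... j + R of its row. Windows are truncated at the matrix edges
#' and renormalized by the actual window length, so edge means are not
#' biased by phantom zeros. All entries are updated simultaneously from
#' the original matrix. R = 0 is the identity.
#'
#' @param X a [HeartbeatMatrix-class].
#' @param R non-negative half-window length in slow-time samples;
#'   default 2 (a 5-sample window).
#' @return Smoothed [HeartbeatMatrix-class] of the same dimensions.
#' @examples
#' signalValues(smoothSlowTime(HeartbeatMatrix(c(1, 2, 3)), R = 1))
#' @export
smoothSlowTime <- function(X, R = 2L) {
    stopifnot(is(X, "HeartbeatMatrix"))
    R <- as.integer(R)
    if (R < 0L) stop("half-window R must be non-negative")
    v <- signalValues(X)
    if (R == 0L) return(X)
    M <- ncol(v)
    lo <- pmax(seq_len(M) - R, 1L)
    hi <- pmin(seq_len(M) + R, M)
    cs <- cbind(0, t(apply(v, 1L, cumsum)))   # N x (M + 1)
    out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
        rep(hi - lo + 1L, each = nrow(v))
    HeartbeatMatrix(out)
}

#' Mean-center each fast-time row over slow time
#'
#' Subtracts the slow-time mean from every row so each output row sums
#' to zero.
#'
#' @param X a [HeartbeatMatrix-class] with at least 2 slow-time columns.
#' @return Centered [HeartbeatMatrix-class].
#' @export
meanCenter <- function(X) {
    stopifnot(is(X, "HeartbeatMatrix"))
    v <- signalValues(X)
    HeartbeatMatrix(v - rowMeans(v))
}

#' PCA decomposition of a centered heartbeat matrix
#'
#' Computes the sample covariance C = Xc Xc' / (M - 1) of the centered
#' matrix and its eigendecomposition, eigenvalues sorted non-increasing.
#' The singular values of Xc are returned alongside; they satisfy
#' lambda = s^2 / (M - 1). Eigenvector signs are fixed by forcing the
#' largest-magnitude component of each vector to be non-negative, so the
#' decomposition is deterministic.
#'
#' @param Xc a mean-centered [HeartbeatMatrix-class] (row means at most
#'   1e-8 in magnitude relative to the row scale).
#' @return A [PCADecomposition-class].
#' @examples
#' X <- meanCenter(HeartbeatMatrix(matrix(rnorm(40), 4, 10)))
#' dec <- pcaDecompose(X)
#' dec@eigenvalues
#' @export
pcaDecompose <- function(Xc) {
    stopifnot(is(Xc, "HeartbeatMatrix"))
    v <- signalValues(Xc)
    scale <- max(mean(abs(v)), .Machine$double.eps)
    if (max(abs(rowMeans(v))) > 1e-8 * max(1, scale))
        stop("input is not mean-centered; call meanCenter() first")
    M <- ncol(v)
    C <- tcrossprod(v) / (M - 1)
    eg <- eigen(C, symmetric = TRUE)
    U <- eg$vectors
    for (j in seq_len(ncol(U))) {
        i <- which.max(abs(U[, j]))
        if (U[i, j] < 0) U[, j] <- -U[, j]
    }
    sv <- svd(v, nu = 0L, nv = min(dim(v)))
    new("PCADecomposition",
        eigenvalues = pmax(eg$values, 0),
        eigenvectors = U,
        singularValues = sv$d,
        rightVectors = sv$v)
}

#' Project a centered heartbeat matrix onto leading components
#'
#' Returns Yk = Uk' Xc, the k x M matrix of scores on the k leading
#' eigenvectors. Projecting onto all components preserves total
#' variance; the variance of score row 1 equals the leading eigenvalue.
#'
#' @param Xc a mean-centered [HeartbeatMatrix-class].
#' @param dec its [PCADecomposition-class].
#' @param k number of leading components, 1 <= k <= N.
#' @return Numeric k x M score matrix.
#' @export
pcaProject <- function(Xc, dec, k) {
    stopifnot(is(Xc, "HeartbeatMatrix"), is(dec, "PCADecomposition"))
    v <- signalValues(Xc)
    k <- as.integer(k)
    if (k < 1L || k > ncol(dec@eigenvectors))
        stop("k must be between 1 and the number of components (",
             ncol(dec@eigenvectors), ")")
    crossprod(dec@eigenvectors[, seq_len(k), drop = FALSE], v)
}
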