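#' @import methods
NULL

#' Posture label universe
#'
#' The four in-bed posture classes used throughout the package, in the
#' canonical order used for tie-breaking and for all probability vectors:
#' supine, prone, left lateral recumbent (LLR), right lateral recumbent
#' (RLR). An optional fifth state, OFFBED, represents time spent out of
#' bed and is used only by the synthetic-sequence generator.
#'
#' @param includeOffbed logical; append the OFFBED calibration state.
#' @return Character vector of posture labels.
#' @examples
#' postureLabels()
#' postureLabels(includeOffbed = TRUE)
#' @export
postureLabels <- function(includeOffbed = FALSE) {
    lab <- c("SUPINE", "PRONE", "LLR", "RLR")
    if (includeOffbed) lab <- c(lab, "OFFBED")
    lab
}

.checkLabels <- function(x, allowOffbed = TRUE) {
    bad <- setdiff(unique(x), postureLabels(includeOffbed = allowOffbed))
    if (length(bad))
        stop("unknown posture label(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    invisible(TRUE)
}

#' PulseImage: a 2-D pulse/pressure intensity map
#'
#' Container for a single frame of the pulse-point sensor array: a matrix
#' of non-negative intensities (dimensionless pulse/pressure units),
#' 64 x 64 by default. All image operators in the package act on this
#' class.
#'
#' @slot pixels numeric matrix of non-negative intensities; rows are the
#'   vertical (head-to-foot) axis, columns the horizontal axis.
#' @seealso [PulseImage()], [standardizeImage()], [thresholdFilter()],
#'   [gaussianFilter()], [alignPrincipalAxis()]
#' @export
setClass("PulseImage", representation(pixels = "matrix"))

setValidity("PulseImage", function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) < 2L || ncol(p) < 2L) return("image must be at least 2 x 2")
    if (anyNA(p) || any(!is.finite(p))) return("pixels must be finite")
    if (any(p < 0)) return("pixel intensities must be non-negative")
    TRUE
})

#' Construct a PulseImage
#'
#' @param pixels numeric matrix (or object coercible to one) of
#'   non-negative intensities.
#' @return A [PulseImage-class] object.
#' @examples
#' img <- PulseImage(matrix(runif(16), 4, 4))
#' dim(img)
#' @export
PulseImage <- function(pixels) {
    pixels <- as.matrix(pixels)
    storage.mode(pixels) <- "double"
    new("PulseImage", pixels = pixels)
}

#' GaussianKernel: a normalized discrete 2-D Gaussian
#'
#' Discrete Gaussian smoothing kernel on an odd-sized square support,
#' renormalized so the weights sum to exactly 1 (the continuous
#' normalizer does not sum to 1 on a truncated grid).
#'
#' @slot weights numeric matrix of kernel weights summing to 1.
#' @slot sigma positive standard deviation in pixels.
#' @seealso [gaussianKernel()], [gaussianFilter()]
#' @export
setClass("GaussianKernel",
         representation(weights = "matrix", sigma = "numeric"))

setValidity("GaussianKernel", function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w) || nrow(w) %% 2L == 0L)
        return("kernel support must be square with odd size")
    if (abs(sum(w) - 1) > 1e-9) return("kernel weights must sum to 1")
    if (length(object@sigma) != 1L || object@sigma <= 0)
        return("sigma must be a single positive number")
    TRUE
})

#' AlignmentResult: outcome of rotation-PCA image alignment
#'
#' @slot rotated the aligned [PulseImage-class] (same dimensions as the
#'   input).
#' @slot angle estimated orientation of the principal axis in degrees,
#'   counter-clockwise positive, in (-90, 90].
#' @slot principalAxis unit 2-vector (x, y) of the leading eigenvector in
#'   mathematical coordinates (x right, y up).
#' @slot degenerate logical; TRUE when the foreground point cloud was
#'   isotropic and the angle defaulted to 0.
#' @seealso [alignPrincipalAxis()]
#' @export
setClass("AlignmentResult",
         representation(rotated = "PulseImage", angle = "numeric",
                        principalAxis = "numeric", degenerate = "logical"))

setValidity("AlignmentResult", function(object) {
    if (abs(sqrt(sum(object@principalAxis^2)) - 1) > 1e-9)
        return("principalAxis must have unit norm")
    if (object@angle <= -90 || object@angle > 90)
        return("angle must lie in (-90, 90]")
    TRUE
})

#' HeartbeatMatrix: fast-time x slow-time signal matrix
#'
#' The heartbeat signal arranged as a 2-D matrix X(i, j) with fast-time
#' index i along rows (N rows, e.g. one row per sensor site) and
#' slow-time index j along columns (M columns, successive observations).
#'
#' @slot values numeric N x M matrix of finite signal values.
#' @seealso [HeartbeatMatrix()], [smoothSlowTime()], [pcaDecompose()]
#' @export
setClass("HeartbeatMatrix", representation(values = "matrix"))

setValidity("HeartbeatMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (nrow(v) < 1L || ncol(v) < 2L)
        return("need at least 1 fast-time row and 2 slow-time columns")
    if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
    TRUE
})

#' Construct a HeartbeatMatrix
#'
#' @param values numeric matrix, fast time along rows, slow time along
#'   columns. A plain vector is treated as a single fast-time row.
#' @return A [HeartbeatMatrix-class] object.
#' @export
HeartbeatMatrix <- function(values) {
    if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("HeartbeatMatrix", values = values)
}

#' PCADecomposition: eigenstructure of a heartbeat covariance matrix
#'
#' @slot eigenvalues non-increasing eigenvalues of the sample covariance
#'   (divisor M - 1).
#' @slot eigenvectors orthonormal eigenvector columns, signs fixed so the
#'   largest-magnitude component of each column is non-negative.
#' @slot singularValues singular values of the centered matrix; the
#'   identity lambda = s^2 / (M - 1) links them to the eigenvalues.
#' @slot rightVectors orthonormal right singular vector columns.
#' @seealso [pcaDecompose()], [pcaProject()]
#' @export
setClass("PCADecomposition",
         representation(eigenvalues = "numeric", eigenvectors = "matrix",
                        singularValues = "numeric", rightVectors = "matrix"))

setValidity("PCADecomposition", function(object) {
    ev <- object@eigenvalues
    if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-9))
        return("eigenvalues must be non-increasing")
    if (any(ev < -1e-9)) return("eigenvalues must be non-negative")
    U <- object@eigenvectors
    if (max(abs(crossprod(U) - diag(ncol(U)))) > 1e-8)
        return("eigenvectors must be orthonormal")
    TRUE
})

#' PostureSequence: ordered posture labels over fixed-length epochs
#'
#' @slot labels character vector of posture labels, one per epoch.
#' @slot epochSeconds positive epoch duration in seconds (default 30).
#' @seealso [PostureSequence()], [estimateOccupancy()], [shiftsPerHour()]
#' @export
setClass("PostureSequence",
         representation(labels = "character", epochSeconds = "numeric"))

setValidity("PostureSequence", function(object) {
    if (length(object@labels) < 1L) return("sequence must be non-empty")
    if (length(object@epochSeconds) != 1L || object@epochSeconds <= 0)
        return("epochSeconds must be a single positive number")
    bad <- setdiff(unique(object@labels), postureLabels(TRUE))
    if (length(bad))
        return(paste("unknown posture label(s):",
                     paste(bad, collapse = ", ")))
    TRUE
})

#' Construct a PostureSequence
#'
#' @param labels character vector of posture labels (see
#'   [postureLabels()]).
#' @param epochSeconds epoch duration in seconds; default 30.
#' @return A [PostureSequence-class] object.
#' @examples
#' s <- PostureSequence(c("SUPINE", "SUPINE", "LLR"))
#' estimateOccupancy(s)
#' @export
PostureSequence <- function(labels, epochSeconds = 30) {
    new("PostureSequence", labels = as.character(labels),
        epochSeconds = as.numeric(epochSeconds))
}

#' TransitionModel: constrained posture-transition distributions
#'
#' Conditional distributions P(next posture | history) of order 1 or 2,
#' with structural zeros: transitions forbidden by the allowed mask have
#' probability exactly 0 regardless of data or smoothing. For order 1 the
#' probability table is an n x n matrix (rows = current state); for order
#' 2 it is an n x n x n array indexed [previous, current, next].
#'
#' @slot order integer, 1 or 2.
#' @slot probs probability table (matrix or 3-D array).
#' @slot mask logical matrix of allowed transitions (from x to).
#' @slot alpha non-negative additive smoothing pseudo-count applied to
#'   allowed targets only.
#' @slot states character vector of state names in canonical order.
#' @seealso [fitTransitionModel()], [predictNext()], [defaultAllowedMask()]
#' @export
setClass("TransitionModel",
         representation(order = "integer", probs = "array",
                        mask = "matrix", alpha = "numeric",
                        states = "character"))

setValidity("TransitionModel", function(object) {
    if (!object@order %in% c(1L, 2L)) return("order must be 1 or 2")
    n <- length(object@states)
    if (!identical(dim(object@mask), c(n, n)))
        return("mask dimensions must match the state set")
    d <- dim(object@probs)
    if (object@order == 1L && !identical(d, c(n, n)))
        return("order-1 probs must be n x n")
    if (object@order == 2L && !identical(d, c(n, n, n)))
        return("order-2 probs must be n x n x n")
    if (object@alpha < 0) return("alpha must be non-negative")
    TRUE
})

#' PredictionResult: posterior over the next posture
#'
#' @slot posterior named probability vector over posture labels, summing
#'   to 1.
#' @slot predicted the argmax label (ties broken by canonical label
#'   order).
#' @slot historyUsed the history labels the prediction conditioned on.
#' @seealso [predictNext()]
#' @export
setClass("PredictionResult",
         representation(posterior = "numeric", predicted = "character",
                        historyUsed = "character"))

setValidity("PredictionResult", function(object) {
    if (abs(sum(object@posterior) - 1) > 1e-9)
        return("posterior must sum to 1")
    if (object@posterior[object@predicted] < max(object@posterior) - 1e-12)
        return("predicted label must attain the maximum posterior")
    TRUE
})

#' PostureFeatures: HOG descriptor with pressure-weight normalization
#'
#' @slot hog non-negative block-normalized gradient-orientation
#'   histogram, flattened.
#' @slot weights per-cell pressure weights summing to 1.
#' @slot scaleFactor sqrt(w_n / w_1), the last-to-first weight-ratio
#'   scale factor.
#' @seealso [extractFeatures()], [computeHOG()], [pressureWeights()]
#' @export
setClass("PostureFeatures",
         representation(hog = "numeric", weights = "numeric",
                        scaleFactor = "numeric"))

setValidity("PostureFeatures", function(object) {
    if (any(object@hog < -1e-12)) return("hog entries must be non-negative")
    if (length(object@weights) &&
        abs(sum(object@weights) - 1) > 1e-9)
        return("weights must sum to 1")
    TRUE
})

#' TemplateClassifier: nearest-centroid soft posture classifier
#'
#' Deterministic stand-in for a learned frame classifier: one centroid
#' (class-mean descriptor) per posture, with squared-distance softmax
#' probabilities p(c) proportional to exp(-d_c^2 / temperature). It sits
#' behind the same interface a learned model would, so it can be swapped
#' out.
#'
#' @slot centroids numeric matrix, one row per posture label (rownames),
#'   columns are descriptor dimensions.
#' @slot temperature positive softness of the distance-to-probability
#'   conversion.
#' @seealso [trainClassifier()], [classifyPosture()]
#' @export
setClass("TemplateClassifier",
         representation(centroids = "matrix", temperature = "numeric"))

setValidity("TemplateClassifier", function(object) {
    need <- postureLabels()
    if (!all(need %in% rownames(object@centroids)))
        return(paste("centroids missing label(s):",
                     paste(setdiff(need, rownames(object@centroids)),
                           collapse = ", ")))
    if (object@temperature <= 0) return("temperature must be positive")
    TRUE
})

#' GeneratorConfig: parameters of the synthetic-data generator
#'
#' Defaults reproduce the accelerometer-cohort statistics the generator
#' is calibrated to: 54.1% of epochs lateral (split equally between LLR
#' and RLR), 37.5% prone, 7.3% supine, with the residual 1.1% modelled as
#' an explicit OFFBED state, and 1.6 posture shifts per hour at 30-second
#' epochs. Image templates and heartbeat means are generator parameters,
#' not published values.
#'
#' @slot occupancyTargets named stationary distribution over
#'   SUPINE/PRONE/LLR/RLR/OFFBED, summing to 1.
#' @slot shiftRatePerHour target posture shifts per hour (> 0).
#' @slot epochSeconds epoch duration in seconds.
#' @slot imageNoiseSd standard deviation of truncated Gaussian pixel
#'   noise added to the class templates.
#' @slot hbrMeans named mean heartbeat rate (bpm) per posture.
#' @slot hbrSd heartbeat-rate standard deviation (bpm).
#' @seealso [generatorConfig()], [calibratedTransitionMatrix()],
#'   [makeDataset()]
#' @export
setClass("GeneratorConfig",
         representation(occupancyTargets = "numeric",
                        shiftRatePerHour = "numeric",
                        epochSeconds = "numeric",
                        imageNoiseSd = "numeric",
                        hbrMeans = "numeric", hbrSd = "numeric"))

setValidity("GeneratorConfig", function(object) {
    occ <- object@occupancyTargets
    if (is.null(names(occ)) ||
        !setequal(names(occ), postureLabels(TRUE)))
        return("occupancyTargets must be named over all five states")
    if (abs(sum(occ) - 1) > 1e-9) return("occupancyTargets must sum to 1")
    if (any(occ < 0)) return("occupancyTargets must be non-negative")
    if (object@shiftRatePerHour <= 0)
        return("shiftRatePerHour must be positive")
    if (object@epochSeconds <= 0) return("epochSeconds must be positive")
    if (object@imageNoiseSd < 0) return("imageNoiseSd must be >= 0")
    if (!all(postureLabels(TRUE) %in% names(object@hbrMeans)))
        return("hbrMeans must cover all five states")
    if (object@hbrSd < 0) return("hbrSd must be >= 0")
    TRUE
})

#' Construct a GeneratorConfig
#'
#' @param occupancyTargets named stationary occupancy targets over the
#'   five states; the default encodes the cohort figures (lateral total
#'   0.541 split evenly, prone 0.375, supine 0.073) with the 1.1%
#'   remainder assigned to OFFBED.
#' @param shiftRatePerHour target shift rate; default 1.6.
#' @param epochSeconds epoch length; default 30.
#' @param imageNoiseSd pixel noise s.d.; default 0.05.
#' @param hbrMeans named per-posture mean bpm (generator parameters).
#' @param hbrSd bpm standard deviation; default 2.
#' @return A [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig()
#' occupancyTargets(cfg)
#' @export
generatorConfig <- function(occupancyTargets = c(SUPINE = 0.073,
                                                 PRONE = 0.375,
                                                 LLR = 0.2705,
                                                 RLR = 0.2705,
                                                 OFFBED = 0.011),
                            shiftRatePerHour = 1.6,
                            epochSeconds = 30,
                            imageNoiseSd = 0.05,
                            hbrMeans = c(SUPINE = 60, PRONE = 56,
                                         LLR = 64, RLR = 68,
                                         OFFBED = 74),
                            hbrSd = 2) {
    new("GeneratorConfig",
        occupancyTargets = occupancyTargets[postureLabels(TRUE)],
        shiftRatePerHour = shiftRatePerHour,
        epochSeconds = epochSeconds,
        imageNoiseSd = imageNoiseSd,
        hbrMeans = hbrMeans[postureLabels(TRUE)],
        hbrSd = hbrSd)
}
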