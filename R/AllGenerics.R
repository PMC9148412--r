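#' Extract the pixel matrix of a PulseImage
#' @param object a [PulseImage-class].
#' @return numeric matrix of intensities.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "PulseImage", function(object) object@pixels)

#' @describeIn PulseImage image dimensions (rows, columns).
#' @param x a PulseImage.
#' @export
setMethod("dim", "PulseImage", function(x) dim(x@pixels))

#' Extract the signal matrix of a HeartbeatMatrix
#' @param object a [HeartbeatMatrix-class].
#' @return numeric matrix, fast time along rows.
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))

#' @rdname signalValues
#' @export
setMethod("signalValues", "HeartbeatMatrix", function(object) object@values)

#' @describeIn HeartbeatMatrix matrix dimensions (N fast, M slow).
#' @param x a HeartbeatMatrix.
#' @export
setMethod("dim", "HeartbeatMatrix", function(x) dim(x@values))

#' Accessors for posture sequences
#' @param object a [PostureSequence-class].
#' @return `epochLabels`: character vector of labels; `epochSeconds`:
#'   epoch duration in seconds.
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))

#' @rdname epochLabels
#' @export
setMethod("epochLabels", "PostureSequence", function(object) object@labels)

#' @rdname epochLabels
#' @export
setGeneric("epochSeconds", function(object) standardGeneric("epochSeconds"))

#' @rdname epochLabels
#' @export
setMethod("epochSeconds", "PostureSequence",
          function(object) object@epochSeconds)

#' @describeIn PostureSequence number of epochs.
#' @param x a PostureSequence.
#' @export
setMethod("length", "PostureSequence", function(x) length(x@labels))

#' Accessors for transition models
#' @param object a [TransitionModel-class].
#' @return `transitionProbs`: the probability table (matrix for order 1,
#'   array for order 2); `allowedMask`: the logical mask of permitted
#'   transitions; `modelOrder`: 1 or 2; `modelStates`: state names.
#' @export
setGeneric("transitionProbs",
           function(object) standardGeneric("transitionProbs"))

#' @rdname transitionProbs
#' @export
setMethod("transitionProbs", "TransitionModel", function(object) {
    if (object@order == 1L) object@probs[, , drop = TRUE] else object@probs
})

#' @rdname transitionProbs
#' @export
setGeneric("allowedMask", function(object) standardGeneric("allowedMask"))

#' @rdname transitionProbs
#' @export
setMethod("allowedMask", "TransitionModel", function(object) object@mask)

#' @rdname transitionProbs
#' @export
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))

#' @rdname transitionProbs
#' @export
setMethod("modelOrder", "TransitionModel", function(object) object@order)

#' @rdname transitionProbs
#' @export
setGeneric("modelStates", function(object) standardGeneric("modelStates"))

#' @rdname transitionProbs
#' @export
setMethod("modelStates", "TransitionModel", function(object) object@states)

#' Accessors for feature vectors
#' @param object a [PostureFeatures-class].
#' @return `hogDescriptor`: the flattened HOG vector; `pressureWeightsOf`:
#'   normalized per-cell pressure weights; `scaleFactor`: sqrt(w_n/w_1).
#' @export
setGeneric("hogDescriptor", function(object) standardGeneric("hogDescriptor"))

#' @rdname hogDescriptor
#' @export
setMethod("hogDescriptor", "PostureFeatures", function(object) object@hog)

#' @rdname hogDescriptor
#' @export
setGeneric("pressureWeightsOf",
           function(object) standardGeneric("pressureWeightsOf"))

#' @rdname hogDescriptor
#' @export
setMethod("pressureWeightsOf", "PostureFeatures",
          function(object) object@weights)

#' @rdname hogDescriptor
#' @export
setGeneric("scaleFactor", function(object) standardGeneric("scaleFactor"))

#' @rdname hogDescriptor
#' @export
setMethod("scaleFactor", "PostureFeatures", function(object) object@scaleFactor)

#' Accessors for generator configurations
#' @param object a [GeneratorConfig-class].
#' @return `occupancyTargets`: named stationary targets;
#'   `shiftRatePerHour`: target shift rate.
#' @export
setGeneric("occupancyTargets",
           function(object) standardGeneric("occupancyTargets"))

#' @rdname occupancyTargets
#' @export
setMethod("occupancyTargets", "GeneratorConfig",
          function(object) object@occupancyTargets)

#' @rdname occupancyTargets
#' @export
setGeneric("shiftRatePerHour",
           function(object) standardGeneric("shiftRatePerHour"))

#' @rdname occupancyTargets
#' @export
setMethod("shiftRatePerHour", "GeneratorConfig",
          function(object) object@shiftRatePerHour)

setMethod("show", "PulseImage", function(object) {
    d <- dim(object@pixels)
    cat("PulseImage", d[1L], "x", d[2L],
        sprintf("| intensity range [%.4g, %.4g]\n",
                min(object@pixels), max(object@pixels)))
})

setMethod("show", "HeartbeatMatrix", function(object) {
    d <- dim(object@values)
    cat("HeartbeatMatrix:", d[1L], "fast-time row(s) x", d[2L],
        "slow-time column(s)\n")
})

setMethod("show", "PostureSequence", function(object) {
    n <- length(object@labels)
    cat("PostureSequence:", n, "epochs of", object@epochSeconds, "s (",
        sprintf("%.2f h", n * object@epochSeconds / 3600), ")\n")
    occ <- round(100 * estimateOccupancy(object), 1)
    cat("  occupancy (%):",
        paste(names(occ), occ, sep = "=", collapse = " "), "\n")
})

setMethod("show", "TransitionModel", function(object) {
    cat("TransitionModel: order", object@order, "over",
        paste(object@states, collapse = "/"),
        sprintf("(alpha = %g)\n", object@alpha))
    if (object@order == 1L)
        print(round(transitionProbs(object), 4))
})

setMethod("show", "PredictionResult", function(object) {
    cat("PredictionResult: predicted", object@predicted, "\n")
    print(round(object@posterior, 4))
})

setMethod("show", "TemplateClassifier", function(object) {
    cat("TemplateClassifier:", nrow(object@centroids), "centroids x",
        ncol(object@centroids), "descriptor dims, temperature",
        object@temperature, "\n")
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig: shift rate", object@shiftRatePerHour,
        "/h, epoch", object@epochSeconds, "s\n  occupancy targets:",
        paste(names(object@occupancyTargets),
              object@occupancyTargets, sep = "=", collapse = " "), "\n")
})
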