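#' Read and write pulse images
#'
#' Images are stored either as 16-bit grayscale TIFF (intensities on
#' [0, 1], quantized to 1/65535) or as plain delimited numeric text (one
#' image row per line, whitespace or comma separated), chosen by file
#' extension (`.tif`/`.tiff` vs anything else).
#'
#' @param path file path.
#' @return `readPulseImage`: a [PulseImage-class].
#' @export
readPulseImage <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        m <- tiff::readTIFF(path)
        if (length(dim(m)) == 3L) m <- m[, , 1L]
        return(PulseImage(m))
    }
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
        tok <- strsplit(trimws(lines[[i]]), "[,[:space:]]+")[[1L]]
        v <- suppressWarnings(as.numeric(tok))
        if (anyNA(v))
            stop("parse error in ", path, " line ", i,
                 ": non-numeric token")
        v
    })
    if (length(unique(lengths(rows))) != 1L)
        stop("parse error in ", path, ": ragged rows")
    PulseImage(do.call(rbind, rows))
}

#' @rdname readPulseImage
#' @param img a [PulseImage-class]; values outside [0, 1] are clipped on
#'   TIFF write.
#' @return `writePulseImage`: the path, invisibly.
#' @export
writePulseImage <- function(img, path) {
    stopifnot(is(img, "PulseImage"))
    p <- pixels(img)
    if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        tiff::writeTIFF(pmin(pmax(p, 0), 1), path,
                        bits.per.sample = 16L)
    } else {
        utils::write.table(p, path, row.names = FALSE,
                           col.names = FALSE, sep = " ")
    }
    invisible(path)
}

#' Read and write posture sequences
#'
#' CSV with header `epoch,label`; labels must belong to
#' [postureLabels()] (OFFBED permitted). Epoch duration is not stored in
#' the file and is supplied on read.
#'
#' @param path file path.
#' @param epochSeconds epoch duration to attach on read; default 30.
#' @return `readPostureSequence`: a [PostureSequence-class].
#' @export
readPostureSequence <- function(path, epochSeconds = 30) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("epoch", "label") %in% names(d)))
        stop("parse error in ", path, ": expected header 'epoch,label'")
    bad <- which(!d$label %in% postureLabels(TRUE))
    if (length(bad))
        stop("parse error in ", path, " line ", bad[1L] + 1L,
             ": unknown label token '", d$label[bad[1L]], "'")
    PostureSequence(d$label[order(d$epoch)], epochSeconds = epochSeconds)
}

#' @rdname readPostureSequence
#' @param seq a [PostureSequence-class].
#' @return `writePostureSequence`: the path, invisibly.
#' @export
writePostureSequence <- function(seq, path) {
    stopifnot(is(seq, "PostureSequence"))
    utils::write.csv(data.frame(epoch = seq_along(epochLabels(seq)),
                                label = epochLabels(seq)),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a heartbeat CSV and pivot it to a HeartbeatMatrix
#'
#' Expects a CSV with header `time_s,bpm,site`. `readHeartbeat` returns
#' the data.frame; `heartbeatToMatrix` pivots it to a
#' [HeartbeatMatrix-class] with one fast-time row per site and slow time
#' along the shared time axis (sites must share the same time grid).
#'
#' @param path file path.
#' @return `readHeartbeat`: data.frame with `time_s`, `bpm`, `site`.
#' @export
readHeartbeat <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("time_s", "bpm", "site") %in% names(d)))
        stop("parse error in ", path,
             ": expected header 'time_s,bpm,site'")
    bad <- which(!is.finite(d$bpm))
    if (length(bad))
        stop("parse error in ", path, " line ", bad[1L] + 1L,
             ": non-numeric bpm")
    d
}

#' @rdname readHeartbeat
#' @param trace data.frame as returned by `readHeartbeat`.
#' @return `heartbeatToMatrix`: a [HeartbeatMatrix-class] with sites as
#'   rownames of the underlying matrix.
#' @export
heartbeatToMatrix <- function(trace) {
    sites <- sort(unique(trace$site))
    times <- sort(unique(trace$time_s))
    m <- matrix(NA_real_, length(sites), length(times),
                dimnames = list(sites, NULL))
    m[cbind(match(trace$site, sites), match(trace$time_s, times))] <-
        trace$bpm
    if (anyNA(m))
        stop("sites do not share a common time grid")
    HeartbeatMatrix(m)
}

#' Serialize transition models and classifiers as JSON
#'
#' Round-trips are exact to numeric precision: probability tables,
#' masks, states, order and smoothing for a [TransitionModel-class];
#' centroids and temperature for a [TemplateClassifier-class].
#'
#' @param model a [TransitionModel-class].
#' @param path file path.
#' @return The path (writers, invisibly) or the reconstructed object
#'   (readers).
#' @export
writeTransitionModel <- function(model, path) {
    stopifnot(is(model, "TransitionModel"))
    obj <- list(order = model@order, alpha = model@alpha,
                states = model@states,
                mask = as.vector(model@mask) * 1L,
                probs = as.vector(model@probs))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeTransitionModel
#' @export
readTransitionModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    n <- length(obj$states)
    mask <- matrix(obj$mask == 1L, n, n,
                   dimnames = list(obj$states, obj$states))
    dims <- if (obj$order == 1L) c(n, n) else c(n, n, n)
    probs <- array(obj$probs, dims,
                   dimnames = rep(list(obj$states), length(dims)))
    new("TransitionModel", order = as.integer(obj$order), probs = probs,
        mask = mask, alpha = obj$alpha, states = obj$states)
}

#' @rdname writeTransitionModel
#' @param clf a [TemplateClassifier-class].
#' @export
writeClassifier <- function(clf, path) {
    stopifnot(is(clf, "TemplateClassifier"))
    obj <- list(temperature = clf@temperature,
                labels = rownames(clf@centroids),
                centroids = apply(clf@centroids, 1L, identity,
                                  simplify = FALSE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeTransitionModel
#' @export
readClassifier <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cent <- do.call(rbind, obj$centroids)
    rownames(cent) <- obj$labels
    new("TemplateClassifier", centroids = cent,
        temperature = obj$temperature)
}
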