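# Seeded RNG helpers: every generator call derives its stream from one
# integer seed so modules are reproducible in isolation.

.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# counter-based split: child seed from (parent seed, stream index)
.splitSeed <- function(seed, stream) {
    as.integer(((as.double(seed) %% 2147483647) * 48271 + stream) %%
               2147483647)
}

#' Build the calibrated constrained transition matrix
#'
#' Constructs a per-epoch stochastic matrix whose support is the allowed
#' mask, whose stationary distribution equals the configured occupancy
#' targets, and whose expected posture-shift rate equals the configured
#' shifts per hour.
#'
#' Two constructions are used depending on the mask. For a symmetric
#' mask a Metropolis--Hastings chain is built (uniform proposal over
#' allowed neighbours, acceptance min(1, pi_j g_ji / (pi_i g_ij))), and
#' the per-epoch move-attempt probability is rescaled by the reciprocal
#' of the stationary-weighted mean acceptance so the realized shift rate
#' matches the target. The posture constraint graph itself, however, is
#' directed (lateral -> prone is allowed, prone -> lateral is not), so
#' no reversible chain on it can occupy the prone state; for that mask
#' family the chain is instead built by balancing probability flow
#' around the elementary cycles supine -> lateral -> supine,
#' supine -> lateral -> prone -> supine and supine -> offbed -> supine,
#' with equal expected bout length for the non-supine postures. Both
#' constructions are exact; the stationarity equation pi P = pi is
#' verified internally to 1e-9 before the matrix is returned (a
#' residual check that stays sharp even in the vanishing-shift-rate
#' limit, where iterative mixing is arbitrarily slow).
#'
#' @param cfg a [GeneratorConfig-class].
#' @param mask logical allowed-transition matrix with state dimnames;
#'   default [defaultAllowedMask()] including OFFBED.
#' @return Row-stochastic matrix with the mask's states as dimnames.
#' @examples
#' P <- calibratedTransitionMatrix(generatorConfig())
#' round(P, 4)
#' @export
calibratedTransitionMatrix <- function(cfg = generatorConfig(),
                                       mask = defaultAllowedMask(TRUE)) {
    stopifnot(is(cfg, "GeneratorConfig"))
    st <- rownames(mask)
    if (is.null(st) || !identical(st, colnames(mask)))
        stop("mask must have matching state dimnames")
    targets <- occupancyTargets(cfg)
    if (!all(st %in% names(targets)))
        stop("occupancy targets missing states: ",
             paste(setdiff(st, names(targets)), collapse = ", "))
    pi0 <- targets[st]
    if (abs(sum(pi0) - 1) > 1e-6) pi0 <- pi0 / sum(pi0)
    if (any(pi0 <= 0))
        stop("infeasible calibration: zero-mass state in targets (",
             paste(st[pi0 <= 0], collapse = ", "), ")")
    if (!.stronglyConnected(mask))
        stop("infeasible calibration: mask disconnects a ",
             "positive-mass state")
    qEpoch <- shiftRatePerHour(cfg) * cfg@epochSeconds / 3600
    P <- if (isTRUE(all(mask == t(mask))))
        .mhMatrix(pi0, mask, qEpoch)
    else
        .cycleFlowMatrix(pi0, mask, qEpoch)
    # stationarity residual: pi P = pi must hold exactly by construction
    resid <- max(abs(as.vector(pi0 %*% P) - pi0))
    if (resid > 1e-9)
        stop("internal error: targets are not stationary for the ",
             "calibrated matrix (residual ", signif(resid, 3), ")")
    P
}

.stronglyConnected <- function(mask) {
    n <- nrow(mask)
    reach <- function(M) {
        R <- M | diag(n)
        for (i in seq_len(n)) R <- R | (R %*% R > 0)
        R
    }
    all(reach(mask)) && all(reach(t(mask)))
}

# Metropolis-Hastings on a symmetric mask, exact shift-rate rescaling
.mhMatrix <- function(pi0, mask, qEpoch) {
    n <- length(pi0)
    g <- mask & !diag(n)
    deg <- rowSums(g)
    G <- g / pmax(deg, 1L)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (g[i, j] && G[i, j] > 0)
            A[i, j] <- min(1, pi0[j] * G[j, i] / (pi0[i] * G[i, j]))
    }
    movePerState <- rowSums(G * A)
    meanMove <- sum(pi0 * movePerState)    # mean acceptance per attempt
    q <- qEpoch / meanMove
    if (any(q * movePerState > 1))
        stop("infeasible calibration: shift rate too high for the mask")
    P <- q * G * A
    diag(P) <- 1 - rowSums(P)
    dimnames(P) <- dimnames(mask)
    P
}

# Flow-balance construction for the directed posture-cycle mask
.cycleFlowMatrix <- function(pi0, mask, qEpoch) {
    st <- names(pi0)
    lat <- intersect(c("LLR", "RLR"), st)
    need <- c("SUPINE", "PRONE", lat)
    if (!all(need %in% st))
        stop("unsupported mask: expected the posture constraint graph")
    expected <- defaultAllowedMask("OFFBED" %in% st)[st, st]
    if (!identical(unname(mask), unname(expected)))
        stop("unsupported mask: expected the posture constraint graph ",
             "(or a symmetric mask)")
    hasOff <- "OFFBED" %in% st
    piL <- pi0[lat]
    piP <- pi0[["PRONE"]]
    piO <- if (hasOff) pi0[["OFFBED"]] else 0
    # equal expected bout length tau (epochs) for non-supine postures:
    # out-flow from each is pi_i / tau; total flow must equal qEpoch
    totalWeight <- 2 * sum(piL) + piP + 2 * piO
    tau <- totalWeight / qEpoch
    gFlow <- piP / (length(lat) * tau)   # lateral -> prone, per lateral
    bFlow <- piL / tau - gFlow           # lateral -> supine, per lateral
    if (any(bFlow < 0))
        stop("infeasible calibration: prone occupancy too large for ",
             "the lateral occupancies under equal bout lengths")
    oFlow <- piO / tau
    n <- length(st)
    P <- matrix(0, n, n, dimnames = list(st, st))
    for (k in seq_along(lat)) {
        l <- lat[k]
        P["SUPINE", l] <- (bFlow[k] + gFlow) / pi0[["SUPINE"]]
        P[l, "SUPINE"] <- bFlow[k] / piL[k]
        P[l, "PRONE"] <- gFlow / piL[k]
    }
    P["PRONE", "SUPINE"] <- length(lat) * gFlow / piP
    if (hasOff) {
        P["SUPINE", "OFFBED"] <- oFlow / pi0[["SUPINE"]]
        P["OFFBED", "SUPINE"] <- oFlow / piO
    }
    leave <- rowSums(P)
    if (any(leave > 1))
        stop("infeasible calibration: shift rate too high for the ",
             "supine occupancy")
    diag(P) <- 1 - leave
    P
}

#' Simulate a posture sequence from a transition matrix
#'
#' Samples a Markov chain of `nEpochs` posture labels from a
#' row-stochastic matrix, starting from `initial` (on-bed start, supine
#' by default). Identical seeds give identical sequences; transitions
#' outside the matrix support can never appear.
#'
#' @param P row-stochastic matrix with state dimnames.
#' @param nEpochs number of epochs to simulate (>= 1).
#' @param seed integer RNG seed.
#' @param initial starting label; default `"SUPINE"`.
#' @param epochSeconds epoch duration for the returned sequence.
#' @return A [PostureSequence-class].
#' @examples
#' P <- calibratedTransitionMatrix(generatorConfig())
#' simulateSequence(P, 10, seed = 1)
#' @export
simulateSequence <- function(P, nEpochs, seed = 1L, initial = "SUPINE",
                             epochSeconds = 30) {
    st <- rownames(P)
    if (is.null(st)) stop("transition matrix must have state dimnames")
    if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-9)
        stop("invalid transition matrix: rows must be non-negative ",
             "and sum to 1")
    nEpochs <- as.integer(nEpochs)
    if (nEpochs < 1L) stop("nEpochs must be at least 1")
    s0 <- match(initial, st)
    if (is.na(s0)) stop("initial state not in the matrix")
    cum <- t(apply(P, 1L, cumsum))
    labels <- .withSeed(seed, {
        u <- stats::runif(nEpochs - 1L)
        out <- integer(nEpochs)
        out[1L] <- s0
        cur <- s0
        for (t in seq_len(nEpochs - 1L)) {
            cur <- findInterval(u[t], cum[cur, ]) + 1L
            out[t + 1L] <- cur
        }
        out
    })
    PostureSequence(st[labels], epochSeconds = epochSeconds)
}

#' Render a synthetic pulse image for a posture
#'
#' Builds a 64 x 64 posture-conditioned intensity template (supine: two
#' symmetric vertical lobes; prone: the same two columns with the
#' vertical intensity profile inverted, peaking toward head and foot;
#' LLR/RLR: a single off-centre lobe, exact horizontal mirrors of each
#' other; OFFBED: empty bed) and adds truncated-at-zero Gaussian pixel
#' noise of standard deviation `imageNoiseSd`, clipping to [0, 1].
#' Deterministic for a fixed (label, seed) pair. Templates are generator
#' inventions, not measured pressure maps.
#'
#' @param label a posture label (see [postureLabels()]).
#' @param cfg a [GeneratorConfig-class] (noise level).
#' @param seed integer RNG seed for the noise.
#' @param size image side length; default 64.
#' @return A [PulseImage-class].
#' @export
renderPostureImage <- function(label, cfg = generatorConfig(), seed = 1L,
                               size = 64L) {
    .checkLabels(label)
    tmpl <- .postureTemplate(label, size)
    sd <- cfg@imageNoiseSd
    if (sd > 0) {
        noise <- .withSeed(seed,
                           matrix(stats::rnorm(size * size, 0, sd),
                                  size, size))
        tmpl <- tmpl + pmax(noise, -tmpl)   # truncate so pixels stay >= 0
    }
    PulseImage(pmin(pmax(tmpl, 0), 1))
}

.lobe <- function(size, cy, cx, sy, sx, amp = 1) {
    r <- seq_len(size); c <- seq_len(size)
    amp * outer(exp(-(r - cy)^2 / (2 * sy^2)),
                exp(-(c - cx)^2 / (2 * sx^2)))
}

.postureTemplate <- function(label, size = 64L) {
    mid <- (size + 1) / 2
    cL <- round(size * 0.34); cR <- size + 1 - cL
    t <- switch(label,
        SUPINE = .lobe(size, mid, cL, size * 0.22, size * 0.08, 0.9) +
                 .lobe(size, mid, cR, size * 0.22, size * 0.08, 0.9),
        PRONE = .lobe(size, size * 0.27, cL, size * 0.10, size * 0.08, 0.9) +
                .lobe(size, size * 0.73, cL, size * 0.10, size * 0.08, 0.9) +
                .lobe(size, size * 0.27, cR, size * 0.10, size * 0.08, 0.9) +
                .lobe(size, size * 0.73, cR, size * 0.10, size * 0.08, 0.9),
        LLR = .lobe(size, mid, round(size * 0.31), size * 0.26,
                    size * 0.10, 0.95),
        RLR = {
            m <- .postureTemplate("LLR", size)
            m[, rev(seq_len(size))]
        },
        OFFBED = matrix(0, size, size))
    pmin(t, 1)
}

#' Simulate a heartbeat trace for a posture
#'
#' Draws `nSamples` beats-per-minute values from a Normal distribution
#' with the configured per-posture mean and standard deviation,
#' truncated to the physiological range [30, 200]. The per-posture means
#' are generator parameters (postures with different circulatory load
#' get separated means), not published measurements.
#'
#' @param label a posture label.
#' @param nSamples number of samples (>= 1).
#' @param cfg a [GeneratorConfig-class].
#' @param seed integer RNG seed.
#' @param site sensor-site tag recorded in the trace; default "wrist".
#' @return data.frame with columns `time_s`, `bpm`, `site` (1 Hz).
#' @export
simulateHeartbeat <- function(label, nSamples, cfg = generatorConfig(),
                              seed = 1L, site = "wrist") {
    .checkLabels(label)
    nSamples <- as.integer(nSamples)
    if (nSamples < 1L) stop("nSamples must be at least 1")
    bpm <- .withSeed(seed,
                     stats::rnorm(nSamples, cfg@hbrMeans[[label]],
                                  cfg@hbrSd))
    bpm <- pmin(pmax(bpm, 30), 200)
    data.frame(time_s = seq_len(nSamples) - 1L, bpm = bpm, site = site)
}

#' Generate a complete synthetic dataset
#'
#' Simulates a calibrated posture sequence and renders one pulse image
#' and one heartbeat window per epoch. With `dir` given, writes
#' `sequence.csv`, `heartbeat.csv`, 16-bit grayscale images under
#' `images/`, and a `manifest.json` recording the configuration and
#' seed, so a run is exactly reproducible.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param nEpochs number of epochs (>= 1).
#' @param seed integer master seed; per-epoch streams are derived from
#'   it by counter-based splitting.
#' @param dir optional output directory.
#' @param heartbeatSamplesPerEpoch samples per epoch window; default one
#'   per second of the epoch.
#' @return List with `sequence` ([PostureSequence-class]), `images`
#'   (list of [PulseImage-class]), `heartbeats` (one data.frame, with an
#'   `epoch` column), `labels` (character truth labels) and `manifest`.
#' @examples
#' ds <- makeDataset(generatorConfig(), nEpochs = 5, seed = 42)
#' ds$labels
#' @export
makeDataset <- function(cfg = generatorConfig(), nEpochs, seed = 1L,
                        dir = NULL,
                        heartbeatSamplesPerEpoch =
                            max(1L, round(cfg@epochSeconds))) {
    stopifnot(is(cfg, "GeneratorConfig"))
    P <- calibratedTransitionMatrix(cfg)
    seqn <- simulateSequence(P, nEpochs, seed = .splitSeed(seed, 1L),
                             epochSeconds = cfg@epochSeconds)
    labels <- epochLabels(seqn)
    images <- lapply(seq_len(nEpochs), function(i)
        renderPostureImage(labels[i], cfg,
                           seed = .splitSeed(seed, 1000L + i)))
    hb <- lapply(seq_len(nEpochs), function(i) {
        d <- simulateHeartbeat(labels[i], heartbeatSamplesPerEpoch, cfg,
                               seed = .splitSeed(seed, 2000000L + i))
        d$epoch <- i
        d
    })
    hb <- do.call(rbind, hb)
    manifest <- list(
        seed = as.integer(seed),
        nEpochs = as.integer(nEpochs),
        epochSeconds = cfg@epochSeconds,
        occupancyTargets = as.list(occupancyTargets(cfg)),
        shiftRatePerHour = shiftRatePerHour(cfg),
        imageNoiseSd = cfg@imageNoiseSd,
        hbrMeans = as.list(cfg@hbrMeans),
        hbrSd = cfg@hbrSd,
        note = paste("image templates and heartbeat means are synthetic",
                     "generator parameters"))
    if (!is.null(dir)) {
        dir.create(file.path(dir, "images"), recursive = TRUE,
                   showWarnings = FALSE)
        writePostureSequence(seqn, file.path(dir, "sequence.csv"))
        utils::write.csv(hb, file.path(dir, "heartbeat.csv"),
                         row.names = FALSE)
        for (i in seq_len(nEpochs))
            writePulseImage(images[[i]],
                            file.path(dir, "images",
                                      sprintf("epoch_%06d.tiff", i)))
        jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(sequence = seqn, images = images, heartbeats = hb,
         labels = labels, manifest = manifest)
}
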