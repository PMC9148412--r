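#' Default allowed-transition mask for in-bed postures
#'
#' Encodes the anatomical transition constraints the predictor assumes:
#' self-transitions are always allowed; prone is entered only from a
#' lateral posture (so SUPINE -> PRONE is forbidden); the lateral
#' postures are entered only from supine (so lateral <-> lateral and
#' PRONE -> lateral are forbidden). Prone exits to supine or stays
#' prone, and every posture may return to supine, which keeps the
#' induced directed graph strongly connected. With
#' `includeOffbed = TRUE` an OFFBED state is appended, reachable to and
#' from SUPINE only.
#'
#' @param includeOffbed logical; include the OFFBED calibration state.
#' @return Logical from x to matrix with posture-label dimnames.
#' @examples
#' m <- defaultAllowedMask()
#' m["SUPINE", "PRONE"] # FALSE
#' m["SUPINE", "LLR"]   # TRUE
#' @export
defaultAllowedMask <- function(includeOffbed = FALSE) {
    st <- postureLabels(includeOffbed)
    m <- matrix(FALSE, length(st), length(st), dimnames = list(st, st))
    diag(m) <- TRUE
    m["SUPINE", c("LLR", "RLR")] <- TRUE
    m[c("LLR", "RLR"), "PRONE"] <- TRUE
    m[c("PRONE", "LLR", "RLR"), "SUPINE"] <- TRUE
    if (includeOffbed) {
        m["SUPINE", "OFFBED"] <- TRUE
        m["OFFBED", "SUPINE"] <- TRUE
    }
    m
}

.seqList <- function(sequences) {
    if (is(sequences, "PostureSequence")) sequences <- list(sequences)
    stopifnot(all(vapply(sequences, is, logical(1L), "PostureSequence")))
    sequences
}

#' Fit a constrained posture-transition model
#'
#' Counts posture transitions over one or more training sequences,
#' adds `alpha` pseudo-counts to the targets the mask allows (never to
#' forbidden ones), and normalizes per history. Forbidden transitions
#' have probability exactly 0 regardless of smoothing. Transitions in
#' the data that violate the mask are skipped with a warning (real data
#' may violate the model). Histories never observed (and alpha = 0)
#' get a uniform distribution over their allowed targets.
#'
#' For order 2 the history is the pair (previous, current) and the
#' allowed targets are those the mask permits from the current state.
#'
#' @param sequences a [PostureSequence-class] or list of them.
#' @param order model order, 1 or 2; default 2.
#' @param alpha non-negative additive smoothing; default 1.
#' @param mask logical allowed-transition matrix; default
#'   [defaultAllowedMask()] extended to cover the labels present.
#' @return A [TransitionModel-class].
#' @examples
#' s <- PostureSequence(c("SUPINE", "LLR", "LLR", "SUPINE", "RLR"))
#' fitTransitionModel(s, order = 1)
#' @export
fitTransitionModel <- function(sequences, order = 2L, alpha = 1,
                               mask = NULL) {
    sequences <- .seqList(sequences)
    order <- as.integer(order)
    if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
    if (alpha < 0) stop("alpha must be non-negative")
    labs <- unique(unlist(lapply(sequences, epochLabels)))
    .checkLabels(labs)
    useOff <- "OFFBED" %in% labs ||
        (!is.null(mask) && "OFFBED" %in% rownames(mask))
    st <- postureLabels(useOff)
    if (is.null(mask)) mask <- defaultAllowedMask(useOff)
    mask <- mask[st, st]
    n <- length(st)
    if (alpha == 0 && !length(sequences))
        stop("need training sequences when alpha = 0")

    nViolations <- 0L
    if (order == 1L) {
        counts <- matrix(0, n, n, dimnames = list(st, st))
        for (s in sequences) {
            lab <- epochLabels(s)
            if (length(lab) < 2L) next
            from <- match(lab[-length(lab)], st)
            to <- match(lab[-1L], st)
            ok <- mask[cbind(from, to)]
            nViolations <- nViolations + sum(!ok)
            tab <- table(factor(from[ok], levels = seq_len(n)),
                         factor(to[ok], levels = seq_len(n)))
            counts <- counts + as.matrix(tab)
        }
        probs <- .normalizeRows(counts + alpha * mask, mask)
        probs <- array(probs, c(n, n), dimnames = list(st, st))
    } else {
        counts <- array(0, c(n, n, n), dimnames = list(st, st, st))
        for (s in sequences) {
            lab <- epochLabels(s)
            if (length(lab) < 3L) next
            i <- match(lab[seq_len(length(lab) - 2L)], st)
            j <- match(lab[seq(2L, length(lab) - 1L)], st)
            k <- match(lab[seq(3L, length(lab))], st)
            ok <- mask[cbind(i, j)] & mask[cbind(j, k)]
            nViolations <- nViolations + sum(!mask[cbind(j, k)])
            flat <- (i + (j - 1L) * n + (k - 1L) * n * n)[ok]
            acc <- rowsum(rep(1, length(flat)), group = flat)
            counts[as.integer(rownames(acc))] <-
                counts[as.integer(rownames(acc))] + acc
        }
        probs <- array(0, c(n, n, n), dimnames = list(st, st, st))
        for (i in seq_len(n)) {
            sl <- counts[i, , ] + alpha * mask
            probs[i, , ] <- .normalizeRows(sl, mask)
        }
    }
    if (nViolations > 0L)
        warning(nViolations, " transition(s) in the training data ",
                "violate the allowed mask; skipped")
    new("TransitionModel", order = order, probs = probs, mask = mask,
        alpha = as.numeric(alpha), states = st)
}

# normalize each row over allowed targets; zero rows -> uniform/allowed
.normalizeRows <- function(m, mask) {
    m[!mask] <- 0
    rs <- rowSums(m)
    for (i in seq_len(nrow(m))) {
        if (rs[i] > 0) m[i, ] <- m[i, ] / rs[i]
        else m[i, mask[i, ]] <- 1 / sum(mask[i, ])
    }
    m
}

#' Predict the next posture from history and an observation likelihood
#'
#' Forms the transition prior P(next | history) from the fitted model
#' (conditioning on the last one or two postures depending on the model
#' order) and fuses it with an optional frame-level observation
#' likelihood by Bayes' rule: posterior proportional to prior times
#' likelihood, renormalized. A missing likelihood is treated as uniform,
#' so the posterior is then the transition row itself. Ties in the
#' argmax are broken by the canonical label order.
#'
#' @param model a [TransitionModel-class].
#' @param history character vector of recent posture labels, oldest
#'   first; must be at least as long as the model order.
#' @param obsLikelihood optional named non-negative likelihood vector
#'   over the model's states (need not be normalized).
#' @return A [PredictionResult-class].
#' @examples
#' s <- PostureSequence(rep(c("SUPINE", "LLR", "PRONE", "SUPINE"), 10))
#' m <- fitTransitionModel(s, order = 1)
#' predictNext(m, history = "SUPINE")
#' @export
predictNext <- function(model, history, obsLikelihood = NULL) {
    stopifnot(is(model, "TransitionModel"))
    history <- as.character(history)
    st <- model@states
    if (length(history) < model@order)
        stop("history must contain at least ", model@order, " label(s)")
    if (!all(history %in% st))
        stop("history contains labels outside the model's state set")
    n <- length(st)
    used <- utils::tail(history, model@order)
    prior <- if (model@order == 1L) {
        model@probs[match(used, st), ]
    } else {
        model@probs[match(used[1L], st), match(used[2L], st), ]
    }
    names(prior) <- st
    if (is.null(obsLikelihood)) {
        lik <- rep(1, n)
    } else {
        if (is.null(names(obsLikelihood))) {
            if (length(obsLikelihood) != n)
                stop("unnamed likelihood must have length ", n)
            lik <- as.numeric(obsLikelihood)
        } else {
            if (!all(st %in% names(obsLikelihood)))
                stop("likelihood is missing states: ",
                     paste(setdiff(st, names(obsLikelihood)),
                           collapse = ", "))
            lik <- as.numeric(obsLikelihood[st])
        }
        if (any(lik < 0)) stop("likelihood must be non-negative")
    }
    post <- prior * lik
    if (sum(post) == 0)
        stop("conflicting evidence: the transition prior (support ",
             paste(st[prior > 0], collapse = "/"),
             ") and the observation likelihood (support ",
             paste(st[lik > 0], collapse = "/"),
             ") share no posture")
    post <- post / sum(post)
    names(post) <- st
    predicted <- st[which.max(post)]   # first max = canonical tie-break
    new("PredictionResult", posterior = post, predicted = predicted,
        historyUsed = used)
}

#' Posture occupancy of a sequence
#'
#' Fraction of epochs spent in each posture; the empirical analogue of
#' the stationary occupancy of the transition model.
#'
#' @param seq a [PostureSequence-class].
#' @return Named fractions over the labels present (plus the four core
#'   labels), summing to 1.
#' @examples
#' estimateOccupancy(PostureSequence(c("SUPINE", "SUPINE", "PRONE", "LLR")))
#' @export
estimateOccupancy <- function(seq) {
    stopifnot(is(seq, "PostureSequence"))
    lab <- epochLabels(seq)
    st <- postureLabels("OFFBED" %in% lab)
    tab <- table(factor(lab, levels = st))
    as.numeric(tab / length(lab)) |> stats::setNames(st)
}

#' Posture shifts per hour
#'
#' Number of epoch-to-epoch label changes divided by the total duration
#' of the sequence in hours (epochs x epoch length).
#'
#' @param seq a [PostureSequence-class] with at least 2 epochs.
#' @return Shift rate in changes per hour.
#' @examples
#' s <- PostureSequence(c("SUPINE", "SUPINE", "LLR", "LLR", "PRONE"))
#' shiftsPerHour(s) # 2 shifts in 2.5 minutes = 48 per hour
#' @export
shiftsPerHour <- function(seq) {
    stopifnot(is(seq, "PostureSequence"))
    lab <- epochLabels(seq)
    if (length(lab) < 2L) stop("need at least 2 epochs")
    nShift <- sum(lab[-1L] != lab[-length(lab)])
    hours <- length(lab) * epochSeconds(seq) / 3600
    nShift / hours
}
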