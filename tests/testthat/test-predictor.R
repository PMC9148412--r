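test_that("defaultAllowedMask encodes the anatomical constraints", {
    m <- defaultAllowedMask()
    expect_false(m["SUPINE", "PRONE"])
    expect_true(m["SUPINE", "LLR"] && m["SUPINE", "RLR"])
    expect_false(m["LLR", "RLR"] || m["RLR", "LLR"])
    expect_false(m["PRONE", "LLR"] || m["PRONE", "RLR"])
    expect_true(all(diag(m)))
    expect_true(all(m[, "SUPINE"] | rownames(m) == "SUPINE"))
    # strong connectivity: powers of (mask + I) reach everything
    n <- nrow(m); R <- m | diag(n) > 0
    for (i in seq_len(n)) R <- R | (R %*% R > 0)
    expect_true(all(R))
    m5 <- defaultAllowedMask(TRUE)
    expect_true(m5["SUPINE", "OFFBED"] && m5["OFFBED", "SUPINE"])
    expect_false(any(m5["OFFBED", c("PRONE", "LLR", "RLR")]))
})

test_that("fitTransitionModel normalizes counts with structural zeros", {
    seqs <- list(PostureSequence(c("SUPINE", "LLR")),
                 PostureSequence(c("SUPINE", "LLR")),
                 PostureSequence(c("SUPINE", "LLR")),
                 PostureSequence(c("SUPINE", "SUPINE")))
    m <- fitTransitionModel(seqs, order = 1, alpha = 0)
    P <- transitionProbs(m)
    expect_equal(P["SUPINE", "LLR"], 0.75)
    expect_equal(P["SUPINE", "SUPINE"], 0.25)
    expect_equal(P["SUPINE", "PRONE"], 0)
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))
})

test_that("pure-prior fits are uniform over allowed targets", {
    m <- fitTransitionModel(list(), order = 1, alpha = 2)
    P <- transitionProbs(m)
    mask <- defaultAllowedMask()
    for (s in rownames(P)) {
        expect_equal(unname(P[s, mask[s, ]]),
                     rep(1 / sum(mask[s, ]), sum(mask[s, ])))
        expect_true(all(P[s, !mask[s, ]] == 0))
    }
    m2 <- fitTransitionModel(list(), order = 2, alpha = 1)
    A <- transitionProbs(m2)
    expect_equal(unname(A["LLR", "SUPINE", ]),
                 unname(defaultAllowedMask()["SUPINE", ] / 3))
})

test_that("forbidden transitions in training data are skipped with warning", {
    s <- PostureSequence(c("SUPINE", "PRONE", "SUPINE", "LLR"))
    expect_warning(m <- fitTransitionModel(s, order = 1, alpha = 0),
                   "violate")
    expect_equal(transitionProbs(m)["SUPINE", "PRONE"], 0)
})

test_that("structural zeros survive fit and predict for any alpha", {
    set.seed(61)
    P0 <- calibratedTransitionMatrix(generatorConfig(),
                                     defaultAllowedMask(TRUE))
    s <- simulateSequence(P0, 20000, seed = 61)
    mask <- defaultAllowedMask(TRUE)
    for (alpha in c(0, 0.5, 5)) {
        for (ord in c(1L, 2L)) {
            m <- fitTransitionModel(s, order = ord, alpha = alpha)
            P <- m@probs
            if (ord == 1L) {
                expect_true(all(P[!mask] == 0))
            } else {
                for (i in seq_len(nrow(mask)))
                    expect_true(all(P[i, , ][!mask] == 0))
            }
            pr <- predictNext(m, rep("SUPINE", ord))
            expect_equal(unname(pr@posterior["PRONE"]), 0)
            expect_equal(sum(pr@posterior), 1, tolerance = 1e-9)
        }
    }
})

test_that("predictNext applies Bayes' rule over the transition prior", {
    st <- postureLabels()
    mask <- defaultAllowedMask()
    probs <- array(0, c(4, 4), dimnames = list(st, st))
    probs["SUPINE", ] <- c(0.5, 0, 0.5, 0)
    probs["PRONE", ] <- c(0.5, 0.5, 0, 0)
    probs["LLR", ] <- c(0.3, 0.3, 0.4, 0)
    probs["RLR", ] <- c(0.3, 0.3, 0, 0.4)
    m <- new("TransitionModel", order = 1L, probs = probs, mask = mask,
             alpha = 0, states = st)
    # uniform likelihood returns the transition row exactly
    expect_equal(predictNext(m, "SUPINE")@posterior,
                 c(SUPINE = 0.5, PRONE = 0, LLR = 0.5, RLR = 0))
    # hand Bayes: prior (0.5,0,0.5,0) x lik (0.2,0.3,0.8,0.7) -> (0.2,0,0.8,0)
    r <- predictNext(m, "SUPINE", c(SUPINE = 0.2, PRONE = 0.3,
                                    LLR = 0.8, RLR = 0.7))
    expect_equal(r@posterior, c(SUPINE = 0.2, PRONE = 0, LLR = 0.8,
                                RLR = 0))
    expect_equal(r@predicted, "LLR")
    # disjoint support errors with both distributions named
    probs2 <- probs; probs2["LLR", ] <- c(0, 1, 0, 0)
    m2 <- new("TransitionModel", order = 1L, probs = probs2,
              mask = mask, alpha = 0, states = st)
    expect_error(predictNext(m2, "LLR", c(SUPINE = 1, PRONE = 0,
                                          LLR = 0, RLR = 0)),
                 "conflicting evidence.*PRONE.*SUPINE")
    expect_error(predictNext(m, character(0)), "history")
})

test_that("posterior normalization holds across random prior/likelihood pairs", {
    set.seed(62)
    st <- postureLabels()
    mask <- defaultAllowedMask()
    for (rep in 1:1000) {
        probs <- array(0, c(4, 4), dimnames = list(st, st))
        for (s in st) {
            w <- runif(4) * mask[s, ]
            probs[s, ] <- w / sum(w)
        }
        m <- new("TransitionModel", order = 1L, probs = probs,
                 mask = mask, alpha = 0, states = st)
        for (j in 1:10) {
            lik <- runif(4, 0.01, 1)
            r <- predictNext(m, sample(st, 1), lik)
            expect_equal(sum(r@posterior), 1, tolerance = 1e-9)
            expect_equal(unname(r@posterior[r@predicted]),
                         max(r@posterior))
        }
    }
})

test_that("greedy argmax iteration follows the maximum-probability path", {
    P <- calibratedTransitionMatrix(generatorConfig(),
                                    defaultAllowedMask(TRUE))
    st <- rownames(P)
    m <- new("TransitionModel", order = 1L,
             probs = array(P, dim(P), dimnames = dimnames(P)),
             mask = defaultAllowedMask(TRUE), alpha = 0, states = st)
    for (len in c(4L, 6L, 8L)) {
        greedy <- "SUPINE"
        for (i in seq_len(len - 1L))
            greedy <- c(greedy,
                        predictNext(m, greedy[length(greedy)])@predicted)
        expect_equal(greedy, ocMaxProbPath(P, "SUPINE", len))
    }
})

test_that("occupancy and shift-rate statistics are exact on small cases", {
    s <- PostureSequence(c("SUPINE", "SUPINE", "PRONE", "LLR"))
    expect_equal(estimateOccupancy(s),
                 c(SUPINE = 0.5, PRONE = 0.25, LLR = 0.25, RLR = 0))
    expect_equal(sum(estimateOccupancy(s)), 1, tolerance = 1e-12)
    expect_equal(unname(estimateOccupancy(
        PostureSequence(rep("PRONE", 5)))["PRONE"]), 1)
    # hand computation: 2 shifts in 5 x 30 s = 48 per hour
    s2 <- PostureSequence(c("SUPINE", "SUPINE", "LLR", "LLR", "PRONE"))
    expect_equal(shiftsPerHour(s2), 48)
    expect_equal(shiftsPerHour(PostureSequence(rep("LLR", 10))), 0)
    # doubling the epoch halves the rate
    s3 <- PostureSequence(epochLabels(s2), epochSeconds = 60)
    expect_equal(shiftsPerHour(s3), 24)
    expect_error(shiftsPerHour(PostureSequence("SUPINE")), "at least 2")
})
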