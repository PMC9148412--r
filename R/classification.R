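#' Train a nearest-centroid posture classifier
#'
#' Computes the per-posture mean descriptor (centroid) from labelled
#' feature vectors. Deterministic; duplicating the training set leaves
#' the classifier unchanged. All four posture classes must be
#' represented.
#'
#' @param features list of [PostureFeatures-class] objects, or a numeric
#'   matrix with one descriptor per row.
#' @param labels character posture labels, one per feature.
#' @param temperature softness of the squared-distance softmax used at
#'   classification time; default 1.
#' @return A [TemplateClassifier-class].
#' @export
trainClassifier <- function(features, labels, temperature = 1) {
    X <- .featureMatrix(features)
    labels <- as.character(labels)
    if (nrow(X) != length(labels))
        stop("features and labels must have equal length")
    .checkLabels(labels, allowOffbed = FALSE)
    missing <- setdiff(postureLabels(), unique(labels))
    if (length(missing))
        stop("invalid training set: no examples for label(s) ",
             paste(missing, collapse = ", "))
    cent <- rowsum(X, group = labels) / as.vector(table(labels)[
        sort(unique(labels))])
    cent <- cent[postureLabels(), , drop = FALSE]
    new("TemplateClassifier", centroids = cent,
        temperature = as.numeric(temperature))
}

.featureMatrix <- function(features) {
    if (is.matrix(features)) return(features)
    if (is(features, "PostureFeatures")) features <- list(features)
    stopifnot(is.list(features))
    lens <- vapply(features, function(f) length(hogDescriptor(f)),
                   integer(1L))
    if (length(unique(lens)) > 1L)
        stop("descriptors have unequal lengths")
    do.call(rbind, lapply(features, hogDescriptor))
}

#' Soft classification of a feature vector
#'
#' Converts squared Euclidean distances to the class centroids into a
#' probability distribution: p(c) proportional to
#' exp(-d_c^2 / temperature), normalized. Distances are offset by the
#' minimum before exponentiation for numerical stability (which leaves
#' the normalized result unchanged).
#'
#' @param clf a [TemplateClassifier-class].
#' @param feat a [PostureFeatures-class] or numeric descriptor vector.
#' @return Named probability vector over the four posture labels.
#' @export
classifyPosture <- function(clf, feat) {
    stopifnot(is(clf, "TemplateClassifier"))
    x <- if (is(feat, "PostureFeatures")) hogDescriptor(feat)
         else as.numeric(feat)
    if (length(x) != ncol(clf@centroids))
        stop("descriptor length ", length(x),
             " does not match classifier dimensionality ",
             ncol(clf@centroids))
    d2 <- rowSums(sweep(clf@centroids, 2L, x)^2)
    z <- exp(-(d2 - min(d2)) / clf@temperature)
    p <- z / sum(z)
    stats::setNames(as.numeric(p), rownames(clf@centroids))
}

#' Fuse an observation distribution with a transition prior
#'
#' Elementwise product of the two distributions, renormalized (Bayes'
#' rule with the transition row as prior). A uniform prior returns the
#' observation distribution unchanged; a structural zero in the prior
#' forces the fused probability of that label to zero.
#'
#' @param obs,prior named distributions over the same labels, each
#'   summing to 1 within 1e-6.
#' @return Named fused distribution summing to 1.
#' @examples
#' fuseWithPrior(c(SUPINE = 0.5, PRONE = 0.5, LLR = 0, RLR = 0),
#'               c(SUPINE = 0.8, PRONE = 0.2, LLR = 0, RLR = 0))
#' @export
fuseWithPrior <- function(obs, prior) {
    if (abs(sum(obs) - 1) > 1e-6 || abs(sum(prior) - 1) > 1e-6)
        stop("obs and prior must each sum to 1")
    if (!is.null(names(obs)) && !is.null(names(prior)))
        prior <- prior[names(obs)]
    f <- obs * prior
    if (sum(f) == 0)
        stop("conflicting evidence: observation and prior have ",
             "disjoint support")
    f / sum(f)
}

#' Evaluate posture predictions against truth
#'
#' @param predicted,truth equal-length character label vectors.
#' @return A list with `confusion` (truth in rows, prediction in
#'   columns), `accuracy` (trace over total) and `recall` (per-class,
#'   NA for classes absent from the truth).
#' @examples
#' evaluatePredictions(c("SUPINE", "PRONE"), c("SUPINE", "LLR"))$accuracy
#' @export
evaluatePredictions <- function(predicted, truth) {
    predicted <- as.character(predicted)
    truth <- as.character(truth)
    if (length(predicted) != length(truth) || !length(truth))
        stop("predicted and truth must be non-empty and equal length")
    st <- postureLabels("OFFBED" %in% c(predicted, truth))
    conf <- table(truth = factor(truth, levels = st),
                  predicted = factor(predicted, levels = st))
    conf <- unclass(conf)
    acc <- sum(diag(conf)) / sum(conf)
    recall <- diag(conf) / rowSums(conf)
    list(confusion = conf, accuracy = acc, recall = recall)
}
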