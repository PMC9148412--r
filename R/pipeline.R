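#' Run the full posture-recognition pipeline on synthetic data
#'
#' End-to-end experiment runner: simulates a calibrated dataset,
#' preprocesses every pulse image (standardize, threshold filter,
#' Gaussian smoothing, optional principal-axis alignment), extracts HOG
#' features, trains the nearest-centroid classifier, fits the
#' constrained transition model on the first `trainFraction` of the
#' sequence, predicts each held-out epoch by fusing the frame
#' likelihood with the transition prior, and evaluates against truth.
#'
#' The classifier is trained on a class-balanced set of freshly
#' rendered exemplar images (`nTrainPerClass` per posture, same noise
#' level as the dataset), not on the simulated night itself: posture
#' bouts last tens of minutes, so a short night need not visit every
#' posture, while the classifier must know all four classes.
#'
#' Epochs labelled OFFBED are generated (they are part of the calibrated
#' sequence) but excluded from frame evaluation, which covers the four
#' on-bed postures.
#'
#' @param nEpochs number of epochs to simulate; default 600.
#' @param seed master RNG seed.
#' @param cfg a [GeneratorConfig-class]; set `imageNoiseSd = 0` for the
#'   noiseless regime.
#' @param trainFraction fraction of the sequence used to fit the
#'   transition model; the remainder is evaluated. Default 0.5.
#' @param nTrainPerClass balanced classifier training exemplars per
#'   posture; default 20.
#' @param threshold `"auto"` (per-image pulse threshold) or a fixed
#'   cutoff on the standardized intensities; default 0.5725.
#' @param thresholdMode `"keep_high"` (default here: denoising keeps the
#'   strong pulse points) or `"keep_low"`.
#' @param gaussianSigma,kernelSize smoothing parameters.
#' @param align logical; run principal-axis alignment (default FALSE:
#'   the synthetic templates are already axis-aligned).
#' @param modelOrder transition-model order; default 1.
#' @param alpha transition smoothing; default 1.
#' @param fuse logical; fuse frame likelihoods with the transition
#'   prior (default TRUE). With FALSE the classifier output alone is
#'   evaluated.
#' @param imageSize standardized image side; default 64 (native
#'   template resolution).
#' @return A list report: `confusion`, `accuracy`, `recall`, `occupancy`,
#'   `shiftsPerHour`, `nTrain`, `nTest`, and the resolved `config`.
#' @examples
#' \donttest{
#' rep <- runPipeline(nEpochs = 200, seed = 7,
#'                    cfg = generatorConfig(imageNoiseSd = 0))
#' rep$accuracy
#' }
#' @export
runPipeline <- function(nEpochs = 600L, seed = 1L,
                        cfg = generatorConfig(),
                        trainFraction = 0.5,
                        nTrainPerClass = 20L,
                        threshold = 0.5725,
                        thresholdMode = c("keep_high", "keep_low"),
                        gaussianSigma = 1, kernelSize = 5L,
                        align = FALSE,
                        modelOrder = 1L, alpha = 1,
                        fuse = TRUE, imageSize = 64L) {
    thresholdMode <- match.arg(thresholdMode)
    ds <- makeDataset(cfg, nEpochs, seed = seed)
    labels <- ds$labels
    feats <- lapply(ds$images, function(im)
        preprocessAndExtract(im, threshold = threshold,
                             thresholdMode = thresholdMode,
                             gaussianSigma = gaussianSigma,
                             kernelSize = kernelSize, align = align,
                             imageSize = imageSize))
    nTrain <- max(1L, floor(nEpochs * trainFraction))
    trainIdx <- seq_len(nTrain)
    testIdx <- setdiff(seq_len(nEpochs), trainIdx)
    onBedTest <- testIdx[labels[testIdx] != "OFFBED"]
    if (!length(onBedTest))
        stop("stage evaluate: no on-bed epochs in the held-out portion")
    st4 <- postureLabels()
    trainLabels <- rep(st4, each = nTrainPerClass)
    trainFeats <- lapply(seq_along(trainLabels), function(i)
        preprocessAndExtract(
            renderPostureImage(trainLabels[i], cfg,
                               seed = .splitSeed(seed, 3000000L + i)),
            threshold = threshold, thresholdMode = thresholdMode,
            gaussianSigma = gaussianSigma, kernelSize = kernelSize,
            align = align, imageSize = imageSize))
    clf <- trainClassifier(trainFeats, trainLabels)
    model <- fitTransitionModel(
        PostureSequence(labels[trainIdx], cfg@epochSeconds),
        order = modelOrder, alpha = alpha,
        mask = defaultAllowedMask(any(labels == "OFFBED")))
    predicted <- character(length(onBedTest))
    for (k in seq_along(onBedTest)) {
        i <- onBedTest[k]
        obs <- classifyPosture(clf, feats[[i]])
        if (fuse && i > modelOrder &&
            all(labels[seq(i - modelOrder, i - 1L)] %in%
                modelStates(model))) {
            pr <- predictNext(model, labels[seq(i - modelOrder, i - 1L)])
            prior4 <- pr@posterior[st4]
            if (sum(prior4) > 0 && sum(obs * (prior4 / sum(prior4))) > 0) {
                obs <- fuseWithPrior(obs, prior4 / sum(prior4))
            }
        }
        predicted[k] <- names(obs)[which.max(obs)]
    }
    ev <- evaluatePredictions(predicted, labels[onBedTest])
    list(confusion = ev$confusion, accuracy = ev$accuracy,
         recall = ev$recall,
         occupancy = estimateOccupancy(ds$sequence),
         shiftsPerHour = shiftsPerHour(ds$sequence),
         nTrain = length(trainLabels), nTest = length(onBedTest),
         config = list(nEpochs = nEpochs, seed = seed,
                       trainFraction = trainFraction,
                       threshold = threshold,
                       thresholdMode = thresholdMode,
                       gaussianSigma = gaussianSigma,
                       kernelSize = kernelSize, align = align,
                       modelOrder = modelOrder, alpha = alpha,
                       fuse = fuse, imageSize = imageSize,
                       imageNoiseSd = cfg@imageNoiseSd))
}

#' Preprocess one pulse image and extract its features
#'
#' The per-frame preprocessing chain used by [runPipeline()]:
#' standardize to [0, 1] at the target resolution, threshold filter
#' (fixed cutoff or the per-image adaptive pulse threshold), Gaussian
#' smoothing, optional principal-axis alignment, then HOG extraction.
#'
#' @inheritParams runPipeline
#' @param img a [PulseImage-class] or raw numeric matrix.
#' @return A [PostureFeatures-class].
#' @export
preprocessAndExtract <- function(img, threshold = 0.5725,
                                 thresholdMode = "keep_high",
                                 gaussianSigma = 1, kernelSize = 5L,
                                 align = FALSE, imageSize = 64L) {
    raw <- if (is(img, "PulseImage")) pixels(img) else as.matrix(img)
    std <- standardizeImage(raw, imageSize, imageSize)
    thr <- if (identical(threshold, "auto")) {
        if (any(pixels(std) > 0)) pulseThreshold(std) else 0
    } else as.numeric(threshold)
    filt <- thresholdFilter(std, thr, mode = thresholdMode)
    sm <- gaussianFilter(filt, gaussianKernel(kernelSize, gaussianSigma))
    if (align) {
        ok <- sum(pixels(sm) > 0.5725) >= 3L
        if (ok) sm <- alignPrincipalAxis(sm)@rotated
    }
    suppressWarnings(extractFeatures(sm))
}
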