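#' @import methods
NULL

#' Canonical keypoint slot names
#'
#' The twelve-coordinate keypoint vector is ordered as six (x, y) pairs:
#' mesial CEJ, mesial alveolar crest, mesial root apex, then the same three
#' landmarks for the distal side. All coordinates are normalized fractions of
#' crop width (x) and crop height (y), in `[0, 1]`, origin at the top-left
#' corner with x rightward and y downward.
#'
#' @return Character vector of length 12 with the canonical slot names.
#' @export
#' @examples
#' kpSlotNames()
kpSlotNames <- function() {
    paste(rep(c("mesial", "distal"), each = 6L),
          rep(rep(c("CEJ", "crest", "apex"), each = 2L), 2L),
          rep(c("x", "y"), 6L), sep = ".")
}

.KP_SLOTS <- paste(rep(c("mesial", "distal"), each = 6L),
                   rep(rep(c("CEJ", "crest", "apex"), each = 2L), 2L),
                   rep(c("x", "y"), 6L), sep = ".")
.LANDMARKS <- c("CEJ", "crest", "apex")
.SIDES <- c("mesial", "distal")
.STAGES <- c("1", "2", "34")
.JAWS <- c("upper", "lower")

## ---------------------------------------------------------------------------
## RadiographAnnotation: one labelled panoramic radiograph
## ---------------------------------------------------------------------------

#' RadiographAnnotation class
#'
#' One annotated panoramic radiograph: image reference and dimensions plus the
#' molar bounding boxes and landmark points, all in radiograph pixel
#' coordinates (0-based, origin top-left, x rightward, y downward).
#'
#' @slot imageId Short identifier, typically the image filename stem.
#' @slot imagePath Path to the image file (possibly relative).
#' @slot width,height Image dimensions in pixels.
#' @slot boxes data.frame with columns `x`, `y`, `w`, `h` (pixels) and `jaw`
#'   (`"upper"` or `"lower"`), one row per molar bounding box.
#' @slot points data.frame with columns `x`, `y` (pixels), `landmark`
#'   (`"CEJ"`, `"crest"` or `"apex"`) and `side` (`"mesial"` or `"distal"`).
#'
#' @export
setClass("RadiographAnnotation",
    representation(imageId = "character", imagePath = "character",
                   width = "numeric", height = "numeric",
                   boxes = "data.frame", points = "data.frame"))

setValidity("RadiographAnnotation", function(object) {
    msg <- character()
    if (length(object@width) != 1L || length(object@height) != 1L ||
        object@width <= 0 || object@height <= 0)
        msg <- c(msg, "width and height must be single positive numbers")
    b <- object@boxes
    if (nrow(b)) {
        if (!all(c("x", "y", "w", "h", "jaw") %in% names(b)))
            msg <- c(msg, "boxes must have columns x, y, w, h, jaw")
        else {
            if (any(b$w < 0 | b$h < 0))
                msg <- c(msg, "negative box dimensions")
            if (any(b$x < -1e-6 | b$y < -1e-6 |
                    b$x + b$w > object@width + 1e-6 |
                    b$y + b$h > object@height + 1e-6))
                msg <- c(msg, "box outside image bounds")
            if (!all(b$jaw %in% .JAWS))
                msg <- c(msg, "box jaw must be 'upper' or 'lower'")
        }
    }
    p <- object@points
    if (nrow(p)) {
        if (!all(c("x", "y", "landmark", "side") %in% names(p)))
            msg <- c(msg, "points must have columns x, y, landmark, side")
        else {
            if (any(p$x < -1e-6 | p$y < -1e-6 |
                    p$x > object@width + 1e-6 | p$y > object@height + 1e-6))
                msg <- c(msg, "point outside image bounds")
            if (!all(p$landmark %in% .LANDMARKS))
                msg <- c(msg, sprintf("unknown landmark label(s): %s",
                    paste(unique(setdiff(p$landmark, .LANDMARKS)), collapse = ", ")))
            if (!all(p$side %in% .SIDES))
                msg <- c(msg, "point side must be 'mesial' or 'distal'")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname RadiographAnnotation-class
#' @param imageId,imagePath,width,height,boxes,points See slot descriptions.
#' @return A `RadiographAnnotation` object.
#' @export
RadiographAnnotation <- function(imageId, imagePath = "", width, height,
                                 boxes = data.frame(), points = data.frame()) {
    new("RadiographAnnotation", imageId = as.character(imageId),
        imagePath = as.character(imagePath),
        width = as.numeric(width), height = as.numeric(height),
        boxes = boxes, points = points)
}

## ---------------------------------------------------------------------------
## MolarCrop: one oriented rectangular molar image with keypoints
## ---------------------------------------------------------------------------

#' MolarCrop class
#'
#' One rectangular molar crop with up to six labelled keypoints. The image is
#' a numeric matrix with rows indexing y (downward) and columns indexing x
#' (rightward), intensities in `[0, 1]`. Keypoints are stored as a named
#' 12-vector of normalized coordinates (see [kpSlotNames()]); a side is either
#' fully labelled (all three landmarks) or entirely `NA` — partially labelled
#' sides are invalid, mirroring the labelling rule that a side counts only
#' when CEJ, crest and apex are all identifiable.
#'
#' Once `oriented` is `TRUE` the crop is guaranteed apex-down: for every
#' labelled side the apex y-coordinate is at least the CEJ y-coordinate.
#'
#' @slot molarId Identifier string.
#' @slot image Numeric matrix, `nrow` = height, `ncol` = width.
#' @slot keypoints Named numeric vector of length 12 (`NA` allowed per side).
#' @slot jaw `"upper"` or `"lower"`.
#' @slot oriented Logical; `TRUE` after [orientMolar()].
#'
#' @export
setClass("MolarCrop",
    representation(molarId = "character", image = "matrix",
                   keypoints = "numeric", jaw = "character",
                   oriented = "logical"))

setValidity("MolarCrop", function(object) {
    msg <- character()
    kp <- object@keypoints
    if (length(kp) != 12L || !identical(names(kp), .KP_SLOTS))
        return("keypoints must be a named numeric vector in kpSlotNames() order")
    ok <- is.na(kp) | (kp >= -1e-9 & kp <= 1 + 1e-9)
    if (!all(ok))
        msg <- c(msg, "keypoint coordinates must lie in [0, 1]")
    for (side in .SIDES) {
        sl <- kp[grep(paste0("^", side), names(kp))]
        if (any(is.na(sl)) && !all(is.na(sl)))
            msg <- c(msg, sprintf("%s side is partially labelled", side))
    }
    if (!(length(object@jaw) == 1L && object@jaw %in% .JAWS))
        msg <- c(msg, "jaw must be 'upper' or 'lower'")
    if (isTRUE(object@oriented)) {
        for (side in .SIDES) {
            ay <- kp[paste0(side, ".apex.y")]
            cy <- kp[paste0(side, ".CEJ.y")]
            if (!is.na(ay) && !is.na(cy) && ay < cy - 1e-9)
                msg <- c(msg, sprintf("oriented crop has %s apex above CEJ", side))
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname MolarCrop-class
#' @param molarId,image,keypoints,jaw,oriented See slot descriptions.
#' @return A `MolarCrop` object.
#' @export
MolarCrop <- function(molarId, image,
                      keypoints = stats::setNames(rep(NA_real_, 12L), kpSlotNames()),
                      jaw = "lower", oriented = FALSE) {
    kp <- asKeypointVector(keypoints, partial = TRUE)
    new("MolarCrop", molarId = as.character(molarId), image = image,
        keypoints = kp, jaw = jaw, oriented = oriented)
}

## ---------------------------------------------------------------------------
## PriorModel: 12 fitted one-dimensional probability functions
## ---------------------------------------------------------------------------

#' PriorModel class
#'
#' The statistical keypoint prior: one fitted one-dimensional probability
#' function per keypoint coordinate, twelve in total. Each fit records the
#' selected family, its maximum-likelihood parameters, and the histogram
#' sum-of-squares error used to rank candidate families. Degenerate
#' (zero-variance) coordinates are stored as a `"pointmass"` pseudo-family.
#'
#' @slot fits List of 12 lists, each with elements `family` (character),
#'   `params` (named numeric) and `fitError` (non-negative numeric).
#' @slot nTrain Number of keypoint vectors the prior was fitted on.
#'
#' @export
setClass("PriorModel",
    representation(fits = "list", nTrain = "integer"))

setValidity("PriorModel", function(object) {
    if (length(object@fits) != 12L)
        return("a PriorModel must hold exactly 12 fitted distributions")
    for (f in object@fits) {
        if (!all(c("family", "params", "fitError") %in% names(f)))
            return("each fit needs elements family, params, fitError")
        if (f$fitError < 0) return("fitError must be non-negative")
    }
    TRUE
})

## ---------------------------------------------------------------------------
## RefinerConfig / RefinerModel
## ---------------------------------------------------------------------------

#' RefinerConfig class
#'
#' Configuration of the convolutional keypoint refiner. The network is an
#' entry-flow style stack of `nBlocks` depthwise-separable convolution blocks
#' with residual shortcuts, each halving the spatial resolution, followed by
#' global moment pooling and a 12-unit linear head. Input images are resized
#' to `inputHeight` by `inputWidth`; the sampled prior prediction enters as
#' six Gaussian heatmap channels of width `heatmapSigma` pixels.
#'
#' Defaults follow the training recipe of the measurement pipeline: adaptive
#' moment (Adam) optimisation at learning rate 0.001, batch size 32, at most
#' 5 epochs with early stopping (patience 2 epochs on validation MSE), and
#' dropout 0.5 on all layers except the final one.
#'
#' @slot inputHeight,inputWidth Input size in pixels; each must be divisible
#'   by `2^nBlocks` so that the pooling stages tile exactly.
#' @slot nBlocks Number of separable-convolution blocks.
#' @slot filters Integer vector of length `nBlocks`: output channels per block.
#' @slot activation Activation function name (`"relu"`).
#' @slot dropoutRate Dropout probability in `[0, 1)`.
#' @slot learningRate Adam step size.
#' @slot batchSize Minibatch size.
#' @slot maxEpochs Maximum training epochs.
#' @slot earlyStopPatience Epochs without validation improvement before stop.
#' @slot heatmapSigma Gaussian heatmap standard deviation in pixels.
#' @slot seed Integer seed controlling initialization, shuffling and dropout.
#'
#' @export
setClass("RefinerConfig",
    representation(inputHeight = "integer", inputWidth = "integer",
                   nBlocks = "integer", filters = "integer",
                   activation = "character", dropoutRate = "numeric",
                   learningRate = "numeric", batchSize = "integer",
                   maxEpochs = "integer", earlyStopPatience = "integer",
                   heatmapSigma = "numeric", seed = "integer"))

setValidity("RefinerConfig", function(object) {
    msg <- character()
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
    if (length(object@filters) != object@nBlocks)
        msg <- c(msg, "filters must have one entry per block")
    div <- 2L^object@nBlocks
    if (object@inputHeight %% div != 0L || object@inputWidth %% div != 0L)
        msg <- c(msg, sprintf("input dimensions must be divisible by %d", div))
    if (object@activation != "relu")
        msg <- c(msg, "only the 'relu' activation is implemented")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname RefinerConfig-class
#' @param inputHeight,inputWidth,nBlocks,filters,activation,dropoutRate,
#'   learningRate,batchSize,maxEpochs,earlyStopPatience,heatmapSigma,seed
#'   See slot descriptions.
#' @return A `RefinerConfig` object.
#' @export
refinerConfig <- function(inputHeight = 128L, inputWidth = 96L,
                          nBlocks = 3L, filters = c(32L, 64L, 128L),
                          activation = "relu", dropoutRate = 0.5,
                          learningRate = 0.001, batchSize = 32L,
                          maxEpochs = 5L, earlyStopPatience = 2L,
                          heatmapSigma = 4, seed = 1L) {
    new("RefinerConfig", inputHeight = as.integer(inputHeight),
        inputWidth = as.integer(inputWidth), nBlocks = as.integer(nBlocks),
        filters = as.integer(filters), activation = activation,
        dropoutRate = dropoutRate, learningRate = learningRate,
        batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
        earlyStopPatience = as.integer(earlyStopPatience),
        heatmapSigma = heatmapSigma, seed = as.integer(seed))
}

#' RefinerModel class
#'
#' A (possibly trained) convolutional keypoint refiner: its configuration,
#' parameter tensors, and per-epoch training history.
#'
#' @slot config The [RefinerConfig-class] the model was built with.
#' @slot params Named list of parameter matrices/vectors.
#' @slot bn Running mean/variance of the pooled features (the feature
#'   normalization statistics used at inference).
#' @slot trained Logical.
#' @slot history data.frame with columns `epoch`, `train_mse`, `val_mse`.
#'
#' @export
setClass("RefinerModel",
    representation(config = "RefinerConfig", params = "list", bn = "list",
                   trained = "logical", history = "data.frame"))

## ---------------------------------------------------------------------------
## SynthParams
## ---------------------------------------------------------------------------

#' SynthParams class
#'
#' Parameters of the synthetic molar-crop generator. The generator renders a
#' stylized two-rooted molar (bright crown and roots over a darker
#' bone-textured background, an alveolar bone band whose top edge passes
#' through the crest keypoints) and emits all six keypoints with an exactly
#' known per-side PBL percentage. The default stage mix reproduces the
#' severity imbalance of the study data (57.14% / 35.71% / 7.14% for stages
#' 1 / 2 / 3-4).
#'
#' @slot imageWidth,imageHeight Crop size in pixels.
#' @slot stageMix Named probabilities over stages `"1"`, `"2"`, `"34"`.
#' @slot pblRanges Named list of per-stage PBL percentage intervals; defaults
#'   keep a 2-point margin from the 15/33 stage boundaries so labels stay
#'   unambiguous under rendering noise.
#' @slot rootLengthRange Root length interval as a fraction of image height.
#' @slot noiseSd Additive Gaussian intensity noise SD.
#' @slot blurSigma Gaussian blur SD in pixels (0 disables).
#' @slot contrastJitter Multiplicative gain jitter half-width.
#' @slot upperFraction Probability a crop is upper-jaw (emitted apex-up).
#' @slot sideCorrelation Correlation of mesial and distal bone levels.
#' @slot seed Integer seed used by [generateDataset()].
#'
#' @export
setClass("SynthParams",
    representation(imageWidth = "integer", imageHeight = "integer",
                   stageMix = "numeric", pblRanges = "list",
                   rootLengthRange = "numeric", noiseSd = "numeric",
                   blurSigma = "numeric", contrastJitter = "numeric",
                   upperFraction = "numeric", sideCorrelation = "numeric",
                   seed = "integer"))

setValidity("SynthParams", function(object) {
    msg <- character()
    if (!identical(names(object@stageMix), .STAGES) ||
        abs(sum(object@stageMix) - 1) > 1e-6)
        msg <- c(msg, "stageMix must be named '1','2','34' and sum to 1")
    if (!identical(names(object@pblRanges), .STAGES))
        msg <- c(msg, "pblRanges must be a named list over '1','2','34'")
    else {
        band <- list(`1` = c(0, 15), `2` = c(15, 33), `34` = c(33, 100))
        for (s in .STAGES) {
            r <- object@pblRanges[[s]]
            if (length(r) != 2L || r[1] > r[2] ||
                r[1] < band[[s]][1] || r[2] > band[[s]][2])
                msg <- c(msg, sprintf(
                    "pblRanges[['%s']] must lie within the stage band [%g, %g]",
                    s, band[[s]][1], band[[s]][2]))
        }
    }
    if (object@upperFraction < 0 || object@upperFraction > 1)
        msg <- c(msg, "upperFraction must be a probability")
    if (abs(object@sideCorrelation) > 1)
        msg <- c(msg, "sideCorrelation must be in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname SynthParams-class
#' @param imageWidth,imageHeight,stageMix,pblRanges,rootLengthRange,noiseSd,
#'   blurSigma,contrastJitter,upperFraction,sideCorrelation,seed
#'   See slot descriptions.
#' @return A `SynthParams` object.
#' @export
synthParams <- function(imageWidth = 96L, imageHeight = 128L,
                        stageMix = c(`1` = 0.5714, `2` = 0.3571, `34` = 0.0714),
                        pblRanges = list(`1` = c(2, 13), `2` = c(17, 31),
                                         `34` = c(35, 60)),
                        rootLengthRange = c(0.45, 0.60),
                        noiseSd = 0.03, blurSigma = 0.8,
                        contrastJitter = 0.15, upperFraction = 0.5,
                        sideCorrelation = 0.7, seed = 1L) {
    mix <- stageMix / sum(stageMix)
    names(mix) <- names(stageMix)
    new("SynthParams", imageWidth = as.integer(imageWidth),
        imageHeight = as.integer(imageHeight), stageMix = mix,
        pblRanges = pblRanges, rootLengthRange = rootLengthRange,
        noiseSd = noiseSd, blurSigma = blurSigma,
        contrastJitter = contrastJitter, upperFraction = upperFraction,
        sideCorrelation = sideCorrelation, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## MetricsTable
## ---------------------------------------------------------------------------

#' MetricsTable class
#'
#' Full rater-evaluation result: per-stage one-vs-rest diagnostic counts and
#' metrics, plus macro, weighted and micro averages. Macro averages are
#' unweighted means over stages; weighted averages weight by true-class
#' support proportion; micro averages are computed from counts pooled across
#' stages (micro sensitivity equals plain multiclass accuracy).
#'
#' @slot perStage data.frame, one row per stage, columns `sensitivity`,
#'   `specificity`, `precision`, `accuracy_recall`, `f1`.
#' @slot macro,weighted Named numeric vectors of the five metrics.
#' @slot micro Named numeric vector: `sensitivity`, `precision`, `f1`.
#' @slot supports Named integer vector of true-class counts per stage.
#' @slot counts 3x4 matrix of pooled TP/TN/FP/FN counts, one row per stage.
#' @slot nItems Number of scored items.
#'
#' @export
setClass("MetricsTable",
    representation(perStage = "data.frame", macro = "numeric",
                   weighted = "numeric", micro = "numeric",
                   supports = "integer", counts = "matrix",
                   nItems = "integer"))

setValidity("MetricsTable", function(object) {
    msg <- character()
    if (!identical(rownames(object@perStage), .STAGES))
        msg <- c(msg, "perStage must have rows '1','2','34'")
    if (nrow(object@counts) == 3L) {
        tot <- rowSums(object@counts)
        if (length(unique(tot)) != 1L || tot[1] != object@nItems)
            msg <- c(msg, "each stage's TP+TN+FP+FN must equal nItems")
    }
    if (length(msg)) msg else TRUE
})
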