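#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Standard accessors for the core S4 classes: crop identity, image matrix,
#' keypoint vector, jaw and orientation of a [MolarCrop-class]; fitted
#' distributions and training size of a [PriorModel-class]; training history
#' of a [RefinerModel-class]; components of a [MetricsTable-class].
#'
#' @param object An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("molarId", function(object) standardGeneric("molarId"))
#' @rdname accessors
#' @export
setGeneric("cropImage", function(object) standardGeneric("cropImage"))
#' @rdname accessors
#' @export
setGeneric("keypoints", function(object) standardGeneric("keypoints"))
#' @rdname accessors
#' @export
setGeneric("jaw", function(object) standardGeneric("jaw"))
#' @rdname accessors
#' @export
setGeneric("isOriented", function(object) standardGeneric("isOriented"))
#' @rdname accessors
#' @export
setGeneric("priorFits", function(object) standardGeneric("priorFits"))
#' @rdname accessors
#' @export
setGeneric("nTrain", function(object) standardGeneric("nTrain"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("stageMetrics", function(object) standardGeneric("stageMetrics"))
#' @rdname accessors
#' @export
setGeneric("macroMetrics", function(object) standardGeneric("macroMetrics"))
#' @rdname accessors
#' @export
setGeneric("weightedMetrics", function(object) standardGeneric("weightedMetrics"))
#' @rdname accessors
#' @export
setGeneric("microMetrics", function(object) standardGeneric("microMetrics"))
#' @rdname accessors
#' @export
setGeneric("stageSupports", function(object) standardGeneric("stageSupports"))
#' @rdname accessors
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname accessors
#' @export
setMethod("molarId", "MolarCrop", function(object) object@molarId)
#' @rdname accessors
#' @export
setMethod("cropImage", "MolarCrop", function(object) object@image)
#' @rdname accessors
#' @export
setMethod("keypoints", "MolarCrop", function(object) object@keypoints)
#' @rdname accessors
#' @export
setMethod("jaw", "MolarCrop", function(object) object@jaw)
#' @rdname accessors
#' @export
setMethod("isOriented", "MolarCrop", function(object) object@oriented)
#' @rdname accessors
#' @export
setMethod("priorFits", "PriorModel", function(object) object@fits)
#' @rdname accessors
#' @export
setMethod("nTrain", "PriorModel", function(object) object@nTrain)
#' @rdname accessors
#' @export
setMethod("trainingHistory", "RefinerModel", function(object) object@history)
#' @rdname accessors
#' @export
setMethod("stageMetrics", "MetricsTable", function(object) object@perStage)
#' @rdname accessors
#' @export
setMethod("macroMetrics", "MetricsTable", function(object) object@macro)
#' @rdname accessors
#' @export
setMethod("weightedMetrics", "MetricsTable", function(object) object@weighted)
#' @rdname accessors
#' @export
setMethod("microMetrics", "MetricsTable", function(object) object@micro)
#' @rdname accessors
#' @export
setMethod("stageSupports", "MetricsTable", function(object) object@supports)
#' @rdname accessors
#' @export
setMethod("stageCounts", "MetricsTable", function(object) object@counts)

setMethod("show", "MolarCrop", function(object) {
    d <- dim(object@image)
    nlab <- sum(!is.na(object@keypoints)) / 2L
    cat(sprintf("MolarCrop '%s': %d x %d px, %s jaw, %s, %d/6 keypoints\n",
        object@molarId, d[2], d[1], object@jaw,
        if (object@oriented) "oriented" else "unoriented", nlab))
})

setMethod("show", "RadiographAnnotation", function(object) {
    cat(sprintf("RadiographAnnotation '%s': %g x %g px, %d boxes, %d points\n",
        object@imageId, object@width, object@height,
        nrow(object@boxes), nrow(object@points)))
})

setMethod("show", "PriorModel", function(object) {
    cat(sprintf("PriorModel fitted on %d keypoint vectors\n", object@nTrain))
    fam <- vapply(object@fits, `[[`, character(1), "family")
    err <- vapply(object@fits, `[[`, numeric(1), "fitError")
    print(data.frame(slot = kpSlotNames(), family = fam,
                     fit_error = signif(err, 4)), row.names = FALSE)
})

setMethod("show", "RefinerConfig", function(object) {
    cat(sprintf(paste0(
        "RefinerConfig: %d x %d input, %d blocks (filters %s), %s\n",
        "  dropout %.2f, lr %g, batch %d, epochs <= %d (patience %d),",
        " heatmap sigma %g px, seed %d\n"),
        object@inputHeight, object@inputWidth, object@nBlocks,
        paste(object@filters, collapse = "/"), object@activation,
        object@dropoutRate, object@learningRate, object@batchSize,
        object@maxEpochs, object@earlyStopPatience, object@heatmapSigma,
        object@seed))
})

setMethod("show", "RefinerModel", function(object) {
    np <- sum(vapply(object@params, length, integer(1)))
    cat(sprintf("RefinerModel (%s): %d parameters\n",
        if (object@trained) "trained" else "untrained", np))
    if (nrow(object@history)) {
        cat(sprintf("  stopped after epoch %d; final val MSE %.5g\n",
            max(object@history$epoch), utils::tail(object@history$val_mse, 1)))
    }
})

setMethod("show", "SynthParams", function(object) {
    cat(sprintf(paste0(
        "SynthParams: %d x %d px crops, stage mix %s, noise %.3g,",
        " blur %.3g px, upper fraction %.2f, seed %d\n"),
        object@imageWidth, object@imageHeight,
        paste(sprintf("%s:%.3f", names(object@stageMix), object@stageMix),
              collapse = " "),
        object@noiseSd, object@blurSigma, object@upperFraction, object@seed))
})

setMethod("show", "MetricsTable", function(object) {
    cat(sprintf("MetricsTable over %d items (supports %s)\n", object@nItems,
        paste(sprintf("%s:%d", names(object@supports), object@supports),
              collapse = " ")))
    cat("Per-stage metrics:\n")
    print(round(object@perStage, 3))
    cat("Macro:   "); print(round(object@macro, 3))
    cat("Weighted:"); print(round(object@weighted, 3))
    cat("Micro:   "); print(round(object@micro, 3))
})
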