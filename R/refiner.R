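#' @include AllClasses.R utils.R nnet.R
NULL

#' Encode an image and a prior prediction as network input
#'
#' Builds the 7-channel input tensor of the refiner: channel 1 is the
#' intensity-normalized (zero-mean, unit-variance) image resized to the
#' configured input size; channels 2-7 are isotropic Gaussian heatmaps of
#' standard deviation `heatmapSigma` pixels centred on the six prior
#' keypoints in the resized frame. Heatmaps preserve the spatial structure
#' of the prior prediction, letting the convolutions relate it to image
#' features directly.
#'
#' @param image Numeric image matrix (rows = y).
#' @param priorVector Keypoint 12-vector (normalized, no missing values).
#' @param config A [RefinerConfig-class].
#' @return Numeric array of dimension `(inputHeight, inputWidth, 7)`.
#' @export
encodeInput <- function(image, priorVector, config) {
    stopifnot(methods::is(config, "RefinerConfig"))
    pv <- asKeypointVector(priorVector)
    H <- config@inputHeight; W <- config@inputWidth
    img <- resizeImage(image, H, W)
    s <- stats::sd(img)
    img <- if (s > 0) (img - mean(img)) / s else img - mean(img)
    out <- array(0, dim = c(H, W, 7L))
    out[, , 1L] <- img
    px <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
    py <- matrix(seq_len(H) - 0.5, H, W)
    sig2 <- 2 * config@heatmapSigma^2
    for (j in seq_len(6L)) {
        cx <- pv[2L * j - 1L] * W
        cy <- pv[2L * j] * H
        out[, , j + 1L] <- exp(-((px - cx)^2 + (py - cy)^2) / sig2)
    }
    out
}

# Flatten an encoded input to the (H*W) x 7 layout used internally.
.flattenInput <- function(enc) {
    d <- dim(enc)
    matrix(enc, d[1] * d[2], d[3])
}

#' Build an untrained refiner
#'
#' Constructs the separable-convolution keypoint refiner described by the
#' configuration: `nBlocks` entry-flow style blocks (two depthwise-separable
#' 3x3 convolutions, 2x2 max pooling, and a 1x1 stride-2 residual shortcut
#' each), global moment pooling (per-channel mean mass plus mass-normalized
#' spatial centroids, computed on the final feature maps and, as an
#' input-level residual, on the 7 input channels), dropout on all layers
#' except the last, and a
#' 12-unit linear output head. Parameters are He-initialized from
#' `config@seed`; two builds with the same seed are identical.
#'
#' @param config A [RefinerConfig-class].
#' @return An untrained [RefinerModel-class].
#' @export
buildRefiner <- function(config) {
    stopifnot(methods::is(config, "RefinerConfig"))
    params <- withSeed(config@seed, .initParams(config))
    new("RefinerModel", config = config, params = params,
        bn = list(mean = 0, var = 1), trained = FALSE,
        history = data.frame(epoch = integer(), train_mse = numeric(),
                             val_mse = numeric()))
}

# Encode all triples once; returns list(X = list of (HW x 7), truth, mask).
.encodeTriples <- function(triples, cfg) {
    list(X = lapply(triples, function(tr)
             .flattenInput(encodeInput(tr$image, tr$prior, cfg))),
         truth = do.call(rbind, lapply(triples, function(tr)
             asKeypointVector(tr$truth))),
         mask = do.call(rbind, lapply(triples, function(tr)
             as.logical(tr$mask))),
         ids = vapply(triples, function(tr) tr$molarId, character(1)))
}

.evalLoss <- function(params, enc, cfg, geomCache, bn, batch = 64L) {
    n <- length(enc$X)
    tot <- 0; nm <- 0
    for (start in seq(1L, n, by = batch)) {
        sel <- start:min(n, start + batch - 1L)
        B <- length(sel)
        g <- geomCache(B)
        fwd <- .refinerForward(params, do.call(rbind, enc$X[sel]), g, cfg, B,
                               training = FALSE, keepCache = FALSE, bn = bn)
        l <- .maskedMSE(fwd$pred, enc$truth[sel, , drop = FALSE],
                        enc$mask[sel, , drop = FALSE])
        tot <- tot + l$loss * l$n
        nm <- nm + l$n
    }
    if (nm == 0) 0 else tot / nm
}

#' Train the refiner
#'
#' Minimizes the mean squared error between the network's 12-dimensional
#' output and the true keypoint vector with the Adam optimizer, for at most
#' `maxEpochs` epochs with early stopping on validation MSE (patience
#' `earlyStopPatience` epochs). Slots flagged as masked (sides without real
#' labels) are excluded from the loss. Validation examples are held out at
#' the image level (a fraction `valFrac` of distinct molar ids) so that
#' augmented copies of a validation image never leak into training; a
#' pre-built validation set can be supplied instead via `valTriples`.
#'
#' Training is deterministic given `config@seed` (shuffling and dropout both
#' draw from the seeded stream).
#'
#' @param model An untrained (or previously trained) [RefinerModel-class].
#' @param triples Training triples from [augmentTrainingSet()].
#' @param valFrac Fraction of molar ids held out for validation.
#' @param valTriples Optional explicit validation triples.
#' @return The trained [RefinerModel-class]; its history (accessible via
#'   [trainingHistory()]) has one row per completed epoch with columns
#'   `epoch`, `train_mse`, `val_mse`.
#' @export
trainRefiner <- function(model, triples, valFrac = 0.2, valTriples = NULL) {
    stopifnot(methods::is(model, "RefinerModel"))
    cfg <- model@config
    if (length(triples) < 2L * cfg@batchSize)
        stop("training needs at least ", 2L * cfg@batchSize,
             " triples, got ", length(triples))
    withSeed(cfg@seed + 1L, {
        if (is.null(valTriples)) {
            ids <- unique(vapply(triples, function(tr) tr$molarId, character(1)))
            if (length(ids) >= 5L) {
                nVal <- max(1L, round(valFrac * length(ids)))
                valIds <- sample(ids, nVal)
                isVal <- vapply(triples, function(tr) tr$molarId %in% valIds,
                                logical(1))
            } else {
                isVal <- seq_along(triples) %in%
                    sample(length(triples), max(1L, round(valFrac * length(triples))))
            }
            valTriples <- triples[isVal]
            triples <- triples[!isVal]
        }
        encTr <- .encodeTriples(triples, cfg)
        encVal <- .encodeTriples(valTriples, cfg)

        geomEnv <- new.env(parent = emptyenv())
        geomCache <- function(B) {
            key <- as.character(B)
            if (is.null(geomEnv[[key]]))
                geomEnv[[key]] <- .refinerGeoms(cfg, B)
            geomEnv[[key]]
        }

        params <- model@params
        bn <- model@bn
        opt <- .adamInit(params)
        n <- length(encTr$X)
        history <- data.frame(epoch = integer(), train_mse = numeric(),
                              val_mse = numeric())
        best <- Inf
        bestParams <- params
        bestBn <- bn
        bad <- 0L
        for (epoch in seq_len(cfg@maxEpochs)) {
            perm <- sample.int(n)
            totLoss <- 0; totN <- 0
            for (start in seq(1L, n, by = cfg@batchSize)) {
                sel <- perm[start:min(n, start + cfg@batchSize - 1L)]
                B <- length(sel)
                g <- geomCache(B)
                fwd <- .refinerForward(params, do.call(rbind, encTr$X[sel]),
                                       g, cfg, B, training = TRUE, bn = bn)
                bn <- fwd$bn
                l <- .maskedMSE(fwd$pred, encTr$truth[sel, , drop = FALSE],
                                encTr$mask[sel, , drop = FALSE])
                if (l$n == 0) next
                grads <- .refinerBackward(params, fwd, g, cfg, B, l$grad)
                # global gradient-norm clipping keeps late-epoch updates stable
                gn <- sqrt(sum(vapply(grads, function(g2) sum(g2^2),
                                      numeric(1))))
                if (gn > 5)
                    grads <- lapply(grads, function(g2) g2 * (5 / gn))
                upd <- .adamStep(params, grads, opt, cfg@learningRate)
                params <- upd$params
                opt <- upd$state
                totLoss <- totLoss + l$loss * l$n
                totN <- totN + l$n
            }
            valLoss <- .evalLoss(params, encVal, cfg, geomCache, bn)
            history <- rbind(history, data.frame(
                epoch = epoch, train_mse = totLoss / max(1, totN),
                val_mse = valLoss))
            if (valLoss < best - 1e-12) {
                best <- valLoss
                bestParams <- params
                bestBn <- bn
                bad <- 0L
            } else {
                bad <- bad + 1L
                if (bad >= cfg@earlyStopPatience) break
            }
        }
        # early stopping restores the weights of the best validation epoch
        methods::initialize(model, params = bestParams, bn = bestBn,
                            trained = TRUE, history = history)
    })
}

#' Predict refined keypoints
#'
#' Runs the trained refiner on an image paired with a prior keypoint
#' prediction and returns the refined 12-vector, clamped to `[0, 1]`.
#' Inference is deterministic (dropout inactive). For batch prediction pass
#' a list of images and a matrix of priors (one row each).
#'
#' @param model A trained [RefinerModel-class].
#' @param image Image matrix, or a list of image matrices.
#' @param priorVector Keypoint 12-vector, or an `n x 12` matrix matching the
#'   image list.
#' @return Named keypoint 12-vector, or an `n x 12` matrix for batch input.
#' @export
predictKeypoints <- function(model, image, priorVector) {
    stopifnot(methods::is(model, "RefinerModel"))
    if (!model@trained) stop("the refiner has not been trained")
    cfg <- model@config
    single <- !is.list(image)
    if (single) {
        image <- list(image)
        priorVector <- matrix(asKeypointVector(priorVector), 1L, 12L)
    }
    n <- length(image)
    stopifnot(nrow(priorVector) == n)
    preds <- matrix(NA_real_, n, 12L, dimnames = list(NULL, .KP_SLOTS))
    batch <- 64L
    geomEnv <- new.env(parent = emptyenv())
    for (start in seq(1L, n, by = batch)) {
        sel <- start:min(n, start + batch - 1L)
        B <- length(sel)
        key <- as.character(B)
        if (is.null(geomEnv[[key]]))
            geomEnv[[key]] <- .refinerGeoms(cfg, B)
        X <- do.call(rbind, lapply(sel, function(i)
            .flattenInput(encodeInput(image[[i]], priorVector[i, ], cfg))))
        fwd <- .refinerForward(model@params, X, geomEnv[[key]], cfg, B,
                               training = FALSE, keepCache = FALSE,
                               bn = model@bn)
        preds[sel, ] <- clamp01(fwd$pred)
    }
    if (single) stats::setNames(preds[1L, ], .KP_SLOTS) else preds
}

#' Masked mean-squared error of a refiner on a set of triples
#'
#' Evaluates the model (dropout inactive) on training-format triples and
#' returns the mean squared error over unmasked slots only. Triples whose
#' every slot is masked contribute nothing to the value.
#'
#' @param model A trained or untrained [RefinerModel-class].
#' @param triples Triples as produced by [augmentTrainingSet()].
#' @return Single numeric MSE.
#' @export
refinerLoss <- function(model, triples) {
    stopifnot(methods::is(model, "RefinerModel"), length(triples) >= 1L)
    cfg <- model@config
    enc <- .encodeTriples(triples, cfg)
    geomEnv <- new.env(parent = emptyenv())
    geomCache <- function(B) {
        key <- as.character(B)
        if (is.null(geomEnv[[key]]))
            geomEnv[[key]] <- .refinerGeoms(cfg, B)
        geomEnv[[key]]
    }
    .evalLoss(model@params, enc, cfg, geomCache, model@bn)
}

#' Save / load a refiner model
#'
#' Model weights, configuration and history are serialized with R's native
#' serialization.
#'
#' @param model A [RefinerModel-class].
#' @param path File path.
#' @return `path` (save) or the restored [RefinerModel-class] (load).
#' @export
saveRefiner <- function(model, path) {
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveRefiner
#' @export
loadRefiner <- function(path) {
    model <- readRDS(path)
    stopifnot(methods::is(model, "RefinerModel"))
    model
}
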