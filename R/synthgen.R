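#' @include AllClasses.R utils.R
NULL

# Sample the molar geometry and per-side PBL for one crop; returns the
# keypoints (normalized, apex-down frame) and the exact per-side PBL.
# Uses the caller's RNG stream.
.sampleGeometry <- function(params, targetStage) {
    jit <- function(w) stats::runif(1L, -w, w)
    yCEJ <- c(mesial = 0.28 + jit(0.03), distal = 0.28 + jit(0.03))
    xCEJ <- c(mesial = 0.20 + jit(0.03), distal = 0.80 + jit(0.03))
    L0 <- stats::runif(1L, params@rootLengthRange[1], params@rootLengthRange[2])
    L <- c(mesial = L0 * (1 + jit(0.03)), distal = L0 * (1 + jit(0.03)))
    yApex <- yCEJ + L
    xApex <- c(mesial = xCEJ[["mesial"]] + 0.07 + jit(0.02),
               distal = xCEJ[["distal"]] - 0.07 + jit(0.02))
    # correlated per-side severities within the target stage's PBL band
    rho <- params@sideCorrelation
    z1 <- stats::rnorm(1L)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1L)
    r <- params@pblRanges[[targetStage]]
    pbl <- r[1] + stats::pnorm(c(mesial = z1, distal = z2)) * (r[2] - r[1])

    kp <- stats::setNames(rep(NA_real_, 12L), .KP_SLOTS)
    for (s in .SIDES) {
        cej <- c(xCEJ[[s]], yCEJ[[s]])
        apex <- c(xApex[[s]], yApex[[s]])
        # crest on the CEJ-apex segment at bone-height fraction (1 - pbl/100);
        # ratios along a line survive the anisotropic pixel scaling, so the
        # Euclidean PBL of the emitted keypoints equals the target exactly
        crest <- apex + (1 - pbl[[s]] / 100) * (cej - apex)
        kp[paste0(s, c(".CEJ.x", ".CEJ.y"))] <- cej
        kp[paste0(s, c(".crest.x", ".crest.y"))] <- crest
        kp[paste0(s, c(".apex.x", ".apex.y"))] <- apex
    }
    list(keypoints = kp, pbl = pbl)
}

# Render the stylized radiograph for a sampled geometry (apex-down frame).
.renderMolar <- function(params, kp) {
    W <- params@imageWidth; H <- params@imageHeight
    xs <- (seq_len(W) - 0.5) / W
    ys <- (seq_len(H) - 0.5) / H
    X <- matrix(xs, H, W, byrow = TRUE)
    Y <- matrix(ys, H, W)

    lineAt <- function(x, p1, p2) {
        # piecewise-linear level through two points, flat outside their span
        t <- (x - p1[1]) / (p2[1] - p1[1])
        p1[2] + pmin(1, pmax(0, t)) * (p2[2] - p1[2])
    }
    crestM <- kp[c("mesial.crest.x", "mesial.crest.y")]
    crestD <- kp[c("distal.crest.x", "distal.crest.y")]
    boneTop <- matrix(lineAt(xs, crestM, crestD), H, W, byrow = TRUE)
    bone <- Y >= boneTop

    cejM <- kp[c("mesial.CEJ.x", "mesial.CEJ.y")]
    cejD <- kp[c("distal.CEJ.x", "distal.CEJ.y")]
    cejLine <- matrix(lineAt(xs, cejM, cejD), H, W, byrow = TRUE)
    yTop <- min(cejM[2], cejD[2]) - 0.16
    crown <- Y >= yTop & Y <= cejLine &
        X >= cejM[1] - 0.04 & X <= cejD[1] + 0.04

    rootMask <- function(side, inward) {
        cej <- kp[paste0(side, c(".CEJ.x", ".CEJ.y"))]
        apex <- kp[paste0(side, c(".apex.x", ".apex.y"))]
        cx0 <- cej[1] + inward
        t <- (Y - cej[2]) / (apex[2] - cej[2])
        inY <- t >= 0 & t <= 1
        cx <- cx0 + t * (apex[1] - cx0)
        halfw <- 0.055 * (1 - t) + 0.012
        inY & abs(X - cx) <= halfw
    }
    tooth <- crown | rootMask("mesial", 0.045) | rootMask("distal", -0.045)

    img <- 0.30 + 0.22 * bone + 0.45 * tooth
    if (params@contrastJitter > 0) {
        gain <- 1 + stats::runif(1L, -params@contrastJitter, params@contrastJitter)
        off <- stats::runif(1L, -params@contrastJitter, params@contrastJitter) * 0.1
        img <- 0.5 + (img - 0.5) * gain + off
    }
    if (params@blurSigma > 0)
        img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                                   sigma = params@blurSigma)))
    if (params@noiseSd > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, params@noiseSd), H, W)
    clamp01(img)
}

.generateMolarFull <- function(params, targetStage, molarId) {
    geo <- .sampleGeometry(params, targetStage)
    img <- .renderMolar(params, geo$keypoints)
    kp <- geo$keypoints
    jawSide <- if (stats::runif(1L) < params@upperFraction) "upper" else "lower"
    if (jawSide == "upper") {
        # upper molars are emitted apex-up, exactly as they appear on the
        # radiograph, leaving the 180-degree inversion to orientMolar()
        img <- img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))), drop = FALSE]
        kp <- stats::setNames(1 - kp, .KP_SLOTS)
    }
    list(crop = MolarCrop(molarId = molarId, image = img, keypoints = kp,
                          jaw = jawSide, oriented = FALSE),
         pbl = geo$pbl)
}

#' Generate one synthetic labelled molar crop
#'
#' Renders a stylized two-rooted molar crop — bright crown and two divergent
#' roots over a darker background, with an alveolar bone band whose top edge
#' passes through the crest keypoints — and emits all six keypoints. The
#' per-side bone heights are sampled (with correlation
#' `params@sideCorrelation` between sides) so that the Euclidean PBL of the
#' emitted keypoints falls inside `params@pblRanges[[targetStage]]` exactly.
#' Noise, blur and contrast jitter are then applied. Upper-jaw crops are
#' emitted apex-up so that [orientMolar()] has real work to do.
#'
#' Consumes the caller's RNG stream: wrap in `set.seed()` for reproducibility.
#'
#' @param params A [SynthParams-class].
#' @param targetStage `"1"`, `"2"` or `"34"`.
#' @param molarId Identifier for the crop.
#' @return A labelled, unoriented [MolarCrop-class].
#' @export
generateMolar <- function(params, targetStage, molarId = "syn") {
    stopifnot(methods::is(params, "SynthParams"))
    targetStage <- match.arg(as.character(targetStage), .STAGES)
    .generateMolarFull(params, targetStage, molarId)$crop
}

#' Generate a synthetic labelled dataset
#'
#' Draws `n` molar crops with stages allocated from `params@stageMix` and
#' returns them together with the exact ground truth. With
#' `allocation = "exact"` the per-stage counts are the largest-remainder
#' rounding of `n * stageMix` (for `n = 84` under the default mix:
#' 48 / 30 / 6); with `"random"` stages are drawn independently.
#'
#' @param params A [SynthParams-class]; `params@seed` makes the output
#'   deterministic.
#' @param n Number of crops.
#' @param allocation `"exact"` or `"random"` stage allocation.
#' @return List with `crops` (list of [MolarCrop-class]) and `truth`
#'   (data.frame: `molar_id`, `side`, `pbl_percent`, `stage`).
#' @export
#' @seealso [writeDataset()] to serialize to PNG + annotation JSON + CSV.
generateDataset <- function(params, n, allocation = c("exact", "random")) {
    stopifnot(methods::is(params, "SynthParams"), n >= 1)
    allocation <- match.arg(allocation)
    withSeed(params@seed, {
        if (allocation == "exact") {
            raw <- n * params@stageMix
            cnt <- floor(raw)
            rem <- n - sum(cnt)
            if (rem > 0) {
                extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
                cnt[extra] <- cnt[extra] + 1L
            }
            stages <- sample(rep(.STAGES, times = cnt))
        } else {
            stages <- sample(.STAGES, n, replace = TRUE, prob = params@stageMix)
        }
        crops <- vector("list", n)
        truth <- vector("list", n)
        for (i in seq_len(n)) {
            id <- sprintf("SYN%04d", i)
            g <- .generateMolarFull(params, stages[i], id)
            crops[[i]] <- g$crop
            truth[[i]] <- data.frame(
                molar_id = id, side = .SIDES,
                pbl_percent = as.numeric(g$pbl[.SIDES]),
                stage = stages[i])
        }
        list(crops = crops, truth = do.call(rbind, truth))
    })
}

#' Write a synthetic dataset to disk
#'
#' Serializes a [generateDataset()] result as one grayscale PNG per crop, an
#' annotation export `annotations.json` in the dialect read by
#' [readAnnotations()] (one full-frame bounding box plus the labelled points
#' per crop, coordinates in percent of image dimensions), and the ground
#' truth as `truth.csv`.
#'
#' @param dataset List with `crops` and `truth` as from [generateDataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    recs <- lapply(dataset$crops, function(crop) {
        img <- cropImage(crop)
        fn <- paste0(molarId(crop), ".png")
        writeGrayImage(img, file.path(dir, fn))
        kp <- keypoints(crop)
        anns <- list(list(type = "box", label = "molar", jaw = jaw(crop),
                          x = 0, y = 0, w = 100, h = 100))
        for (s in .SIDES) for (lm in .LANDMARKS) {
            u <- kp[paste(s, lm, "x", sep = ".")]
            v <- kp[paste(s, lm, "y", sep = ".")]
            if (!is.na(u))
                anns[[length(anns) + 1L]] <- list(type = "point", label = lm,
                    side = s, x = 100 * unname(u), y = 100 * unname(v))
        }
        list(image = fn, width = ncol(img), height = nrow(img),
             annotations = anns)
    })
    jsonlite::write_json(recs, file.path(dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    invisible(dir)
}
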