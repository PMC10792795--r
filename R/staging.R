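#' @include AllClasses.R utils.R
NULL

#' Assign the periodontal stage for a PBL percentage
#'
#' Stage bands of the Classification of Periodontal and Peri-Implant
#' Diseases and Conditions: stage 1 for PBL below 15%, stage 2 for 15-33%
#' (both boundaries inclusive, forced by the strict inequalities of the
#' neighbouring bands), stage 3/4 (single category, token `"34"`) above 33%.
#'
#' @param pblPercent Numeric vector of PBL percentages in `[0, 100]`.
#' @return Character vector of stage tokens `"1"`, `"2"` or `"34"`.
#' @export
#' @examples
#' assignStage(c(10.58, 24.84, 46.66))  # "1" "2" "34"
#' assignStage(c(15, 33))               # both "2"
assignStage <- function(pblPercent) {
    p <- as.numeric(pblPercent)
    if (any(is.na(p) | p < 0 | p > 100))
        stop("PBL percentages must lie in [0, 100]")
    ifelse(p < 15, "1", ifelse(p <= 33, "2", "34"))
}

#' Compute root length, bone height, PBL and stage for one side
#'
#' Denormalizes the three landmark points by the image dimensions, draws the
#' two measurement lines — root length `A` from CEJ to apex and bone height
#' `B` from alveolar crest to apex, both Euclidean pixel lengths — and
#' computes `PBL% = 100 * (A - B) / A`, clamped to `[0, 100]` (a crest
#' predicted beyond the CEJ or the apex would otherwise leave the range).
#' The stage follows from [assignStage()].
#'
#' If any point is missing, or the root degenerates (`A` below 1 pixel), the
#' side is returned with `valid = FALSE` and no measurements.
#'
#' @param cej,crest,apex Normalized `(x, y)` ordered pairs.
#' @param imageDims `(width, height)` in pixels.
#' @param side Side label carried into the result.
#' @return One-row data.frame: `side`, `A_px`, `B_px`, `pbl_percent`,
#'   `stage`, `valid`.
#' @export
#' @examples
#' computeSideMeasurement(c(0, 0), c(0, 0.2), c(0, 1), c(50, 100))
computeSideMeasurement <- function(cej, crest, apex, imageDims,
                                   side = "mesial") {
    invalid <- data.frame(side = side, A_px = NA_real_, B_px = NA_real_,
                          pbl_percent = NA_real_, stage = NA_character_,
                          valid = FALSE)
    pts <- c(cej, crest, apex)
    if (length(pts) != 6L || any(is.na(pts))) return(invalid)
    scale <- as.numeric(imageDims)  # (width, height)
    cejPx <- cej * scale
    crestPx <- crest * scale
    apexPx <- apex * scale
    A <- sqrt(sum((cejPx - apexPx)^2))
    B <- sqrt(sum((crestPx - apexPx)^2))
    if (A < 1) return(invalid)
    pbl <- min(100, max(0, 100 * (A - B) / A))
    data.frame(side = side, A_px = A, B_px = B, pbl_percent = pbl,
               stage = assignStage(pbl), valid = TRUE)
}

#' Measure both sides of a molar from its keypoint vector
#'
#' Applies [computeSideMeasurement()] independently to the mesial and distal
#' landmark triplets of a keypoint vector. A degenerate or unlabelled side
#' yields `valid = FALSE` without affecting the other side.
#'
#' @param keypoints Keypoint 12-vector (`NA` allowed per side).
#' @param imageDims `(width, height)` in pixels.
#' @param molarId Identifier carried into the result rows.
#' @return Two-row data.frame: `molar_id`, `side`, `A_px`, `B_px`,
#'   `pbl_percent`, `stage`, `valid`.
#' @export
measureMolar <- function(keypoints, imageDims, molarId = "molar") {
    kp <- asKeypointVector(keypoints, partial = TRUE)
    rows <- lapply(.SIDES, function(s)
        computeSideMeasurement(
            cej = kp[paste0(s, c(".CEJ.x", ".CEJ.y"))],
            crest = kp[paste0(s, c(".crest.x", ".crest.y"))],
            apex = kp[paste0(s, c(".apex.x", ".apex.y"))],
            imageDims = imageDims, side = s))
    cbind(molar_id = molarId, do.call(rbind, rows))
}

#' Measure a list of molar crops
#'
#' Convenience wrapper: runs [measureMolar()] over each crop using its own
#' stored keypoints and image dimensions.
#'
#' @param molars List of [MolarCrop-class] objects.
#' @return data.frame with two rows per crop (see [measureMolar()]).
#' @export
measureCrops <- function(molars) {
    do.call(rbind, lapply(molars, function(m) {
        d <- dim(cropImage(m))
        measureMolar(keypoints(m), c(d[2], d[1]), molarId(m))
    }))
}
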