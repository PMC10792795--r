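## Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

clamp01 <- function(x) {
    y <- pmin(1, pmax(0, x))
    if (!is.null(dim(x))) dim(y) <- dim(x) else names(y) <- names(x)
    y
}

#' Coerce to a keypoint vector
#'
#' Validates and names a 12-value keypoint vector in the canonical slot order
#' (see [kpSlotNames()]). Accepts a bare numeric vector (assumed already in
#' canonical order) or a named vector in any order.
#'
#' @param x Numeric vector of length 12.
#' @param partial Logical; if `TRUE`, `NA` entries are allowed (used for
#'   partially labelled crops), otherwise all 12 values must be finite.
#' @return Named numeric vector of length 12 in canonical order.
#' @export
#' @examples
#' asKeypointVector(runif(12))
asKeypointVector <- function(x, partial = FALSE) {
    x <- as.numeric(unlist(x))
    if (length(x) != 12L)
        stop("a keypoint vector must have exactly 12 values")
    nm <- names(x)
    if (!is.null(nm) && all(.KP_SLOTS %in% nm)) x <- x[.KP_SLOTS]
    names(x) <- .KP_SLOTS
    if (!partial && any(!is.finite(x)))
        stop("keypoint vector contains missing values")
    bad <- !is.na(x) & (x < -1e-9 | x > 1 + 1e-9)
    if (any(bad))
        stop("keypoint coordinates must lie in [0, 1]")
    x
}

# Indices of the six slots belonging to one side.
sideSlots <- function(side) grep(paste0("^", side, "\\."), .KP_SLOTS)

# Keypoint matrix (n x 12) from a list of MolarCrop or a matrix.
keypointMatrix <- function(x) {
    if (is.matrix(x)) {
        stopifnot(ncol(x) == 12L)
        colnames(x) <- .KP_SLOTS
        return(x)
    }
    if (is.list(x) && length(x) && methods::is(x[[1]], "MolarCrop")) {
        m <- do.call(rbind, lapply(x, keypoints))
        colnames(m) <- .KP_SLOTS
        return(m)
    }
    stop("expected a numeric matrix or a list of MolarCrop objects")
}

# Read a grayscale image file into the package's matrix convention
# (rows = y, columns = x, intensities in [0, 1]).
readGrayImage <- function(path) {
    img <- EBImage::readImage(path)
    dat <- EBImage::imageData(img)
    if (length(dim(dat)) == 3L) dat <- dat[, , 1L]  # take first channel
    t(dat)  # EBImage stores (x, y); transpose to (y, x)
}

writeGrayImage <- function(image, path) {
    EBImage::writeImage(EBImage::Image(t(clamp01(image))), path)
    invisible(path)
}

# Bilinear resize to height x width via EBImage (which indexes (x, y)).
resizeImage <- function(image, height, width) {
    if (nrow(image) == height && ncol(image) == width) return(image)
    e <- EBImage::Image(t(image))
    t(EBImage::imageData(EBImage::resize(e, w = width, h = height)))
}
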