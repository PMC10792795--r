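#' @include AllClasses.R utils.R
NULL

#' Read an annotation export
#'
#' Parses a JSON annotation export into [RadiographAnnotation-class] objects.
#' The dialect is a list of per-image records:
#'
#' ```
#' [{"image": "SB001.png", "width": 2900, "height": 1400,
#'   "annotations": [
#'     {"type": "box",   "label": "molar", "jaw": "lower",
#'      "x": 10.0, "y": 40.0, "w": 5.0, "h": 10.0},
#'     {"type": "point", "label": "CEJ",   "side": "mesial",
#'      "x": 11.2, "y": 42.5}, ...]}]
#' ```
#'
#' with `x`, `y`, `w`, `h` expressed in percent of the image dimensions
#' (Label-Studio export semantics); they are converted to pixels on load.
#'
#' @param path Path to the JSON file.
#' @return List of [RadiographAnnotation-class] objects, one per image record.
#' @export
#' @seealso [extractCrops()], [writeDataset()] which emits this dialect.
readAnnotations <- function(path) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
        error = function(e) stop("failed to parse annotation export '", path,
                                 "': ", conditionMessage(e)))
    if (!is.list(recs)) stop("annotation export must be a JSON list")
    lapply(seq_along(recs), function(i) {
        r <- recs[[i]]
        where <- sprintf("record %d of '%s'", i, basename(path))
        for (f in c("image", "width", "height", "annotations"))
            if (is.null(r[[f]]))
                stop("missing field '", f, "' in ", where)
        W <- as.numeric(r$width); H <- as.numeric(r$height)
        boxes <- list(); points <- list()
        for (j in seq_along(r$annotations)) {
            a <- r$annotations[[j]]
            if (is.null(a$type))
                stop("annotation ", j, " without type in ", where)
            if (a$type == "box") {
                boxes[[length(boxes) + 1L]] <- data.frame(
                    x = as.numeric(a$x) / 100 * W,
                    y = as.numeric(a$y) / 100 * H,
                    w = as.numeric(a$w) / 100 * W,
                    h = as.numeric(a$h) / 100 * H,
                    jaw = if (is.null(a$jaw)) "lower" else as.character(a$jaw))
            } else if (a$type == "point") {
                lab <- as.character(a$label)
                if (!lab %in% .LANDMARKS)
                    stop("unknown landmark label '", lab, "' in ", where)
                if (is.null(a$side) || !a$side %in% .SIDES)
                    stop("point without valid side in ", where)
                points[[length(points) + 1L]] <- data.frame(
                    x = as.numeric(a$x) / 100 * W,
                    y = as.numeric(a$y) / 100 * H,
                    landmark = lab, side = as.character(a$side))
            } else {
                stop("unknown annotation type '", a$type, "' in ", where)
            }
        }
        RadiographAnnotation(
            imageId = sub("\\.[A-Za-z]+$", "", basename(as.character(r$image))),
            imagePath = as.character(r$image), width = W, height = H,
            boxes = if (length(boxes)) do.call(rbind, boxes) else
                data.frame(x = numeric(), y = numeric(), w = numeric(),
                           h = numeric(), jaw = character()),
            points = if (length(points)) do.call(rbind, points) else
                data.frame(x = numeric(), y = numeric(),
                           landmark = character(), side = character()))
    })
}

#' Extract molar crops from an annotated radiograph
#'
#' Cuts one [MolarCrop-class] per bounding box out of the radiograph. Each
#' landmark point falling inside a box is re-referenced to the box frame and
#' normalized by the box width and height. Points outside every box are
#' dropped with a warning. A side whose three landmarks (CEJ, crest, apex)
#' are not all present within the box is cleared entirely, enforcing the
#' labelling rule that PBL can only be measured when all three points of a
#' side are identifiable.
#'
#' @param annotation A [RadiographAnnotation-class].
#' @param image Optional numeric image matrix (rows = y); when `NULL` the
#'   image is read from the annotation's `imagePath`, resolved against
#'   `imagesDir`.
#' @param imagesDir Directory to resolve `imagePath` against.
#' @return List of unoriented [MolarCrop-class] objects, one per box.
#' @export
extractCrops <- function(annotation, image = NULL, imagesDir = ".") {
    stopifnot(methods::is(annotation, "RadiographAnnotation"))
    if (is.null(image))
        image <- readGrayImage(file.path(imagesDir, annotation@imagePath))
    boxes <- annotation@boxes
    pts <- annotation@points
    crops <- list()
    inAny <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(boxes))) {
        b <- boxes[i, ]
        if (b$w <= 0 || b$h <= 0) {
            warning(sprintf("box %d of '%s' has zero area; skipped",
                            i, annotation@imageId))
            next
        }
        rows <- max(1L, floor(b$y) + 1L):min(nrow(image), ceiling(b$y + b$h))
        cols <- max(1L, floor(b$x) + 1L):min(ncol(image), ceiling(b$x + b$w))
        kp <- stats::setNames(rep(NA_real_, 12L), .KP_SLOTS)
        if (nrow(pts)) {
            inside <- pts$x >= b$x - 1e-9 & pts$x <= b$x + b$w + 1e-9 &
                      pts$y >= b$y - 1e-9 & pts$y <= b$y + b$h + 1e-9
            inAny <- inAny | inside
            for (j in which(inside)) {
                slot <- paste(pts$side[j], pts$landmark[j], sep = ".")
                kp[paste0(slot, ".x")] <- (pts$x[j] - b$x) / b$w
                kp[paste0(slot, ".y")] <- (pts$y[j] - b$y) / b$h
            }
        }
        # all-three rule: clear any partially labelled side
        for (side in .SIDES) {
            sl <- sideSlots(side)
            if (any(is.na(kp[sl])) && !all(is.na(kp[sl]))) {
                warning(sprintf(
                    "'%s' box %d: %s side lacks one of CEJ/crest/apex; side cleared",
                    annotation@imageId, i, side))
                kp[sl] <- NA_real_
            }
        }
        crops[[length(crops) + 1L]] <- MolarCrop(
            molarId = sprintf("%s_m%02d", annotation@imageId, i),
            image = image[rows, cols, drop = FALSE],
            keypoints = clamp01(kp), jaw = b$jaw, oriented = FALSE)
    }
    if (any(!inAny))
        warning(sprintf("'%s': %d point(s) outside every box were dropped",
                        annotation@imageId, sum(!inAny)))
    crops
}

#' Orient a molar crop apex-down
#'
#' Upper-jaw crops are rotated by 180 degrees — image reversed along both
#' axes and each normalized keypoint `(u, v)` mapped to `(1 - u, 1 - v)` — so
#' that every crop presents its root apices in the lower portion of the
#' image, the convention the refiner is trained under. Lower-jaw crops are
#' returned unchanged apart from the `oriented` flag.
#'
#' @param molar An unoriented [MolarCrop-class].
#' @return The oriented [MolarCrop-class]; for each labelled side the apex
#'   y-coordinate is then at least the CEJ y-coordinate.
#' @export
orientMolar <- function(molar) {
    stopifnot(methods::is(molar, "MolarCrop"))
    if (isOriented(molar)) stop("molar '", molarId(molar), "' is already oriented")
    img <- molar@image
    kp <- molar@keypoints
    if (jaw(molar) == "upper") {
        img <- img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))), drop = FALSE]
        kp <- 1 - kp
        names(kp) <- .KP_SLOTS
    }
    methods::initialize(molar, image = img, keypoints = kp, oriented = TRUE)
}

#' Split molar crops into train / validation / test partitions
#'
#' Samples exactly `testN` crops uniformly at random (without replacement)
#' for the test partition and strips their keypoints, mirroring the study
#' protocol in which the test images had their labelled PBL points removed.
#' The remainder is shuffled and divided into `floor(trainFrac * n)` training
#' crops, with the rest forming the internal validation partition. The same
#' seed always yields the same membership.
#'
#' With 2010 crops, `testN = 40` and `trainFrac = 0.8` this produces the
#' 1576 / 394 / 40 partition sizes of the study design.
#'
#' @param molars List of [MolarCrop-class] objects.
#' @param testN Number of test crops.
#' @param trainFrac Training fraction of the non-test remainder, in (0, 1).
#' @param seed Integer seed.
#' @return Named list with elements `train`, `validation`, `test`.
#' @export
splitDataset <- function(molars, testN = 40L, trainFrac = 0.8, seed = 1L) {
    n <- length(molars)
    if (testN >= n)
        stop("testN (", testN, ") must be smaller than the number of crops (", n, ")")
    if (trainFrac <= 0 || trainFrac >= 1)
        stop("trainFrac must lie strictly between 0 and 1")
    perm <- withSeed(seed, sample.int(n))
    test <- lapply(molars[perm[seq_len(testN)]], function(m)
        methods::initialize(m, keypoints = stats::setNames(rep(NA_real_, 12L),
                                                           .KP_SLOTS)))
    rest <- perm[-seq_len(testN)]
    nTrainCrops <- floor(trainFrac * length(rest))
    list(train = molars[rest[seq_len(nTrainCrops)]],
         validation = molars[rest[-seq_len(nTrainCrops)]],
         test = test)
}
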