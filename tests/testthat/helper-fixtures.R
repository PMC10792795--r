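# Shared fixtures, all built in code.

# A minimal annotation export: one radiograph, two molar boxes (one upper,
# one lower), six points per box in percent-of-image coordinates.
writeTinyExport <- function(path = tempfile(fileext = ".json")) {
    pctPoint <- function(label, side, x, y)
        list(type = "point", label = label, side = side, x = x, y = y)
    boxA <- list(type = "box", label = "molar", jaw = "lower",
                 x = 10, y = 40, w = 10, h = 30)
    boxB <- list(type = "box", label = "molar", jaw = "upper",
                 x = 60, y = 10, w = 10, h = 30)
    ptsA <- list(
        pctPoint("CEJ", "mesial", 12, 45), pctPoint("crest", "mesial", 12.5, 48),
        pctPoint("apex", "mesial", 13, 65), pctPoint("CEJ", "distal", 18, 45),
        pctPoint("crest", "distal", 17.5, 48), pctPoint("apex", "distal", 17, 65))
    ptsB <- list(
        pctPoint("CEJ", "mesial", 62, 32), pctPoint("crest", "mesial", 62.5, 30),
        pctPoint("apex", "mesial", 63, 15), pctPoint("CEJ", "distal", 68, 32),
        pctPoint("crest", "distal", 67.5, 30), pctPoint("apex", "distal", 67, 15))
    rec <- list(list(image = "SB001.png", width = 200, height = 100,
                     annotations = c(list(boxA), ptsA, list(boxB), ptsB)))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    path
}

# A fully labelled crop with a trivial image, cheap enough to make by the
# thousand for split/augmentation tests.
fakeCrop <- function(id, jaw = "lower", oriented = TRUE) {
    kp <- stats::setNames(c(0.2, 0.3, 0.25, 0.4, 0.3, 0.8,
                            0.8, 0.3, 0.75, 0.4, 0.7, 0.8), kpSlotNames())
    MolarCrop(molarId = id, image = matrix(0.5, 4, 3), keypoints = kp,
              jaw = jaw, oriented = oriented)
}

# Quiet generator settings shared by several suites.
cleanParams <- function(...) synthParams(noiseSd = 0, blurSigma = 0,
                                         contrastJitter = 0, ...)
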