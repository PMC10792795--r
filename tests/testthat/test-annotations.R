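test_that("annotation exports parse with percent-to-pixel conversion", {
    path <- writeTinyExport()
    anns <- readAnnotations(path)
    expect_length(anns, 1L)
    a <- anns[[1]]
    expect_equal(a@imageId, "SB001")
    expect_equal(nrow(a@boxes), 2L)
    expect_equal(nrow(a@points), 12L)
    # percent coordinates scaled by the 200 x 100 image
    expect_equal(a@boxes$x[1], 20)
    expect_equal(a@boxes$h[1], 30)
    expect_equal(a@points$x[1], 24)
    expect_equal(a@points$y[1], 45)
})

test_that("empty exports and malformed records are handled", {
    empty <- tempfile(fileext = ".json")
    writeLines("[]", empty)
    expect_identical(readAnnotations(empty), list())

    bad <- tempfile(fileext = ".json")
    jsonlite::write_json(list(list(image = "x.png", width = 10, height = 10,
        annotations = list(list(type = "point", label = "root",
                                side = "mesial", x = 5, y = 5)))),
        bad, auto_unbox = TRUE)
    expect_error(readAnnotations(bad), "unknown landmark")

    expect_error(readAnnotations(tempfile()), "not found")
})

test_that("crop extraction normalizes points to the box frame", {
    ann <- RadiographAnnotation("im", "", width = 200, height = 100,
        boxes = data.frame(x = 40, y = 60, w = 20, h = 40, jaw = "lower"),
        points = data.frame(
            x = c(50, 52, 54, 44, 46, 48),
            y = c(80, 82, 96, 80, 82, 96),
            landmark = rep(c("CEJ", "crest", "apex"), 2),
            side = rep(c("distal", "mesial"), each = 3)))
    crops <- extractCrops(ann, image = matrix(0, 100, 200))
    expect_length(crops, 1L)
    kp <- keypoints(crops[[1]])
    expect_equal(unname(kp["distal.CEJ.x"]), 0.5)
    expect_equal(unname(kp["distal.CEJ.y"]), 0.5)
    expect_false(anyNA(kp))
    expect_equal(dim(cropImage(crops[[1]])), c(40, 20))
})

test_that("a side lacking one of its three landmarks is cleared entirely", {
    ann <- RadiographAnnotation("im", "", width = 100, height = 100,
        boxes = data.frame(x = 0, y = 0, w = 100, h = 100, jaw = "lower"),
        points = data.frame(x = c(10, 20), y = c(10, 80),
                            landmark = c("CEJ", "apex"),
                            side = c("mesial", "mesial")))
    expect_warning(crops <- extractCrops(ann, image = matrix(0, 100, 100)),
                   "side cleared")
    expect_true(all(is.na(keypoints(crops[[1]]))))
})

test_that("zero-area boxes are skipped and stray points warned about", {
    ann <- RadiographAnnotation("im", "", width = 100, height = 100,
        boxes = data.frame(x = c(0, 50), y = c(0, 50), w = c(0, 20),
                           h = c(10, 20), jaw = "lower"),
        points = data.frame(x = 30, y = 30, landmark = "CEJ",
                            side = "mesial"))
    warns <- capture_warnings(crops <- extractCrops(ann, image = matrix(0, 100, 100)))
    expect_length(crops, 1L)
    expect_true(any(grepl("zero area", warns)))
    expect_true(any(grepl("outside every box", warns)))
})

test_that("orientation flips upper crops by 180 degrees and is involutive", {
    kp <- stats::setNames(rep(NA_real_, 12), kpSlotNames())
    kp[sideSlots <- grep("^mesial", kpSlotNames())] <-
        c(0.3, 0.2, 0.32, 0.25, 0.35, 0.7)
    # upper-jaw labelling: apex above CEJ in the as-stored frame
    kpUp <- 1 - kp
    names(kpUp) <- kpSlotNames()
    img <- matrix(seq_len(12) / 12, 4, 3)
    up <- MolarCrop("u1", img, kpUp, jaw = "upper")
    o <- orientMolar(up)
    expect_true(isOriented(o))
    expect_equal(unname(keypoints(o)["mesial.CEJ.x"]), 0.3)
    expect_equal(unname(keypoints(o)["mesial.CEJ.y"]), 0.2)
    expect_equal(cropImage(o), img[4:1, 3:1])
    # the 180-degree map applied twice is the identity
    expect_equal(1 - (1 - kpUp), kpUp)

    low <- MolarCrop("l1", img, kp, jaw = "lower")
    ol <- orientMolar(low)
    expect_identical(keypoints(ol), kp)
    expect_identical(cropImage(ol), img)
    expect_true(isOriented(ol))
    expect_error(orientMolar(ol), "already oriented")
})

test_that("oriented crops satisfy the apex-below-CEJ invariant on a corpus", {
    ds <- generateDataset(synthParams(seed = 21L), 40)
    for (crop in ds$crops) {
        o <- orientMolar(crop)
        kp <- keypoints(o)
        for (s in c("mesial", "distal"))
            expect_gte(kp[paste0(s, ".apex.y")], kp[paste0(s, ".CEJ.y")])
    }
})

test_that("dataset splitting reproduces the study partition sizes", {
    crops <- lapply(sprintf("c%04d", 1:2010), fakeCrop)
    parts <- splitDataset(crops, testN = 40, trainFrac = 0.8, seed = 3)
    expect_length(parts$train, 1576L)
    expect_length(parts$validation, 394L)
    expect_length(parts$test, 40L)
    # test crops have their labels removed
    expect_true(all(vapply(parts$test, function(m) all(is.na(keypoints(m))),
                           logical(1))))
    # partitions are disjoint and exhaustive by molar id
    ids <- lapply(parts, function(p) vapply(p, molarId, character(1)))
    expect_length(unique(unlist(ids)), 2010L)
    expect_length(intersect(ids$train, ids$test), 0L)
    expect_length(intersect(ids$train, ids$validation), 0L)
})

test_that("splitting is deterministic in the seed and rejects bad sizes", {
    crops <- lapply(sprintf("c%03d", 1:50), fakeCrop)
    p1 <- splitDataset(crops, testN = 10, seed = 9)
    p2 <- splitDataset(crops, testN = 10, seed = 9)
    for (part in names(p1))
        expect_identical(vapply(p1[[part]], molarId, character(1)),
                         vapply(p2[[part]], molarId, character(1)))
    expect_error(splitDataset(crops[1:10], testN = 10), "smaller")
    expect_error(splitDataset(crops, testN = 5, trainFrac = 1.2), "strictly")
})
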