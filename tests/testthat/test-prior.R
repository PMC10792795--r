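test_that("a normal coordinate is recovered with its closed-form MLE", {
    set.seed(13)
    kp <- matrix(runif(2000 * 12, 0.2, 0.8), 2000, 12)
    x <- pmin(pmax(rnorm(2000, 0.5, 0.05), 0), 1)
    kp[, 3] <- x
    # candidates restricted to families that are not mutual mimics of the
    # normal (a symmetric beta or a large-shape gamma fits normal data
    # essentially as well, making the family label unidentifiable)
    prior <- fitPrior(kp, candidates = c("norm", "lnorm", "unif"))
    f <- priorFits(prior)[[3]]
    expect_identical(f$family, "norm")
    # maximum-likelihood estimates: sample mean and sqrt(biased variance)
    expect_equal(unname(f$params[["mean"]]), mean(x), tolerance = 1e-6)
    expect_equal(unname(f$params[["sd"]]),
                 sqrt(mean((x - mean(x))^2)), tolerance = 1e-3)
    expect_lt(abs(f$params[["mean"]] - 0.5), 0.02)
    expect_lt(abs(f$params[["sd"]] - 0.05), 0.01)
    expect_equal(nTrain(prior), 2000L)
    expect_length(priorFits(prior), 12L)
})

test_that("the selected family minimizes the histogram criterion", {
    set.seed(19)
    kp <- matrix(rbeta(500 * 12, 4, 2), 500, 12)
    cand <- c("norm", "beta", "logis", "unif")
    prior <- fitPrior(kp, candidates = cand)
    for (slot in c(1L, 7L)) {
        best <- priorFits(prior)[[slot]]
        for (fam in cand) {
            single <- priorFits(fitPrior(kp, candidates = fam))[[slot]]
            expect_gte(single$fitError, best$fitError)
        }
    }
})

test_that("degenerate zero-variance slots become point masses", {
    kp <- matrix(runif(50 * 12, 0.3, 0.7), 50, 12)
    kp[, 5] <- 0.42
    prior <- fitPrior(kp)
    f <- priorFits(prior)[[5]]
    expect_identical(f$family, "pointmass")
    expect_equal(f$fitError, 0)
    s <- samplePrior(prior, 30, seed = 1)
    expect_true(all(s[, 5] == 0.42))
})

test_that("prior fitting rejects undersized or invalid input", {
    kp <- matrix(runif(29 * 12), 29, 12)
    expect_error(fitPrior(kp), "at least 30")
    expect_error(fitPrior(matrix(runif(40 * 12), 40, 12),
                          candidates = character()), "empty")
    expect_error(fitPrior(matrix(runif(40 * 12), 40, 12),
                          candidates = "cauchy"), "unknown")
    kpNA <- matrix(runif(40 * 12), 40, 12)
    kpNA[1, 1] <- NA
    expect_error(fitPrior(kpNA), "fully labelled")
})

test_that("prior samples respect the unit square and the seed contract", {
    set.seed(3)
    kp <- matrix(pmin(pmax(rnorm(200 * 12, 0.5, 0.3), 0), 1), 200, 12)
    prior <- fitPrior(kp)
    s <- samplePrior(prior, 25, seed = 7)
    expect_equal(dim(s), c(25L, 12L))
    expect_true(all(s >= 0 & s <= 1))
    expect_identical(s, samplePrior(prior, 25, seed = 7))
    expect_false(identical(s, samplePrior(prior, 25, seed = 8)))
})

test_that("sampling a fitted normal slot obeys the law of large numbers", {
    set.seed(13)
    kp <- matrix(runif(2000 * 12, 0.2, 0.8), 2000, 12)
    kp[, 3] <- pmin(pmax(rnorm(2000, 0.5, 0.05), 0), 1)
    prior <- fitPrior(kp, candidates = c("norm", "lnorm", "unif"))
    s <- samplePrior(prior, 1e4, seed = 5)
    expect_equal(mean(s[, 3]), 0.5, tolerance = 0.01)
})

test_that("augmentation emits k triples per image deterministically", {
    crops <- lapply(sprintf("m%03d", 1:402), fakeCrop)
    prior <- fitPrior(crops[1:60])
    triples <- augmentTrainingSet(crops, prior, k = 25, seed = 2)
    expect_length(triples, 10050L)
    expect_length(augmentTrainingSet(crops, prior, k = 1, seed = 2), 402L)
    t2 <- augmentTrainingSet(crops, prior, k = 25, seed = 2)
    expect_identical(lapply(triples, `[[`, "prior"),
                     lapply(t2, `[[`, "prior"))
    expect_error(augmentTrainingSet(list(), prior, k = 1), "empty")
})

test_that("unlabelled sides are filled from the prior and masked", {
    half <- fakeCrop("h1")
    kp <- keypoints(half)
    kp[grep("^distal", names(kp))] <- NA
    half <- MolarCrop("h1", cropImage(half), kp, jaw = "lower", oriented = TRUE)
    prior <- fitPrior(lapply(sprintf("m%03d", 1:40), fakeCrop))
    tr <- augmentTrainingSet(list(half), prior, k = 3, seed = 4)
    for (t in tr) {
        expect_identical(unname(t$mask), rep(c(TRUE, FALSE), each = 6))
        expect_equal(t$truth[7:12], t$prior[7:12])
        expect_false(anyNA(t$truth))
    }
})

test_that("prior models survive a JSON round trip", {
    set.seed(8)
    kp <- matrix(pmin(pmax(rnorm(100 * 12, 0.5, 0.2), 0), 1), 100, 12)
    kp[, 2] <- 0.5
    prior <- fitPrior(kp)
    path <- tempfile(fileext = ".json")
    writePrior(prior, path)
    back <- readPrior(path)
    expect_equal(nTrain(back), nTrain(prior))
    for (i in 1:12) {
        expect_identical(priorFits(back)[[i]]$family, priorFits(prior)[[i]]$family)
        expect_equal(priorFits(back)[[i]]$params, priorFits(prior)[[i]]$params)
    }
    expect_equal(samplePrior(back, 10, seed = 1),
                 samplePrior(prior, 10, seed = 1))
})
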