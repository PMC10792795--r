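test_that("one-vs-rest binarization assigns the documented index patterns", {
    expect_identical(binarizeStage("1", "1"),
                     c(`1` = "TP", `2` = "TN", `34` = "TN"))
    expect_identical(binarizeStage("2", "1"),
                     c(`1` = "FP", `2` = "FN", `34` = "TN"))
    expect_identical(binarizeStage("34", "34"),
                     c(`1` = "TN", `2` = "TN", `34` = "TP"))
    expect_error(binarizeStage("3", "1"), "invalid stage")
})

test_that("metrics follow their defining ratios with the 0/0-as-0 convention", {
    m <- metricsFromCounts(c(TP = 3, TN = 30, FP = 5, FN = 2))
    expect_equal(m[["sensitivity"]], 3 / 5)
    expect_equal(m[["specificity"]], 30 / 35)
    expect_equal(m[["precision"]], 3 / 8)
    expect_equal(m[["accuracy_recall"]], 33 / 40)
    expect_equal(m[["f1"]], 2 * (3 / 5) * (3 / 8) / (3 / 5 + 3 / 8))

    # a rater who never uses the class: TP = FP = 0 -> precision and F1 are 0
    z <- metricsFromCounts(c(TP = 0, TN = 35, FP = 0, FN = 5))
    expect_equal(z[["precision"]], 0)
    expect_equal(z[["f1"]], 0)

    # perfect classifier
    p <- metricsFromCounts(c(TP = 10, TN = 30, FP = 0, FN = 0))
    expect_true(all(p == 1))

    expect_error(metricsFromCounts(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("macro, weighted and micro averages reduce correctly", {
    perStage <- rbind(`1` = c(1, 0.5, 0.8, 0.9, 0.6),
                      `2` = c(0.4, 0.7, 0.2, 0.5, 0.3),
                      `34` = c(0.1, 0.9, 0.5, 0.7, 0.15))
    colnames(perStage) <- c("sensitivity", "specificity", "precision",
                            "accuracy_recall", "f1")
    pooled <- matrix(c(10, 20, 5, 5, 8, 25, 2, 5, 1, 35, 1, 3), 3, 4,
                     byrow = TRUE,
                     dimnames = list(c("1", "2", "34"),
                                     c("TP", "TN", "FP", "FN")))
    avg <- averageMetrics(perStage, c(`1` = 15, `2` = 13, `34` = 4), pooled)
    expect_equal(unname(avg$macro), unname(colMeans(perStage)))
    w <- c(15, 13, 4) / 32
    expect_equal(unname(avg$weighted), unname(as.numeric(w %*% perStage)))
    expect_equal(avg$micro[["sensitivity"]], 19 / 32)

    # all support on one stage: weighted collapses to that stage's row
    one <- averageMetrics(perStage, c(`1` = 0, `2` = 9, `34` = 0), pooled)
    expect_equal(unname(one$weighted), unname(perStage["2", ]))
    expect_error(averageMetrics(perStage, c(`1` = 0, `2` = 0, `34` = 0), pooled),
                 "zero")
})

test_that("evaluateRater produces the full table and warns about misses", {
    set.seed(41)
    truth <- data.frame(item_id = rep(sprintf("q%02d", 1:42), each = 2),
                        side = rep(c("mesial", "distal"), 42),
                        stage = sample(rep(c("1", "2", "34"), c(48, 30, 6))))
    perfect <- evaluateRater(truth, truth)
    expect_s4_class(perfect, "MetricsTable")
    expect_true(all(stageMetrics(perfect)$sensitivity == 1))
    expect_equal(unname(stageSupports(perfect)), c(48L, 30L, 6L))
    # the study's class mix: supports at 57.14% / 35.71% / 7.14%
    expect_equal(unname(stageSupports(perfect)) / 84,
                 c(0.5714, 0.3571, 0.0714), tolerance = 1e-3)

    # a rater answering stage 1 throughout: blind to stage 3/4 positives but
    # never falsely alarms on them
    always1 <- truth
    always1$stage <- "1"
    m <- evaluateRater(always1, truth)
    expect_equal(stageMetrics(m)["34", "sensitivity"], 0)
    expect_equal(stageMetrics(m)["34", "specificity"], 1)

    # missing items are dropped with a warning; empty intersection errors
    expect_warning(evaluateRater(truth[-(1:4), ], truth), "dropped")
    other <- truth
    other$item_id <- paste0("z", other$item_id)
    expect_error(evaluateRater(other, truth), "no items")
})

test_that("pooled indices cover each item once and micro equals accuracy", {
    set.seed(17)
    for (rep in 1:5) {
        n <- sample(30:80, 1)
        truth <- data.frame(item_id = sprintf("i%03d", 1:n), side = "mesial",
                            stage = sample(c("1", "2", "34"), n, replace = TRUE,
                                           prob = c(0.5, 0.35, 0.15)))
        ans <- truth
        ans$stage <- sample(c("1", "2", "34"), n, replace = TRUE)
        m <- evaluateRater(ans, truth)
        counts <- stageCounts(m)
        # exactly one stage takes TP or FN per item
        expect_equal(sum(counts[, "TP"] + counts[, "FN"]), n)
        expect_true(all(rowSums(counts) == n))
        expect_equal(microMetrics(m)[["sensitivity"]],
                     mean(ans$stage == truth$stage))
    }
})

test_that("ICC recovers agreement structure", {
    set.seed(23)
    subj <- rnorm(100, 0, 2)
    expect_equal(iccAgreement(subj, subj), 1)
    # systematic rater offset lowers absolute agreement below consistency
    shifted <- iccAgreement(subj, subj + 2)
    expect_lt(shifted, 1)
    expect_gt(shifted, 0.5)
    expect_error(iccAgreement(rep(1, 10), rep(1, 10)), "undefined")
    expect_error(iccAgreement(1:2, 1:2), "at least 3")
    expect_error(iccAgreement(1:5, 1:4), "length")
})

test_that("null ratings give near-zero ICC", {
    set.seed(29)
    vals <- replicate(3, iccAgreement(rnorm(500), rnorm(500)))
    expect_true(all(abs(vals) < 0.1))
})
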