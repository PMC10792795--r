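#' @include AllClasses.R utils.R
NULL

.checkStage <- function(x, what) {
    x <- as.character(x)
    bad <- !x %in% .STAGES
    if (any(bad))
        stop(what, " contains invalid stage token(s): ",
             paste(unique(x[bad]), collapse = ", "),
             " (expected '1', '2' or '34')")
    x
}

#' One-vs-rest binarization of a staged answer
#'
#' Treats each of the three possible stage answers as a separate binary
#' test: for stage `s` the item counts as TP if both truth and answer equal
#' `s`, FN if only the truth does, FP if only the answer does, and TN
#' otherwise — so exactly one stage receives TP or FN per item.
#'
#' @param truth,answer Stage tokens (`"1"`, `"2"` or `"34"`).
#' @return Named character vector over stages with values `"TP"`, `"TN"`,
#'   `"FP"` or `"FN"`.
#' @export
#' @examples
#' binarizeStage("1", "1")   # stage 1 TP, stages 2 and 3/4 TN
#' binarizeStage("2", "1")   # stage 2 FN, stage 1 FP, stage 3/4 TN
binarizeStage <- function(truth, answer) {
    truth <- .checkStage(truth, "truth")
    answer <- .checkStage(answer, "answer")
    stopifnot(length(truth) == 1L, length(answer) == 1L)
    out <- vapply(.STAGES, function(s) {
        if (truth == s) {
            if (answer == s) "TP" else "FN"
        } else {
            if (answer == s) "FP" else "TN"
        }
    }, character(1))
    out
}

# Pooled one-vs-rest counts over item vectors: 3 x 4 matrix.
.confusionCounts <- function(truths, answers) {
    truths <- .checkStage(truths, "truth")
    answers <- .checkStage(answers, "answer")
    stopifnot(length(truths) == length(answers))
    counts <- matrix(0L, 3L, 4L,
                     dimnames = list(.STAGES, c("TP", "TN", "FP", "FN")))
    for (s in .STAGES) {
        counts[s, "TP"] <- sum(truths == s & answers == s)
        counts[s, "FN"] <- sum(truths == s & answers != s)
        counts[s, "FP"] <- sum(truths != s & answers == s)
        counts[s, "TN"] <- sum(truths != s & answers != s)
    }
    counts
}

.METRIC_NAMES <- c("sensitivity", "specificity", "precision",
                   "accuracy_recall", "f1")

#' Per-stage metrics from diagnostic counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, the joint positive-and-negative success rate
#' `(TP+TN)/total` (reported in the source tables as "recall", hence named
#' `accuracy_recall` here to avoid collision with the conventional
#' recall = sensitivity), and the F1 score as the harmonic mean of
#' sensitivity and precision. Any 0/0 ratio is defined as 0, matching the
#' printed `0.000` convention for raters who never used a class.
#'
#' @param counts Named numeric vector (or 1-row slice) with elements `TP`,
#'   `TN`, `FP`, `FN`.
#' @return Named numeric vector of the five metrics.
#' @export
#' @examples
#' metricsFromCounts(c(TP = 3, TN = 30, FP = 5, FN = 2))
metricsFromCounts <- function(counts) {
    counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
    if (any(is.na(counts) | counts < 0))
        stop("counts must contain non-negative TP, TN, FP, FN")
    total <- sum(counts)
    if (total == 0) stop("total count is zero")
    sdiv <- function(a, b) if (b == 0) 0 else a / b
    sens <- sdiv(counts[["TP"]], counts[["TP"]] + counts[["FN"]])
    spec <- sdiv(counts[["TN"]], counts[["TN"]] + counts[["FP"]])
    prec <- sdiv(counts[["TP"]], counts[["TP"]] + counts[["FP"]])
    acc <- (counts[["TP"]] + counts[["TN"]]) / total
    f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
    stats::setNames(c(sens, spec, prec, acc, f1), .METRIC_NAMES)
}

#' Macro, weighted and micro metric averages
#'
#' Aggregates per-stage metrics: the macro average is the unweighted mean
#' over stages; the weighted average weights each stage by its true-class
#' support proportion; the micro average applies [metricsFromCounts()] to
#' the counts pooled (summed) across stages and reports sensitivity,
#' precision and F1 — its sensitivity equals plain multiclass accuracy.
#'
#' @param perStage Numeric matrix or data.frame, one row per stage in order
#'   `"1", "2", "34"`, columns the five metrics of [metricsFromCounts()].
#' @param supports Named numeric vector of true-class counts per stage.
#' @param pooled 3x4 count matrix as rows of `TP`, `TN`, `FP`, `FN`.
#' @return List with `macro`, `weighted` (five metrics each) and `micro`
#'   (`sensitivity`, `precision`, `f1`).
#' @export
averageMetrics <- function(perStage, supports, pooled) {
    perStage <- as.matrix(perStage)
    stopifnot(nrow(perStage) == 3L, ncol(perStage) == 5L)
    supports <- unlist(supports)[.STAGES]
    if (any(is.na(supports)))
        stop("supports must be named over all three stages")
    if (sum(supports) == 0) stop("total support is zero")
    w <- supports / sum(supports)
    macro <- stats::setNames(colMeans(perStage), .METRIC_NAMES)
    weighted <- stats::setNames(as.numeric(w %*% perStage), .METRIC_NAMES)
    micro <- metricsFromCounts(colSums(pooled))[c("sensitivity", "precision", "f1")]
    list(macro = macro, weighted = weighted, micro = micro)
}

#' Evaluate a rater's answer sheet against a truth sheet
#'
#' Joins the two sheets on `(item_id, side)`, binarizes every item
#' one-vs-rest, and produces the full [MetricsTable-class]: per-stage
#' diagnostic counts and metrics plus macro, weighted and micro averages.
#' Items present in only one sheet are dropped with a warning.
#'
#' @param answers,truth data.frames with columns `item_id`, `side` and
#'   `stage` (a `pbl_percent` column may be present and is ignored here).
#' @return A [MetricsTable-class].
#' @export
evaluateRater <- function(answers, truth) {
    need <- c("item_id", "side", "stage")
    stopifnot(all(need %in% names(answers)), all(need %in% names(truth)))
    ka <- paste(answers$item_id, answers$side)
    kt <- paste(truth$item_id, truth$side)
    common <- intersect(ka, kt)
    if (!length(common))
        stop("the answer and truth sheets share no items")
    dropped <- (length(ka) - length(common)) + (length(kt) - length(common))
    if (dropped > 0)
        warning(dropped, " item(s) missing from one of the sheets were dropped")
    a <- .checkStage(answers$stage[match(common, ka)], "answer")
    t <- .checkStage(truth$stage[match(common, kt)], "truth")
    counts <- .confusionCounts(t, a)
    perStage <- t(apply(counts, 1L, metricsFromCounts))
    colnames(perStage) <- .METRIC_NAMES
    supports <- stats::setNames(
        vapply(.STAGES, function(s) sum(t == s), integer(1)), .STAGES)
    avg <- averageMetrics(perStage, supports, counts)
    new("MetricsTable",
        perStage = as.data.frame(perStage), macro = avg$macro,
        weighted = avg$weighted, micro = avg$micro,
        supports = supports, counts = counts, nItems = length(common))
}

#' Write a metrics report
#'
#' Serializes a [MetricsTable-class] as two CSV files mirroring the
#' per-stage and averages table layout: `metrics_per_stage.csv` and
#' `metrics_averages.csv`.
#'
#' @param metrics A [MetricsTable-class].
#' @param dir Output directory (created if needed).
#' @param digits Decimal places for display rounding (half-up), default 3.
#' @return `dir`, invisibly.
#' @export
writeMetricsReport <- function(metrics, dir, digits = 3L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rnd <- function(x) floor(x * 10^digits + 0.5) / 10^digits  # half-up
    per <- cbind(stage = rownames(metrics@perStage),
                 as.data.frame(lapply(metrics@perStage, rnd)),
                 support = as.integer(metrics@supports))
    utils::write.csv(per, file.path(dir, "metrics_per_stage.csv"),
                     row.names = FALSE)
    avg <- rbind(
        data.frame(average = "macro", t(rnd(metrics@macro))),
        data.frame(average = "weighted", t(rnd(metrics@weighted))),
        data.frame(average = "micro",
                   sensitivity = rnd(metrics@micro[["sensitivity"]]),
                   specificity = NA, precision = rnd(metrics@micro[["precision"]]),
                   accuracy_recall = NA, f1 = rnd(metrics@micro[["f1"]])))
    utils::write.csv(avg, file.path(dir, "metrics_averages.csv"),
                     row.names = FALSE)
    invisible(dir)
}

#' Two-way intraclass correlation (absolute agreement, single rater)
#'
#' Computes the ICC of two repeated measurement series under the two-way
#' random-effects, absolute-agreement, single-rater model (ICC(A,1) in the
#' Shrout-Fleiss/McGraw-Wong taxonomy), from the two-way ANOVA mean squares:
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#'
#' with `k = 2` raters/occasions and `n` subjects. This is the standard
#' calibration statistic for intra-rater agreement of repeated labelling.
#'
#' @param ratingsA,ratingsB Numeric vectors of equal length (>= 3), one
#'   value per subject and occasion.
#' @return Single numeric ICC in `(-1, 1]`.
#' @export
#' @examples
#' x <- rnorm(50)
#' iccAgreement(x, x)  # exactly 1
iccAgreement <- function(ratingsA, ratingsB) {
    a <- as.numeric(ratingsA)
    b <- as.numeric(ratingsB)
    if (length(a) != length(b)) stop("rating series differ in length")
    n <- length(a)
    if (n < 3L) stop("ICC needs at least 3 subjects")
    if (any(is.na(a)) || any(is.na(b))) stop("ratings contain missing values")
    Y <- cbind(a, b)
    k <- 2L
    grand <- mean(Y)
    rowM <- rowMeans(Y)
    colM <- colMeans(Y)
    if (stats::var(rowM) < 1e-24)
        stop("between-subject variance is zero; the ICC is undefined")
    MSR <- k * sum((rowM - grand)^2) / (n - 1)
    MSC <- n * sum((colM - grand)^2) / (k - 1)
    MSE <- sum((Y - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2) / ((n - 1) * (k - 1))
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}
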