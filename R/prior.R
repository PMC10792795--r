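#' @include AllClasses.R utils.R
NULL

.PRIOR_FAMILIES <- c("norm", "lnorm", "beta", "gamma", "unif", "logis")

# Density of a fitted family at q.
.familyDensity <- function(family, params, q) {
    switch(family,
        norm  = stats::dnorm(q, params[["mean"]], params[["sd"]]),
        lnorm = stats::dlnorm(q, params[["meanlog"]], params[["sdlog"]]),
        beta  = stats::dbeta(q, params[["shape1"]], params[["shape2"]]),
        gamma = stats::dgamma(q, params[["shape"]], params[["rate"]]),
        unif  = stats::dunif(q, params[["min"]], params[["max"]]),
        logis = stats::dlogis(q, params[["location"]], params[["scale"]]),
        stop("unknown family '", family, "'"))
}

# Random draws from a fitted family (consumes the caller's RNG stream).
.familySample <- function(family, params, n) {
    switch(family,
        norm  = stats::rnorm(n, params[["mean"]], params[["sd"]]),
        lnorm = stats::rlnorm(n, params[["meanlog"]], params[["sdlog"]]),
        beta  = stats::rbeta(n, params[["shape1"]], params[["shape2"]]),
        gamma = stats::rgamma(n, params[["shape"]], params[["rate"]]),
        unif  = stats::runif(n, params[["min"]], params[["max"]]),
        logis = stats::rlogis(n, params[["location"]], params[["scale"]]),
        pointmass = rep(params[["value"]], n))
}

# Maximum-likelihood fit of one family to one coordinate's sample.
# The uniform MLE is the sample range, computed analytically because numeric
# optimizers do not find the boundary solution; positive-support and
# (0,1)-support families see the sample nudged off the boundaries.
.fitFamily <- function(x, family) {
    if (family == "unif")
        return(c(min = min(x), max = max(x)))
    xf <- switch(family,
        lnorm = , gamma = pmax(x, 1e-9),
        beta = pmin(pmax(x, 1e-9), 1 - 1e-9),
        x)
    fit <- fitdistrplus::fitdist(xf, family, method = "mle")
    fit$estimate
}

# Histogram sum-of-squares fit criterion: squared differences between the
# empirical histogram density over `bins` equal-width bins spanning the
# sample range and the fitted density at the bin midpoints.
.histogramSSE <- function(x, family, params, bins) {
    br <- seq(min(x), max(x), length.out = bins + 1L)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    d <- .familyDensity(family, params, h$mids)
    d[!is.finite(d)] <- 0
    sum((h$density - d)^2)
}

#' Fit the statistical keypoint prior
#'
#' For each of the 12 keypoint coordinate slots, fits every candidate family
#' by maximum likelihood, ranks the candidates by the histogram
#' sum-of-squares criterion (squared differences between the empirical
#' histogram density and the fitted density, `bins` bins over the sample
#' range), and stores the minimizer — yielding the 12 one-dimensional
#' probability functions that constitute the statistical prior.
#' Zero-variance slots are stored as a point-mass pseudo-family with fit
#' error 0. A family that fails to converge on a slot is skipped with a
#' warning; fitting only fails if no family converges at all.
#'
#' Note that families in the candidate set can be near-equivalent on a given
#' sample (a symmetric beta is numerically indistinguishable from a normal),
#' in which case the selected *family* is decided by histogram noise even
#' though the selected *density* is essentially unique.
#'
#' @param vectors Numeric matrix (n x 12) of keypoint vectors, or a list of
#'   fully-labelled [MolarCrop-class] objects.
#' @param candidates Character vector of candidate family names, a subset of
#'   `norm`, `lnorm`, `beta`, `gamma`, `unif`, `logis`.
#' @param bins Histogram bin count for the ranking criterion.
#' @return A [PriorModel-class].
#' @export
#' @examples
#' kp <- matrix(runif(40 * 12, 0.3, 0.7), 40, 12)
#' fitPrior(kp, candidates = c("norm", "unif"))
fitPrior <- function(vectors, candidates = .PRIOR_FAMILIES, bins = 100L) {
    m <- keypointMatrix(vectors)
    if (any(is.na(m)))
        stop("prior fitting requires fully labelled keypoint vectors")
    if (nrow(m) < 30L)
        stop("prior fitting needs at least 30 keypoint vectors, got ", nrow(m))
    if (!length(candidates)) stop("candidate family list is empty")
    bad <- setdiff(candidates, .PRIOR_FAMILIES)
    if (length(bad)) stop("unknown candidate families: ", paste(bad, collapse = ", "))

    fits <- lapply(seq_len(12L), function(slot) {
        x <- m[, slot]
        if (stats::sd(x) < 1e-12)
            return(list(family = "pointmass",
                        params = c(value = x[1]), fitError = 0))
        best <- NULL
        for (fam in candidates) {
            est <- tryCatch(.fitFamily(x, fam), error = function(e) NULL)
            if (is.null(est) || any(!is.finite(est))) {
                warning(sprintf("slot %d ('%s'): family '%s' failed to fit; skipped",
                                slot, .KP_SLOTS[slot], fam))
                next
            }
            err <- .histogramSSE(x, fam, est, bins)
            if (is.null(best) || err < best$fitError)
                best <- list(family = fam, params = est, fitError = err)
        }
        if (is.null(best))
            stop("no candidate family could be fitted to slot ", slot)
        best
    })
    new("PriorModel", fits = fits, nTrain = nrow(m))
}

#' Sample keypoint vectors from the prior
#'
#' Draws each of the 12 coordinates independently from its fitted
#' distribution; sampling all twelve functions simultaneously yields a
#' purely statistical keypoint prediction. Values are clamped to `[0, 1]`.
#'
#' @param prior A [PriorModel-class].
#' @param n Number of vectors to draw.
#' @param seed Integer seed; the same seed yields identical output.
#' @return Numeric matrix (n x 12) with columns in [kpSlotNames()] order.
#' @export
samplePrior <- function(prior, n, seed = 1L) {
    stopifnot(methods::is(prior, "PriorModel"), n >= 1)
    withSeed(seed, {
        out <- vapply(prior@fits, function(f)
            clamp01(.familySample(f$family, f$params, n)), numeric(n))
        out <- matrix(out, nrow = n, ncol = 12L,
                      dimnames = list(NULL, .KP_SLOTS))
        out
    })
}

#' Augment a training set with prior-sampled predictions
#'
#' Pairs every training crop with `k` statistical prior predictions, turning
#' each labelled image into `k` training examples — the data-augmentation
#' role of the prior. Slots of the true vector belonging to an unlabelled
#' side are filled with the prior sample for those slots and flagged in the
#' `mask` so that the training loss can exclude them.
#'
#' @param train List of [MolarCrop-class] objects, each fully labelled on at
#'   least one side.
#' @param prior A [PriorModel-class].
#' @param k Prior samples per image (default 25).
#' @param seed Integer seed.
#' @return List of length `k * length(train)`; each element a list with
#'   `molarId`, `image`, `prior` (12-vector), `truth` (12-vector) and `mask`
#'   (logical 12-vector, `TRUE` where `truth` is a real label).
#' @export
augmentTrainingSet <- function(train, prior, k = 25L, seed = 1L) {
    if (!length(train)) stop("training set is empty")
    stopifnot(methods::is(prior, "PriorModel"), k >= 1L)
    labelled <- vapply(train, function(m) any(!is.na(keypoints(m))), logical(1))
    if (!all(labelled))
        stop(sum(!labelled), " training crop(s) have no labelled side")
    n <- length(train)
    draws <- samplePrior(prior, n * k, seed = seed)
    triples <- vector("list", n * k)
    for (i in seq_len(n)) {
        crop <- train[[i]]
        kp <- keypoints(crop)
        mask <- !is.na(kp)
        for (j in seq_len(k)) {
            row <- (i - 1L) * k + j
            pv <- draws[row, ]
            tv <- kp
            tv[!mask] <- pv[!mask]
            triples[[row]] <- list(molarId = molarId(crop),
                                   image = cropImage(crop),
                                   prior = pv, truth = tv, mask = mask)
        }
    }
    triples
}

#' Serialize a prior model to JSON
#'
#' @param prior A [PriorModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePrior <- function(prior, path) {
    fits <- lapply(prior@fits, function(f)
        list(family = f$family, params = as.list(f$params),
             fit_error = f$fitError))
    jsonlite::write_json(list(n_train = prior@nTrain, slots = kpSlotNames(),
                              fits = fits),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a prior model from JSON
#'
#' @param path Path written by [writePrior()].
#' @return A [PriorModel-class].
#' @export
readPrior <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    fits <- lapply(obj$fits, function(f)
        list(family = f$family, params = unlist(f$params),
             fitError = as.numeric(f$fit_error)))
    new("PriorModel", fits = fits, nTrain = as.integer(obj$n_train))
}
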