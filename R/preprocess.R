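#' Convert intensities to the log2 scale
#'
#' @param x a linear-scale \linkS4class{ProteinQuantTable}.
#' @return The table with non-missing entries replaced by their base-2
#'   logarithm (\code{scaleTag = "log2"}); missing entries stay missing.
#' @export
log2Transform <- function(x) {
    stopifnot(is(x, "ProteinQuantTable"))
    if (scaleTag(x) == "log2")
        stop("table is already on the log2 scale (double-transform guard)")
    .updatePQT(x, intensity = log2(intensities(x)), scaleTag = "log2",
               step = "log2")
}

#' Filter proteins by detection rate
#'
#' Retains proteins whose non-missing fraction is at least
#' \code{minFracGlobal} over all samples \emph{and} at least
#' \code{minFracOneCondition} within at least one condition. Both thresholds
#' are inclusive (a protein at exactly the minimum is kept). Detection is
#' judged on the original missingness mask, so the operation is idempotent
#' and unaffected by imputation.
#'
#' @param x a \linkS4class{ProteinQuantTable}.
#' @param design a \linkS4class{StudyDesign} covering every sample of
#'   \code{x}.
#' @param minFracGlobal minimum overall detection fraction (default 0).
#' @param minFracOneCondition minimum detection fraction in the best
#'   condition (default 0.60).
#' @return The filtered table, row order preserved.
#' @export
filterByDetection <- function(x, design, minFracGlobal = 0,
                              minFracOneCondition = 0.60) {
    stopifnot(is(x, "ProteinQuantTable"), is(design, "StudyDesign"))
    stopifnot(minFracGlobal >= 0, minFracGlobal <= 1,
              minFracOneCondition >= 0, minFracOneCondition <= 1)
    if (nrow(design) == 0L)
        stop("empty study design")
    unassigned <- setdiff(colnames(x), as.character(design$sample_id))
    if (length(unassigned))
        stop("samples not in design: ", paste(unassigned, collapse = ", "))
    det <- !missingMask(x)
    fracGlobal <- rowMeans(det)
    conds <- unique(as.character(design$condition[
        as.character(design$sample_id) %in% colnames(x)]))
    condFrac <- vapply(conds, function(cc) {
        cols <- samplesOf(design, cc)
        cols <- cols[cols %in% colnames(x)]
        rowMeans(det[, cols, drop = FALSE])
    }, numeric(nrow(x)))
    bestCond <- if (nrow(x) == 1L) max(condFrac) else
        apply(as.matrix(condFrac), 1L, max)
    keep <- fracGlobal >= minFracGlobal & bestCond >= minFracOneCondition
    out <- x[keep, ]
    .updatePQT(out, step = "filter",
               params = list(minFracGlobal = minFracGlobal,
                             minFracOneCondition = minFracOneCondition,
                             removed = sum(!keep)))
}

# internal: evaluate `expr` under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Impute missing values from a left-shifted Gaussian (MNAR)
#'
#' Label-free proteomics missingness is predominantly left-censored: low
#' abundance proteins drop below the detection limit. Missing cells in
#' sample j are therefore replaced by independent draws from
#' \deqn{N(\mu_j - shiftSd \cdot \sigma_j, \; (widthSd \cdot \sigma_j)^2)}
#' where \eqn{\mu_j, \sigma_j} are the mean and standard deviation of the
#' observed log2 intensities of that sample (Perseus-style convention;
#' set \code{perSample = FALSE} to pool the statistics over all samples).
#' Observed cells are never altered and the detection mask is preserved.
#'
#' @param x a log2-scale \linkS4class{ProteinQuantTable}.
#' @param shiftSd downward shift in sample-SD units (default 1.8).
#' @param widthSd width of the imputation distribution in sample-SD units
#'   (default 0.3); 0 collapses every draw to \eqn{\mu_j - shiftSd\sigma_j}.
#' @param seed optional integer; the draw is bit-reproducible given a seed
#'   and leaves the caller's RNG state untouched.
#' @param perSample compute \eqn{\mu, \sigma} per sample (default) or from
#'   all observed values pooled.
#' @return The table with \code{isImputed(x)} \code{TRUE} and no NAs.
#' @export
imputeMNAR <- function(x, shiftSd = 1.8, widthSd = 0.3, seed = NULL,
                       perSample = TRUE) {
    stopifnot(is(x, "ProteinQuantTable"), widthSd >= 0)
    if (scaleTag(x) != "log2")
        stop("imputeMNAR expects a log2-scale table")
    int <- intensities(x)
    nobs <- colSums(!is.na(int))
    if (any(nobs == 0L))
        stop("sample(s) entirely missing: ",
             paste(colnames(int)[nobs == 0L], collapse = ", "))
    if (any(nobs < 2L & colSums(is.na(int)) > 0L))
        stop("sample(s) with missing values but fewer than 2 observed: ",
             paste(colnames(int)[nobs < 2L], collapse = ", "))
    if (!perSample) {
        muAll <- mean(int, na.rm = TRUE)
        sdAll <- stats::sd(int[!is.na(int)])
    }
    .withSeed(seed, {
        for (j in seq_len(ncol(int))) {
            miss <- which(is.na(int[, j]))
            if (!length(miss)) next
            if (perSample) {
                mu <- mean(int[, j], na.rm = TRUE)
                sg <- stats::sd(int[!is.na(int[, j]), j])
            } else {
                mu <- muAll; sg <- sdAll
            }
            int[miss, j] <- stats::rnorm(length(miss),
                                         mean = mu - shiftSd * sg,
                                         sd = widthSd * sg)
        }
    })
    .updatePQT(x, intensity = int, imputed = TRUE, step = "impute_mnar",
               params = list(shiftSd = shiftSd, widthSd = widthSd,
                             seed = seed, perSample = perSample))
}

#' Normalize an imputed log2 table across samples
#'
#' \describe{
#'   \item{vsn_like}{Per-sample robust affine calibration against a pooled
#'     reference, followed by a generalized-log (inverse hyperbolic sine)
#'     stabilization. The reference is the mean of the samples' sorted
#'     log2 vectors (rank-matched quantiles); each sample is scale-and-
#'     shifted (median/IQR) onto it, then the calibrated intensities pass
#'     through \code{asinh(2^y / 2)/log(2)}, which equals the identity for
#'     intensities well above zero and tempers only the near-zero tail.
#'     The calibration is monotone within each sample, so ranks are
#'     preserved and log2 fold changes of well-measured proteins are
#'     essentially unaffected.}
#'   \item{median_center}{Subtract each sample's median log2 intensity.}
#'   \item{none}{Identity (the method is still recorded in provenance).}
#' }
#'
#' @param x an imputed log2-scale \linkS4class{ProteinQuantTable}.
#' @param method one of \code{"vsn_like"}, \code{"median_center"},
#'   \code{"none"}.
#' @return The normalized table; the method used is recorded in provenance.
#' @export
normalizeIntensities <- function(x, method = c("vsn_like", "median_center",
                                               "none")) {
    method <- match.arg(method)
    stopifnot(is(x, "ProteinQuantTable"))
    if (scaleTag(x) != "log2")
        stop("normalization expects a log2-scale table")
    int <- intensities(x)
    if (anyNA(int))
        stop("normalization expects a fully imputed table (no NAs); ",
             "run imputeMNAR first")
    if (method == "median_center") {
        int <- sweep(int, 2L, apply(int, 2L, stats::median))
    } else if (method == "vsn_like") {
        if (ncol(int) < 2L)
            stop("vsn_like calibration needs at least 2 samples")
        ref <- rowMeans(apply(int, 2L, sort))
        refMed <- stats::median(ref)
        refIqr <- stats::IQR(ref)
        for (j in seq_len(ncol(int))) {
            iqr <- stats::IQR(int[, j])
            if (iqr == 0)
                stop("sample '", colnames(int)[j],
                     "' has zero spread; cannot calibrate")
            int[, j] <- (int[, j] - stats::median(int[, j])) / iqr * refIqr +
                refMed
        }
        # generalized-log guard: agrees with the identity for intensities
        # well above zero, compresses only the (rare) near-zero tail
        int <- asinh(2^int / 2) / log(2)
    }
    .updatePQT(x, intensity = int, step = "normalize",
               params = list(method = method))
}

#' Z-score matrix rows
#'
#' Standardizes each row to mean 0 and SD 1, the transformation applied to
#' expression heatmaps before clustering. The default uses the population
#' SD (divide by n); set \code{sdType = "sample"} for the n-1 convention.
#'
#' @param m numeric matrix with at least 2 columns.
#' @param sdType \code{"population"} (default) or \code{"sample"}.
#' @return The row-standardized matrix.
#' @export
zscoreRows <- function(m, sdType = c("population", "sample")) {
    sdType <- match.arg(sdType)
    m <- as.matrix(m)
    ctr <- m - rowMeans(m)
    ss <- rowMeans(ctr^2)
    if (sdType == "sample")
        ss <- ss * ncol(m) / (ncol(m) - 1L)
    sds <- sqrt(ss)
    if (any(sds == 0)) {
        bad <- rownames(m)[sds == 0]
        if (is.null(bad)) bad <- which(sds == 0)
        stop("constant row(s), cannot z-score: ", paste(bad, collapse = ", "))
    }
    ctr / sds
}
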