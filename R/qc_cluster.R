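#' Principal component analysis of samples
#'
#' PCA of the centered (optionally unit-scaled) imputed log2 matrix, samples
#' as observations.
#'
#' @param x an imputed log2-scale \linkS4class{ProteinQuantTable}.
#' @param nComponents number of components to return (default 2; at most
#'   \code{min(nsamples - 1, nproteins)}).
#' @param scale. unit-variance scale proteins before PCA (default FALSE).
#' @return list with \code{coords} (samples x components) and
#'   \code{varianceExplained} (fractions, non-increasing, summing to <= 1).
#' @export
runPCA <- function(x, nComponents = 2, scale. = FALSE) {
    stopifnot(is(x, "ProteinQuantTable"))
    int <- intensities(x)
    if (anyNA(int))
        stop("PCA expects an imputed table")
    if (ncol(int) < 2L)
        stop("PCA needs at least 2 samples")
    kmax <- min(ncol(int) - 1L, nrow(int))
    if (nComponents > kmax)
        stop("nComponents must be <= ", kmax)
    pr <- stats::prcomp(t(int), center = TRUE, scale. = scale.)
    ve <- pr$sdev^2 / sum(pr$sdev^2)
    list(coords = pr$x[, seq_len(nComponents), drop = FALSE],
         varianceExplained = ve[seq_len(nComponents)])
}

#' Pairwise Pearson correlation of samples
#'
#' @param x a \linkS4class{ProteinQuantTable} (imputed, or correlation uses
#'   complete observations).
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
pearsonMatrix <- function(x) {
    int <- intensities(x)
    if (ncol(int) < 2L)
        stop("need at least 2 samples")
    sds <- apply(int, 2L, stats::sd, na.rm = TRUE)
    if (any(!is.na(sds) & sds == 0))
        stop("constant sample(s): ",
             paste(colnames(int)[!is.na(sds) & sds == 0], collapse = ", "))
    stats::cor(int, use = "pairwise.complete.obs", method = "pearson")
}

#' Compare per-sample detection counts between two conditions
#'
#' Counts detected proteins per sample on the pre-imputation mask and
#' compares the two groups with a two-sided unpaired Student t-test
#' (equal-variance).
#'
#' @param x a \linkS4class{ProteinQuantTable}.
#' @param design a \linkS4class{StudyDesign}.
#' @param condA,condB condition labels, each with at least 2 samples.
#' @return list with \code{counts} (named per-sample counts),
#'   \code{groups} (condition of each counted sample), \code{meanDiff}
#'   (mean A minus mean B) and \code{p}.
#' @export
compareDetectedCounts <- function(x, design, condA, condB) {
    colsA <- .condCols(x, design, condA, min_n = 2L)
    colsB <- .condCols(x, design, condB, min_n = 2L)
    det <- !missingMask(x)
    cA <- colSums(det[, colsA, drop = FALSE])
    cB <- colSums(det[, colsB, drop = FALSE])
    # degenerate spreads make the t statistic undefined; report the
    # deterministic limit instead
    p <- if (stats::sd(cA) == 0 && stats::sd(cB) == 0) {
        if (mean(cA) == mean(cB)) 1 else 0
    } else {
        stats::t.test(cA, cB, var.equal = TRUE)$p.value
    }
    list(counts = c(cA, cB),
         groups = c(rep(condA, length(cA)), rep(condB, length(cB))),
         meanDiff = mean(cA) - mean(cB),
         p = p)
}

# internal: percentages to `digits` decimals by largest-remainder
# allocation, so the printed values sum exactly to 100
.largestRemainderPct <- function(counts, digits = 2L) {
    total <- sum(counts)
    unit <- 10^digits
    raw <- counts / total * 100 * unit
    base <- floor(raw + 1e-9)
    shortfall <- round(100 * unit - sum(base))
    if (shortfall > 0) {
        rem <- raw - base
        top <- order(rem, decreasing = TRUE)[seq_len(shortfall)]
        base[top] <- base[top] + 1
    }
    base / unit
}

#' Detection-overlap partition between two conditions
#'
#' A protein counts as detected in a condition when it is non-missing in at
#' least one of that condition's samples. The union of proteins detected in
#' either condition is partitioned into condition-A-only, condition-B-only
#' and shared sets; percentages (of the union) are reported to 2 decimals
#' with largest-remainder rounding so they sum to exactly 100.00.
#'
#' @param x a \linkS4class{ProteinQuantTable}.
#' @param design a \linkS4class{StudyDesign}.
#' @param condA,condB condition labels.
#' @return list with \code{counts} (a_only, b_only, shared, total) and
#'   \code{percentages} (a_only, b_only, shared).
#' @export
overlapPartition <- function(x, design, condA, condB) {
    colsA <- .condCols(x, design, condA, min_n = 1L)
    colsB <- .condCols(x, design, condB, min_n = 1L)
    det <- !missingMask(x)
    inA <- rowSums(det[, colsA, drop = FALSE]) >= 1L
    inB <- rowSums(det[, colsB, drop = FALSE]) >= 1L
    total <- sum(inA | inB)
    if (total == 0L)
        stop("no protein detected in either condition")
    counts <- c(a_only = sum(inA & !inB),
                b_only = sum(!inA & inB),
                shared = sum(inA & inB))
    pct <- .largestRemainderPct(counts)
    list(counts = c(counts, total = total),
         percentages = pct)
}

#' Agglomerative hierarchical clustering of rows or columns
#'
#' Euclidean distance with average linkage by default, matching the
#' standard expression-heatmap configuration; input is typically the
#' row-z-scored log2 matrix.
#'
#' @param m numeric matrix without missing values.
#' @param axis cluster \code{"rows"} (default) or \code{"cols"}.
#' @param metric distance metric for \code{\link[stats]{dist}}.
#' @param linkage linkage method for \code{\link[stats]{hclust}}.
#' @param k optional number of flat clusters to cut.
#' @return list with \code{order} (leaf permutation), \code{linkage} (the
#'   \code{hclust} tree), \code{heights}, and \code{clusters} (named
#'   assignment, when \code{k} given).
#' @export
hierarchicalCluster <- function(m, axis = c("rows", "cols"),
                                metric = "euclidean", linkage = "average",
                                k = NULL) {
    axis <- match.arg(axis)
    m <- as.matrix(m)
    if (anyNA(m))
        stop("matrix must not contain missing values")
    if (axis == "cols")
        m <- t(m)
    if (!is.null(k) && k > nrow(m))
        stop("k must be <= number of items (", nrow(m), ")")
    hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
    list(order = hc$order,
         linkage = hc,
         heights = hc$height,
         clusters = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
}

#' Normality summary of a set of values
#'
#' Skewness, excess kurtosis (population moments) and an omnibus
#' (Anderson-Darling) normality p-value, for checking that log2 LFQ values
#' are near-Gaussian before parametric testing.
#'
#' @param values numeric vector with at least 8 non-missing values.
#' @return list with \code{skewness}, \code{excessKurtosis}, \code{p},
#'   \code{n}.
#' @export
gaussianCheck <- function(values) {
    values <- values[!is.na(values)]
    if (length(values) < 8L)
        stop("need at least 8 values")
    if (stats::sd(values) == 0)
        stop("constant input; normality is undefined")
    m <- mean(values)
    m2 <- mean((values - m)^2)
    list(skewness = mean((values - m)^3) / m2^1.5,
         excessKurtosis = mean((values - m)^4) / m2^2 - 3,
         p = nortest::ad.test(values)$p.value,
         n = length(values))
}
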