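#' Per-protein two-group contrast
#'
#' Fits the protein-wise two-group linear model: the log2 fold change is the
#' difference of group means (\code{condA} minus \code{condB}) and s^2 the
#' pooled within-group variance on \code{n_a + n_b - 2} degrees of freedom.
#'
#' @param x an imputed log2-scale \linkS4class{ProteinQuantTable}.
#' @param design a \linkS4class{StudyDesign}.
#' @param condA,condB condition labels; both need at least 2 samples.
#' @return data.frame with columns \code{protein_id}, \code{log2fc},
#'   \code{avg_expr}, \code{s2}, \code{df}, and attributes \code{n_a},
#'   \code{n_b}.
#' @export
fitGroupContrast <- function(x, design, condA, condB) {
    stopifnot(is(x, "ProteinQuantTable"), is(design, "StudyDesign"))
    if (!condA %in% as.character(design$condition))
        stop("condition '", condA, "' absent from design")
    if (!condB %in% as.character(design$condition))
        stop("condition '", condB, "' absent from design")
    if (anyNA(intensities(x)))
        stop("contrast requires an imputed table (no NAs)")
    colsA <- .condCols(x, design, condA, min_n = 2L)
    colsB <- .condCols(x, design, condB, min_n = 2L)
    a <- intensities(x)[, colsA, drop = FALSE]
    b <- intensities(x)[, colsB, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    mA <- rowMeans(a); mB <- rowMeans(b)
    ss <- rowSums((a - mA)^2) + rowSums((b - mB)^2)
    d <- na + nb - 2L
    out <- data.frame(protein_id = proteinIds(x),
                      log2fc = mA - mB,
                      avg_expr = (na * mA + nb * mB) / (na + nb),
                      s2 = ss / d,
                      df = d,
                      row.names = NULL,
                      stringsAsFactors = FALSE)
    attr(out, "n_a") <- na
    attr(out, "n_b") <- nb
    out
}

# Newton inversion of the trigamma function, for the moment-matching prior
# fit. Converges in a handful of iterations for the y values arising from
# log-variance dispersions.
.trigammaInverse <- function(y) {
    vapply(y, function(yy) {
        if (yy > 1e7) return(1 / sqrt(yy))
        if (yy < 1e-6) return(1 / yy)
        x <- 0.5 + 1 / yy
        for (i in 1:50) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
            x <- x + dif
            if (abs(dif / x) < 1e-10) break
        }
        x
    }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-F model \eqn{s^2 \sim s0sq \cdot F(d, d0)} to the observed
#' per-protein variances by matching the first two moments of \eqn{\log s^2}
#' via digamma/trigamma inversion. When the dispersion of \eqn{\log s^2}
#' does not exceed the sampling floor \eqn{\psi'(d/2)}, \code{d0} is
#' infinite and \code{s0sq} the (geometric-mean-based) common variance.
#'
#' @param s2 per-protein residual variances (positive).
#' @param df residual degrees of freedom (scalar or per-protein vector).
#' @return An \linkS4class{EBayesPrior}.
#' @export
estimateEBayesPrior <- function(s2, df) {
    df <- rep_len(df, length(s2))
    ok <- is.finite(s2) & s2 > 0
    if (all(!ok) || all(s2[is.finite(s2)] == 0))
        stop("all variances are zero or non-finite; cannot estimate prior")
    if (any(!ok)) {
        warning(sum(!ok), " non-positive or non-finite variance(s) ignored ",
                "in prior estimation")
        s2 <- s2[ok]; df <- df[ok]
    }
    if (length(s2) < 2L)
        stop("need at least 2 positive variances to estimate the prior")
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        # no excess dispersion of log s2 beyond its sampling floor: common
        # variance, best estimated by the plain mean
        d0 <- Inf
        s0sq <- mean(s2)
    }
    EBayesPrior(d0 = d0, s0sq = s0sq)
}

#' Moderated t-statistics
#'
#' Shrinks each protein's variance toward the prior,
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and tests \code{log2fc} with \eqn{t = log2fc / (\tilde s \sqrt{1/n_a +
#' 1/n_b})} on \eqn{d + d_0} total degrees of freedom (normal reference
#' when \eqn{d_0 = \infty}). \code{d0 = 0} recovers the ordinary two-sample
#' t-statistic.
#'
#' @param contrasts output of \code{\link{fitGroupContrast}} (or a
#'   data.frame with \code{log2fc}, \code{s2}, \code{df}).
#' @param prior an \linkS4class{EBayesPrior}; \code{d0 = 0} is additionally
#'   accepted here as the no-shrinkage limit.
#' @param nA,nB group sizes; taken from \code{contrasts} attributes when
#'   omitted.
#' @return data.frame with \code{protein_id}, \code{log2fc},
#'   \code{avg_expr}, \code{t_mod}, \code{df_total}, \code{p_value}.
#' @export
moderatedT <- function(contrasts, prior, nA = attr(contrasts, "n_a"),
                       nB = attr(contrasts, "n_b")) {
    d0 <- if (is(prior, "EBayesPrior")) prior@d0 else prior$d0
    s0sq <- if (is(prior, "EBayesPrior")) prior@s0sq else prior$s0sq
    stopifnot(d0 >= 0, s0sq > 0, !is.null(nA), !is.null(nB))
    d <- contrasts$df
    s2post <- if (is.infinite(d0)) rep_len(s0sq, nrow(contrasts))
              else (d0 * s0sq + d * contrasts$s2) / (d0 + d)
    se <- sqrt(s2post * (1 / nA + 1 / nB))
    t <- contrasts$log2fc / se
    dfTotal <- d + d0
    p <- 2 * stats::pt(-abs(t), df = dfTotal)
    data.frame(protein_id = contrasts$protein_id,
               log2fc = contrasts$log2fc,
               avg_expr = if (!is.null(contrasts$avg_expr))
                   contrasts$avg_expr else NA_real_,
               t_mod = t, df_total = dfTotal, p_value = p,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order. Input values must lie
#' in (0, 1].
#'
#' @param p vector of raw p-values.
#' @return vector of adjusted p-values, each >= its raw value.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (anyNA(p) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Select enriched candidates at the run thresholds
#'
#' @param results data.frame with \code{protein_id}, \code{log2fc},
#'   \code{adj_p}.
#' @param alpha adjusted-p cutoff (default 0.01).
#' @param lfcCut log2 fold-change cutoff (default 2).
#' @param direction \code{"bait_enriched"} (default; \code{log2fc >= lfcCut})
#'   or \code{"both"} (\code{|log2fc| >= lfcCut}, for symmetric volcano
#'   counting).
#' @return character vector of selected protein ids.
#' @export
selectCandidates <- function(results, alpha = 0.01, lfcCut = 2,
                             direction = c("bait_enriched", "both")) {
    direction <- match.arg(direction)
    stopifnot(all(c("protein_id", "log2fc", "adj_p") %in% colnames(results)))
    fcOK <- if (direction == "bait_enriched") results$log2fc >= lfcCut
            else abs(results$log2fc) >= lfcCut
    as.character(results$protein_id[results$adj_p < alpha & fcOK])
}

#' Full bait-versus-control differential enrichment
#'
#' Convenience wrapper: contrast fit, prior estimation, moderated t, BH
#' adjustment, and the significance flag at the run thresholds.
#'
#' @inheritParams fitGroupContrast
#' @inheritParams selectCandidates
#' @return data.frame (one row per protein): \code{protein_id},
#'   \code{log2fc}, \code{avg_expr}, \code{t_mod}, \code{df_total},
#'   \code{p_value}, \code{adj_p}, \code{significant}; the fitted prior is
#'   attached as attribute \code{"prior"}.
#' @examples
#' sim <- generatePulldown(simParams(nProteins = 200, seed = 1))
#' tab <- normalizeIntensities(imputeMNAR(filterByDetection(
#'     log2Transform(sim$table), sim$design), seed = 2))
#' res <- diffEnrichment(tab, sim$design, "BAIT_INTACT", "GST_CTRL")
#' head(res[order(res$adj_p), ])
#' @export
diffEnrichment <- function(x, design, condA, condB, alpha = 0.01,
                           lfcCut = 2, direction = c("bait_enriched", "both")) {
    direction <- match.arg(direction)
    ctr <- fitGroupContrast(x, design, condA, condB)
    prior <- estimateEBayesPrior(ctr$s2, ctr$df)
    res <- moderatedT(ctr, prior)
    # extreme t can underflow p to 0; floor at the smallest double so the
    # (0,1] contract of the BH step holds
    res$adj_p <- bhAdjust(pmax(res$p_value, .Machine$double.xmin))
    fcOK <- if (direction == "bait_enriched") res$log2fc >= lfcCut
            else abs(res$log2fc) >= lfcCut
    res$significant <- res$adj_p < alpha & fcOK
    attr(res, "prior") <- prior
    attr(res, "params") <- list(alpha = alpha, lfcCut = lfcCut,
                                direction = direction,
                                condA = condA, condB = condB)
    res
}
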