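#' Paired GTPgammaS versus GDPbetaS comparison
#'
#' For each protein, the per-pair difference of log2 intensities between the
#' GTPgammaS- and GDPbetaS-loaded pulldown of the same lysate portion is
#' computed; \code{log2_delta_fc} is the mean difference and
#' \code{p_paired} the two-sided paired t-test on the differences. Pairs in
#' which either member is missing for a protein are dropped
#' (\code{n_pairs} reflects it); by default only originally observed values
#' are used even on an imputed table, since with three pairs imputation
#' noise would dominate (\code{useImputed = TRUE} overrides).
#'
#' @param x a log2-scale \linkS4class{ProteinQuantTable} containing the
#'   loading samples.
#' @param design a \linkS4class{StudyDesign} with at least 2 complete
#'   GTPgammaS/GDPbetaS pairs.
#' @param proteins protein ids to test (default: all).
#' @param useImputed include imputed cells in the differences
#'   (default FALSE).
#' @return data.frame: \code{protein_id}, \code{log2_delta_fc},
#'   \code{p_paired}, \code{n_pairs}, \code{insufficient_pairs} (TRUE where
#'   fewer than 2 usable pairs; such rows carry NA statistics).
#' @export
pairedDelta <- function(x, design, proteins = proteinIds(x),
                        useImputed = FALSE) {
    stopifnot(is(x, "ProteinQuantTable"), is(design, "StudyDesign"))
    if (scaleTag(x) != "log2")
        stop("paired comparison expects a log2-scale table")
    unknown <- setdiff(proteins, proteinIds(x))
    if (length(unknown))
        stop("unknown protein(s): ", paste(unknown, collapse = ", "))
    pid <- as.character(design$pair_id)
    cond <- as.character(design$condition)
    sid <- as.character(design$sample_id)
    pairIds <- unique(pid[!is.na(pid)])
    gtp <- vapply(pairIds, function(p)
        sid[!is.na(pid) & pid == p & cond == "BAIT_GTPGS"], character(1))
    gdp <- vapply(pairIds, function(p)
        sid[!is.na(pid) & pid == p & cond == "BAIT_GDPBS"], character(1))
    keep <- gtp %in% colnames(x) & gdp %in% colnames(x)
    gtp <- gtp[keep]; gdp <- gdp[keep]
    if (length(gtp) < 2L)
        stop("need at least 2 complete GTPgammaS/GDPbetaS pairs")
    int <- intensities(x)[proteins, , drop = FALSE]
    usable <- !missingMask(x)[proteins, , drop = FALSE]
    if (!useImputed)
        usable <- usable & !is.na(int)
    else
        usable <- !is.na(int)
    res <- lapply(seq_along(proteins), function(i) {
        ok <- usable[i, gtp] & usable[i, gdp]
        d <- int[i, gtp[ok]] - int[i, gdp[ok]]
        n <- length(d)
        if (n < 2L)
            return(data.frame(log2_delta_fc = if (n) mean(d) else NA_real_,
                              p_paired = NA_real_, n_pairs = n,
                              insufficient_pairs = TRUE))
        m <- mean(d)
        if (stats::sd(d) == 0) {
            # degenerate: all differences identical; p is 1 under the null
            # value, else effectively 0
            p <- if (abs(m) < .Machine$double.eps^0.5) 1 else 0
        } else {
            p <- stats::t.test(d)$p.value
        }
        data.frame(log2_delta_fc = m, p_paired = p, n_pairs = n,
                   insufficient_pairs = FALSE)
    })
    out <- do.call(rbind, res)
    nIns <- sum(out$insufficient_pairs)
    if (nIns)
        warning(nIns, " protein(s) had fewer than 2 usable pairs; ",
                "no p-value emitted")
    cbind(data.frame(protein_id = proteins, stringsAsFactors = FALSE), out)
}

#' Flag nucleotide-state-dependent binding
#'
#' A protein is state-dependent when the absolute mean log2 difference
#' reaches \code{deltaCut} and the paired test is significant at
#' \code{alpha}.
#'
#' @param results output of \code{\link{pairedDelta}}.
#' @param deltaCut minimum |log2 delta FC| (default 0.2).
#' @param alpha significance level (default 0.05).
#' @return \code{results} with a logical \code{state_dependent} column.
#' @export
flagStateDependence <- function(results, deltaCut = 0.2, alpha = 0.05) {
    stopifnot(all(c("log2_delta_fc", "p_paired") %in% colnames(results)))
    results$state_dependent <- !is.na(results$p_paired) &
        !is.na(results$log2_delta_fc) &
        abs(results$log2_delta_fc) >= deltaCut &
        results$p_paired < alpha
    results
}
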