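#' Detection rate of proteins within a condition
#'
#' Fraction of a condition's samples in which the protein was detected,
#' always computed on the original (pre-imputation) missingness mask.
#'
#' @param x a \linkS4class{ProteinQuantTable}.
#' @param design a \linkS4class{StudyDesign}.
#' @param condition condition label with at least one sample.
#' @param proteins protein ids (default: all); unknown ids are an error.
#' @return named numeric vector of fractions in [0, 1].
#' @examples
#' # a protein seen in 5 of 5 co-IP samples has rate 1.0,
#' # one seen in 4 of 6 pulldowns has rate 0.667
#' @export
detectionRate <- function(x, design, condition, proteins = proteinIds(x)) {
    stopifnot(is(x, "ProteinQuantTable"), is(design, "StudyDesign"))
    cols <- .condCols(x, design, condition, min_n = 1L)
    unknown <- setdiff(proteins, proteinIds(x))
    if (length(unknown))
        stop("unknown protein(s): ", paste(unknown, collapse = ", "))
    det <- !missingMask(x)[proteins, cols, drop = FALSE]
    rowMeans(det)
}

#' Confidence label from a detection rate
#'
#' Maps co-IP detection rates onto the three-level confidence score:
#' above 80\% is \code{high}, 60--80\% inclusive is \code{moderate}, below
#' 60\% is \code{unlikely} (the candidate is excluded from the tiers).
#' Boundaries are inclusive for \code{moderate} on both ends.
#'
#' @param rate numeric vector of fractions in [0, 1].
#' @param lower,upper the band edges (defaults 0.60 and 0.80).
#' @return character vector in \code{c("high", "moderate", "unlikely")}.
#' @export
confidenceLabel <- function(rate, lower = 0.60, upper = 0.80) {
    stopifnot(all(rate >= 0 & rate <= 1))
    ifelse(rate > upper, "high",
           ifelse(rate >= lower, "moderate", "unlikely"))
}

#' Enrichment label from a fold change
#'
#' \code{high} when the fold change exceeds the threshold, \code{low}
#' otherwise (a value exactly at the threshold is \code{low}; documented
#' tie rule).
#'
#' @param fc positive fold changes (scale must match the threshold's).
#' @param threshold the cutoff, typically \code{\link{medianFCThreshold}} of
#'   the examined candidates.
#' @return character vector in \code{c("high", "low")}.
#' @export
enrichmentLabel <- function(fc, threshold) {
    if (any(!is.na(fc) & fc <= 0))
        stop("fold changes must be positive")
    ifelse(fc > threshold, "high", "low")
}

#' Median fold-change threshold
#'
#' The enrichment cutoff is the sample median (midpoint convention for even
#' counts) of the examined candidates' co-IP fold changes, recomputed from
#' the data at hand rather than fixed.
#'
#' @param fcs positive fold changes of the examined candidates.
#' @return the median.
#' @export
medianFCThreshold <- function(fcs) {
    fcs <- fcs[is.finite(fcs)]
    if (length(fcs) == 0L)
        stop("no finite fold changes to take a median of")
    if (any(fcs <= 0))
        stop("fold changes must be positive")
    stats::median(fcs)
}

#' Credibility category from confidence and enrichment labels
#'
#' The four-tier classification of candidate interactors:
#' \tabular{lll}{
#'   confidence \tab enrichment \tab category \cr
#'   unlikely \tab any \tab unlikely (excluded) \cr
#'   moderate \tab low \tab low_credibility \cr
#'   moderate \tab high \tab satisfactory \cr
#'   high \tab low \tab satisfactory \cr
#'   high \tab high \tab high_credibility \cr
#' }
#'
#' @param confidence character vector in \code{c("high","moderate","unlikely")}.
#' @param enrichment character vector in \code{c("high","low")} (ignored
#'   where confidence is \code{unlikely}).
#' @return character vector of categories.
#' @export
classifyCredibility <- function(confidence, enrichment) {
    stopifnot(all(confidence %in% c("high", "moderate", "unlikely")))
    stopifnot(all(enrichment %in% c("high", "low") | confidence == "unlikely"))
    out <- character(length(confidence))
    out[confidence == "unlikely"] <- "unlikely"
    out[confidence == "high" & enrichment == "high"] <- "high_credibility"
    out[confidence == "high" & enrichment == "low"] <- "satisfactory"
    out[confidence == "moderate" & enrichment == "high"] <- "satisfactory"
    out[confidence == "moderate" & enrichment == "low"] <- "low_credibility"
    out
}

#' Score pulldown candidates against co-immunoprecipitation data
#'
#' For each candidate: the detection rate across the co-IP bait samples
#' (confidence), the bait-versus-control fold change (enrichment, judged
#' against the median fold change of the evaluable candidates unless a
#' threshold is supplied), and the resulting credibility category.
#' Candidates absent from the co-IP table are reported as not evaluable,
#' never silently dropped; the bait protein itself is excluded from the
#' tier counts.
#'
#' @param candidates character vector of candidate protein ids (non-empty).
#' @param coipTable a log2-scale \linkS4class{ProteinQuantTable} of the
#'   co-IP experiment (imputed or not; group means use observed values when
#'   unimputed).
#' @param design a \linkS4class{StudyDesign} covering the co-IP samples.
#' @param baitCondition,controlCondition condition labels (defaults
#'   \code{COIP_BAIT} / \code{IGG_CTRL}).
#' @param scale \code{"linear"} (fold change \code{2^log2fc}; default) or
#'   \code{"log2"}; the median threshold is taken on the same scale.
#' @param threshold optional fixed enrichment cutoff overriding the median.
#' @param baitProtein optional id of the bait, excluded from tier counts.
#' @return list with \code{records} (data.frame: protein_id,
#'   detection_rate, confidence, fold_change, enrichment, category),
#'   \code{tierCounts} (named counts over the four categories, bait
#'   excluded), \code{threshold}, and \code{notEvaluable}.
#' @export
scoreCandidates <- function(candidates, coipTable, design,
                            baitCondition = "COIP_BAIT",
                            controlCondition = "IGG_CTRL",
                            scale = c("linear", "log2"),
                            threshold = NULL, baitProtein = NULL) {
    scale <- match.arg(scale)
    if (length(candidates) == 0L)
        stop("empty candidate list")
    if (scaleTag(coipTable) != "log2")
        stop("co-IP table must be on the log2 scale")
    present <- candidates[candidates %in% proteinIds(coipTable)]
    notEvaluable <- setdiff(candidates, present)
    if (length(present) == 0L)
        stop("none of the candidates appear in the co-IP table")
    rate <- detectionRate(coipTable, design, baitCondition, present)
    bCols <- .condCols(coipTable, design, baitCondition, min_n = 1L)
    cCols <- .condCols(coipTable, design, controlCondition, min_n = 1L)
    int <- intensities(coipTable)[present, , drop = FALSE]
    mB <- rowMeans(int[, bCols, drop = FALSE], na.rm = TRUE)
    mC <- rowMeans(int[, cCols, drop = FALSE], na.rm = TRUE)
    lfc <- mB - mC
    fc <- if (scale == "linear") 2^lfc else lfc
    conf <- confidenceLabel(rate)
    evaluable <- conf != "unlikely" &
        !(present %in% baitProtein) & is.finite(fc)
    if (is.null(threshold)) {
        threshold <- if (scale == "linear") medianFCThreshold(fc[evaluable])
                     else stats::median(fc[evaluable & !is.na(fc)])
    }
    # log2-scale fold changes may legitimately be negative, so the
    # positivity contract of enrichmentLabel applies to linear FCs only
    enr <- if (scale == "linear") enrichmentLabel(fc, threshold)
           else ifelse(fc > threshold, "high", "low")
    cat4 <- classifyCredibility(conf, enr)
    records <- data.frame(protein_id = present,
                          detection_rate = unname(rate),
                          confidence = conf,
                          fold_change = unname(fc),
                          enrichment = enr,
                          category = cat4,
                          row.names = NULL, stringsAsFactors = FALSE)
    tallied <- records$protein_id[!(records$protein_id %in% baitProtein)]
    tierCounts <- table(factor(records$category[records$protein_id %in% tallied],
                               levels = c("unlikely", "low_credibility",
                                          "satisfactory", "high_credibility")))
    list(records = records,
         tierCounts = c(tierCounts),
         threshold = threshold,
         notEvaluable = notEvaluable)
}
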