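#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Recognised experimental conditions
#'
#' The six condition labels the pipeline understands: GST-only pulldown
#' control, bait pulldown from intact lysate, bait pulldown from GTPgammaS-
#' or GDPbetaS-loaded lysate, IgG co-immunoprecipitation control, and the
#' bait co-immunoprecipitation.
#'
#' @export
apmsConditions <- c("GST_CTRL", "BAIT_INTACT", "BAIT_GTPGS", "BAIT_GDPBS",
                    "IGG_CTRL", "COIP_BAIT")

#' ProteinQuantTable: protein-by-sample LFQ intensities with missingness
#'
#' A \linkS4class{SummarizedExperiment} carrying two assays: \code{intensity}
#' (MaxLFQ intensities; \code{NA} where not detected, until imputation) and
#' \code{missing} (logical detection mask, \code{TRUE} = not detected in the
#' source data). The mask records the *original* detection pattern and is
#' preserved through imputation, so detection rates and per-sample counts are
#' always computed on pre-imputation missingness. Metadata tracks the scale
#' (\code{"linear"} or \code{"log2"}), whether missing cells have been
#' imputed, and a provenance list of the transformations applied.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("ProteinQuantTable", contains = "SummarizedExperiment")

.validProteinQuantTable <- function(object) {
    msg <- character()
    a <- assays(object)
    if (!all(c("intensity", "missing") %in% names(a)))
        return("assays must contain 'intensity' and 'missing'")
    int <- a$intensity
    mis <- a$missing
    if (!identical(dim(int), dim(mis)))
        msg <- c(msg, "'intensity' and 'missing' must have identical dimensions")
    if (!is.logical(mis) || anyNA(mis))
        msg <- c(msg, "'missing' must be a logical matrix without NAs")
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "protein ids (rownames) must be present and unique")
    st <- metadata(object)$scaleTag
    if (is.null(st) || !st %in% c("linear", "log2"))
        msg <- c(msg, "metadata scaleTag must be 'linear' or 'log2'")
    imp <- isTRUE(metadata(object)$imputed)
    if (imp) {
        if (anyNA(int))
            msg <- c(msg, "imputed table must have no NA intensities")
    } else if (length(msg) == 0L) {
        if (!identical(unname(is.na(int)), unname(mis)))
            msg <- c(msg, "NA intensities must correspond exactly to the missing mask")
    }
    if (identical(st, "linear") && length(msg) == 0L &&
        any(int[!mis] <= 0, na.rm = TRUE))
        msg <- c(msg, "linear-scale intensities must be > 0 where detected")
    if (length(msg)) msg else TRUE
}
setValidity("ProteinQuantTable", .validProteinQuantTable)

#' Construct a ProteinQuantTable
#'
#' @param intensities numeric matrix, proteins in rows, samples in columns.
#'   On the linear scale, zeros are converted to missing.
#' @param proteinIds character vector of unique protein accessions
#'   (defaults to rownames of \code{intensities}).
#' @param sampleIds character vector of sample names (defaults to colnames).
#' @param geneSymbols optional character vector of gene symbols per protein.
#' @param missingMask optional logical matrix (\code{TRUE} = not detected);
#'   derived from zeros/NAs of \code{intensities} when omitted.
#' @param scaleTag \code{"linear"} or \code{"log2"}.
#' @param imputed logical; \code{TRUE} once missing cells carry imputed values.
#' @param provenance list recording transformations applied so far.
#' @return A \linkS4class{ProteinQuantTable}.
#' @examples
#' m <- matrix(c(100, 0, 250, 80, 120, 0), nrow = 3,
#'             dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' pqt <- ProteinQuantTable(m)
#' sum(missingMask(pqt))
#' @export
ProteinQuantTable <- function(intensities, proteinIds = rownames(intensities),
                              sampleIds = colnames(intensities),
                              geneSymbols = NULL, missingMask = NULL,
                              scaleTag = c("linear", "log2"),
                              imputed = FALSE, provenance = list()) {
    scaleTag <- match.arg(scaleTag)
    intensities <- as.matrix(intensities)
    if (is.null(proteinIds))
        stop("protein ids are required (rownames of the intensity matrix)")
    if (anyDuplicated(proteinIds))
        stop("protein ids must be unique; duplicated: ",
             paste(unique(proteinIds[duplicated(proteinIds)]), collapse = ", "))
    if (is.null(sampleIds))
        sampleIds <- paste0("sample", seq_len(ncol(intensities)))
    if (is.null(missingMask)) {
        missingMask <- is.na(intensities)
        if (scaleTag == "linear")
            missingMask <- missingMask | (!is.na(intensities) & intensities == 0)
    }
    storage.mode(intensities) <- "double"
    if (!imputed)
        intensities[missingMask] <- NA_real_
    dimnames(intensities) <- list(proteinIds, sampleIds)
    dimnames(missingMask) <- dimnames(intensities)
    rd <- DataFrame(row.names = proteinIds)
    rd$gene_symbol <- if (is.null(geneSymbols)) rep(NA_character_, nrow(intensities)) else geneSymbols
    se <- SummarizedExperiment(
        assays = list(intensity = intensities, missing = missingMask),
        rowData = rd)
    metadata(se) <- list(scaleTag = scaleTag, imputed = imputed,
                         provenance = provenance)
    new("ProteinQuantTable", se)
}

#' StudyDesign: sample-to-condition map with replicate and pairing structure
#'
#' A \linkS4class{DFrame} with columns \code{sample_id}, \code{condition}
#' (one of \code{apmsConditions}), \code{replicate} (positive integer) and
#' \code{pair_id} (links the GTPgammaS and GDPbetaS pulldowns derived from
#' the same lysate portion; \code{NA} elsewhere).
#'
#' @export
setClass("StudyDesign", contains = "DFrame")

.validStudyDesign <- function(object) {
    msg <- character()
    need <- c("sample_id", "condition", "replicate", "pair_id")
    if (!all(need %in% colnames(object)))
        return(paste("design must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(object$sample_id))
        msg <- c(msg, paste("duplicated sample_id:",
                 paste(unique(object$sample_id[duplicated(object$sample_id)]),
                       collapse = ", ")))
    bad <- setdiff(unique(as.character(object$condition)), apmsConditions)
    if (length(bad))
        msg <- c(msg, paste("unknown condition(s):", paste(bad, collapse = ", ")))
    if (any(is.na(object$replicate)) || any(object$replicate < 1))
        msg <- c(msg, "replicate must be a positive integer")
    pid <- object$pair_id
    for (p in unique(pid[!is.na(pid)])) {
        members <- as.character(object$condition[!is.na(pid) & pid == p])
        if (!identical(sort(members), c("BAIT_GDPBS", "BAIT_GTPGS")))
            msg <- c(msg, paste0("pair_id '", p,
                "' must link exactly one BAIT_GTPGS and one BAIT_GDPBS sample"))
    }
    if (length(msg)) msg else TRUE
}
setValidity("StudyDesign", .validStudyDesign)

#' Construct a StudyDesign
#'
#' @param sample_id character vector of unique sample names.
#' @param condition character vector of condition labels (see
#'   \code{\link{apmsConditions}}).
#' @param replicate positive integer replicate index within condition.
#' @param pair_id optional character; shared by exactly one GTPgammaS and one
#'   GDPbetaS sample from the same lysate.
#' @return A \linkS4class{StudyDesign}.
#' @examples
#' StudyDesign(sample_id = c("c1", "c2", "b1", "b2"),
#'             condition = c("GST_CTRL", "GST_CTRL", "BAIT_INTACT", "BAIT_INTACT"),
#'             replicate = c(1, 2, 1, 2))
#' @export
StudyDesign <- function(sample_id, condition, replicate,
                        pair_id = rep(NA_character_, length(sample_id))) {
    df <- DataFrame(sample_id = as.character(sample_id),
                    condition = as.character(condition),
                    replicate = as.integer(replicate),
                    pair_id = as.character(pair_id))
    new("StudyDesign", df)
}

#' EBayesPrior: hyperparameters of the scaled inverse-chi-squared variance prior
#'
#' The moderated-t framework models per-protein residual variances s^2 as
#' draws from s0sq * chi^2_d0 / d0. \code{d0} is the prior degrees of
#' freedom (possibly infinite when variances show no excess dispersion) and
#' \code{s0sq} the prior (typical) variance.
#'
#' @slot d0 prior degrees of freedom, positive (may be \code{Inf}).
#' @slot s0sq prior variance, positive.
#' @export
setClass("EBayesPrior", representation(d0 = "numeric", s0sq = "numeric"))

setValidity("EBayesPrior", function(object) {
    if (length(object@d0) != 1L || is.na(object@d0) || object@d0 <= 0)
        return("d0 must be a single positive number (possibly Inf)")
    if (length(object@s0sq) != 1L || !is.finite(object@s0sq) || object@s0sq <= 0)
        return("s0sq must be a single positive finite number")
    TRUE
})

#' @describeIn EBayesPrior constructor.
#' @param d0,s0sq prior degrees of freedom and prior variance.
#' @export
EBayesPrior <- function(d0, s0sq) new("EBayesPrior", d0 = d0, s0sq = s0sq)

setMethod("show", "ProteinQuantTable", function(object) {
    cat("ProteinQuantTable:", nrow(object), "proteins x", ncol(object),
        "samples\n")
    cat("  scale:", metadata(object)$scaleTag,
        "| imputed:", isTRUE(metadata(object)$imputed),
        "| missing cells:", sum(assay(object, "missing")), "\n")
    prov <- metadata(object)$provenance
    if (length(prov))
        cat("  provenance:", paste(vapply(prov, function(p) p$step, ""),
                                   collapse = " -> "), "\n")
    invisible(NULL)
})

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", nrow(object), "samples\n")
    print(table(condition = as.character(object$condition)))
    invisible(NULL)
})

setMethod("show", "EBayesPrior", function(object) {
    cat("EBayesPrior: d0 =", object@d0, ", s0sq =", object@s0sq, "\n")
    invisible(NULL)
})
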