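#' @rdname ProteinQuantTable-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname ProteinQuantTable-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname ProteinQuantTable-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname ProteinQuantTable-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname ProteinQuantTable-accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname ProteinQuantTable-accessors
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))
#' @rdname ProteinQuantTable-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accessors for ProteinQuantTable
#'
#' \code{intensities} returns the intensity matrix (NA at unimputed missing
#' cells); \code{missingMask} the original detection mask (TRUE = not
#' detected, preserved through imputation); \code{proteinIds} the accessions;
#' \code{geneSymbols} per-protein symbols; \code{scaleTag} \code{"linear"}
#' or \code{"log2"}; \code{isImputed} whether missing cells carry imputed
#' values; \code{provenance} the list of recorded processing steps.
#'
#' @param x a \linkS4class{ProteinQuantTable}.
#' @return matrix, character vector, string, logical or list as described.
#' @name ProteinQuantTable-accessors
#' @aliases intensities missingMask proteinIds geneSymbols scaleTag isImputed
#'   provenance
NULL

#' @rdname ProteinQuantTable-accessors
#' @export
setMethod("intensities", "ProteinQuantTable",
          function(x) assay(x, "intensity"))
#' @rdname ProteinQuantTable-accessors
#' @export
setMethod("missingMask", "ProteinQuantTable",
          function(x) assay(x, "missing"))
#' @rdname ProteinQuantTable-accessors
#' @export
setMethod("proteinIds", "ProteinQuantTable", function(x) rownames(x))
#' @rdname ProteinQuantTable-accessors
#' @export
setMethod("geneSymbols", "ProteinQuantTable",
          function(x) rowData(x)$gene_symbol)
#' @rdname ProteinQuantTable-accessors
#' @export
setMethod("scaleTag", "ProteinQuantTable",
          function(x) metadata(x)$scaleTag)
#' @rdname ProteinQuantTable-accessors
#' @export
setMethod("isImputed", "ProteinQuantTable",
          function(x) isTRUE(metadata(x)$imputed))
#' @rdname ProteinQuantTable-accessors
#' @export
setMethod("provenance", "ProteinQuantTable",
          function(x) metadata(x)$provenance)

# internal: rebuild a ProteinQuantTable around a new intensity matrix /
# metadata while keeping everything else
.updatePQT <- function(x, intensity = intensities(x),
                       missing = missingMask(x),
                       scaleTag = metadata(x)$scaleTag,
                       imputed = isTRUE(metadata(x)$imputed),
                       step = NULL, params = list()) {
    assays(x) <- list(intensity = intensity, missing = missing)
    md <- metadata(x)
    md$scaleTag <- scaleTag
    md$imputed <- imputed
    if (!is.null(step))
        md$provenance <- c(md$provenance, list(c(list(step = step), params)))
    metadata(x) <- md
    validObject(x)
    x
}

#' Samples assigned to a condition
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param condition one of \code{\link{apmsConditions}}.
#' @return character vector of sample ids (possibly empty).
#' @export
samplesOf <- function(design, condition) {
    stopifnot(is(design, "StudyDesign"))
    as.character(design$sample_id[as.character(design$condition) == condition])
}

# internal: columns of x belonging to `condition`, with checks
.condCols <- function(x, design, condition, min_n = 1L) {
    ids <- samplesOf(design, condition)
    ids <- ids[ids %in% colnames(x)]
    if (length(ids) < min_n)
        stop("condition '", condition, "' has fewer than ", min_n,
             " samples in the table", call. = FALSE)
    ids
}
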