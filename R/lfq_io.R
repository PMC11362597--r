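#' Read a FragPipe-style combined-protein quantification table
#'
#' Parses a tab-separated combined-protein table: one row per protein, a
#' protein-identifier column, an optional \code{Gene} column, and one
#' quantification column per sample whose header ends with
#' \code{intensitySuffix}. Zero and blank cells are recorded as missing
#' (the standard LFQ not-detected convention) and the returned table is on
#' the linear intensity scale.
#'
#' @param path path to the TSV file.
#' @param intensitySuffix suffix identifying per-sample quantification
#'   columns; the sample id is the header with the suffix stripped.
#'   Default \code{"MaxLFQ Intensity"}.
#' @return A \linkS4class{ProteinQuantTable} with \code{scaleTag = "linear"},
#'   sample order as in the file.
#' @export
readCombinedProteinTsv <- function(path, intensitySuffix = "MaxLFQ Intensity") {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    idCol <- intersect(c("Protein ID", "Protein"), colnames(df))[1]
    if (is.na(idCol))
        stop("format error in '", path,
             "': expected a protein-identifier column named ",
             "'Protein ID' or 'Protein' in the header")
    ids <- as.character(df[[idCol]])
    if (anyDuplicated(ids))
        stop("duplicate protein ids in '", path, "': ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    qCols <- grep(paste0(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              intensitySuffix), "$"),
                  colnames(df), value = TRUE)
    qCols <- setdiff(qCols, idCol)
    if (length(qCols) == 0L)
        stop("format error in '", path, "': no column ends with '",
             intensitySuffix, "'")
    sampleIds <- trimws(substr(qCols, 1L, nchar(qCols) - nchar(intensitySuffix)))
    m <- as.matrix(df[, qCols, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- list(ids, sampleIds)
    genes <- if ("Gene" %in% colnames(df)) as.character(df$Gene) else NULL
    ProteinQuantTable(m, proteinIds = ids, sampleIds = sampleIds,
                      geneSymbols = genes, scaleTag = "linear",
                      provenance = list(list(step = "read",
                                             path = as.character(path))))
}

#' Read a study-design table
#'
#' Expects a delimited text file (tab- or comma-separated, detected from the
#' header line) with columns \code{sample_id}, \code{condition},
#' \code{replicate} and optionally \code{pair_id}. Conditions must be among
#' \code{\link{apmsConditions}}; a GTPgammaS sample whose \code{pair_id}
#' lacks a GDPbetaS partner is rejected.
#'
#' @param path path to the design file.
#' @return A \linkS4class{StudyDesign}.
#' @export
readStudyDesign <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "replicate")
    if (!all(need %in% colnames(df)))
        stop("design file '", path, "' must have columns ",
             paste(need, collapse = ", "), " (optional pair_id)")
    if (!"pair_id" %in% colnames(df))
        df$pair_id <- NA_character_
    StudyDesign(df$sample_id, df$condition, df$replicate, df$pair_id)
}

#' Write a results table as TSV
#'
#' Columns are written in their current (documented, stable) order; numeric
#' columns are serialized at a fixed 15 significant digits so that writing
#' the same table twice yields byte-identical files and a read-back recovers
#' values to serialization precision.
#'
#' @param results a non-empty data.frame.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeResultsTsv <- function(results, path) {
    if (!is.data.frame(results) || nrow(results) == 0L)
        stop("results table must be a non-empty data.frame")
    out <- results
    for (j in seq_along(out)) {
        if (is.double(out[[j]]))
            out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
        out[[j]] <- as.character(out[[j]])
        out[[j]][is.na(results[[j]])] <- "NA"
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(out), collapse = "\t"), con)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
    invisible(path)
}

#' Read back a results TSV written by \code{writeResultsTsv}
#'
#' @param path path to the TSV.
#' @return data.frame with numeric columns restored where parseable.
#' @export
readResultsTsv <- function(path) {
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE, na.strings = "NA")
    df
}
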