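#' Default pipeline configuration
#'
#' @return nested list of all stage parameters with their defaults; see
#'   \code{\link{runFullPipeline}} for the keys.
#' @export
defaultPipelineConfig <- function() {
    list(
        input = NULL,                # path to combined-protein TSV, or table
        design = NULL,               # path to design file, or StudyDesign
        intensity_suffix = "MaxLFQ Intensity",
        cond_a = "BAIT_INTACT",
        cond_b = "GST_CTRL",
        filter = list(min_frac_global = 0, min_frac_one_condition = 0.60),
        impute = list(shift_sd = 1.8, width_sd = 0.3, per_sample = TRUE),
        normalize = list(method = "vsn_like"),
        alpha = 0.01,
        lfc_cut = 2,
        direction = "bait_enriched",
        coip = NULL,                 # list(input=, design=, scale=, bait_protein=)
        loading = NULL,              # list(input=, design=, proteins=,
                                     #      delta_cut=0.2, alpha=0.05)
        clustering = list(k = 3),
        seed = 1L
    )
}

.mergeConfig <- function(base, user, path = "config") {
    extra <- setdiff(names(user), names(base))
    if (length(extra))
        stop("unknown ", path, " key(s): ", paste(extra, collapse = ", "))
    for (k in names(user)) {
        if (is.list(base[[k]]) && is.list(user[[k]]) &&
            !is.null(names(base[[k]])))
            base[[k]] <- .mergeConfig(base[[k]], user[[k]],
                                      paste0(path, "$", k))
        else
            base[[k]] <- user[[k]]
    }
    base
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.resolveTable <- function(input, suffix) {
    if (is(input, "ProteinQuantTable")) return(input)
    if (is.character(input)) return(readCombinedProteinTsv(input, suffix))
    stop("input must be a ProteinQuantTable or a file path")
}

.resolveDesign <- function(design) {
    if (is(design, "StudyDesign")) return(design)
    if (is.character(design)) {
        if (!file.exists(design))
            stop("design file not found: ", design)
        return(readStudyDesign(design))
    }
    stop("design must be a StudyDesign or a file path")
}

#' Run the full AP-MS enrichment pipeline
#'
#' Chains read, log2 transform, detection filtering, MNAR imputation,
#' normalization, moderated-t differential enrichment, candidate selection,
#' optional co-IP credibility scoring, optional paired nucleotide-loading
#' analysis, and the QC battery. One global seed fans out to fixed
#' per-stage seeds so stages are individually reproducible. When
#' \code{outDir} is given, results tables, a QC summary, the tier summary
#' and a run manifest (fully resolved configuration, seed, input checksums)
#' are written there.
#'
#' @param config a (partial) configuration list, or the path to a YAML file
#'   with the same structure; unknown keys are rejected. See
#'   \code{\link{defaultPipelineConfig}} for keys and defaults.
#' @param outDir optional output directory.
#' @return list with \code{results} (per-protein statistics),
#'   \code{candidates}, \code{credibility} (when co-IP data given),
#'   \code{loading} (when loading data given), \code{qc},
#'   \code{clustering}, and \code{manifest}.
#' @export
runFullPipeline <- function(config = list(), outDir = NULL) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    cfg <- .mergeConfig(defaultPipelineConfig(), config)
    seed <- as.integer(cfg$seed)

    tab <- .stage("read", .resolveTable(cfg$input, cfg$intensity_suffix))
    des <- .stage("read_design", .resolveDesign(cfg$design))
    tab <- .stage("log2", log2Transform(tab))
    tab <- .stage("filter", filterByDetection(
        tab, des, cfg$filter$min_frac_global,
        cfg$filter$min_frac_one_condition))
    tab <- .stage("impute", imputeMNAR(
        tab, shiftSd = cfg$impute$shift_sd, widthSd = cfg$impute$width_sd,
        seed = seed + 101L, perSample = cfg$impute$per_sample))
    tab <- .stage("normalize", normalizeIntensities(tab,
                                                    cfg$normalize$method))
    res <- .stage("diff_enrichment", diffEnrichment(
        tab, des, cfg$cond_a, cfg$cond_b, alpha = cfg$alpha,
        lfcCut = cfg$lfc_cut, direction = cfg$direction))
    candidates <- res$protein_id[res$significant]

    credibility <- NULL
    if (!is.null(cfg$coip) && length(candidates)) {
        credibility <- .stage("coip_scoring", {
            ctab <- .resolveTable(cfg$coip$input, cfg$intensity_suffix)
            cdes <- .resolveDesign(cfg$coip$design)
            ctab <- log2Transform(ctab)
            scoreCandidates(candidates, ctab, cdes,
                            scale = if (is.null(cfg$coip$scale)) "linear"
                                    else cfg$coip$scale,
                            baitProtein = cfg$coip$bait_protein)
        })
    }

    loading <- NULL
    if (!is.null(cfg$loading)) {
        loading <- .stage("loading", {
            ltab <- log2Transform(.resolveTable(cfg$loading$input,
                                                cfg$intensity_suffix))
            ldes <- .resolveDesign(cfg$loading$design)
            prot <- cfg$loading$proteins
            if (is.null(prot))
                prot <- intersect(candidates, proteinIds(ltab))
            pd <- pairedDelta(ltab, ldes, proteins = prot)
            flagStateDependence(
                pd,
                deltaCut = if (is.null(cfg$loading$delta_cut)) 0.2
                           else cfg$loading$delta_cut,
                alpha = if (is.null(cfg$loading$alpha)) 0.05
                        else cfg$loading$alpha)
        })
    }

    qc <- .stage("qc", list(
        pca = runPCA(tab, nComponents = min(2L, ncol(tab) - 1L)),
        pearson = pearsonMatrix(tab),
        detectedCounts = compareDetectedCounts(tab, des, cfg$cond_a,
                                               cfg$cond_b),
        overlap = overlapPartition(tab, des, cfg$cond_a, cfg$cond_b)))

    clustering <- .stage("clustering", {
        z <- zscoreRows(intensities(tab))
        k <- min(cfg$clustering$k, nrow(z))
        list(rows = hierarchicalCluster(z, "rows", k = k),
             cols = hierarchicalCluster(z, "cols"))
    })

    # in-memory S4 inputs are not serializable; record placeholders
    sanitize <- function(x) {
        if (isS4(x)) return("<in-memory object>")
        if (is.list(x)) return(lapply(x, sanitize))
        x
    }
    manifest <- list(
        config = sanitize(cfg),
        seed = seed,
        stage_seeds = list(impute = seed + 101L),
        n_proteins_in = length(proteinIds(tab)),
        n_candidates = length(candidates),
        input_md5 = if (is.character(cfg$input))
            unname(tools::md5sum(cfg$input)) else NA_character_)

    bundle <- list(table = tab, results = res, candidates = candidates,
                   credibility = credibility, loading = loading, qc = qc,
                   clustering = clustering, manifest = manifest)

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeResultsTsv(res, file.path(outDir, "enrichment_results.tsv"))
        if (!is.null(credibility))
            writeResultsTsv(credibility$records,
                            file.path(outDir, "credibility_records.tsv"))
        if (!is.null(loading))
            writeResultsTsv(loading, file.path(outDir, "loading_results.tsv"))
        jsonlite::write_json(
            list(overlap = qc$overlap,
                 detected_counts = qc$detectedCounts[c("counts", "meanDiff",
                                                       "p")],
                 variance_explained = qc$pca$varianceExplained),
            file.path(outDir, "qc_summary.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
        if (!is.null(credibility))
            jsonlite::write_json(as.list(credibility$tierCounts),
                                 file.path(outDir, "tier_summary.json"),
                                 auto_unbox = TRUE, pretty = TRUE)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    bundle
}
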