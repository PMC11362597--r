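# Fixtures and oracles shared across test files. Everything is built in
# code; no binary data.

# small ProteinQuantTable straight from a matrix
makePQT <- function(m, scaleTag = "log2", imputed = TRUE, ...) {
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
    if (is.null(colnames(m)))
        colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
    ProteinQuantTable(m, scaleTag = scaleTag, imputed = imputed, ...)
}

# two-group design over the columns of a matrix/table
makeTwoGroupDesign <- function(sampleIds, nA, condA = "BAIT_INTACT",
                               condB = "GST_CTRL") {
    n <- length(sampleIds)
    StudyDesign(sample_id = sampleIds,
                condition = c(rep(condA, nA), rep(condB, n - nA)),
                replicate = c(seq_len(nA), seq_len(n - nA)))
}

# Independent brute-force Benjamini-Hochberg step-up oracle, straight from
# the definition: sort ascending, adj_(i) = min_{j >= i} p_(j) * n / j,
# capped at 1, returned in input order.
bruteForceBH <- function(p) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(n)
    for (i in seq_len(n))
        adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
    out <- numeric(n)
    out[o] <- adj
    out
}

# write a small FragPipe-style combined-protein TSV; values is a matrix
# with sample names as colnames (suffix appended here)
writeCombinedTsv <- function(values, path,
                             suffix = "MaxLFQ Intensity",
                             idColName = "Protein ID") {
    header <- c(idColName, "Gene",
                paste(colnames(values), suffix))
    rows <- vapply(seq_len(nrow(values)), function(i) {
        paste(c(rownames(values)[i], paste0("G", i),
                as.character(values[i, ])), collapse = "\t")
    }, character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
    path
}

# one full preprocessing + enrichment pass on a pulldown simulation;
# returns selected ids and truth
runEnrichmentOnce <- function(params, imputeSeed) {
    sim <- generatePulldown(params)
    tab <- log2Transform(sim$table)
    tab <- filterByDetection(tab, sim$design)
    tab <- imputeMNAR(tab, seed = imputeSeed)
    tab <- normalizeIntensities(tab, "vsn_like")
    res <- diffEnrichment(tab, sim$design, "BAIT_INTACT", "GST_CTRL")
    list(selected = res$protein_id[res$significant],
         truth = sim$truth, results = res)
}
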