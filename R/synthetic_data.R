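#' Simulation parameters for synthetic AP-MS data
#'
#' Defaults mirror the pulldown/co-IP/loading study design the pipeline
#' targets: six GST-control and six bait pulldowns, five IgG and five bait
#' co-IP replicates, three GTPgammaS/GDPbetaS lysate pairs; log2 baseline
#' intensities 25 +/- 2, replicate noise SD 0.5; a 10\% minority of true
#' interactors with uniform log2 effects in [2.5, 6]; logistic
#' intensity-dependent dropout (midpoint 22, slope 1 per log2 unit); half
#' of the true interactors GTP-state-dependent with a 0.785 log2 shift.
#'
#' @param nProteins number of simulated proteins.
#' @param fracTrue fraction of proteins that are true bait interactors.
#' @param effectRange bounds of the uniform log2 fold-change of true
#'   interactors.
#' @param baselineMean,baselineSd population of protein log2 baselines.
#' @param noiseSd replicate (within-condition) SD on the log2 scale.
#' @param nCtrl,nBait,nCoip,nIgg,nPairs replicate counts per condition.
#' @param mnarMid,mnarSlope logistic dropout parameters: a cell of log2
#'   intensity v is missing with probability
#'   \code{plogis((mnarMid - v) * mnarSlope)}.
#' @param fracStateDependent fraction of true interactors whose binding is
#'   GTP-state-dependent.
#' @param stateEffect log2 shift added to GTPgammaS members for
#'   state-dependent proteins.
#' @param coipAttenuation multiplier on true effects in the co-IP
#'   experiment.
#' @param coipNoiseSd replicate SD of the co-IP experiment.
#' @param fracLowDetection fraction of true interactors rendered
#'   low-detection in the co-IP bait samples (exercises the excluded tier).
#' @param pairSd SD of the shared per-pair (lysate portion) random effect
#'   in the loading experiment.
#' @param loadingNoiseSd residual replicate SD of the loading experiment;
#'   the SD of a per-pair difference is \code{sqrt(2) * loadingNoiseSd}.
#' @param seed integer seed driving all three generators.
#' @return validated parameter list of class \code{"SimParams"}.
#' @export
simParams <- function(nProteins = 800, fracTrue = 0.1,
                      effectRange = c(2.5, 6),
                      baselineMean = 25, baselineSd = 2, noiseSd = 0.5,
                      nCtrl = 6, nBait = 6, nCoip = 5, nIgg = 5, nPairs = 3,
                      mnarMid = 22, mnarSlope = 1,
                      fracStateDependent = 0.5, stateEffect = 0.785,
                      coipAttenuation = 0.85, coipNoiseSd = 0.5,
                      fracLowDetection = 0.15,
                      pairSd = 0.3, loadingNoiseSd = 0.5,
                      seed = NULL) {
    stopifnot(nProteins >= 1,
              fracTrue >= 0, fracTrue <= 1,
              length(effectRange) == 2L, effectRange[1] <= effectRange[2],
              noiseSd > 0, baselineSd > 0,
              fracStateDependent >= 0, fracStateDependent <= 1,
              fracLowDetection >= 0, fracLowDetection <= 1,
              pairSd >= 0, loadingNoiseSd > 0, coipNoiseSd > 0)
    p <- as.list(environment())
    class(p) <- "SimParams"
    p
}

# internal: apply logistic MNAR dropout to a log2 matrix; returns the
# linear-scale table plus the per-cell dropout probabilities
.applyDropout <- function(log2mat, params) {
    pDrop <- stats::plogis((params$mnarMid - log2mat) * params$mnarSlope)
    miss <- matrix(stats::runif(length(log2mat)) < pDrop, nrow = nrow(log2mat))
    lin <- 2^log2mat
    lin[miss] <- 0
    dimnames(miss) <- dimnames(log2mat)
    dimnames(pDrop) <- dimnames(log2mat)
    list(linear = lin, missing = miss, pDrop = pDrop)
}

.proteinIds <- function(n) sprintf("P%04d", seq_len(n))

#' Generate a synthetic GST-control versus bait pulldown experiment
#'
#' Control samples draw protein log2 intensities around per-protein
#' baselines; bait samples add the assigned log2 effects of the true
#' interactors; replicate noise is added everywhere and
#' intensity-dependent logistic dropout converts low cells to missing.
#' The returned table is on the linear scale with zeros at dropped cells,
#' exactly as a quantification export would show them.
#'
#' @param params a \code{\link{simParams}} object.
#' @return list with \code{table} (\linkS4class{ProteinQuantTable}),
#'   \code{design} (\linkS4class{StudyDesign}) and \code{truth} (list:
#'   \code{trueInteractors}, \code{log2fc} named effects,
#'   \code{stateDependent}, \code{baselines}, \code{dropoutProb}).
#' @export
generatePulldown <- function(params = simParams()) {
    stopifnot(inherits(params, "SimParams"))
    .withSeed(params$seed, {
        n <- params$nProteins
        ids <- .proteinIds(n)
        baselines <- stats::rnorm(n, params$baselineMean, params$baselineSd)
        names(baselines) <- ids
        nTrue <- floor(params$fracTrue * n)
        if (nTrue < 1L && params$fracTrue > 0)
            warning("fracTrue * nProteins < 1; no true interactors simulated")
        trueIdx <- sort(sample.int(n, nTrue))
        effects <- stats::setNames(numeric(n), ids)
        effects[trueIdx] <- stats::runif(nTrue, params$effectRange[1],
                                         params$effectRange[2])
        nStateDep <- floor(params$fracStateDependent * nTrue)
        stateDep <- sort(trueIdx[sample.int(length(trueIdx), nStateDep)])
        sampleIds <- c(sprintf("GST_%d", seq_len(params$nCtrl)),
                       sprintf("BAIT_%d", seq_len(params$nBait)))
        mu <- cbind(matrix(baselines, n, params$nCtrl),
                    matrix(baselines + effects, n, params$nBait))
        log2mat <- mu + matrix(stats::rnorm(n * length(sampleIds),
                                            sd = params$noiseSd),
                               n, length(sampleIds))
        dimnames(log2mat) <- list(ids, sampleIds)
        drop <- .applyDropout(log2mat, params)
        table <- ProteinQuantTable(drop$linear, proteinIds = ids,
                                   sampleIds = sampleIds,
                                   geneSymbols = sub("^P", "GENE", ids),
                                   scaleTag = "linear",
                                   provenance = list(list(step = "simulate",
                                                          kind = "pulldown")))
        design <- StudyDesign(
            sample_id = sampleIds,
            condition = c(rep("GST_CTRL", params$nCtrl),
                          rep("BAIT_INTACT", params$nBait)),
            replicate = c(seq_len(params$nCtrl), seq_len(params$nBait)))
        truth <- list(trueInteractors = ids[trueIdx],
                      log2fc = effects[trueIdx],
                      stateDependent = ids[stateDep],
                      baselines = baselines,
                      dropoutProb = drop$pDrop)
        list(table = table, design = design, truth = truth)
    })
}

#' Generate a synthetic co-immunoprecipitation experiment
#'
#' Uses the ground truth of a pulldown simulation: the same true
#' interactors are enriched in the co-IP bait samples over IgG controls
#' with attenuated effects and the experiment's own dropout. A configurable
#' fraction of true interactors is forced to a sub-60\% detection rate in
#' the bait samples, exercising the excluded ('unlikely') tier of the
#' credibility scorer.
#'
#' @param params a \code{\link{simParams}} object.
#' @param truth the \code{truth} component of \code{\link{generatePulldown}}.
#' @param seed optional seed (defaults to \code{params$seed + 1} when the
#'   params carry one).
#' @return list with \code{table}, \code{design} and \code{lowDetection}
#'   (ids forced to low detection).
#' @export
generateCoip <- function(params, truth, seed = NULL) {
    stopifnot(inherits(params, "SimParams"))
    if (is.null(seed) && !is.null(params$seed))
        seed <- params$seed + 1L
    .withSeed(seed, {
        n <- params$nProteins
        ids <- names(truth$baselines)
        effects <- stats::setNames(numeric(n), ids)
        effects[truth$trueInteractors] <-
            params$coipAttenuation * truth$log2fc
        sampleIds <- c(sprintf("IGG_%d", seq_len(params$nIgg)),
                       sprintf("COIP_%d", seq_len(params$nCoip)))
        mu <- cbind(matrix(truth$baselines, n, params$nIgg),
                    matrix(truth$baselines + effects, n, params$nCoip))
        log2mat <- mu + matrix(stats::rnorm(n * length(sampleIds),
                                            sd = params$coipNoiseSd),
                               n, length(sampleIds))
        dimnames(log2mat) <- list(ids, sampleIds)
        drop <- .applyDropout(log2mat, params)
        nLow <- floor(params$fracLowDetection * length(truth$trueInteractors))
        lowDet <- sort(truth$trueInteractors[
            sample.int(length(truth$trueInteractors), nLow)])
        coipCols <- grep("^COIP_", sampleIds)
        for (pp in lowDet) {
            # keep at most 2 bait samples observed -> rate <= 2/nCoip < 0.6
            kill <- sample(coipCols, length(coipCols) - 2L)
            drop$linear[pp, kill] <- 0
            drop$missing[pp, kill] <- TRUE
        }
        table <- ProteinQuantTable(drop$linear, proteinIds = ids,
                                   sampleIds = sampleIds,
                                   scaleTag = "linear",
                                   provenance = list(list(step = "simulate",
                                                          kind = "coip")))
        design <- StudyDesign(
            sample_id = sampleIds,
            condition = c(rep("IGG_CTRL", params$nIgg),
                          rep("COIP_BAIT", params$nCoip)),
            replicate = c(seq_len(params$nIgg), seq_len(params$nCoip)))
        list(table = table, design = design, lowDetection = lowDet)
    })
}

#' Generate a synthetic nucleotide-loading experiment
#'
#' Paired bait pulldowns from GTPgammaS- and GDPbetaS-loaded portions of
#' the same lysate: the two members of a pair share a per-protein lysate
#' random effect (SD \code{pairSd}), state-dependent true interactors gain
#' \code{stateEffect} log2 units in the GTPgammaS member only, and
#' independent residual noise (SD \code{loadingNoiseSd}) is added per
#' sample.
#'
#' @inheritParams generateCoip
#' @param seed optional seed (defaults to \code{params$seed + 2}).
#' @return list with \code{table} and \code{design} (pair ids
#'   \code{"pair1"}, ...).
#' @export
generateLoading <- function(params, truth, seed = NULL) {
    stopifnot(inherits(params, "SimParams"))
    if (is.null(seed) && !is.null(params$seed))
        seed <- params$seed + 2L
    .withSeed(seed, {
        n <- params$nProteins
        ids <- names(truth$baselines)
        effects <- stats::setNames(numeric(n), ids)
        effects[truth$trueInteractors] <- truth$log2fc
        state <- stats::setNames(numeric(n), ids)
        state[truth$stateDependent] <- params$stateEffect
        nP <- params$nPairs
        gtpIds <- sprintf("GTPGS_%d", seq_len(nP))
        gdpIds <- sprintf("GDPBS_%d", seq_len(nP))
        log2mat <- matrix(NA_real_, n, 2L * nP,
                          dimnames = list(ids, c(gtpIds, gdpIds)))
        for (p in seq_len(nP)) {
            lysate <- stats::rnorm(n, sd = params$pairSd)
            base <- truth$baselines + effects + lysate
            log2mat[, gtpIds[p]] <- base + state +
                stats::rnorm(n, sd = params$loadingNoiseSd)
            log2mat[, gdpIds[p]] <- base +
                stats::rnorm(n, sd = params$loadingNoiseSd)
        }
        drop <- .applyDropout(log2mat, params)
        table <- ProteinQuantTable(drop$linear, proteinIds = ids,
                                   sampleIds = colnames(log2mat),
                                   scaleTag = "linear",
                                   provenance = list(list(step = "simulate",
                                                          kind = "loading")))
        design <- StudyDesign(
            sample_id = c(gtpIds, gdpIds),
            condition = c(rep("BAIT_GTPGS", nP), rep("BAIT_GDPBS", nP)),
            replicate = c(seq_len(nP), seq_len(nP)),
            pair_id = c(sprintf("pair%d", seq_len(nP)),
                        sprintf("pair%d", seq_len(nP))))
        list(table = table, design = design)
    })
}
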