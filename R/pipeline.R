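## End-to-end orchestration on synthetic data with planted ground truth.

#' Run the full mechanism-of-action pipeline on synthetic data
#'
#' Generates a signed network, plants a regulator (the node with the
#' largest unambiguous depth-2 downstream reach, activated by the insult
#' and inhibited by the compound), simulates the insult and treatment
#' factorial experiments, and runs every analysis stream: quantile
#' normalisation, factorial differential expression with within-gene FWER
#' and the p* rule, DEG selection, gene-set over-representation, TF
#' activity scoring, causal reasoning at the final two timepoints with
#' consensus pooling, similarity-based target prediction on a synthetic
#' bioactivity corpus, reversal analysis, and three-stream evidence
#' integration against a process map containing the planted process and two
#' decoys.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param nNodes,meanOutDegree,inhibitoryFraction network parameters.
#' @param effectSize,noiseSd,plateSd,nBackgroundGenes experiment parameters.
#' @param lfcMin,pMax DEG thresholds.
#' @param deltaMax,nPerm causal-reasoning parameters.
#' @param quantileNormalize whether to quantile-normalise before fitting.
#' @return list with the intermediate results of every stage, the planted
#'   truth, and the final process ranking.
#' @export
runPipeline <- function(seed = 1L, nNodes = 120L, meanOutDegree = 3,
                        inhibitoryFraction = 0.3, effectSize = 2,
                        noiseSd = 0.3, plateSd = 0.2,
                        nBackgroundGenes = 300L, lfcMin = 1.5, pMax = 0.05,
                        deltaMax = 5L, nPerm = 1000L,
                        quantileNormalize = TRUE) {
    network <- simulateNetwork(nNodes, meanOutDegree, inhibitoryFraction,
                               seed = seed)
    ## plant the regulator with the widest unambiguous depth-2 reach
    reach <- vapply(nodes(network), function(h)
        sum(predictDownstream(network, h, 1L, 2L) != 0L), numeric(1))
    regulator <- names(reach)[which.max(reach)]
    seedExp <- simulateExperiment(
        network, data.frame(protein = regulator, sign = 1L),
        effectSize = effectSize, noiseSd = noiseSd,
        design = makeFactorialDesign(condition = "seed-vs-control"),
        plateSd = plateSd, nBackgroundGenes = nBackgroundGenes,
        seed = seed * 13L + 1L)
    treatExp <- simulateExperiment(
        network, data.frame(protein = regulator, sign = -1L),
        effectSize = effectSize, noiseSd = noiseSd,
        design = makeFactorialDesign(condition = "compound-vs-vehicle"),
        plateSd = plateSd, nBackgroundGenes = nBackgroundGenes,
        seed = seed * 13L + 2L)
    runDge <- function(exp) {
        m <- SummarizedExperiment::assay(exp$se)
        if (quantileNormalize) m <- normalizeQuantile(m)
        fit <- fitFactorialModel(m,
            as.data.frame(SummarizedExperiment::colData(exp$se)))
        fit <- adjustWithinGene(fit, seed = seed)
        ps <- pstarProcedure(contrastTable(fit))
        list(fit = fit, pstar = ps, table = ps$table)
    }
    seedDge <- runDge(seedExp)
    treatDge <- runDge(treatExp)
    degs <- selectDegs(treatDge$table, lfcMin = lfcMin, pMax = pMax)
    allGenes <- rownames(SummarizedExperiment::assay(treatExp$se))
    contrasts <- treatDge$fit$contrasts
    lastContrast <- contrasts[length(contrasts)]
    prevContrast <- contrasts[length(contrasts) - 1L]
    degGenes <- unique(degs$gene[degs$contrast == lastContrast])
    ## discrete observed states over network genes for causal reasoning
    observedStates <- function(tab, contrast) {
        sub <- tab[tab$contrast == contrast &
                   tab$gene %in% nodes(network), , drop = FALSE]
        st <- ifelse(abs(sub$log2FC) >= lfcMin & sub$fwerP <= pMax,
                     sign(sub$log2FC), 0L)
        setNames(as.integer(st), sub$gene)
    }
    obsLast <- observedStates(treatDge$table, lastContrast)
    obsPrev <- observedStates(treatDge$table, prevContrast)
    ## gene sets built around the planted perturbation
    gs <- simulateGenesets(perturbedGenes(treatExp$truth)$gene, allGenes,
                           seed = seed * 13L + 3L)
    enrichment <- overrepresentation(degGenes, allGenes, gs$sets)
    ann <- simulateAnnotations(network,
                               perturbedGenes(treatExp$truth)$gene,
                               allGenes = allGenes,
                               seed = seed * 13L + 4L)
    ## TF activity on the final-timepoint measurements
    measLast <- treatDge$table[treatDge$table$contrast == lastContrast, ]
    tfa <- tfActivity(data.frame(gene = measLast$gene,
                                 log2FC = measLast$log2FC,
                                 p = measLast$fwerP),
                      ann$regulons, seed = seed)
    tfa <- discretizeActivity(tfa)
    ## causal reasoning at the final two timepoints, pooled
    rankLast <- rankHypotheses(network, obsLast, deltaMax = deltaMax,
                               nPerm = nPerm, seed = seed)
    rankPrev <- rankHypotheses(network, obsPrev, deltaMax = deltaMax,
                               nPerm = nPerm, seed = seed)
    consLast <- consensusNodes(rankLast)
    consPrev <- consensusNodes(rankPrev)
    pooled <- poolSetups(list(final = consLast, previous = consPrev),
                         minFrequency = 1L, network = network)
    ## structure-based target prediction on the synthetic corpus
    predictions <- predictTargets(ann$queryFingerprint, ann$bioactivity,
                                  fingerprints = ann$fingerprints)
    ## process map: the planted process plus two decoys
    set.seed(seed * 13L + 5L)
    others <- setdiff(nodes(network),
                      c(regulator, perturbedGenes(treatExp$truth)$gene))
    decoySets <- setdiff(names(gs$sets), gs$enriched)
    processMap <- list(
        planted = list(genes = c(regulator, ann$activeTarget),
                       pathways = gs$enriched),
        decoyA = list(genes = c(sample(others, 2L), "T04"),
                      pathways = sample(decoySets, 2L)),
        decoyB = list(genes = c(sample(others, 2L), "T05"),
                      pathways = sample(decoySets, 2L)))
    evidence <- buildEvidenceMatrix(predictions, pooled$pooled, enrichment,
                                    processMap)
    processRanking <- rankProcessHypotheses(evidence)
    ## reversal between the insult and treatment signatures
    sigTab <- function(dge) {
        sub <- dge$table[dge$table$contrast == lastContrast, ]
        data.frame(gene = sub$gene, log2FC = sub$log2FC,
                   significant = abs(sub$log2FC) >= lfcMin &
                       sub$fwerP <= pMax)
    }
    reversal <- reversalAnalysis(sigTab(seedDge), sigTab(treatDge))
    list(network = network, regulator = regulator,
         truth = treatExp$truth, seedExperiment = seedExp,
         treatmentExperiment = treatExp, seedDge = seedDge,
         treatmentDge = treatDge, degs = degs, genesets = gs,
         enrichment = enrichment, annotations = ann, tfActivity = tfa,
         causal = list(final = rankLast, previous = rankPrev),
         consensus = list(final = consLast, previous = consPrev),
         pooled = pooled, predictions = predictions,
         processMap = processMap, evidence = evidence,
         processRanking = processRanking, reversal = reversal)
}
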