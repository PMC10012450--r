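## Synthetic-data generators with planted ground truth. These emulate the
## data model of a 2-treatment x 3-timepoint factorial perturbation
## experiment on cultured neurons: a signed regulatory network, planted
## active regulators whose downstream targets shift in a sign- and
## time-dependent way, gene sets and annotations consistent with the
## network, and a bioactivity corpus containing near neighbours of a query
## compound. Expression is generated directly on the log2 scale.

#' Simulate a signed directed network
#'
#' Draws approximately \code{nNodes * meanOutDegree} distinct ordered node
#' pairs uniformly (no self-loops, at most one edge per ordered pair, so no
#' opposite-sign parallel edges), each inhibitory with probability
#' \code{inhibitoryFraction}. Deterministic for a fixed seed.
#'
#' @param nNodes number of proteins (>= 2).
#' @param meanOutDegree expected out-degree (> 0).
#' @param inhibitoryFraction probability an edge is inhibitory, in [0, 1].
#' @param seed RNG seed.
#' @param nodePrefix prefix for the synthetic protein identifiers.
#' @return A [SignedNetwork-class].
#' @examples
#' net <- simulateNetwork(50, 3, 0.3, seed = 1)
#' @export
simulateNetwork <- function(nNodes, meanOutDegree, inhibitoryFraction = 0.3,
                            seed = 1L, nodePrefix = "P") {
    if (nNodes < 2L) stop("nNodes must be >= 2")
    if (meanOutDegree <= 0) stop("meanOutDegree must be positive")
    if (inhibitoryFraction < 0 || inhibitoryFraction > 1)
        stop("inhibitoryFraction must lie in [0, 1]")
    nEdges <- round(nNodes * meanOutDegree)
    maxEdges <- nNodes * (nNodes - 1L)
    if (nEdges > maxEdges)
        stop("meanOutDegree too large for ", nNodes, " nodes")
    nodesv <- sprintf("%s%04d", nodePrefix, seq_len(nNodes))
    set.seed(seed)
    code <- sample.int(maxEdges, nEdges)        # ordered pairs, no diagonal
    from <- (code - 1L) %/% (nNodes - 1L) + 1L
    off <- (code - 1L) %% (nNodes - 1L) + 1L
    to <- ifelse(off >= from, off + 1L, off)
    sgn <- ifelse(runif(nEdges) < inhibitoryFraction, -1L, 1L)
    SignedNetwork(data.frame(from = nodesv[from], to = nodesv[to],
                             sign = sgn),
                  nodes = nodesv)
}

#' Build a balanced factorial design table
#'
#' Two treatments crossed with timepoints (days in vitro), with a fixed
#' number of replicates per cell; replicate r of every cell sits on plate r,
#' so plates are balanced across treatment and time.
#'
#' @param replicates replicates per treatment x DIV cell (>= 2).
#' @param divs days-in-vitro levels.
#' @param treatments two treatment labels; the second receives the planted
#'   effect in [simulateExperiment()].
#' @param condition experiment-level condition label (e.g. "seeded").
#' @return data.frame with columns \code{sample}, \code{treatment},
#'   \code{condition}, \code{div}, \code{plate}, \code{replicate}.
#' @export
makeFactorialDesign <- function(replicates = 3L, divs = c(3L, 7L, 14L),
                                treatments = c("vehicle", "compound"),
                                condition = "seeded") {
    if (replicates < 2L) stop("need >= 2 replicates per factorial cell")
    if (length(treatments) != 2L) stop("exactly two treatment levels")
    g <- expand.grid(replicate = seq_len(replicates), div = divs,
                     treatment = treatments, stringsAsFactors = FALSE)
    data.frame(sample = sprintf("S_%s_d%02d_r%d", g$treatment, g$div,
                                g$replicate),
               treatment = g$treatment, condition = condition,
               div = as.integer(g$div), plate = sprintf("PL%d", g$replicate),
               replicate = g$replicate, stringsAsFactors = FALSE)
}

#' Simulate a factorial perturbation experiment with planted regulators
#'
#' Genes downstream of the planted regulators (within
#' \code{propagationDepth} signed shortest-path steps; sign-ambiguous genes
#' are left unperturbed) receive a treatment-dependent mean shift whose sign
#' is the regulator sign times the path sign product and whose magnitude is
#' \code{effectSize} scaled by timepoint (linearly in DIV, reaching
#' \code{effectSize} at the last timepoint, so effects grow with time in
#' culture). A scalar plate effect is drawn once per plate with standard
#' deviation \code{plateSd}; Gaussian residual noise has standard deviation
#' \code{noiseSd}. Background genes outside the network are never perturbed.
#'
#' @param network a [SignedNetwork-class]; its nodes double as gene ids.
#' @param regulators data.frame with columns \code{protein}, \code{sign},
#'   or a named sign vector; must be network nodes. May be empty (null
#'   model).
#' @param effectSize mean |log2FC| at the final timepoint.
#' @param noiseSd residual standard deviation (log2 units).
#' @param design design table from [makeFactorialDesign()].
#' @param plateSd plate-effect standard deviation.
#' @param nBackgroundGenes unperturbed genes added outside the network.
#' @param propagationDepth planting depth (default 2: regulator -> TF ->
#'   transcript).
#' @param seed RNG seed.
#' @return list with \code{se} (a
#'   \linkS4class{SummarizedExperiment}; assay \code{"log2expr"}, colData =
#'   design) and \code{truth} (a [GroundTruth-class]).
#' @export
simulateExperiment <- function(network, regulators, effectSize = 2,
                               noiseSd = 0.3,
                               design = makeFactorialDesign(),
                               plateSd = 0.2, nBackgroundGenes = 350L,
                               propagationDepth = 2L, seed = 1L) {
    stopifnot(is(network, "SignedNetwork"))
    if (noiseSd < 0 || plateSd < 0) stop("noise parameters must be >= 0")
    if (is.numeric(regulators) && !is.null(names(regulators)))
        regulators <- data.frame(protein = names(regulators),
                                 sign = as.integer(regulators))
    if (is.null(regulators))
        regulators <- data.frame(protein = character(0), sign = integer(0))
    if (nrow(regulators) && !all(regulators$protein %in% nodes(network)))
        stop("all regulators must be network nodes")
    ## expected signed shift per downstream gene, summed over regulators
    total <- setNames(numeric(length(nodes(network))), nodes(network))
    depth <- setNames(rep(NA_integer_, length(nodes(network))),
                      nodes(network))
    for (r in seq_len(nrow(regulators))) {
        st <- predictDownstream(network, regulators$protein[r],
                                regulators$sign[r],
                                delta = propagationDepth)
        total[names(st)] <- total[names(st)] + st
        d <- attr(st, "dist")
        depth[names(d)] <- pmin(depth[names(d)], d, na.rm = TRUE)
    }
    netSign <- sign(total)
    perturbed <- names(netSign)[netSign != 0]
    genes <- c(nodes(network),
               if (nBackgroundGenes > 0)
                   sprintf("BG%04d", seq_len(nBackgroundGenes)))
    set.seed(seed)
    mu <- rnorm(length(genes), mean = 7, sd = 1.5)
    names(mu) <- genes
    plates <- unique(design$plate)
    plateEff <- setNames(rnorm(length(plates), 0, plateSd), plates)
    trt2 <- unique(design$treatment)[2]     # the perturbed arm
    mat <- matrix(rnorm(length(genes) * nrow(design), 0, noiseSd),
                  length(genes), nrow(design),
                  dimnames = list(genes, design$sample))
    mat <- mat + mu
    mat <- sweep(mat, 2, plateEff[design$plate], "+")
    shift <- setNames(rep(0, length(genes)), genes)
    shift[perturbed] <- netSign[perturbed] * effectSize
    for (j in seq_len(nrow(design)))
        if (design$treatment[j] == trt2)
            mat[, j] <- mat[, j] +
                shift * (design$div[j] / max(design$div))
    truth <- GroundTruth(
        regulators = regulators, effectSize = effectSize,
        perturbed = data.frame(gene = perturbed,
                               sign = as.integer(netSign[perturbed]),
                               depth = as.integer(depth[perturbed])))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = mat),
        colData = S4Vectors::DataFrame(design, row.names = design$sample))
    list(se = se, truth = truth)
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Enriched sets draw a configurable majority (\code{purity}) of their
#' members from the perturbed genes; background sets draw uniformly from all
#' genes. The result is GMT-serialisable via [writeGmt()].
#'
#' @param perturbedGenes character vector, a subset of \code{allGenes}.
#' @param allGenes the measured gene universe.
#' @param nSets total number of sets.
#' @param setSizeRange integer interval of set sizes.
#' @param enrichedFraction fraction of sets built to be enriched.
#' @param purity fraction of an enriched set drawn from the perturbed genes.
#' @param seed RNG seed.
#' @return list with \code{sets} (named list of character vectors) and
#'   \code{enriched} (ids of the truly enriched sets).
#' @export
simulateGenesets <- function(perturbedGenes, allGenes, nSets = 50L,
                             setSizeRange = c(10L, 40L),
                             enrichedFraction = 0.2, purity = 0.8,
                             seed = 1L) {
    if (!all(perturbedGenes %in% allGenes))
        stop("perturbedGenes must be a subset of allGenes")
    if (max(setSizeRange) > length(allGenes))
        stop("setSizeRange exceeds the size of allGenes")
    if (enrichedFraction < 0 || enrichedFraction > 1)
        stop("enrichedFraction must lie in [0, 1]")
    set.seed(seed)
    nEnriched <- round(nSets * enrichedFraction)
    ids <- sprintf("SET%03d", seq_len(nSets))
    enrichedIdx <- if (nEnriched > 0) sort(sample.int(nSets, nEnriched))
                   else integer(0)
    rest <- setdiff(allGenes, perturbedGenes)
    sets <- vector("list", nSets)
    names(sets) <- ids
    for (i in seq_len(nSets)) {
        sz <- sample(seq(setSizeRange[1], setSizeRange[2]), 1L)
        if (i %in% enrichedIdx) {
            nPert <- min(round(purity * sz), length(perturbedGenes))
            sets[[i]] <- c(sample(perturbedGenes, nPert),
                           sample(rest, sz - nPert))
        } else {
            sets[[i]] <- sample(allGenes, sz)
        }
    }
    list(sets = sets, enriched = ids[enrichedIdx])
}

## Synthetic fingerprint with a controlled Tanimoto similarity to `query`:
## keep the query's bit count B and share i = round(2*B*s / (1+s)) bits, so
## T = i / (2B - i) is as close to s as the integer lattice allows.
.fingerprintNear <- function(query, similarity) {
    qb <- fpBits(query)
    B <- length(qb)
    i <- round(2 * B * similarity / (1 + similarity))
    keep <- if (i > 0) sample(qb, i) else integer(0)
    pool <- setdiff(seq_len(fpLength(query)), qb)
    Fingerprint(c(keep, sample(pool, B - i)), nbits = fpLength(query),
                source = "synthetic")
}

#' Simulate annotation resources consistent with a network
#'
#' Generates the side inputs of the pipeline with controlled properties: an
#' ortholog map with configured counts of 1:1, 1:many and many:1 mappings; a
#' scored disease-association gene list whose overlap with the perturbed
#' genes has a configured odds ratio; TF regulons equal to the network's
#' signed edges; a sparse pathway coefficient matrix whose first pathway is
#' aligned with the perturbed genes; and a bioactivity corpus of synthetic
#' fingerprint bit-vectors with controlled Tanimoto similarity to a query
#' compound, with the high-similarity neighbours active on a planted target.
#'
#' @param network a [SignedNetwork-class].
#' @param perturbedGenes genes perturbed in the companion experiment.
#' @param allGenes measured gene universe (defaults to the network nodes).
#' @param seed RNG seed.
#' @param nOneToMany source ids mapped to two target ids.
#' @param nManyToOne source-id pairs sharing one target id.
#' @param diseaseOddsRatio odds ratio of disease membership for perturbed vs
#'   other genes (1 = independence).
#' @param diseaseBaseRate disease membership probability for unperturbed
#'   genes.
#' @param nCompounds corpus size.
#' @param nTargets number of protein targets with bioactivity data.
#' @param neighbourSimilarities Tanimoto similarities of the planted
#'   near-neighbour compounds to the query.
#' @param nbits fingerprint length.
#' @param queryBits set bits in the query fingerprint.
#' @param activeThreshold activity value (uM) given to planted actives.
#' @return list with elements \code{orthologs} (source, target),
#'   \code{disease} (gene, score), \code{regulons} (tf, target, sign),
#'   \code{pathwayCoefficients} (matrix), \code{bioactivity} (compound,
#'   target, activity_uM, fingerprint hex), \code{queryFingerprint}
#'   ([Fingerprint-class]) and \code{activeTarget}.
#' @export
simulateAnnotations <- function(network, perturbedGenes,
                                allGenes = nodes(network), seed = 1L,
                                nOneToMany = 3L, nManyToOne = 3L,
                                diseaseOddsRatio = 3, diseaseBaseRate = 0.15,
                                nCompounds = 30L, nTargets = 6L,
                                neighbourSimilarities =
                                    c(1.0, 0.8, 0.7, 0.6, 0.5, 0.4),
                                nbits = 2048L, queryBits = 48L,
                                activeThreshold = 1) {
    set.seed(seed)
    genes <- allGenes
    if (nOneToMany + 2L * nManyToOne > length(genes))
        stop("not enough genes for the requested mapping structure")
    ## ortholog map: default 1:1, then planted 1:many and many:1 blocks
    special <- sample(genes, nOneToMany + 2L * nManyToOne)
    oneToMany <- head(special, nOneToMany)
    manyToOne <- matrix(utils::tail(special, 2L * nManyToOne), ncol = 2L)
    plain <- setdiff(genes, special)
    orth <- rbind(
        data.frame(source = plain, target = paste0("h_", plain)),
        data.frame(source = rep(oneToMany, each = 2L),
                   target = paste0("h_", rep(oneToMany, each = 2L),
                                   c("", "b"))),
        data.frame(source = as.vector(manyToOne),
                   target = rep(paste0("h_shared",
                                       seq_len(nManyToOne)), 2L)))
    rownames(orth) <- NULL
    ## disease list with controlled odds ratio against perturbed genes
    p0 <- diseaseBaseRate
    odds1 <- diseaseOddsRatio * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    prob <- ifelse(genes %in% perturbedGenes, p1, p0)
    inDisease <- runif(length(genes)) < prob
    disease <- data.frame(gene = genes[inDisease],
                          score = round(runif(sum(inDisease)), 3))
    ## regulons: the network's signed TF -> target edges
    e <- edges(network)
    regulons <- data.frame(tf = e$from, target = e$to, sign = e$sign)
    ## pathway coefficients: pathway 1 aligned with the perturbation
    nPath <- 8L
    coef <- matrix(0, nPath, length(genes),
                   dimnames = list(sprintf("PW%02d", seq_len(nPath)), genes))
    if (length(perturbedGenes))
        coef[1L, perturbedGenes] <- 1
    for (i in 2:nPath) {
        picked <- sample(genes, min(20L, length(genes)))
        coef[i, picked] <- round(rnorm(length(picked), 0, 0.5), 3)
    }
    ## bioactivity corpus with controlled similarity to the query
    query <- Fingerprint(sample.int(nbits, queryBits), nbits = nbits,
                         source = "synthetic")
    compounds <- sprintf("C%03d", seq_len(nCompounds))
    nNb <- length(neighbourSimilarities)
    if (nNb >= nCompounds) stop("need more compounds than neighbours")
    fps <- vector("list", nCompounds)
    names(fps) <- compounds
    for (i in seq_len(nNb))
        fps[[i]] <- .fingerprintNear(query, neighbourSimilarities[i])
    for (i in seq(nNb + 1L, nCompounds))
        fps[[i]] <- Fingerprint(sample.int(nbits, queryBits), nbits = nbits,
                                source = "synthetic")
    targets <- sprintf("T%02d", seq_len(nTargets))
    activeTarget <- targets[1L]
    g <- expand.grid(compound = compounds, target = targets,
                     stringsAsFactors = FALSE)
    active <- g$target == activeTarget &
        match(g$compound, compounds) <= nNb
    act <- round(runif(nrow(g), 50, 500), 1)
    act[active] <- round(runif(sum(active), 0.1, 1) * activeThreshold, 3)
    hex <- vapply(fps, fingerprintToHex, character(1))
    bio <- data.frame(compound = g$compound, target = g$target,
                      activity_uM = act,
                      fingerprint = unname(hex[g$compound]))
    list(orthologs = orth, disease = disease, regulons = regulons,
         pathwayCoefficients = coef, bioactivity = bio,
         queryFingerprint = query, fingerprints = fps,
         activeTarget = activeTarget)
}
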