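#' @import methods
#' @importFrom stats p.adjust phyper pt rnorm rchisq runif setNames fisher.test
#'   rbinom quantile sd
#' @importFrom utils head read.table write.table
NULL

#' Signed directed protein-interaction network
#'
#' A directed graph whose edges carry a regulatory sign: \code{+1} for
#' activation, \code{-1} for inhibition. This is the substrate for causal
#' reasoning: observed transcriptional changes are explained by propagating a
#' hypothetical up- or down-regulation of a protein along signed shortest
#' paths.
#'
#' Validity rules: edge signs are exactly \code{+1} or \code{-1}; self-loops
#' are not allowed; at most one edge per ordered node pair, so parallel edges
#' of opposite sign cannot occur.
#'
#' @slot nodes character vector of protein identifiers.
#' @slot edges data.frame with columns \code{from}, \code{to} (node ids) and
#'   \code{sign} (integer, +1 or -1).
#'
#' @seealso [simulateNetwork()], [readSif()], [predictDownstream()]
#' @export
setClass("SignedNetwork",
    representation(nodes = "character", edges = "data.frame"))

setValidity("SignedNetwork", function(object) {
    e <- object@edges
    msg <- character(0)
    if (!all(c("from", "to", "sign") %in% names(e)))
        return("edges must have columns 'from', 'to', 'sign'")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicated node identifiers")
    if (nrow(e)) {
        if (!all(e$sign %in% c(-1L, 1L)))
            msg <- c(msg, "edge signs must be +1 or -1")
        if (any(e$from == e$to))
            msg <- c(msg, "self-loops are not allowed")
        if (anyDuplicated(e[, c("from", "to")]))
            msg <- c(msg, "parallel edges between the same ordered pair")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be network nodes")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SignedNetwork
#'
#' @param nodes character vector of node identifiers. Defaults to the union of
#'   edge endpoints.
#' @param edges data.frame with columns \code{from}, \code{to}, \code{sign}.
#' @return A [SignedNetwork-class] object.
#' @examples
#' net <- SignedNetwork(edges = data.frame(
#'     from = c("A", "B"), to = c("B", "C"), sign = c(1L, -1L)))
#' nodes(net)
#' @export
SignedNetwork <- function(edges, nodes = NULL) {
    edges <- as.data.frame(edges)
    if (nrow(edges)) {
        edges$from <- as.character(edges$from)
        edges$to <- as.character(edges$to)
        edges$sign <- as.integer(edges$sign)
    } else {
        edges <- data.frame(from = character(0), to = character(0),
                            sign = integer(0))
    }
    if (is.null(nodes))
        nodes <- unique(c(edges$from, edges$to))
    rownames(edges) <- NULL
    new("SignedNetwork", nodes = as.character(nodes), edges = edges)
}

#' @describeIn SignedNetwork node identifiers
#' @param x a \code{SignedNetwork}
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname SignedNetwork
#' @export
setMethod("nodes", "SignedNetwork", function(x) x@nodes)

#' @describeIn SignedNetwork signed edge table
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname SignedNetwork
#' @export
setMethod("edges", "SignedNetwork", function(x) x@edges)

setMethod("show", "SignedNetwork", function(object) {
    e <- object@edges
    cat("SignedNetwork with", length(object@nodes), "nodes and",
        nrow(e), "signed edges\n")
    if (nrow(e))
        cat(sprintf("  activating: %d  inhibitory: %d\n",
                    sum(e$sign == 1L), sum(e$sign == -1L)))
})

#' Planted ground truth of a synthetic experiment
#'
#' Records everything the synthetic-data generator planted, so downstream
#' stages can be scored against a known answer: which regulators were
#' activated or inhibited, which genes should respond (and in which
#' direction), which gene sets were built to be enriched, and which
#' compound-target pairs were set active.
#'
#' @slot regulators data.frame with columns \code{protein}, \code{sign}.
#' @slot effectSize mean |log2 fold change| induced on downstream targets at
#'   the final timepoint.
#' @slot perturbed data.frame with columns \code{gene}, \code{sign},
#'   \code{depth} (shortest signed path length from a planted regulator).
#' @slot enrichedSets identifiers of gene sets constructed to be enriched.
#' @slot activeTargets data.frame of compound-target pairs set active.
#'
#' @export
setClass("GroundTruth",
    representation(regulators = "data.frame", effectSize = "numeric",
                   perturbed = "data.frame", enrichedSets = "character",
                   activeTargets = "data.frame"))

setValidity("GroundTruth", function(object) {
    msg <- character(0)
    if (nrow(object@regulators) &&
        !all(object@regulators$sign %in% c(-1L, 1L)))
        msg <- c(msg, "regulator signs must be +1 or -1")
    if (length(msg)) msg else TRUE
})

GroundTruth <- function(regulators = data.frame(protein = character(0),
                                                sign = integer(0)),
                        effectSize = numeric(0),
                        perturbed = data.frame(gene = character(0),
                                               sign = integer(0),
                                               depth = integer(0)),
                        enrichedSets = character(0),
                        activeTargets = data.frame(compound = character(0),
                                                   target = character(0))) {
    new("GroundTruth", regulators = regulators, effectSize = effectSize,
        perturbed = perturbed, enrichedSets = enrichedSets,
        activeTargets = activeTargets)
}

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@regulators), "planted regulator(s),",
        nrow(object@perturbed), "perturbed gene(s),",
        length(object@enrichedSets), "enriched set(s)\n")
})

#' @describeIn GroundTruth planted regulator table
#' @param x a \code{GroundTruth}
#' @export
setGeneric("plantedRegulators", function(x) standardGeneric("plantedRegulators"))
#' @rdname GroundTruth
#' @export
setMethod("plantedRegulators", "GroundTruth", function(x) x@regulators)

#' @describeIn GroundTruth perturbed gene table (gene, expected sign, depth)
#' @export
setGeneric("perturbedGenes", function(x) standardGeneric("perturbedGenes"))
#' @rdname GroundTruth
#' @export
setMethod("perturbedGenes", "GroundTruth", function(x) x@perturbed)

#' @describeIn GroundTruth ids of gene sets built to be enriched
#' @export
setGeneric("enrichedSets", function(x) standardGeneric("enrichedSets"))
#' @rdname GroundTruth
#' @export
setMethod("enrichedSets", "GroundTruth", function(x) x@enrichedSets)

#' @describeIn GroundTruth compound-target pairs planted active
#' @export
setGeneric("activeTargets", function(x) standardGeneric("activeTargets"))
#' @rdname GroundTruth
#' @export
setMethod("activeTargets", "GroundTruth", function(x) x@activeTargets)

#' Binary molecular fingerprint
#'
#' A fixed-length bit vector encoding circular substructures of a molecule
#' (ECFP4-equivalent when derived from a structure with
#' [fingerprintSmiles()]), stored sparsely as the sorted positions of the set
#' bits (1-based). Synthetic corpora may carry fingerprints that are plain
#' bit vectors with no structural meaning; the \code{source} tag records
#' which kind this is.
#'
#' @slot bits sorted integer positions (1-based) of the set bits.
#' @slot nbits total fingerprint length (default 2048).
#' @slot source \code{"structure"} or \code{"synthetic"}.
#' @export
setClass("Fingerprint",
    representation(bits = "integer", nbits = "integer", source = "character"))

setValidity("Fingerprint", function(object) {
    msg <- character(0)
    if (length(object@nbits) != 1L || object@nbits < 1L)
        msg <- c(msg, "nbits must be a single positive integer")
    else if (length(object@bits) &&
             (min(object@bits) < 1L || max(object@bits) > object@nbits))
        msg <- c(msg, "bit positions must lie in [1, nbits]")
    if (is.unsorted(object@bits, strictly = TRUE))
        msg <- c(msg, "bits must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Construct a Fingerprint from set-bit positions
#'
#' @param bits integer positions (1-based) of set bits.
#' @param nbits fingerprint length.
#' @param source provenance tag, \code{"structure"} or \code{"synthetic"}.
#' @return A [Fingerprint-class] object.
#' @examples
#' fp <- Fingerprint(c(3L, 17L, 101L), nbits = 2048L)
#' @export
Fingerprint <- function(bits, nbits = 2048L, source = "synthetic") {
    new("Fingerprint", bits = sort(unique(as.integer(bits))),
        nbits = as.integer(nbits), source = source)
}

setMethod("show", "Fingerprint", function(object) {
    cat(sprintf("Fingerprint: %d/%d bits set (%s)\n", length(object@bits),
                object@nbits, object@source))
})

#' @describeIn Fingerprint positions of the set bits
#' @param x a \code{Fingerprint}
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))
#' @rdname Fingerprint
#' @export
setMethod("fpBits", "Fingerprint", function(x) x@bits)

#' @describeIn Fingerprint fingerprint length in bits
#' @export
setGeneric("fpLength", function(x) standardGeneric("fpLength"))
#' @rdname Fingerprint
#' @export
setMethod("fpLength", "Fingerprint", function(x) x@nbits)

#' Consensus causal subnetwork
#'
#' The union, over all consensus regulator hypotheses, of every
#' sign-concordant shortest path from a consensus node to an observed entity
#' it explains. Edges carry the signs of the source network; nodes carry
#' their role (consensus regulator, intermediate, explained observation) and
#' observed/predicted state.
#'
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{sign}.
#' @slot nodes data.frame with columns \code{node}, \code{role}, \code{state}.
#' @slot provenance data.frame mapping consensus nodes to the observations
#'   they explain.
#' @export
setClass("ConsensusSubnetwork",
    representation(edges = "data.frame", nodes = "data.frame",
                   provenance = "data.frame"))

setMethod("show", "ConsensusSubnetwork", function(object) {
    cat("ConsensusSubnetwork:", nrow(object@nodes), "nodes,",
        nrow(object@edges), "edges;",
        sum(object@nodes$role == "consensus"), "consensus regulator(s),",
        sum(object@nodes$role == "explained"), "explained observation(s)\n")
})

#' @rdname ConsensusSubnetwork-class
#' @param x a \code{ConsensusSubnetwork}
#' @export
setMethod("edges", "ConsensusSubnetwork", function(x) x@edges)

#' @rdname ConsensusSubnetwork-class
#' @export
setMethod("nodes", "ConsensusSubnetwork", function(x) x@nodes$node)
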