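## Reversal analysis, three-stream evidence matrix and process-hypothesis
## ranking.

#' Classify genes by reversal between two signatures
#'
#' Compares a disease/insult signature (e.g. seeded vs unseeded) with a
#' treatment signature (e.g. compound vs vehicle) at the same timepoint and
#' in the same namespace. Genes significant in both with opposite log2FC
#' signs are reversed (\code{reversed-down} when up in the insult and down
#' under treatment, \code{reversed-up} for the converse); same signs are
#' \code{concordant}; significance in only one signature is
#' \code{single-sided}.
#'
#' @param seedSignature,treatmentSignature data.frames with columns
#'   \code{gene}, \code{log2FC}, \code{significant}.
#' @return data.frame with columns \code{gene}, \code{seedLog2FC},
#'   \code{treatmentLog2FC}, \code{class}, one row per gene significant in
#'   at least one signature.
#' @export
reversalAnalysis <- function(seedSignature, treatmentSignature) {
    need <- c("gene", "log2FC", "significant")
    stopifnot(all(need %in% names(seedSignature)),
              all(need %in% names(treatmentSignature)))
    m <- merge(seedSignature[, need], treatmentSignature[, need],
               by = "gene", all = TRUE, suffixes = c(".seed", ".trt"))
    m$significant.seed[is.na(m$significant.seed)] <- FALSE
    m$significant.trt[is.na(m$significant.trt)] <- FALSE
    m <- m[m$significant.seed | m$significant.trt, , drop = FALSE]
    cls <- character(nrow(m))
    both <- m$significant.seed & m$significant.trt
    opp <- both & sign(m$log2FC.seed) != sign(m$log2FC.trt)
    cls[both & !opp] <- "concordant"
    cls[opp & m$log2FC.seed > 0] <- "reversed-down"
    cls[opp & m$log2FC.seed < 0] <- "reversed-up"
    cls[!both] <- "single-sided"
    out <- data.frame(gene = m$gene, seedLog2FC = m$log2FC.seed,
                      treatmentLog2FC = m$log2FC.trt, class = cls)
    rownames(out) <- NULL
    out
}

#' Assemble the three-stream evidence matrix
#'
#' Collects, per biological process, the supporting evidence from the three
#' analysis streams: structure-based target predictions (kept when
#' probability and applicability domain pass their thresholds), pooled
#' causal-reasoning regulators, and significantly enriched pathways. The
#' process map is an explicit, user-supplied input assigning genes/proteins
#' and pathway ids to each named process; the stream count of a process is
#' the number of streams contributing at least one item.
#'
#' @param predictions data.frame from [predictTargets()].
#' @param regulators character vector of pooled regulator ids (e.g.
#'   \code{poolSetups()$pooled}).
#' @param enrichments data.frame from [overrepresentation()].
#' @param processMap named list; each element a list with elements
#'   \code{genes} (protein/target ids) and \code{pathways} (set ids).
#' @param probMin minimum predicted probability for the target stream.
#' @param adMin minimum applicability-domain percentile for the target
#'   stream.
#' @return data.frame with one row per process: the per-stream evidence
#'   (semicolon-collapsed), per-stream counts and \code{streamCount}.
#' @export
buildEvidenceMatrix <- function(predictions, regulators, enrichments,
                                processMap, probMin = 0.5, adMin = 50) {
    if (is.null(processMap) || !length(processMap))
        stop("an explicit process map is required")
    keep <- predictions$probability >= probMin &
        (!is.na(predictions$ad) & predictions$ad >= adMin)
    targets <- unique(predictions$target[keep])
    sigSets <- unique(enrichments$set[enrichments$significant])
    regulators <- unique(as.character(regulators))
    rows <- lapply(names(processMap), function(pr) {
        pm <- processMap[[pr]]
        tg <- intersect(targets, pm$genes)
        rg <- intersect(regulators, pm$genes)
        pw <- intersect(sigSets, pm$pathways)
        data.frame(process = pr,
                   targets = paste(tg, collapse = ";"),
                   regulators = paste(rg, collapse = ";"),
                   pathways = paste(pw, collapse = ";"),
                   nTargets = length(tg), nRegulators = length(rg),
                   nPathways = length(pw),
                   streamCount = (length(tg) > 0) + (length(rg) > 0) +
                       (length(pw) > 0))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Rank process hypotheses by evidence convergence
#'
#' Orders processes by stream count (descending), then total evidence-item
#' count, then label; processes with no evidence are excluded from the
#' headline list. Processes supported by two or more streams form the
#' consensus tier.
#'
#' @param evidence data.frame from [buildEvidenceMatrix()].
#' @return list with \code{ranked} (all processes, ordered),
#'   \code{headline} (stream count >= 1), \code{consensus} (stream count
#'   >= 2) and \code{status} (\code{"ok"} or \code{"no consensus"}).
#' @export
rankProcessHypotheses <- function(evidence) {
    ev <- evidence
    ev$totalItems <- ev$nTargets + ev$nRegulators + ev$nPathways
    ev <- ev[order(-ev$streamCount, -ev$totalItems, ev$process), ,
             drop = FALSE]
    rownames(ev) <- NULL
    headline <- ev[ev$streamCount >= 1L, , drop = FALSE]
    consensus <- ev[ev$streamCount >= 2L, , drop = FALSE]
    list(ranked = ev, headline = headline, consensus = consensus,
         status = if (nrow(headline)) "ok" else "no consensus")
}
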