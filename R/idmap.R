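## Ortholog mapping of per-gene measurements between identifier namespaces.

#' Map per-gene measurements across an ortholog table
#'
#' Applies the expansion-then-aggregation rule: a source gene mapping to
#' several target genes has its measurement row duplicated for each target
#' (expansion); several source genes sharing one target are aggregated by
#' the arithmetic mean of their log2FC and of their p-values. Unmapped
#' source ids are dropped and counted. Averaging p-values mirrors the
#' mapping convention used with programmatic enrichment pipelines and is
#' statistically improper; a Fisher combination is available behind
#' \code{combineP = "fisher"} (default off).
#'
#' @param table data.frame keyed by the source namespace, with columns
#'   \code{gene}, \code{log2FC}, \code{p}.
#' @param map data.frame with columns \code{source}, \code{target}
#'   (many-to-many allowed; duplicate pairs are dropped).
#' @param combineP \code{"mean"} (the stated rule) or \code{"fisher"}.
#' @return data.frame in the target namespace with columns \code{gene},
#'   \code{log2FC}, \code{p}, \code{nSources}; the dropped source ids are in
#'   attribute \code{"unmapped"}.
#' @examples
#' tab <- data.frame(gene = c("R1", "R2", "R3"),
#'                   log2FC = c(2, 2, 4), p = c(0.01, 0.02, 0.04))
#' map <- data.frame(source = c("R1", "R1", "R2", "R3"),
#'                   target = c("H1", "H2", "H3", "H3"))
#' mapMeasurements(tab, map)
#' @export
mapMeasurements <- function(table, map, combineP = c("mean", "fisher")) {
    combineP <- match.arg(combineP)
    if (is.null(map) || !nrow(map)) stop("empty ortholog map")
    stopifnot(all(c("source", "target") %in% names(map)),
              all(c("gene", "log2FC", "p") %in% names(table)))
    map <- unique(map[, c("source", "target")])
    unmapped <- setdiff(table$gene, map$source)
    ## expansion: one row per (source, target) pair
    exp <- merge(table, map, by.x = "gene", by.y = "source")
    if (!nrow(exp)) {
        out <- data.frame(gene = character(0), log2FC = numeric(0),
                          p = numeric(0), nSources = integer(0))
        attr(out, "unmapped") <- unmapped
        return(out)
    }
    ## aggregation: many source rows per target collapse to their mean
    tgt <- factor(exp$target)
    lfc <- tapply(exp$log2FC, tgt, mean)
    pv <- if (combineP == "mean") tapply(exp$p, tgt, mean)
          else tapply(exp$p, tgt, function(p) {
              stat <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
              stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
          })
    n <- tapply(exp$p, tgt, length)
    out <- data.frame(gene = levels(tgt), log2FC = as.numeric(lfc),
                      p = as.numeric(pv), nSources = as.integer(n))
    rownames(out) <- NULL
    attr(out, "unmapped") <- unmapped
    out
}
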