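## Over-representation analysis against the measured background,
## cross-condition overlap coefficients, and disease-list overlap tests.

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric (upper-tail) test of each gene set against the
#' query, with the background fixed to the measured gene universe. Sets are
#' intersected with the background before testing; p-values are
#' Benjamini-Hochberg adjusted across sets and a set is called significant
#' when its adjusted p is at or below \code{fdr}.
#'
#' @param query gene set of interest (must be a subset of
#'   \code{background}); an empty query yields p = 1 everywhere.
#' @param background the measured gene universe.
#' @param sets named list of gene sets (e.g. from [readGmt()] or
#'   [simulateGenesets()]).
#' @param fdr significance threshold on the adjusted p.
#' @return data.frame with one row per set: \code{set}, \code{setSize}
#'   (within background), \code{querySize}, \code{overlap}, \code{p},
#'   \code{adjP}, \code{significant}, ordered by p.
#' @export
overrepresentation <- function(query, background, sets, fdr = 0.05) {
    if (!length(background)) stop("empty background")
    background <- unique(background)
    query <- unique(query)
    if (!all(query %in% background))
        stop("query must be a subset of the background")
    N <- length(background)
    n <- length(query)
    res <- lapply(names(sets), function(id) {
        s <- intersect(sets[[id]], background)
        m <- length(s)
        k <- length(intersect(s, query))
        p <- if (m == 0L || n == 0L) 1
             else phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
        data.frame(set = id, setSize = m, querySize = n, overlap = k,
                   p = p)
    })
    out <- do.call(rbind, res)
    out$adjP <- p.adjust(out$p, method = "BH")
    out$significant <- out$adjP <= fdr
    out <- out[order(out$p, out$set), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Overlap coefficient between two sets
#'
#' The intersection size divided by the smaller set size,
#' |A intersect B| / min(|A|, |B|), in [0, 1]. With an empty input the
#' coefficient is undefined and reported as 0 with a flag. The
#' \code{coefficient} element is rounded to two decimals for reporting; the
#' unrounded value is kept in \code{raw}.
#'
#' @param a,b identifier sets (character vectors).
#' @return list with \code{intersection}, \code{coefficient} (2 dp),
#'   \code{raw}, \code{undefined}.
#' @examples
#' overlapCoefficient(c("P1", "P2", "P3"), c("P2", "P3", "P4", "P5"))
#' @export
overlapCoefficient <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) || !length(b))
        return(list(intersection = 0L, coefficient = 0, raw = 0,
                    undefined = TRUE))
    i <- length(intersect(a, b))
    raw <- i / min(length(a), length(b))
    list(intersection = i, coefficient = round(raw, 2), raw = raw,
         undefined = FALSE)
}

#' Disease-list overlap test
#'
#' Unions one or more scored disease gene lists, intersects everything with
#' the measured background, and tests the 2x2 overlap between the
#' differentially expressed genes and the disease union over the background.
#' Reports the sample odds ratio (with a Haldane 0.5 correction only when a
#' cell is zero) and the two-sided Fisher exact p-value.
#'
#' @param degs differentially expressed gene set.
#' @param diseaseLists a single list/vector or a list of them; elements may
#'   be character vectors or data.frames with a \code{gene} column.
#' @param background the measured gene universe; must be at least as large
#'   as the union of the inputs.
#' @return list with \code{table} (2x2 matrix), \code{oddsRatio}, \code{p},
#'   \code{unionSize} (disease union before background intersection).
#' @export
diseaseOverlap <- function(degs, diseaseLists, background) {
    if (is.data.frame(diseaseLists) || is.character(diseaseLists))
        diseaseLists <- list(diseaseLists)
    lists <- lapply(diseaseLists, function(x)
        unique(if (is.data.frame(x)) as.character(x$gene)
               else as.character(x)))
    disUnion <- unique(unlist(lists))
    background <- unique(background)
    if (length(background) < length(unique(c(degs, disUnion))))
        stop("background smaller than the union of the inputs")
    degs <- intersect(unique(degs), background)
    dis <- intersect(disUnion, background)
    a <- length(intersect(degs, dis))
    b <- length(degs) - a
    cc <- length(dis) - a
    d <- length(background) - a - b - cc
    tab <- matrix(c(a, b, cc, d), 2L, 2L, byrow = TRUE,
                  dimnames = list(deg = c("yes", "no"),
                                  disease = c("yes", "no")))
    orTab <- if (any(tab == 0)) tab + 0.5 else tab
    oddsRatio <- (orTab[1, 1] * orTab[2, 2]) / (orTab[1, 2] * orTab[2, 1])
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    list(table = tab, oddsRatio = oddsRatio, p = p,
         unionSize = length(disUnion))
}
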