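## Gene-level statistics -> transcription-factor activities and pathway
## scores, with discretisation for causal reasoning.

#' Transcription-factor activity from regulon enrichment
#'
#' The gene statistic is the log2FC of each gene passing the significance
#' gate (p <= \code{pGate}) and 0 otherwise. A TF's raw score is the
#' weighted sum of its regulon targets' statistics (weights are the regulon
#' signs); the normalised score (NES) standardises the raw score against a
#' null built by permuting gene labels of the statistic vector
#' \code{nPerm} times with a fixed seed. Regulons with no measured target
#' are omitted (logged); regulons with fewer than 3 measured targets are
#' flagged low-confidence.
#'
#' @param measurements data.frame with columns \code{gene}, \code{log2FC},
#'   \code{p}.
#' @param regulons data.frame with columns \code{tf}, \code{target},
#'   \code{sign} (duplicate (tf, target) pairs are an error).
#' @param pGate significance gate on the gene p-values.
#' @param nPerm number of gene-label permutations.
#' @param seed RNG seed.
#' @return data.frame with columns \code{tf}, \code{nTargets}, \code{raw},
#'   \code{nes}, \code{lowConfidence}; omitted regulons are listed in
#'   attribute \code{"omitted"}.
#' @export
tfActivity <- function(measurements, regulons, pGate = 0.05,
                       nPerm = 1000L, seed = 1L) {
    stopifnot(all(c("gene", "log2FC", "p") %in% names(measurements)),
              all(c("tf", "target", "sign") %in% names(regulons)))
    if (anyDuplicated(regulons[, c("tf", "target")]))
        stop("duplicate (tf, target) pairs in the regulon table")
    x <- ifelse(measurements$p <= pGate, measurements$log2FC, 0)
    names(x) <- measurements$gene
    reg <- regulons[regulons$target %in% names(x), , drop = FALSE]
    omitted <- setdiff(unique(regulons$tf), unique(reg$tf))
    if (!nrow(reg)) stop("no regulon target overlaps the measured genes")
    tfs <- unique(reg$tf)
    idx <- split(match(reg$target, names(x)), reg$tf)[tfs]
    wts <- split(as.numeric(reg$sign), reg$tf)[tfs]
    raw <- vapply(tfs, function(t)
        sum(wts[[t]] * x[idx[[t]]]), numeric(1))
    set.seed(seed)
    permIdx <- vapply(seq_len(nPerm),
                      function(i) sample.int(length(x)),
                      integer(length(x)))
    X <- matrix(x[permIdx], length(x), nPerm)
    nullMean <- numeric(length(tfs))
    nullSd <- numeric(length(tfs))
    for (i in seq_along(tfs)) {
        ns <- as.vector(crossprod(wts[[i]],
                                  X[idx[[i]], , drop = FALSE]))
        nullMean[i] <- mean(ns)
        nullSd[i] <- sd(ns)
    }
    nes <- ifelse(nullSd > 0, (raw - nullMean) / nullSd, 0)
    out <- data.frame(tf = tfs,
                      nTargets = lengths(idx),
                      raw = raw, nes = nes,
                      lowConfidence = lengths(idx) < 3L)
    rownames(out) <- NULL
    attr(out, "omitted") <- omitted
    out
}

#' Pathway scores from weighted gene statistics
#'
#' The score of a pathway is the coefficient-weighted sum of the gene-level
#' z statistics over the genes shared between the coefficient matrix and
#' the measurements; genes missing from the measurements contribute 0.
#'
#' @param z named numeric vector of gene z-statistics.
#' @param coefficients pathways x genes weight matrix.
#' @return data.frame with columns \code{pathway}, \code{score}.
#' @export
pathwayScores <- function(z, coefficients) {
    common <- intersect(colnames(coefficients), names(z))
    if (!length(common))
        stop("no overlap between coefficient genes and measurements")
    sc <- as.vector(coefficients[, common, drop = FALSE] %*% z[common])
    data.frame(pathway = rownames(coefficients), score = sc)
}

#' Discretise activity scores for causal reasoning
#'
#' Maps the normalised score to a discrete regulatory state: +1 (activated)
#' when NES >= \code{zThresh}, -1 (inactivated) when NES <= -\code{zThresh}
#' (boundaries inclusive), else 0 (no change). The default threshold 1.96 is
#' the two-sided 5% normal quantile.
#'
#' @param activity data.frame with an \code{nes} column (from
#'   [tfActivity()]).
#' @param zThresh discretisation threshold.
#' @return the input with an added integer \code{state} column.
#' @export
discretizeActivity <- function(activity, zThresh = 1.96) {
    stopifnot("nes" %in% names(activity))
    st <- integer(nrow(activity))
    st[activity$nes >= zThresh] <- 1L
    st[activity$nes <= -zThresh] <- -1L
    activity$state <- st
    activity
}
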