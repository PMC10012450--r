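## Ligand-based target prediction: ECFP4-equivalent fingerprints, Tanimoto
## similarity, similarity-weighted kNN probabilities per target and activity
## threshold, applicability-domain percentiles, nearest-neighbour reporting
## and the unbound-Cmax arithmetic.

.smilesAlphabet <- c(LETTERS, letters, 0:9, "(", ")", "[", "]", "=", "#",
                     "-", "+", "@", "/", "\\", "%", ".", "*", ":")

#' ECFP4-equivalent fingerprint of a molecule
#'
#' Computes a circular substructure fingerprint of radius 2 (diameter 4)
#' from a SMILES string, via OpenBabel's ECFP4 implementation, and folds it
#' by bitwise OR to the requested length (default 2048 bits). Deterministic
#' per structure: different SMILES spellings of the same molecule give the
#' same bits.
#'
#' @param smiles a single SMILES string.
#' @param nbits folded fingerprint length.
#' @return A [Fingerprint-class] with \code{source = "structure"}.
#' @examples
#' \donttest{
#' fp <- fingerprintSmiles("CCO")
#' }
#' @export
fingerprintSmiles <- function(smiles, nbits = 2048L) {
    stopifnot(is.character(smiles), length(smiles) == 1L)
    bad <- which(!strsplit(smiles, "")[[1]] %in% .smilesAlphabet)
    if (length(bad))
        stop("cannot parse SMILES: illegal character '",
             substr(smiles, bad[1], bad[1]), "' at position ", bad[1])
    mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    raw <- tryCatch(ChemmineOB::fingerprint_OB(mol, "ECFP4"),
                    error = function(e)
                        stop("cannot parse SMILES '", smiles, "': ",
                             conditionMessage(e)))
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
    v <- as.integer(raw[1L, ] != 0)
    if (!sum(v))
        stop("cannot parse SMILES '", smiles,
             "': no atoms perceived at position 1")
    if (length(v) %% nbits != 0L)
        stop("nbits must divide the native fingerprint length ", length(v))
    folded <- as.integer(colSums(matrix(v, ncol = nbits, byrow = TRUE)) > 0)
    Fingerprint(which(folded == 1L), nbits = nbits, source = "structure")
}

#' Tanimoto similarity between two fingerprints
#'
#' |A and B| / |A or B| over the set bits. Symmetric; 1 exactly when the two
#' non-empty bit sets are identical. Two empty fingerprints are defined to
#' have similarity 0, flagged in attribute \code{"undefined"}.
#'
#' @param a,b [Fingerprint-class] objects of equal length.
#' @return similarity in [0, 1].
#' @examples
#' tanimoto(Fingerprint(c(1L, 2L), 8L), Fingerprint(c(2L, 3L, 4L), 8L))
#' @export
tanimoto <- function(a, b) {
    stopifnot(is(a, "Fingerprint"), is(b, "Fingerprint"))
    if (fpLength(a) != fpLength(b))
        stop("fingerprints must have equal lengths")
    i <- length(intersect(fpBits(a), fpBits(b)))
    u <- length(fpBits(a)) + length(fpBits(b)) - i
    if (u == 0L)
        return(structure(0, undefined = TRUE))
    i / u
}

## percentile of `stat` within a reference distribution: 100 * fraction of
## reference values <= stat
.percentileFromReference <- function(reference, stat) {
    100 * mean(reference <= stat)
}

## mean similarity of `fp` to its k nearest fingerprints in `others`
.knnStat <- function(fp, others, k) {
    sims <- vapply(others, function(o) tanimoto(fp, o), numeric(1))
    mean(sort(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))])
}

#' Applicability-domain percentile of a query compound
#'
#' The query statistic is its mean Tanimoto similarity to its \code{k}
#' nearest training compounds. The reference distribution is the same
#' statistic computed for every training compound against the rest of the
#' training set (leave-self-out). The percentile is 100 times the fraction
#' of reference statistics at or below the query's: 100 means the query sits
#' deeper inside the training chemistry than any training compound.
#'
#' @param query a [Fingerprint-class].
#' @param training list of training [Fingerprint-class]s (>= 2).
#' @param k neighbour count.
#' @return percentile in [0, 100].
#' @export
applicabilityPercentile <- function(query, training, k = 5L) {
    if (length(training) < 2L) stop("need at least 2 training compounds")
    qstat <- .knnStat(query, training, k)
    ref <- vapply(seq_along(training), function(i)
        .knnStat(training[[i]], training[-i], k), numeric(1))
    .percentileFromReference(ref, qstat)
}

#' Similarity-weighted kNN target prediction
#'
#' For each (target, activity threshold) pair, a training compound is active
#' iff its measured activity is at or below the threshold (potency at least
#' that strong). The predicted probability of activity is the
#' similarity-weighted fraction of actives among the \code{k} training
#' compounds most similar to the query that have data for the target:
#' sum(T_i y_i) / sum(T_i), with ties in similarity broken by compound id.
#' Each target also reports its nearest training neighbour (the most
#' structurally similar compound with data for it), that neighbour's
#' Tanimoto similarity, and the applicability-domain percentile of the query
#' against the target's training compounds.
#'
#' This transparent kNN predictor has the same interface as pre-trained
#' per-target classifiers (targets x thresholds x probability x
#' applicability x nearest neighbour) while remaining reproducible from the
#' bioactivity table alone.
#'
#' @param query a [Fingerprint-class].
#' @param corpus data.frame with columns \code{compound}, \code{target},
#'   \code{activity_uM} and either a \code{fingerprint} column of hex
#'   strings (see [fingerprintToHex()]) or a parallel list of fingerprints
#'   passed via \code{fingerprints}.
#' @param fingerprints optional named list of [Fingerprint-class]s keyed by
#'   compound id, overriding the hex column.
#' @param thresholds activity thresholds in uM.
#' @param k neighbour count.
#' @return data.frame with one row per (target, threshold):
#'   \code{target}, \code{threshold}, \code{probability}, \code{ad},
#'   \code{nearestNeighbour}, \code{nnSimilarity}, sorted by probability
#'   (descending).
#' @export
predictTargets <- function(query, corpus, fingerprints = NULL,
                           thresholds = c(0.1, 1, 10, 100), k = 5L) {
    stopifnot(is(query, "Fingerprint"),
              all(c("compound", "target", "activity_uM") %in% names(corpus)))
    if (!nrow(corpus)) stop("empty bioactivity corpus")
    if (any(corpus$activity_uM <= 0)) stop("activities must be positive")
    compounds <- unique(corpus$compound)
    if (is.null(fingerprints)) {
        if (!"fingerprint" %in% names(corpus))
            stop("corpus needs a 'fingerprint' column or a fingerprints list")
        hex <- corpus$fingerprint[match(compounds, corpus$compound)]
        fingerprints <- setNames(lapply(hex, hexToFingerprint,
                                        nbits = fpLength(query)), compounds)
    }
    sims <- vapply(compounds, function(cm)
        tanimoto(query, fingerprints[[cm]]), numeric(1))
    out <- list()
    for (tg in unique(corpus$target)) {
        sub <- corpus[corpus$target == tg, , drop = FALSE]
        ## one activity per compound for this target: take the most potent
        act <- tapply(sub$activity_uM, sub$compound, min)
        cms <- names(act)
        s <- sims[cms]
        ord <- order(-s, cms)                 # ties by lexicographic id
        ad <- if (length(cms) >= 2L)
            applicabilityPercentile(query, fingerprints[cms], k) else NA_real_
        nn <- cms[ord[1L]]
        for (th in thresholds) {
            kn <- ord[seq_len(min(k, length(ord)))]
            y <- as.numeric(act[kn] <= th)
            w <- s[kn]
            prob <- if (sum(w) > 0) sum(w * y) / sum(w) else 0
            out[[length(out) + 1L]] <- data.frame(
                target = tg, threshold = th, probability = prob,
                ad = ad, nearestNeighbour = nn,
                nnSimilarity = unname(s[nn]))
        }
    }
    res <- do.call(rbind, out)
    res <- res[order(-res$probability, res$target, res$threshold), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Unbound Cmax from total Cmax and the unbound fraction
#'
#' The maximum free (non-protein-bound) concentration available to engage
#' targets: total Cmax times the fraction unbound. Used to judge whether
#' predicted activity thresholds are pharmacologically reachable.
#'
#' @param cmaxTotal total maximum concentration (uM), >= 0.
#' @param fractionUnbound fraction unbound, in [0, 1].
#' @return unbound Cmax in uM.
#' @examples
#' unboundCmax(125, 0.08)  # 10
#' @export
unboundCmax <- function(cmaxTotal, fractionUnbound) {
    if (any(cmaxTotal < 0) || any(fractionUnbound < 0))
        stop("inputs must be non-negative")
    if (any(fractionUnbound > 1))
        stop("fractionUnbound must not exceed 1")
    cmaxTotal * fractionUnbound
}

#' Serialise a fingerprint to a hex string
#'
#' @param fp a [Fingerprint-class].
#' @return hex string of length nbits/4.
#' @export
fingerprintToHex <- function(fp) {
    stopifnot(is(fp, "Fingerprint"))
    v <- integer(fpLength(fp))
    v[fpBits(fp)] <- 1L
    nib <- matrix(v, nrow = 4L)
    vals <- as.integer(crossprod(nib, c(8L, 4L, 2L, 1L)))
    paste(sprintf("%x", vals), collapse = "")
}

#' Parse a hex string back into a fingerprint
#'
#' @param hex hex string from [fingerprintToHex()].
#' @param nbits fingerprint length (must equal 4 * nchar(hex)).
#' @param source provenance tag.
#' @return A [Fingerprint-class].
#' @export
hexToFingerprint <- function(hex, nbits = 4L * nchar(hex),
                             source = "synthetic") {
    if (nbits != 4L * nchar(hex))
        stop("nbits inconsistent with hex length")
    vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
    bits <- as.vector(vapply(vals, function(v)
        as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0), integer(4)))
    Fingerprint(which(bits == 1L), nbits = nbits, source = source)
}
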