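## Causal reasoning on signed networks: signed shortest-path propagation,
## permutation-based hypothesis scoring, ranking over path lengths 1..5,
## consensus nodes, concordant subnetwork reconstruction and ensemble pooling.

## Layered BFS from `root` recording, per reached node, the shortest-path
## distance and the set of achievable sign products over *all* shortest
## paths (coded 1 = {+}, 2 = {-}, 3 = both), plus the set of shortest-path
## predecessor edges (for subnetwork reconstruction when keepParents).
## Integer-indexed and layer-vectorised: each depth processes all outgoing
## edges of the frontier at once.
.graphIndex <- function(net) {
    nd <- nodes(net)
    e <- edges(net)
    n <- length(nd)
    from <- match(e$from, nd)
    list(nd = nd, e = e, n = n, from = from, to = match(e$to, nd),
         adj = split(seq_len(nrow(e)), factor(from, levels = seq_len(n))))
}

.signedBfs <- function(net, root, deltaMax, keepParents = FALSE,
                       gi = .graphIndex(net)) {
    nd <- gi$nd
    e <- gi$e
    n <- gi$n
    from <- gi$from
    to <- gi$to
    adj <- gi$adj
    rootI <- match(root, nd)
    dist <- rep(NA_integer_, n)
    scode <- integer(n)
    parents <- if (keepParents) vector("list", n)
    dist[rootI] <- 0L
    scode[rootI] <- 1L                      # + : empty product
    swap <- c(2L, 1L, 3L)                   # inhibitory edge flips the set
    frontier <- rootI
    d <- 0L
    while (length(frontier) && d < deltaMax) {
        d <- d + 1L
        cand <- unlist(adj[frontier], use.names = FALSE)
        if (!length(cand)) break
        w <- to[cand]
        code <- scode[from[cand]]
        neg <- e$sign[cand] == -1L
        code[neg] <- swap[code[neg]]
        ## all edges of one layer are processed in a single batch, so a
        ## target is either already settled at a smaller depth or new here
        open <- is.na(dist[w])
        cand <- cand[open]; w <- w[open]; code <- code[open]
        if (!length(cand)) break
        ## OR-combine the sign codes of all edges entering each target
        b1 <- rowsum(as.integer(bitwAnd(code, 1L) > 0L), w) > 0L
        b2 <- rowsum(as.integer(bitwAnd(code, 2L) > 0L), w) > 0L
        tgt <- as.integer(rownames(b1))
        dist[tgt] <- d
        scode[tgt] <- as.integer(b1) + 2L * as.integer(b2)
        if (keepParents)
            for (i in seq_along(cand))
                parents[[w[i]]] <- c(parents[[w[i]]], cand[i])
        frontier <- tgt
    }
    reachedI <- which(!is.na(dist) & seq_len(n) != rootI)
    state <- integer(length(reachedI))
    names(state) <- nd[reachedI]
    state[scode[reachedI] == 1L] <- 1L
    state[scode[reachedI] == 2L] <- -1L     # code 3 stays 0 = ambiguous
    names(parents) <- if (keepParents) nd
    list(dist = setNames(dist[reachedI], nd[reachedI]), state = state,
         parents = parents)
}

#' Predict downstream node states from a regulator hypothesis
#'
#' Propagates an assumed activation (\code{sign = +1}) or inhibition
#' (\code{sign = -1}) of a protein along signed shortest paths, breadth-first
#' up to path length \code{delta}. The predicted state of a reached node is
#' the hypothesis sign times the product of edge signs along a shortest path;
#' if two shortest paths of equal length disagree in sign the node is
#' ambiguous and predicted 0. Unreached nodes (and the hypothesis node
#' itself, unless re-reached through a cycle) carry no prediction.
#'
#' @param network a [SignedNetwork-class].
#' @param hypothesis a node identifier.
#' @param sign assumed regulator state, +1 or -1.
#' @param delta maximum path length (>= 1).
#' @return Named integer vector of predicted states in \{-1, 0, +1\} for
#'   reached nodes, with the shortest-path distance in attribute
#'   \code{"dist"}.
#' @examples
#' net <- SignedNetwork(data.frame(from = c("h", "a"), to = c("a", "b"),
#'                                 sign = c(1L, -1L)))
#' predictDownstream(net, "h", 1L, delta = 2L)  # a:+1, b:-1
#' @export
predictDownstream <- function(network, hypothesis, sign = 1L, delta = 2L) {
    stopifnot(is(network, "SignedNetwork"))
    if (!hypothesis %in% nodes(network))
        stop("hypothesis node '", hypothesis, "' is not in the network")
    if (!sign %in% c(-1L, 1L))
        stop("sign must be +1 or -1")
    if (delta < 1L)
        stop("delta must be >= 1")
    b <- .signedBfs(network, hypothesis, delta)
    state <- as.integer(sign) * b$state
    attr(state, "dist") <- b$dist
    state
}

## All permutations of 1..n as an (n! x n) matrix; n <= 8.
.allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPermutations(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    r <- 0L
    for (k in seq_len(n)) {
        block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
        out[r + seq_len(nrow(sub)), ] <- block
        r <- r + nrow(sub)
    }
    out
}

#' Score a regulator hypothesis against observations
#'
#' Over nodes with a nonzero prediction and a nonzero observation, an
#' agreement counts +1 (correct) and a disagreement -1 (incorrect);
#' the score is their sum. Significance comes from a permutation null that
#' shuffles the observed multiset across all measured nodes: the p-value is
#' the fraction of permutations scoring at least as high as the observed
#' score. With at most 8 measured nodes the null is enumerated exactly;
#' otherwise it is sampled Monte-Carlo with a fixed seed.
#'
#' @param predictions named integer vector of predicted states (from
#'   [predictDownstream()]).
#' @param observed named integer vector of observed states in \{-1, 0, +1\};
#'   its names define the measured nodes.
#' @param null \code{"auto"} (exact when <= 8 measured nodes),
#'   \code{"exact_permutation"} or \code{"monte_carlo"}.
#' @param nPerm Monte-Carlo permutation count.
#' @param seed RNG seed for Monte-Carlo.
#' @return A one-row data.frame with columns \code{nCorrect},
#'   \code{nIncorrect}, \code{nAmbiguous}, \code{score}, \code{p}.
#' @examples
#' pred <- c(a = 1L, b = -1L, c = 1L)
#' obs <- c(a = 1L, b = -1L, c = -1L)
#' scoreHypothesis(pred, obs)  # score 1, exact p = 2/3
#' @export
scoreHypothesis <- function(predictions, observed,
                            null = c("auto", "exact_permutation",
                                     "monte_carlo"),
                            nPerm = 10000L, seed = 1L) {
    null <- match.arg(null)
    if (!all(observed %in% c(-1L, 0L, 1L)))
        stop("observed states must be in {-1, 0, +1}")
    measured <- names(observed)
    pred <- setNames(rep(0L, length(measured)), measured)
    common <- intersect(names(predictions), measured)
    pred[common] <- predictions[common]
    support <- pred != 0L & observed != 0L
    nCorrect <- sum(pred[support] == observed[support])
    nIncorrect <- sum(support) - nCorrect
    nAmbiguous <- sum(names(observed) %in% names(predictions) &
                      pred == 0L & observed != 0L)
    score <- nCorrect - nIncorrect
    obsvals <- as.integer(observed)
    n <- length(obsvals)
    if (n == 0L || all(pred == 0L) || all(obsvals == 0L)) {
        p <- 1
    } else if (null == "exact_permutation" || (null == "auto" && n <= 8L)) {
        perms <- .allPermutations(n)
        nullScores <- as.vector(matrix(obsvals[perms], nrow(perms), n) %*%
                                pred)
        p <- mean(nullScores >= score)
    } else {
        set.seed(seed)
        nullScores <- vapply(seq_len(nPerm),
                             function(i) sum(pred * sample(obsvals)),
                             numeric(1))
        p <- mean(nullScores >= score)
    }
    data.frame(nCorrect = nCorrect, nIncorrect = nIncorrect,
               nAmbiguous = nAmbiguous, score = score, p = p)
}

#' Rank regulator hypotheses across path lengths
#'
#' Tests every network protein, at both assumed signs, as an upstream
#' regulator of the observed states, for each path length 1..\code{deltaMax}.
#' All hypotheses at a given path length share one seeded permutation
#' ensemble of the observed multiset, so p-values across hypotheses are
#' computed under the identical null. Results are ranked by score
#' (descending), ties by p (ascending) then protein id.
#'
#' @param network a [SignedNetwork-class].
#' @param observed named integer vector of observed states over measured
#'   nodes (\{-1, 0, +1\}).
#' @param deltaMax maximum path length (default 5).
#' @param alpha significance level for the \code{significant} flag.
#' @param nPerm permutations for the shared null.
#' @param seed RNG seed.
#' @return data.frame with one row per (protein, sign, delta): counts,
#'   score, p, significant, rank (within delta).
#' @export
rankHypotheses <- function(network, observed, deltaMax = 5L, alpha = 0.05,
                           nPerm = 1000L, seed = 1L) {
    stopifnot(is(network, "SignedNetwork"))
    measured <- names(observed)
    obsvals <- as.integer(observed)
    n <- length(obsvals)
    set.seed(seed)
    permMat <- if (n)
        matrix(obsvals[vapply(seq_len(nPerm), function(i) sample.int(n),
                              integer(n))], n, nPerm)
    else matrix(0L, 0L, nPerm)
    gi <- .graphIndex(network)
    res <- vector("list", length(nodes(network)))
    names(res) <- nodes(network)
    for (h in nodes(network)) {
        b <- .signedBfs(network, h, deltaMax, gi = gi)
        hit <- intersect(names(b$state), measured)
        rows <- list()
        for (delta in seq_len(deltaMax)) {
            within <- hit[b$dist[hit] <= delta]
            predvals <- b$state[within]            # states for sign = +1
            idx <- match(within, measured)
            nz <- predvals != 0L
            obsHit <- obsvals[idx]
            supp <- nz & obsHit != 0L
            nCor <- sum(predvals[supp] == obsHit[supp])
            nInc <- sum(supp) - nCor
            nAmb <- sum(!nz & obsHit != 0L)
            s <- nCor - nInc
            if (any(supp)) {
                nullScores <- as.vector(crossprod(
                    predvals[nz], permMat[idx[nz], , drop = FALSE]))
                pPlus <- mean(nullScores >= s)
                pMinus <- mean(-nullScores >= -s)
            } else {
                pPlus <- pMinus <- 1
            }
            rows[[delta]] <- data.frame(
                protein = h, sign = c(1L, -1L), delta = delta,
                nCorrect = c(nCor, nInc), nIncorrect = c(nInc, nCor),
                nAmbiguous = nAmb, score = c(s, -s), p = c(pPlus, pMinus))
        }
        res[[h]] <- do.call(rbind, rows)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out$significant <- out$p <= alpha
    out <- out[order(out$delta, -out$score, out$p, out$protein, -out$sign), ]
    out$rank <- stats::ave(out$score, out$delta,
                           FUN = function(x) seq_along(x))
    rownames(out) <- NULL
    out
}

#' Consensus regulator nodes across path lengths
#'
#' Counts, per (protein, sign) hypothesis, at how many path-length settings
#' it scored significantly, and returns all hypotheses attaining the maximum
#' count (ties all retained). With no significant hypothesis anywhere the
#' consensus is empty.
#'
#' @param scores data.frame from [rankHypotheses()] (needs columns
#'   \code{protein}, \code{sign}, \code{delta}, \code{significant}).
#' @return data.frame with columns \code{protein}, \code{sign},
#'   \code{nLevels}.
#' @export
consensusNodes <- function(scores) {
    stopifnot(all(c("protein", "sign", "delta", "significant") %in%
                  names(scores)))
    sig <- scores[scores$significant, , drop = FALSE]
    if (!nrow(sig))
        return(data.frame(protein = character(0), sign = integer(0),
                          nLevels = integer(0)))
    key <- paste(sig$protein, sig$sign)
    counts <- tapply(sig$delta, key, function(d) length(unique(d)))
    top <- names(counts)[counts == max(counts)]
    parts <- do.call(rbind, strsplit(top, " "))
    out <- data.frame(protein = parts[, 1], sign = as.integer(parts[, 2]),
                      nLevels = as.integer(counts[top]))
    out[order(out$protein, -out$sign), , drop = FALSE]
}

#' Reconstruct the concordant consensus subnetwork
#'
#' For each consensus regulator hypothesis, includes every shortest path (up
#' to \code{deltaMax}) from the regulator to each observed entity whose
#' predicted and observed states agree, and unions the paths over all
#' consensus nodes. Every edge of the result exists in the source network,
#' and every included path is sign-concordant with both endpoint states.
#'
#' @param network a [SignedNetwork-class].
#' @param consensus data.frame with columns \code{protein}, \code{sign}
#'   (e.g. from [consensusNodes()]).
#' @param observed named integer vector of observed states.
#' @param deltaMax maximum path length.
#' @return A [ConsensusSubnetwork-class].
#' @export
reconstructSubnetwork <- function(network, consensus, observed,
                                  deltaMax = 5L) {
    stopifnot(is(network, "SignedNetwork"))
    if (!all(consensus$protein %in% nodes(network)))
        stop("consensus nodes must be network nodes")
    e <- edges(network)
    edgeIdx <- integer(0)
    prov <- list()
    roles <- list()
    for (r in seq_len(nrow(consensus))) {
        h <- consensus$protein[r]
        sgn <- consensus$sign[r]
        b <- .signedBfs(network, h, deltaMax, keepParents = TRUE)
        pred <- as.integer(sgn) * b$state
        explained <- names(pred)[pred != 0L &
                                 names(pred) %in% names(observed)]
        explained <- explained[observed[explained] != 0L &
                               pred[explained] == observed[explained]]
        for (g in explained) {
            ## walk the shortest-path predecessor DAG from g back to h
            seen <- character(0)
            stack <- g
            while (length(stack)) {
                w <- stack[[1]]
                stack <- stack[-1]
                if (w %in% seen || w == h) next
                seen <- c(seen, w)
                par <- b$parents[[w]]
                edgeIdx <- c(edgeIdx, par)
                stack <- c(stack, e$from[par])
            }
        }
        if (length(explained)) {
            prov[[length(prov) + 1L]] <- data.frame(
                consensus = h, sign = sgn, explained = explained,
                state = as.integer(observed[explained]))
            roles[[length(roles) + 1L]] <-
                data.frame(node = h, role = "consensus", state = sgn)
        }
    }
    edgeIdx <- sort(unique(edgeIdx))
    sub <- e[edgeIdx, , drop = FALSE]
    rownames(sub) <- NULL
    prov <- if (length(prov)) do.call(rbind, prov) else
        data.frame(consensus = character(0), sign = integer(0),
                   explained = character(0), state = integer(0))
    nodeIds <- unique(c(sub$from, sub$to))
    role <- rep("intermediate", length(nodeIds))
    role[nodeIds %in% prov$consensus] <- "consensus"
    role[nodeIds %in% prov$explained] <- "explained"
    state <- rep(0L, length(nodeIds))
    state[match(prov$explained, nodeIds)] <- prov$state
    state[nodeIds %in% prov$consensus] <-
        prov$sign[match(nodeIds[nodeIds %in% prov$consensus],
                        prov$consensus)]
    new("ConsensusSubnetwork", edges = sub,
        nodes = data.frame(node = nodeIds, role = role, state = state),
        provenance = prov)
}

#' Pool regulator hypotheses across analysis setups
#'
#' Given regulator hypothesis sets recovered under several setups
#' (algorithm x network x condition combinations), counts for each protein
#' the number of setups recovering it and pools those recovered at least
#' \code{minFrequency} times. When a prior-knowledge network is supplied,
#' the pooled regulators are connected by the known directed interactions
#' among them for display.
#'
#' @param setups list of character vectors (or data.frames with a
#'   \code{protein} column), one per setup.
#' @param minFrequency minimum number of setups; default is half the setup
#'   count, rounded up.
#' @param network optional [SignedNetwork-class] for the display subnetwork.
#' @return list with \code{frequency} (data.frame protein, frequency),
#'   \code{pooled} (character) and \code{display} (edge data.frame or NULL).
#' @export
poolSetups <- function(setups, minFrequency = NULL, network = NULL) {
    stopifnot(length(setups) >= 1L)
    proteins <- lapply(setups, function(s)
        unique(if (is.data.frame(s)) as.character(s$protein)
               else as.character(s)))
    if (is.null(minFrequency))
        minFrequency <- ceiling(length(setups) / 2)
    tab <- table(unlist(proteins))
    freq <- data.frame(protein = names(tab),
                       frequency = as.integer(tab))
    freq <- freq[order(-freq$frequency, freq$protein), , drop = FALSE]
    rownames(freq) <- NULL
    pooled <- freq$protein[freq$frequency >= minFrequency]
    display <- NULL
    if (!is.null(network)) {
        e <- edges(network)
        display <- e[e$from %in% pooled & e$to %in% pooled, , drop = FALSE]
        rownames(display) <- NULL
    }
    list(frequency = freq, pooled = pooled, display = display)
}
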