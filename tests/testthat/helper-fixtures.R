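# Shared fixtures, built in code.

# tiny chain network: h -(+)-> a -(-)-> b
chainNet <- function() {
    SignedNetwork(data.frame(from = c("h", "a"), to = c("a", "b"),
                             sign = c(1L, -1L)))
}

# random small signed graph for oracle comparisons (allows cycles)
randomSmallNet <- function(n, p = 0.25, seed = 1) {
    set.seed(seed)
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- runif(nrow(pairs)) < p
    e <- pairs[keep, , drop = FALSE]
    if (!nrow(e)) e <- pairs[1, , drop = FALSE]
    SignedNetwork(data.frame(from = paste0("n", e$from),
                             to = paste0("n", e$to),
                             sign = sample(c(-1L, 1L), nrow(e),
                                           replace = TRUE)),
                  nodes = paste0("n", seq_len(n)))
}

# brute-force signed shortest-path oracle: enumerate all simple paths up to
# maxLen, keep the minimum-length ones per target, and derive the state
bruteForceStates <- function(net, root, maxLen) {
    e <- edges(net)
    best <- list()   # node -> list(len, signs)
    recurse <- function(node, visited, len, sgn) {
        if (len > 0) {
            b <- best[[node]]
            if (is.null(b) || len < b$len) {
                best[[node]] <<- list(len = len, signs = sgn)
            } else if (len == b$len) {
                best[[node]]$signs <<- union(b$signs, sgn)
            }
        }
        if (len == maxLen) return()
        out <- e[e$from == node, , drop = FALSE]
        for (i in seq_len(nrow(out))) {
            w <- out$to[i]
            if (w %in% visited) next
            recurse(w, c(visited, w), len + 1L, sgn * out$sign[i])
        }
    }
    recurse(root, root, 0L, 1L)
    states <- vapply(best, function(b)
        if (length(b$signs) > 1L) 0L else as.integer(b$signs), integer(1))
    dists <- vapply(best, function(b) b$len, integer(1))
    list(state = states, dist = dists)
}

# direct Benjamini-Hochberg evaluation (sort, scale, cumulative minimum)
bhDirect <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# exact hypergeometric upper tail via the combinatorial sum (exact in
# doubles for the small backgrounds it is used with)
hyperUpperExact <- function(k, m, N, n) {
    js <- k:min(m, n)
    sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# synthetic FactorialFit with a chosen contrast correlation and df, for
# testing the max-|t| adjustment in isolation
syntheticFit <- function(tmat, corr, df) {
    k <- ncol(tmat)
    structure(list(estimates = tmat, se = matrix(1, nrow(tmat), k),
                   t = tmat, rawP = 2 * pt(-abs(tmat), df), df = df,
                   corr = corr,
                   contrasts = paste0("c", seq_len(k)),
                   sigma2 = rep(1, nrow(tmat)), model = "synthetic",
                   log = list()),
              class = "FactorialFit")
}
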