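test_that("signed propagation follows shortest paths and flags conflicts", {
    net <- chainNet()
    st <- predictDownstream(net, "h", 1L, delta = 2L)
    expect_equal(st[["a"]], 1L)
    expect_equal(st[["b"]], -1L)
    # inhibition hypothesis flips everything
    stNeg <- predictDownstream(net, "h", -1L, delta = 2L)
    expect_equal(unname(stNeg[c("a", "b")]), c(-1L, 1L))

    # conflicting equal-length paths are ambiguous
    net2 <- SignedNetwork(data.frame(
        from = c("h", "h", "x", "y"), to = c("x", "y", "a", "a"),
        sign = c(1L, -1L, 1L, 1L)))
    st2 <- predictDownstream(net2, "h", 1L, delta = 2L)
    expect_equal(st2[["a"]], 0L)

    expect_error(predictDownstream(net, "h", 1L, delta = 0L), "delta")
    expect_error(predictDownstream(net, "zz"), "not in the network")
})

test_that("propagation agrees with brute-force path enumeration", {
    for (seed in 1:6) {
        net <- randomSmallNet(10, p = 0.2, seed = seed)
        root <- nodes(net)[1]
        for (delta in c(1L, 3L, 5L)) {
            oracle <- bruteForceStates(net, root, delta)
            st <- predictDownstream(net, root, 1L, delta)
            keep <- setdiff(names(oracle$state), root)
            expect_setequal(names(st), keep)
            expect_equal(st[keep], oracle$state[keep])
            expect_equal(attr(st, "dist")[keep], oracle$dist[keep])
        }
    }
})

test_that("larger delta extends predictions without changing them", {
    for (seed in 7:10) {
        net <- randomSmallNet(12, p = 0.25, seed = seed)
        root <- nodes(net)[2]
        prev <- predictDownstream(net, root, 1L, 1L)
        for (k in 2:5) {
            cur <- predictDownstream(net, root, 1L, k)
            expect_true(all(names(prev) %in% names(cur)))
            expect_equal(cur[names(prev)], prev[names(prev)])
            prev <- cur
        }
    }
})

test_that("hypothesis scoring matches the exact permutation null", {
    # worked 3-node example: arrangements of {+1,-1,-1} score (1,-3,1)
    pred <- c(a = 1L, b = -1L, c = 1L)
    obs <- c(a = 1L, b = -1L, c = -1L)
    sc <- scoreHypothesis(pred, obs)
    expect_equal(sc$score, 1)
    expect_equal(sc$nCorrect, 2)
    expect_equal(sc$nIncorrect, 1)
    expect_equal(sc$p, 2 / 3)

    # perfect agreement: p = 1 / number of distinct arrangements
    predP <- c(a = 1L, b = 1L, c = -1L)
    obsP <- c(a = 1L, b = 1L, c = -1L)
    scP <- scoreHypothesis(predP, obsP)
    expect_equal(scP$score, 3)
    expect_equal(scP$p, 1 / 3)          # 3 distinct arrangements

    # all-zero observations: score 0, p 1
    scZ <- scoreHypothesis(pred, c(a = 0L, b = 0L, c = 0L))
    expect_equal(scZ$score, 0)
    expect_equal(scZ$p, 1)

    # disjoint supports: score 0, p 1
    scD <- scoreHypothesis(c(z = 1L), obs)
    expect_equal(scD$score, 0)
    expect_equal(scD$p, 1)

    expect_error(scoreHypothesis(pred, c(a = 2L)), "observed states")
})

test_that("exact and Monte-Carlo permutation p agree", {
    set.seed(31)
    for (rep in 1:5) {
        n <- 8
        pred <- setNames(sample(c(-1L, 0L, 1L), n, replace = TRUE),
                         letters[1:n])
        obs <- setNames(sample(c(-1L, 0L, 1L), n, replace = TRUE),
                        letters[1:n])
        if (all(pred == 0L) || all(obs == 0L)) next
        ex <- scoreHypothesis(pred, obs, null = "exact_permutation")
        mc <- scoreHypothesis(pred, obs, null = "monte_carlo",
                              nPerm = 10000, seed = rep)
        se <- sqrt(ex$p * (1 - ex$p) / 10000)
        expect_lte(abs(mc$p - ex$p), 3 * se + 1e-9)
    }
})

test_that("a planted regulator ranks first at zero noise", {
    net <- simulateNetwork(60, 3, 0.3, seed = 12)
    reg <- nodes(net)[1]
    ex <- simulateExperiment(net, data.frame(protein = reg, sign = 1L),
                             noiseSd = 0, plateSd = 0,
                             nBackgroundGenes = 0, seed = 2)
    truth <- perturbedGenes(ex$truth)
    obs <- setNames(rep(0L, length(nodes(net))), nodes(net))
    obs[truth$gene] <- truth$sign
    rk <- rankHypotheses(net, obs, deltaMax = 5, nPerm = 500, seed = 1)
    for (d in 2:5) {
        top <- rk[rk$delta == d & rk$rank == 1, ]
        expect_equal(top$protein, reg)
        expect_equal(top$sign, 1L)
    }
    # sign symmetry: negated observations invert every hypothesis sign
    rkNeg <- rankHypotheses(net, -obs, deltaMax = 3, nPerm = 500, seed = 1)
    m <- merge(rk[rk$delta <= 3, ], rkNeg,
               by = c("protein", "delta"),
               suffixes = c(".pos", ".neg"))
    m <- m[m$sign.pos == -m$sign.neg, ]
    expect_true(all(m$score.pos == m$score.neg))

    # empty observation: nothing significant
    rkE <- rankHypotheses(net, setNames(integer(length(nodes(net))),
                                        nodes(net)),
                          deltaMax = 2, nPerm = 100, seed = 1)
    expect_false(any(rkE$significant))
})

test_that("consensus nodes take the maximum significance count with ties", {
    mk <- function(protein, sign, deltas) {
        data.frame(protein = protein, sign = sign, delta = deltas,
                   significant = TRUE)
    }
    sc <- rbind(mk("P1", 1L, c(1, 2, 3)), mk("P2", 1L, 2))
    sc$significant <- TRUE
    cn <- consensusNodes(sc)
    expect_equal(cn$protein, "P1")
    expect_equal(cn$nLevels, 3L)

    scTie <- rbind(mk("P1", 1L, c(1, 2)), mk("P2", -1L, c(2, 3)))
    cnTie <- consensusNodes(scTie)
    expect_setequal(cnTie$protein, c("P1", "P2"))

    scNone <- data.frame(protein = "P1", sign = 1L, delta = 1,
                         significant = FALSE)
    expect_equal(nrow(consensusNodes(scNone)), 0)
})

test_that("subnetwork reconstruction keeps only concordant paths", {
    # h activates a and b, inhibits c; observations agree for a and b only
    net <- SignedNetwork(data.frame(
        from = c("h", "h", "h", "a"), to = c("a", "b", "c", "d"),
        sign = c(1L, 1L, -1L, 1L)))
    obs <- c(a = 1L, b = 1L, c = 1L, d = 0L)
    cons <- data.frame(protein = "h", sign = 1L)
    sub <- reconstructSubnetwork(net, cons, obs, deltaMax = 2)
    e <- edges(sub)
    expect_equal(nrow(e), 2)
    expect_setequal(e$to, c("a", "b"))
    # the subnetwork edge set is always a subset of the network's
    expect_true(nrow(merge(e, edges(net))) == nrow(e))

    # two consensus nodes sharing an explained gene: union, no duplicates
    net2 <- SignedNetwork(data.frame(
        from = c("h1", "h2"), to = c("g", "g"), sign = c(1L, 1L)))
    sub2 <- reconstructSubnetwork(net2,
        data.frame(protein = c("h1", "h2"), sign = c(1L, 1L)),
        c(g = 1L), deltaMax = 2)
    expect_equal(nrow(edges(sub2)), 2)
    expect_equal(anyDuplicated(edges(sub2)[, c("from", "to")]), 0L)

    # all shortest concordant paths are included, not just one
    net3 <- SignedNetwork(data.frame(
        from = c("h", "h", "x", "y"), to = c("x", "y", "g", "g"),
        sign = c(1L, 1L, 1L, 1L)))
    sub3 <- reconstructSubnetwork(net3, data.frame(protein = "h",
                                                   sign = 1L),
                                  c(g = 1L), deltaMax = 2)
    expect_equal(nrow(edges(sub3)), 4)
})

test_that("pooling across setups counts recovery frequency", {
    setups <- list(s1 = c("A", "B"), s2 = "A", s3 = c("A", "C"))
    pooled <- poolSetups(setups, minFrequency = 2)
    expect_equal(pooled$pooled, "A")
    expect_equal(pooled$frequency$frequency[
        pooled$frequency$protein == "A"], 3L)

    # min frequency 1 pools the union
    expect_setequal(poolSetups(setups, minFrequency = 1)$pooled,
                    c("A", "B", "C"))

    # a protein recovered in all 8 setups reports frequency 8
    eight <- rep(list("ATF"), 8)
    p8 <- poolSetups(eight)
    expect_equal(p8$frequency$frequency, 8L)

    # default threshold is half the setups, rounded up
    expect_equal(poolSetups(setups)$pooled, "A")

    # display network connects pooled regulators by known edges
    net <- SignedNetwork(data.frame(from = c("A", "B"), to = c("C", "A"),
                                    sign = c(1L, -1L)))
    disp <- poolSetups(list(c("A", "C"), c("A", "C")), 2, net)$display
    expect_equal(nrow(disp), 1)
    expect_equal(disp$from, "A")
})

test_that("planted regulators are recovered across noisy seeds", {
    net <- simulateNetwork(60, 3, 0.3, seed = 20)
    reach <- vapply(nodes(net), function(h)
        sum(predictDownstream(net, h, 1L, 2L) != 0L), numeric(1))
    reg <- names(reach)[which.max(reach)]
    recoverRate <- function(noise, seeds) {
        hits <- 0
        for (s in seeds) {
            ex <- simulateExperiment(net,
                data.frame(protein = reg, sign = 1L), effectSize = 2,
                noiseSd = noise, plateSd = 0.2, nBackgroundGenes = 0,
                seed = s)
            fit <- adjustWithinGene(fitFactorialModel(ex$se),
                                    nDraws = 5000, seed = s)
            ct <- contrastTable(fit)
            ct <- ct[ct$contrast == "compound-vehicle@DIV14", ]
            obs <- setNames(ifelse(abs(ct$log2FC) >= 1.5 &
                                   ct$fwerP <= 0.05,
                                   sign(ct$log2FC), 0L), ct$gene)
            rk <- rankHypotheses(net, obs, deltaMax = 5, nPerm = 500,
                                 seed = s)
            top <- rk[rk$delta == 2 & rk$rank == 1, ]
            hits <- hits + (top$protein == reg && top$sign == 1L)
        }
        hits / length(seeds)
    }
    expect_gte(recoverRate(0.3, 1:20), 0.9)
    # recovery degrades monotonically with noise
    r1 <- recoverRate(0.3, 1:8)
    r2 <- recoverRate(1.5, 1:8)
    r3 <- recoverRate(3.0, 1:8)
    expect_gte(r1, r2)
    expect_gte(r2, r3)
    expect_gt(r1, r3)
})
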