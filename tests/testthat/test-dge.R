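test_that("quantile normalisation forces the shared distribution", {
    # two identical columns are a fixed point
    m <- cbind(a = c(1, 5, 3), b = c(1, 5, 3))
    expect_equal(normalizeQuantile(m), m)

    # hand-computed reference of the standard algorithm
    m2 <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
    out <- normalizeQuantile(m2)
    expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
    expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

    # defining property: equal column means afterwards
    set.seed(1)
    m3 <- matrix(rnorm(60, sd = 3), 10, 6)
    cm <- colMeans(normalizeQuantile(m3))
    expect_equal(max(cm) - min(cm), 0, tolerance = 1e-12)

    expect_error(normalizeQuantile(matrix(1:3, 3, 1)), "2 samples")
})

test_that("the factorial fit recovers noiseless contrasts exactly", {
    net <- simulateNetwork(30, 2.5, 0.3, seed = 2)
    reg <- data.frame(protein = nodes(net)[1], sign = 1L)
    ex <- simulateExperiment(net, reg, effectSize = 2, noiseSd = 0,
                             plateSd = 0, nBackgroundGenes = 10, seed = 3)
    fit <- fitFactorialModel(ex$se)
    truth <- perturbedGenes(ex$truth)
    est14 <- fit$estimates[truth$gene, "compound-vehicle@DIV14"]
    expect_equal(unname(est14), truth$sign * 2, tolerance = 1e-9)
    # unperturbed genes come out at exactly zero effect with zero SE
    bg <- setdiff(rownames(fit$estimates), truth$gene)
    expect_equal(max(abs(fit$estimates[bg, ])), 0, tolerance = 1e-9)
})

test_that("a balanced two-group toy gives contrast 2 with SE 0", {
    design <- data.frame(sample = c("s1", "s2", "s3", "s4"),
                         treatment = c("vehicle", "vehicle", "compound",
                                       "compound"),
                         div = 3L, plate = "PL1",
                         replicate = c(1L, 2L, 1L, 2L))
    m <- matrix(c(1, 1, 3, 3), 1, 4,
                dimnames = list("g1", design$sample))
    fit <- fitFactorialModel(m, design)
    expect_equal(unname(fit$estimates[1, 1]), 2)
    expect_equal(unname(fit$se[1, 1]), 0)
})

test_that("estimates agree with an independent normal-equations solve", {
    net <- simulateNetwork(25, 2, 0.3, seed = 4)
    reg <- data.frame(protein = nodes(net)[2], sign = -1L)
    ex <- simulateExperiment(net, reg, noiseSd = 0.4, plateSd = 0.3,
                             nBackgroundGenes = 15, seed = 5)
    m <- SummarizedExperiment::assay(ex$se)
    d <- as.data.frame(SummarizedExperiment::colData(ex$se))
    fit <- fitFactorialModel(m, d)
    # oracle: generic per-gene lm with the same parameterisation
    d$treatment <- factor(d$treatment, levels = unique(d$treatment))
    d$div <- factor(d$div)
    for (g in rownames(m)[c(1, 10, 25)]) {
        lmfit <- lm(m[g, ] ~ treatment * div + plate, data = d)
        cf <- coef(lmfit)
        est3 <- cf["treatmentcompound"]
        est14 <- cf["treatmentcompound"] + cf["treatmentcompound:div14"]
        expect_equal(unname(fit$estimates[g, "compound-vehicle@DIV3"]),
                     unname(est3), tolerance = 1e-8)
        expect_equal(unname(fit$estimates[g, "compound-vehicle@DIV14"]),
                     unname(est14), tolerance = 1e-8)
    }
})

test_that("rank-deficient designs fail with the aliased terms named", {
    design <- makeFactorialDesign()
    design$plate <- design$treatment   # plate aliased with treatment
    m <- matrix(rnorm(2 * nrow(design)), 2, nrow(design),
                dimnames = list(c("g1", "g2"), design$sample))
    expect_error(fitFactorialModel(m, design), "aliased")
})

test_that("max-|t| adjustment matches closed forms and stays monotone", {
    # degenerate family of one contrast: adjusted equals raw
    one <- syntheticFit(matrix(2.1, 3, 1), matrix(1, 1, 1), df = 10)
    adj1 <- adjustWithinGene(one, nDraws = 2000, seed = 1)
    expect_equal(adj1$fwerP, adj1$rawP)

    # three effectively independent contrasts at raw p = 0.05 each:
    # adjusted p approx 1 - 0.95^3 (high df makes the shared chi negligible)
    df <- 1e5
    tval <- qt(0.975, df)
    fit3 <- syntheticFit(matrix(tval, 1, 3), diag(3), df = df)
    adj3 <- adjustWithinGene(fit3, nDraws = 2e5, seed = 2)
    expect_equal(unname(adj3$fwerP[1, 1]), 1 - 0.95^3, tolerance = 0.005)

    # monotone non-decreasing in |t| rank order, never below raw
    set.seed(3)
    R <- stats::cov2cor(crossprod(matrix(rnorm(9), 3, 3)) + diag(3))
    tm <- matrix(rnorm(30, sd = 2), 10, 3)
    fitR <- syntheticFit(tm, R, df = 8)
    adjR <- adjustWithinGene(fitR, nDraws = 5000, seed = 4)
    o <- order(abs(as.vector(adjR$t)))
    expect_true(all(diff(as.vector(adjR$fwerP)[o]) <= 1e-12))
    expect_true(all(adjR$fwerP >= adjR$rawP))
})

test_that("max-|t| Monte-Carlo agrees with the mvtnorm oracle", {
    skip_if_not_installed("mvtnorm")
    set.seed(5)
    R <- stats::cov2cor(crossprod(matrix(rnorm(9), 3, 3)) + diag(3))
    df <- 12
    tv <- c(1.2, 2.4, 3.1)
    fit <- syntheticFit(matrix(tv, 1, 3), R, df = df)
    adj <- adjustWithinGene(fit, nDraws = 2e5, seed = 6)
    for (j in 1:3) {
        oracle <- 1 - as.numeric(mvtnorm::pmvt(
            lower = rep(-abs(tv[j]), 3), upper = rep(abs(tv[j]), 3),
            corr = R, df = df))
        expect_equal(unname(adj$fwerP[1, j]), oracle, tolerance = 0.01)
    }
})

test_that("the p* rule resolves significant contrasts as specified", {
    # hand-executed worked example: minima (0.005, 0.02, 0.5)
    ct <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 3),
                     contrast = rep(c("c1", "c2", "c3"), 3),
                     log2FC = 0,
                     fwerP = c(0.005, 0.8, 0.9,
                               0.02, 0.03, 0.7,
                               0.5, 0.6, 0.9))
    ps <- pstarProcedure(ct)
    expect_equal(sort(unname(ps$genes$q)), c(0.015, 0.03, 0.5))
    expect_equal(ps$pStar, 0.02)
    expect_equal(ps$table$significant, ct$fwerP <= 0.02)

    # all minima 1: p* undefined, nothing significant
    ct1 <- data.frame(gene = c("g1", "g2"), contrast = "c1", log2FC = 0,
                      fwerP = c(1, 1))
    ps1 <- pstarProcedure(ct1)
    expect_true(is.na(ps1$pStar))
    expect_false(any(ps1$table$significant))

    # single gene: q = min p = p*, its contrast significant
    ct2 <- data.frame(gene = "g1", contrast = "c1", log2FC = 0,
                      fwerP = 0.01)
    ps2 <- pstarProcedure(ct2)
    expect_equal(ps2$pStar, 0.01)
    expect_true(ps2$table$significant)

    expect_error(pstarProcedure(ct[0, ]), "empty")
})

test_that("BH adjustment agrees with direct sort-and-cummin evaluation", {
    set.seed(7)
    for (i in 1:5) {
        p <- runif(50)^2
        expect_equal(p.adjust(p, method = "BH"), bhDirect(p))
    }
})

test_that("DEG selection applies inclusive boundaries and direction", {
    ct <- data.frame(gene = c("g1", "g2", "g3"),
                     contrast = "c1",
                     log2FC = c(1.6, -1.5, 2.0),
                     fwerP = c(0.01, 0.05, 0.06))
    out <- selectDegs(ct)
    expect_equal(out$gene, c("g1", "g2"))
    expect_equal(out$direction, c("up", "down"))
})

test_that("the DE stage controls FDR under the global null", {
    net <- simulateNetwork(30, 2, 0.3, seed = 1)
    design <- makeFactorialDesign()
    falsePos <- 0; total <- 0
    for (s in 1:100) {
        ex <- simulateExperiment(net, NULL, noiseSd = 0.3, plateSd = 0.2,
                                 nBackgroundGenes = 120, seed = s)
        fit <- fitFactorialModel(ex$se)
        fit <- adjustWithinGene(fit, nDraws = 5000, seed = s)
        ps <- pstarProcedure(contrastTable(fit))
        falsePos <- falsePos + sum(ps$genes$q < 0.05)
        total <- total + nrow(ps$genes)
    }
    frac <- falsePos / total
    expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("planted perturbations are recovered in the day-14 DEG set", {
    net <- simulateNetwork(40, 2.5, 0.3, seed = 6)
    reg <- data.frame(protein = nodes(net)[1], sign = 1L)
    found <- 0; planted <- 0
    for (s in 1:20) {
        ex <- simulateExperiment(net, reg, effectSize = 2, noiseSd = 0.3,
                                 plateSd = 0.2, nBackgroundGenes = 60,
                                 seed = s)
        fit <- adjustWithinGene(fitFactorialModel(ex$se), nDraws = 5000,
                                seed = s)
        degs <- selectDegs(contrastTable(fit))
        d14 <- unique(degs$gene[degs$contrast == "compound-vehicle@DIV14"])
        truth <- perturbedGenes(ex$truth)$gene
        found <- found + length(intersect(truth, d14))
        planted <- planted + length(truth)
    }
    expect_gte(found / planted, 0.9)
})
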