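## Factorial differential expression with within-gene FWER control and the
## p* contrast-resolution rule.
##
## Model: per gene, ordinary least squares on treatment x DIV (days in
## vitro), with plate as a fixed covariate whenever the design has more than
## one plate. The reported contrasts are the within-DIV treatment
## differences. The within-gene family of those contrasts is adjusted by a
## single-step max-|t| procedure (Monte-Carlo from the multivariate t
## implied by the shared contrast correlation and residual df); the p* rule
## then resolves which contrasts are significant package-wide.

#' Quantile-normalise an expression matrix
#'
#' Forces every sample (column) onto the same distribution: the row-wise
#' mean of the sorted columns, with ties sharing the mean of their would-be
#' quantiles. Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param x numeric matrix (genes x samples) or a SummarizedExperiment
#'   (first assay is used).
#' @return object of the same shape with normalised values.
#' @export
normalizeQuantile <- function(x) {
    se <- NULL
    if (is(x, "SummarizedExperiment")) {
        se <- x
        x <- SummarizedExperiment::assay(x)
    }
    if (!is.matrix(x) || ncol(x) < 2L)
        stop("need a matrix with at least 2 samples")
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    if (!is.null(se)) {
        SummarizedExperiment::assay(se) <- out
        return(se)
    }
    out
}

#' Fit the per-gene factorial model
#'
#' Ordinary least squares of each gene's expression on treatment x DIV
#' (both factors, fully crossed), plus plate as a fixed covariate when the
#' design has more than one plate level. Returns the within-DIV treatment
#' contrasts (second treatment level minus the first, at each DIV) with
#' estimates, standard errors, t statistics, raw p-values, the residual
#' degrees of freedom and the contrast correlation matrix, which is shared
#' across genes because the design is.
#'
#' @param x genes x samples matrix, or SummarizedExperiment whose colData
#'   carries the design.
#' @param design design table (see [makeFactorialDesign()]); must cover all
#'   samples and have every treatment x DIV cell non-empty.
#' @return A \code{FactorialFit} list: \code{estimates}, \code{se},
#'   \code{t}, \code{rawP} (genes x contrasts), \code{df}, \code{corr},
#'   \code{contrasts}, \code{sigma2}.
#' @export
fitFactorialModel <- function(x, design = NULL) {
    if (is(x, "SummarizedExperiment")) {
        if (is.null(design))
            design <- as.data.frame(SummarizedExperiment::colData(x))
        x <- SummarizedExperiment::assay(x)
    }
    if (is.null(design)) stop("a design table is required")
    if (!all(colnames(x) %in% design$sample))
        stop("design does not cover all samples")
    design <- design[match(colnames(x), design$sample), , drop = FALSE]
    design$treatment <- factor(design$treatment,
                               levels = unique(design$treatment))
    design$div <- factor(design$div)
    design$plate <- factor(design$plate)
    cells <- table(design$treatment, design$div)
    if (any(cells == 0L))
        stop("every treatment x DIV cell must be non-empty")
    rhs <- if (nlevels(design$div) > 1L) "treatment * div" else "treatment"
    if (nlevels(design$plate) > 1L) rhs <- paste(rhs, "+ plate")
    form <- stats::as.formula(paste("~", rhs))
    X <- stats::model.matrix(form, design)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
        aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
        stop("rank-deficient design; aliased terms: ",
             paste(aliased, collapse = ", "))
    }
    XtXinv <- chol2inv(qr.R(qx))
    dimnames(XtXinv) <- list(colnames(X), colnames(X))
    ## contrasts: treatment2 - treatment1 at each DIV, via predicted cells
    trt <- levels(design$treatment)
    divs <- levels(design$div)
    nd <- data.frame(treatment = factor(rep(trt, length(divs)),
                                        levels = trt),
                     div = factor(rep(divs, each = 2L), levels = divs),
                     plate = factor(levels(design$plate)[1L],
                                    levels = levels(design$plate)))
    Xnd <- stats::model.matrix(form, nd)
    C <- Xnd[seq(2L, nrow(Xnd), by = 2L), , drop = FALSE] -
         Xnd[seq(1L, nrow(Xnd), by = 2L), , drop = FALSE]
    rownames(C) <- sprintf("%s-%s@DIV%s", trt[2L], trt[1L], divs)
    beta <- qr.coef(qx, t(x))                       # p x G
    est <- t(C %*% beta)                            # G x k
    resid <- t(x) - X %*% beta
    df <- nrow(X) - qx$rank
    sigma2 <- colSums(resid^2) / df
    V0 <- C %*% XtXinv %*% t(C)
    se <- sqrt(outer(sigma2, diag(V0)))
    ## guard the noiseless limit: residuals at machine precision must not
    ## manufacture significance for genes whose contrasts are numerically 0
    zeroSe <- se < 1e-12
    tiny <- abs(est) < 1e-8
    se[zeroSe] <- 0
    tstat <- est / se
    tstat[zeroSe & tiny] <- 0
    tstat[zeroSe & !tiny] <- sign(est[zeroSe & !tiny]) * Inf
    rawP <- 2 * pt(-abs(tstat), df)
    dimnames(est) <- dimnames(se) <- dimnames(tstat) <- dimnames(rawP) <-
        list(rownames(x), rownames(C))
    structure(list(estimates = est, se = se, t = tstat, rawP = rawP,
                   df = df, corr = stats::cov2cor(V0),
                   contrasts = rownames(C), sigma2 = sigma2,
                   model = deparse(form),
                   log = list(plateCovariate = nlevels(design$plate) > 1L)),
              class = "FactorialFit")
}

#' @export
print.FactorialFit <- function(x, ...) {
    cat("FactorialFit:", nrow(x$estimates), "genes,",
        length(x$contrasts), "contrasts (", paste(x$contrasts,
        collapse = ", "), "), residual df =", x$df, "\n")
    invisible(x)
}

#' Within-gene FWER adjustment by single-step max-|t|
#'
#' Adjusts each contrast's p-value for the within-gene family of contrasts:
#' the adjusted p of contrast j is P(max over the family of |T| >= |t_j|)
#' under the joint null, where T follows the multivariate t distribution
#' implied by the shared contrast correlation matrix and residual df. The
#' tail probability is estimated once by Monte-Carlo (the correlation
#' structure is identical for every gene) with a fixed, logged seed.
#' Adjusted p-values are never smaller than the raw ones, and a family of
#' one contrast is returned unchanged.
#'
#' @param fit a \code{FactorialFit} from [fitFactorialModel()].
#' @param nDraws Monte-Carlo draws (a value below 1000 is accepted but
#'   flagged in the run log with a warning).
#' @param seed RNG seed.
#' @return the fit with an added genes x contrasts matrix \code{fwerP} and
#'   Monte-Carlo metadata in \code{log}.
#' @export
adjustWithinGene <- function(fit, nDraws = 20000L, seed = 1L) {
    stopifnot(inherits(fit, "FactorialFit"))
    k <- length(fit$contrasts)
    if (nDraws < 1000L) {
        warning("nDraws < 1000: max-|t| tail estimate will be coarse")
        fit$log$lowDraws <- TRUE
    }
    if (k == 1L) {
        fit$fwerP <- fit$rawP
    } else {
        R <- fit$corr
        U <- tryCatch(chol(R), error = function(e)
            chol(R + diag(1e-8, nrow(R))))
        set.seed(seed)
        Z <- matrix(rnorm(nDraws * k), nDraws, k) %*% U
        W <- sqrt(rchisq(nDraws, fit$df) / fit$df)
        maxT <- sort(apply(abs(Z / W), 1L, max))
        tv <- abs(fit$t)
        cnt <- nDraws - findInterval(tv, maxT)  # draws with maxT > |t|
        fwer <- matrix(cnt / nDraws, nrow(tv), ncol(tv),
                       dimnames = dimnames(tv))
        fit$fwerP <- pmax(fwer, fit$rawP)
    }
    fit$log$nDraws <- nDraws
    fit$log$seed <- seed
    fit
}

#' Long-format contrast table
#'
#' @param fit a \code{FactorialFit}, after [adjustWithinGene()].
#' @return data.frame with one row per gene x contrast: \code{gene},
#'   \code{contrast}, \code{log2FC}, \code{se}, \code{t}, \code{rawP},
#'   \code{fwerP}.
#' @export
contrastTable <- function(fit) {
    stopifnot(inherits(fit, "FactorialFit"))
    if (is.null(fit$fwerP))
        stop("run adjustWithinGene() first")
    k <- length(fit$contrasts)
    genes <- rownames(fit$estimates)
    data.frame(gene = rep(genes, times = k),
               contrast = rep(fit$contrasts, each = length(genes)),
               log2FC = as.vector(fit$estimates),
               se = as.vector(fit$se),
               t = as.vector(fit$t),
               rawP = as.vector(fit$rawP),
               fwerP = as.vector(fit$fwerP))
}

#' The p* contrast-resolution procedure
#'
#' Per gene, take the minimum FWER-adjusted p over its contrasts;
#' Benjamini-Hochberg-adjust these minima across genes; p* is the largest
#' minimum among genes passing the FDR threshold. A contrast is significant
#' overall iff its FWER p-value is at most p* (so the gene that defines p*
#' is itself significant). When no gene passes the FDR threshold, p* is
#' undefined and nothing is significant.
#'
#' @param ct contrast table from [contrastTable()] (columns \code{gene},
#'   \code{fwerP} required).
#' @param fdr across-gene false discovery rate (default 0.05).
#' @return A \code{PStarResult} list: \code{pStar} (NA when undefined),
#'   \code{fdr}, \code{genes} (per-gene minima and BH q), \code{table}
#'   (the input with a \code{significant} flag).
#' @export
pstarProcedure <- function(ct, fdr = 0.05) {
    if (!nrow(ct)) stop("empty contrast table")
    if (any(is.na(ct$fwerP))) stop("FWER p-values must be present")
    minP <- tapply(ct$fwerP, ct$gene, min)
    q <- p.adjust(minP, method = "BH")
    pass <- q < fdr
    pStar <- if (any(pass)) max(minP[pass]) else NA_real_
    ct$significant <- if (is.na(pStar)) FALSE else ct$fwerP <= pStar
    structure(list(pStar = pStar, fdr = fdr,
                   genes = data.frame(gene = names(minP),
                                      minFwerP = as.numeric(minP),
                                      q = as.numeric(q),
                                      passFdr = as.logical(pass)),
                   table = ct),
              class = "PStarResult")
}

#' @export
print.PStarResult <- function(x, ...) {
    cat("PStarResult: p* =",
        if (is.na(x$pStar)) "undefined" else format(x$pStar),
        "at FDR", x$fdr, "-", sum(x$genes$passFdr), "of",
        nrow(x$genes), "genes pass;", sum(x$table$significant),
        "significant contrasts\n")
    invisible(x)
}

#' Select differentially expressed genes
#'
#' Retains contrast rows with |log2FC| at or above \code{lfcMin} and
#' adjusted p at or below \code{pMax} (both boundaries inclusive) and
#' records the direction of change.
#'
#' @param ct contrast table (needs \code{log2FC} and the chosen p column).
#' @param lfcMin absolute log2 fold-change threshold (default 1.5).
#' @param pMax adjusted-p threshold (default 0.05).
#' @param pColumn which p-value column to threshold (default the
#'   within-gene FWER-adjusted one).
#' @return the retained rows with an added \code{direction} column
#'   (\code{"up"}/\code{"down"}).
#' @export
selectDegs <- function(ct, lfcMin = 1.5, pMax = 0.05, pColumn = "fwerP") {
    keep <- abs(ct$log2FC) >= lfcMin & ct[[pColumn]] <= pMax
    out <- ct[keep, , drop = FALSE]
    out$direction <- ifelse(out$log2FC >= 0, "up", "down")
    rownames(out) <- NULL
    out
}
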