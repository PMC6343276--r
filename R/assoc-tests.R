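.newTestResult <- function(statistic, pValue, testName, df, converged,
                           method = "analytic") {
    new("TestResult", statistic = statistic, pValue = pValue,
        testName = testName, dfOrEigencount = as.integer(df),
        converged = converged, method = method)
}

.checkPhenotype <- function(y, n) {
    y <- as.integer(y)
    if (length(y) != n)
        stop("phenotype length does not match the genotype data")
    if (!all(y == 0L | y == 1L))
        stop("phenotype must be binary (1 = case, 0 = control)")
    if (length(unique(y)) < 2L)
        stop("phenotype must contain both cases and controls")
    y
}

# Deterministic label canonicalization: both tests are mathematically
# invariant under exchanging case and control labels (pooled weights,
# symmetric likelihood), but floating-point evaluation of y - mu is not.
# Orienting every phenotype to its minority class (ties broken on the
# first element) makes the reversal symmetry exact to the bit.
.canonicalLabels <- function(y) {
    k <- sum(y)
    n <- length(y)
    if (k > n - k || (2L * k == n && y[1L] == 1L)) 1L - y else y
}

# Binomial deviance of the intercept-only model.
.nullDeviance <- function(y) {
    p0 <- mean(y)
    -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
}

.burdenTestScores <- function(scores, phenotype) {
    y <- .canonicalLabels(.checkPhenotype(phenotype, length(scores)))
    if (var(scores) == 0)
        return(.newTestResult(0, 1, "burden", 1L, FALSE))
    separated <- FALSE
    fit <- withCallingHandlers(
        glm.fit(cbind(1, scores), y, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                separated <<- TRUE
            invokeRestart("muffleWarning")
        })
    dev0 <- .nullDeviance(y)
    stat <- max(dev0 - fit$deviance, 0)
    # boundary fitted probabilities signal (quasi-)complete separation
    # even when IRLS reports convergence
    mu <- fit$fitted.values
    if (any(mu < 1e-8) || any(mu > 1 - 1e-8))
        separated <- TRUE
    converged <- isTRUE(fit$converged) && !separated
    .newTestResult(stat, pchisq(stat, df = 1, lower.tail = FALSE),
                   "burden", 1L, converged)
}

#' Weighted burden test (logistic regression likelihood-ratio test)
#'
#' Tests association between the collapsed weighted genetic score (see
#' [burdenScores()]) and case status by comparing intercept-only and
#' intercept-plus-score logistic regressions fitted by iteratively
#' reweighted least squares. The p-value is the likelihood-ratio
#' (deviance) statistic referred to chi-square with 1 degree of freedom.
#'
#' Degenerate inputs are reported rather than failed on: a zero-variance
#' score yields `p = 1` with `converged = FALSE`; under complete
#' separation the statistic is the (finite) deviance drop at the last
#' IRLS iterate and `converged = FALSE`.
#'
#' @param object numeric vector of per-individual scores, or a
#'   [RareVariantCohort-class] (scores are then computed with
#'   [mbWeights()] and [burdenScores()]).
#' @param phenotype binary vector (required for the score-vector
#'   method).
#' @param pseudocount passed to [mbWeights()] for the cohort method.
#' @param ... unused.
#' @return A [TestResult-class].
#' @examples
#' set.seed(1)
#' score <- rnorm(100)
#' y <- rbinom(100, 1, plogis(score))
#' pValue(burdenTest(score, y))
#' @export
setMethod("burdenTest", "numeric",
    function(object, phenotype, ...) .burdenTestScores(object, phenotype))

#' @rdname burdenTest
#' @export
setMethod("burdenTest", "RareVariantCohort",
    function(object, pseudocount = 1, ...) {
        g <- genotypes(object)
        w <- mbWeights(g, pseudocount)
        .burdenTestScores(burdenScores(g, w), caseStatus(object))
    })

.skatTestMatrix <- function(g, phenotype, weights = NULL,
                            eigenTol = 1e-10) {
    n <- nrow(g)
    y <- .canonicalLabels(.checkPhenotype(phenotype, n))
    if (is.null(weights))
        weights <- mbWeights(g)
    w <- if (is(weights, "WeightVector")) weights@weights
         else as.numeric(weights)
    if (length(w) != ncol(g))
        stop("number of loci in genotypes and weights must agree")
    cs <- colSums(g)
    if (all(n * colSums(g * g) == cs^2))  # zero variance at every locus
        return(.newTestResult(0, 1, "skat", 0L, FALSE))
    mu <- mean(y)
    v <- mu * (1 - mu)
    # score statistic Q = (y - mu)' G W^2 G' (y - mu)
    z <- w * as.vector(crossprod(g, y - mu))
    q <- sum(z^2)
    # kernel eigenvalues: W G' P0 G W with P0 = v (I - 11'/n) for the
    # intercept-only binomial null model
    k <- v * (tcrossprod(w) * (crossprod(g) - tcrossprod(cs) / n))
    lambda <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
    lambda <- lambda[lambda > eigenTol * max(lambda)]
    if (!length(lambda))
        return(.newTestResult(q, 1, "skat", 0L, FALSE))
    pv <- pMixtureChisq(q, lambda)
    .newTestResult(q, min(max(pv$p, 0), 1), "skat", length(lambda),
                   TRUE, pv$method)
}

#' SKAT: sequence kernel association (variance-component score) test
#'
#' Computes the SKAT statistic
#' `Q = (y - mu)' G W^2 G' (y - mu)` for a binary phenotype `y`, genotype
#' matrix `G` and diagonal weight matrix `W`, under the intercept-only
#' logistic null model (`mu` = case fraction; no covariates are
#' simulated). The null distribution of `Q` is the weighted sum
#' `sum_k lambda_k chi2_1`, with `lambda_k` the nonzero eigenvalues of
#' `W G' P0 G W` where `P0` is the null-model projected variance matrix;
#' eigenvalues below `1e-10` times the largest are discarded. P-values
#' come from [pMixtureChisq()] (characteristic-function inversion with
#' moment-matching fallback).
#'
#' By default loci are weighted with the pooled-sample Madsen-Browning
#' weights of [mbWeights()], which makes the test invariant under
#' case/control label reversal; pass a different `weights` argument
#' (e.g. Beta-density weights) to override.
#'
#' An all-monomorphic bin yields `p = 1` with `converged = FALSE`.
#'
#' @param object genotype matrix (individuals in rows) or a
#'   [RareVariantCohort-class].
#' @param phenotype binary vector (matrix method).
#' @param weights a [WeightVector-class] or numeric vector; default
#'   Madsen-Browning pooled weights.
#' @param ... unused.
#' @return A [TestResult-class] with `dfOrEigencount` the number of
#'   retained eigenvalues.
#' @examples
#' set.seed(1)
#' g <- matrix(rbinom(600, 2, 0.1), nrow = 200)
#' y <- rep(0:1, each = 100)
#' pValue(skatTest(g, y))
#' @export
setMethod("skatTest", "matrix",
    function(object, phenotype, weights = NULL, ...)
        .skatTestMatrix(object, phenotype, weights))

#' @rdname skatTest
#' @export
setMethod("skatTest", "RareVariantCohort",
    function(object, weights = NULL, ...)
        .skatTestMatrix(genotypes(object), caseStatus(object), weights))

#' Permutation p-value oracle for either test
#'
#' Recomputes the observed test statistic under `nPerm` random
#' permutations of the phenotype labels and returns
#' `(1 + #permuted >= observed) / (1 + nPerm)`. Weights are computed once
#' from the pooled genotypes (they are permutation-invariant). Intended
#' as a slow, assumption-free cross-check of the analytic p-values.
#' Uses the current R random number generator.
#'
#' @param genotypes matrix of minor-allele counts (individuals in rows).
#' @param phenotype binary vector.
#' @param whichTest `"skat"` or `"burden"`.
#' @param nPerm number of permutations (>= 1).
#' @param pseudocount passed to [mbWeights()].
#' @return A single permutation p-value.
#' @export
permutationPvalue <- function(genotypes, phenotype,
                              whichTest = c("skat", "burden"),
                              nPerm = 1000, pseudocount = 1) {
    whichTest <- match.arg(whichTest)
    nPerm <- as.integer(nPerm)
    if (nPerm < 1L)
        stop("nPerm must be at least 1")
    n <- nrow(genotypes)
    y <- .checkPhenotype(phenotype, n)
    wv <- mbWeights(genotypes, pseudocount)
    if (whichTest == "skat") {
        b <- genotypes %*% diag(wv@weights, ncol(genotypes))
        mu <- mean(y)
        base <- mu * colSums(b)
        qOf <- function(yy) sum((as.vector(crossprod(b, yy)) - base)^2)
        obs <- qOf(y)
        exceed <- 0L
        for (i in seq_len(nPerm))
            exceed <- exceed + (qOf(sample(y)) >= obs)
    } else {
        s <- burdenScores(genotypes, wv)
        obs <- .burdenTestScores(s, y)@statistic
        exceed <- 0L
        for (i in seq_len(nPerm))
            exceed <- exceed +
                (.burdenTestScores(s, sample(y))@statistic >= obs)
    }
    (1 + exceed) / (1 + nPerm)
}

#' @rdname rvpower-accessors
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @rdname rvpower-accessors
#' @export
setMethod("statistic", "TestResult", function(object) object@statistic)

#' @rdname rvpower-accessors
#' @export
setMethod("testName", "TestResult", function(object) object@testName)

setMethod("show", "TestResult", function(object) {
    cat(sprintf("TestResult [%s]: statistic = %.6g, p = %.4g\n",
                object@testName, object@statistic, object@pValue))
    cat(sprintf("  df/eigencount = %d, converged = %s, method = %s\n",
                object@dfOrEigencount, object@converged, object@method))
})

#' Convert test results to a data frame
#'
#' @param x a [TestResult-class] or a list of them.
#' @param row.names,optional,... passed through for generic
#'   compatibility; unused.
#' @return A `data.frame` with columns `test`, `statistic`, `p_value`,
#'   `df_or_eigencount`, `converged`, `method`.
#' @method as.data.frame TestResult
#' @export
as.data.frame.TestResult <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
    data.frame(test = x@testName, statistic = x@statistic,
               p_value = x@pValue, df_or_eigencount = x@dfOrEigencount,
               converged = x@converged, method = x@method,
               stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "TestResult",
    function(x, row.names = NULL, optional = FALSE, ...)
        as.data.frame.TestResult(x, row.names, optional, ...))
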