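# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Brute-force logistic likelihood-ratio deviance by coarse-to-fine grid
# search over (intercept, slope); independent of glm/IRLS.
oracleLogisticLrt <- function(score, y, rounds = 6, halfWidth = 10) {
    loglik <- function(b0, b1) {
        eta <- b0 + b1 * score
        sum(y * eta - log1p(exp(eta)))
    }
    maximise <- function(fixedSlopeZero) {
        c0 <- 0
        c1 <- 0
        hw <- halfWidth
        for (r in seq_len(rounds)) {
            b0s <- seq(c0 - hw, c0 + hw, length.out = 41)
            b1s <- if (fixedSlopeZero) 0
                   else seq(c1 - hw, c1 + hw, length.out = 41)
            ll <- outer(b0s, b1s, Vectorize(loglik))
            best <- arrayInd(which.max(ll), dim(ll))
            c0 <- b0s[best[1]]
            c1 <- b1s[best[2]]
            hw <- hw / 8
        }
        loglik(c0, c1)
    }
    2 * (maximise(FALSE) - maximise(TRUE))
}

# Monte Carlo prevalence estimate written independently of the package's
# estimator: simulates full genotype vectors and Bernoulli disease
# status, returning the case fraction (binomial standard error applies).
oracleBernoulliPrevalence <- function(mafs, model, nSim) {
    q <- freqs(mafs)
    p <- length(q)
    g <- matrix(rbinom(nSim * p, 2, rep(q, each = nSim)), nSim, p)
    pr <- plogis(intercept(model) + as.vector(g %*% logOdds(model)))
    mean(runif(nSim) < pr)
}

# Small deterministic cohort for I/O and algebra tests.
toyCohort <- function(n = 6, p = 4, seed = 11) {
    set.seed(seed)
    g <- matrix(rbinom(n * p, 2, 0.25), n, p)
    RareVariantCohort(g, rep(c(1L, 0L), length.out = n),
                      maf = seq(0.05, 0.2, length.out = p))
}
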