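test_that("the SKAT statistic is a non-negative quadratic form", {
    set.seed(17)
    for (i in 1:10) {
        n <- sample(20:60, 1)
        p <- sample(2:6, 1)
        g <- matrix(rbinom(n * p, 2, runif(p, 0.05, 0.3)), n, p,
                    byrow = TRUE)
        y <- rbinom(n, 1, 0.4)
        if (length(unique(y)) < 2) y[1] <- 1L - y[1]
        r <- skatTest(g, y)
        expect_gte(statistic(r), 0)
        expect_gte(pValue(r), 0)
        expect_lte(pValue(r), 1)
    }
})

test_that("a single-variant bin reduces to the classical score test", {
    set.seed(18)
    g <- matrix(rbinom(80, 2, 0.2), 80, 1)
    y <- rbinom(80, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1L - y[1]
    r <- skatTest(g, y)
    expect_equal(r@dfOrEigencount, 1L)
    # compute the single eigenvalue independently
    w <- weights(mbWeights(g))
    mu <- mean(y)
    v <- mu * (1 - mu)
    lam <- v * w^2 * sum((g - mean(g))^2)
    expect_equal(pValue(r),
                 pchisq(statistic(r) / lam, 1, lower.tail = FALSE),
                 tolerance = 1e-5)
})

test_that("an all-monomorphic bin yields p = 1, not convergence", {
    g <- matrix(0L, 30, 4)
    g[, 2] <- 2L
    y <- rep(c(1L, 0L), 15)
    r <- skatTest(g, y)
    expect_equal(pValue(r), 1)
    expect_false(r@converged)
})

test_that("analytic p converges to the permutation law as n grows", {
    # the mixture-of-chi-squares null is asymptotic in n; at n = 200
    # it should sit within Monte Carlo noise plus a small O(1/n)
    # finite-population allowance of the exact permutation p
    set.seed(19)
    n <- 200
    g <- matrix(rbinom(n * 3, 2, c(0.15, 0.25, 0.35)), n, 3,
                byrow = TRUE)
    y <- rep(c(1L, 0L), n / 2)
    analytic <- pValue(skatTest(g, y))
    nPerm <- 5e4
    perm <- permutationPvalue(g, y, "skat", nPerm = nPerm)
    se <- sqrt(perm * (1 - perm) / nPerm)
    expect_lt(abs(analytic - perm), 3 * se + 3 / n)
})

test_that("permutation p-value bounds hold by construction", {
    set.seed(20)
    g <- matrix(rbinom(40 * 2, 2, 0.3), 40, 2)
    y <- rep(c(1L, 0L), 20)
    p1 <- permutationPvalue(g, y, "skat", nPerm = 50)
    expect_gte(p1, 1 / 51)
    expect_lte(p1, 1)
    p2 <- permutationPvalue(g, y, "burden", nPerm = 30)
    expect_gte(p2, 1 / 31)
    expect_lte(p2, 1)
})

test_that("burden permutation oracle tracks the analytic LRT p-value", {
    set.seed(23)
    n <- 400
    g <- matrix(rbinom(n * 5, 2, 0.1), n, 5)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1L - y[1]
    analytic <- pValue(burdenTest(burdenScores(g, mbWeights(g)), y))
    perm <- permutationPvalue(g, y, "burden", nPerm = 2000)
    se <- sqrt(perm * (1 - perm) / 2000)
    expect_lt(abs(analytic - perm), 4 * se + 0.02)
})
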