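test_that("ascertainment fills the quotas exactly, in any imbalance", {
    set.seed(77)
    s <- sampleMafSpectrum(30)
    m <- calibrateIntercept(s, buildEffectModel(30, "uniform_or", 4))
    for (quota in list(c(200, 1000), c(10, 300), c(0, 50), c(25, 0))) {
        co <- sampleCohort(quota[1], quota[2], s, m)
        expect_equal(nCases(co), quota[1])
        expect_equal(nControls(co), quota[2])
        expect_equal(dim(genotypes(co)), c(sum(quota), 30))
        expect_true(all(genotypes(co) %in% 0:2))
        expect_false(anyNA(genotypes(co)))
        expect_false(anyNA(caseStatus(co)))
    }
})

test_that("the draw cap raises an error naming the unfilled quota", {
    s <- MafSpectrum(rep(0.005, 5))
    m <- calibrateIntercept(s, buildEffectModel(5, "null"))
    set.seed(3)
    expect_error(sampleCohort(500, 10, s, m, maxDraws = 100),
                 "case quota")
})

test_that("null-model genotypes follow Hardy-Weinberg marginals", {
    # pooled minor-allele counts at each locus ~ Binomial(2n, q_j);
    # one-degree chi-square goodness of fit at level 0.01 across 143
    # independent loci should fail only a handful of times
    set.seed(88)
    s <- sampleMafSpectrum(143, shape = 1)
    m <- calibrateIntercept(s, buildEffectModel(143, "null"))
    co <- sampleCohort(1500, 1500, s, m)
    n2 <- 2 * 3000
    counts <- colSums(genotypes(co))
    exp <- n2 * freqs(s)
    z2 <- (counts - exp)^2 / (exp * (1 - freqs(s)))
    fails <- sum(pchisq(z2, 1, lower.tail = FALSE) < 0.01)
    expect_lte(fails, 7)  # P(Binom(143, .01) > 7) < 1e-3
})

test_that("risk loci are enriched in cases", {
    set.seed(99)
    s <- sampleMafSpectrum(40, 0.005, 0.02)
    m <- calibrateIntercept(s, buildEffectModel(40, "uniform_or", 10))
    wins <- 0
    reps <- 40
    for (i in seq_len(reps)) {
        co <- sampleCohort(150, 150, s, m)
        g <- genotypes(co)
        y <- caseStatus(co)
        dl <- diseaseLoci(m)
        wins <- wins +
            (mean(g[y == 1, dl]) > mean(g[y == 0, dl]))
    }
    # sign test: under no enrichment wins ~ Binomial(reps, 0.5)
    expect_lt(pbinom(wins - 1, reps, 0.5, lower.tail = FALSE), 0.01)
})

test_that("cohort sampling is deterministic given the seed", {
    s <- MafSpectrum(seq(0.002, 0.009, length.out = 25))
    m <- calibrateIntercept(s, buildEffectModel(25, "null"))
    set.seed(1234)
    a <- sampleCohort(60, 90, s, m)
    set.seed(1234)
    b <- sampleCohort(60, 90, s, m)
    expect_identical(genotypes(a), genotypes(b))
    expect_identical(caseStatus(a), caseStatus(b))
})

test_that("cohort container validates its invariants", {
    expect_error(RareVariantCohort(matrix(3L, 2, 2), c(0L, 1L)),
                 "minor-allele counts")
    expect_error(RareVariantCohort(matrix(0L, 2, 2), c(0L, 2L)),
                 "binary")
    expect_error(RareVariantCohort(matrix(0L, 2, 2), c(0L)),
                 "one entry per")
    co <- toyCohort()
    expect_equal(nCases(co) + nControls(co), length(caseStatus(co)))
})
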