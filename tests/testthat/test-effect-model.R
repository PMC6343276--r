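test_that("effect scenarios assign the intended odds ratios", {
    set.seed(7)
    null <- buildEffectModel(143, "null")
    expect_true(all(logOdds(null) == 0))
    expect_length(diseaseLoci(null), 0)

    uni <- buildEffectModel(143, "uniform_or", 10, 2.5)
    expect_length(diseaseLoci(uni), 10)
    expect_equal(sum(logOdds(uni) != 0), 10)
    expect_true(all(logOdds(uni)[diseaseLoci(uni)] == log(2.5)))

    for (lvl in c("mixed_low", "mixed_moderate", "mixed_high")) {
        m <- buildEffectModel(143, lvl, 10)
        ors <- sort(round(exp(logOdds(m)[diseaseLoci(m)]), 3))
        tab <- mixedOddsRatios(lvl)
        expect_equal(ors, sort(round(c(tab$risk, tab$protective), 3)))
        expect_equal(sum(logOdds(m) > 0), 5)
        expect_equal(sum(logOdds(m) < 0), 5)
    }
    # the low-signal protective values are the printed reciprocals
    low <- mixedOddsRatios("mixed_low")
    expect_equal(low$risk, c(2.3, 2.73, 3.15, 3.58, 4))
    expect_equal(low$protective, c(0.43, 0.37, 0.32, 0.28, 0.25))
})

test_that("mixed scenarios reject odd disease-locus counts", {
    expect_error(buildEffectModel(143, "mixed_low", 9), "even")
    expect_error(buildEffectModel(5, "uniform_or", 10), "exceed")
})

test_that("disease-locus placement is uniform draws without replacement", {
    set.seed(21)
    for (i in 1:20) {
        m <- buildEffectModel(50, "uniform_or", 10)
        dl <- diseaseLoci(m)
        expect_equal(anyDuplicated(dl), 0)
        expect_true(all(dl >= 1 & dl <= 50))
    }
})

test_that("disease probability follows the logistic closed form", {
    # intercept-only: all-zero genotype returns the prevalence
    m0 <- buildEffectModel(3, "null")
    m0 <- calibrateIntercept(MafSpectrum(c(0.01, 0.02, 0.03)), m0)
    expect_equal(diseaseProbability(c(0, 0, 0), m0), 0.05,
                 tolerance = 1e-9)

    # alpha = 0, one copy of an allele with OR 2.5 -> 2.5 / 3.5
    m1 <- new("EffectModel", logOdds = c(log(2.5), 0), intercept = 0,
              diseaseLoci = 1L, targetPrevalence = 0.05,
              calibrated = TRUE)
    expect_equal(diseaseProbability(c(1, 0), m1), 2.5 / 3.5,
                 tolerance = 1e-12)
    # monotone in each risk genotype
    expect_true(diseaseProbability(c(2, 0), m1) >
                diseaseProbability(c(1, 0), m1))
    expect_true(all(diseaseProbability(rbind(c(0, 0), c(1, 0)), m1) ==
                    c(0.5, 2.5 / 3.5)))
    expect_error(diseaseProbability(c(1, 0, 0), m1), "match")
})
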