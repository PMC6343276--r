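test_that("exact prevalence matches hand enumeration for one locus", {
    q <- 0.01
    b <- log(2.5)
    a <- qlogis(0.05)
    model <- new("EffectModel", logOdds = c(b, 0, 0), intercept = a,
                 diseaseLoci = 1L, targetPrevalence = 0.05,
                 calibrated = TRUE)
    mafs <- MafSpectrum(c(q, 0.005, 0.003))
    expected <- (1 - q)^2 * plogis(a) + 2 * q * (1 - q) * plogis(a + b) +
        q^2 * plogis(a + 2 * b)
    expect_equal(exactPrevalence(mafs, model), expected,
                 tolerance = 1e-12)
})

test_that("null model prevalence is the inverse-logit of the intercept", {
    m <- buildEffectModel(5, "null")
    m <- calibrateIntercept(MafSpectrum(rep(0.005, 5)), m)
    expect_equal(intercept(m), qlogis(0.05), tolerance = 1e-9)
    expect_equal(exactPrevalence(MafSpectrum(rep(0.005, 5)), m), 0.05,
                 tolerance = 1e-12)
})

test_that("exact enumeration agrees with Monte Carlo oracles", {
    set.seed(33)
    mafs <- sampleMafSpectrum(20, shape = 1)
    for (eff in c("uniform_or", "mixed_low")) {
        model <- calibrateIntercept(mafs, buildEffectModel(20, eff, 10))
        exact <- exactPrevalence(mafs, model)
        # package Monte Carlo estimator (penetrance averaging)
        mc <- monteCarloPrevalence(mafs, model, nSim = 2e5)
        se <- sqrt(exact * (1 - exact) / 2e5)
        expect_lt(abs(mc - exact), 4 * se)
        # fully independent Bernoulli-simulation oracle
        mc2 <- oracleBernoulliPrevalence(mafs, model, 2e5)
        expect_lt(abs(mc2 - exact), 4 * se)
    }
})

test_that("unequal-effect enumeration equals the generic 3^d expansion", {
    # the equal-effect fast path and the generic path must agree with a
    # direct expand.grid enumeration on a small model
    set.seed(44)
    q <- c(0.02, 0.05, 0.01)
    betas <- list(rep(log(2), 3), log(c(2, 3, 0.5)))
    for (b in betas) {
        model <- new("EffectModel", logOdds = c(b, 0), intercept = -3,
                     diseaseLoci = 1:3, targetPrevalence = 0.05,
                     calibrated = TRUE)
        mafs <- MafSpectrum(c(q, 0.005))
        grid <- as.matrix(expand.grid(0:2, 0:2, 0:2))
        hw <- function(x, qq) dbinom(x, 2, qq)
        pr <- hw(grid[, 1], q[1]) * hw(grid[, 2], q[2]) *
            hw(grid[, 3], q[3])
        expected <- sum(pr * plogis(-3 + grid %*% b))
        expect_equal(exactPrevalence(mafs, model), expected,
                     tolerance = 1e-12)
    }
})

test_that("enumeration refuses more than 15 disease loci", {
    mafs <- MafSpectrum(rep(0.005, 20))
    model <- new("EffectModel", logOdds = c(rep(log(2), 16), rep(0, 4)),
                 intercept = -3, diseaseLoci = 1:16,
                 targetPrevalence = 0.05, calibrated = TRUE)
    expect_error(exactPrevalence(mafs, model), "15")
    # the Monte Carlo estimator still works there
    set.seed(5)
    expect_true(is.finite(monteCarloPrevalence(mafs, model, 1e4)))
})

test_that("calibration hits the target prevalence to 1e-6", {
    set.seed(55)
    for (eff in c("uniform_or", "mixed_high")) {
        mafs <- sampleMafSpectrum(143)
        model <- calibrateIntercept(mafs, buildEffectModel(143, eff, 10))
        expect_true(isCalibrated(model))
        expect_lt(abs(exactPrevalence(mafs, model) - 0.05), 1e-6)
    }
})

test_that("adding risk effects lowers the calibrated intercept", {
    set.seed(66)
    mafs <- sampleMafSpectrum(10)
    base <- calibrateIntercept(mafs, buildEffectModel(10, "null"))
    prev <- intercept(base)
    for (k in c(2, 4, 6)) {
        m <- new("EffectModel",
                 logOdds = c(rep(log(2.5), k), rep(0, 10 - k)),
                 intercept = NA_real_, diseaseLoci = seq_len(k),
                 targetPrevalence = 0.05, calibrated = FALSE)
        m <- calibrateIntercept(mafs, m)
        expect_lt(intercept(m), prev)
        prev <- intercept(m)
    }
})
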