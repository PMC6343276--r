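test_that("runDataset is deterministic and composes the pipeline", {
    sc <- Scenario(150, 150, mafShape = 1)
    a <- runDataset(sc, 20240101)
    b <- runDataset(sc, 20240101)
    expect_equal(pValue(a$burden), pValue(b$burden))
    expect_equal(pValue(a$skat), pValue(b$skat))
    expect_true(all(vapply(a, pValue, numeric(1)) > 0))
    expect_true(all(vapply(a, pValue, numeric(1)) <= 1))

    # composition oracle: re-run the stages by hand from the same seed
    set.seed(20240101)
    mafs <- sampleMafSpectrum(sc@nLoci, sc@mafLower, sc@mafUpper,
                              sc@mafShape)
    model <- calibrateIntercept(
        mafs, buildEffectModel(sc@nLoci, sc@effect, sc@nDiseaseLoci,
                               sc@oddsRatio, sc@prevalence))
    co <- sampleCohort(sc@nCases, sc@nControls, mafs, model)
    w <- mbWeights(co)
    expect_equal(pValue(a$burden),
                 pValue(burdenTest(burdenScores(genotypes(co), w),
                                   caseStatus(co))))
    expect_equal(pValue(a$skat),
                 pValue(skatTest(genotypes(co), caseStatus(co), w)))
})

test_that("rejection rates recount the persisted p-value table", {
    stubP <- function(p) {
        function(scenario, datasetSeed, tests = c("burden", "skat")) {
            lapply(setNames(nm = tests), function(tn)
                new("TestResult", statistic = 0, pValue = p,
                    testName = tn, dfOrEigencount = 1L,
                    converged = TRUE, method = "stub"))
        }
    }
    sc <- Scenario(10, 10)
    always <- estimateRejectionRate(sc, nDatasets = 25, baseSeed = 1,
                                    .runner = stubP(0))
    expect_equal(unname(always$rates), c(1, 1))
    never <- estimateRejectionRate(sc, nDatasets = 25, baseSeed = 1,
                                   .runner = stubP(1))
    expect_equal(unname(never$rates), c(0, 0))
    # recount oracle
    recount <- with(never$pvalues,
                    tapply(p_value <= sc@alphaLevel, test, mean))
    expect_equal(unname(never$rates["burden"]),
                 unname(recount["burden"]))
})

test_that("replicates aggregate into PowerEstimate objects", {
    set.seed(1)
    stubRandom <- function(scenario, datasetSeed,
                           tests = c("burden", "skat")) {
        set.seed(datasetSeed)
        lapply(setNames(nm = tests), function(tn)
            new("TestResult", statistic = 0, pValue = runif(1),
                testName = tn, dfOrEigencount = 1L, converged = TRUE,
                method = "stub"))
    }
    sc <- Scenario(10, 10)
    out <- runReplicates(sc, nDatasets = 40, nReplicates = 3,
                         baseSeed = 9, .runner = stubRandom)
    expect_s4_class(out$burden, "PowerEstimate")
    expect_length(rates(out$burden), 3)
    expect_equal(meanRate(out$burden), mean(rates(out$burden)))
    # single replicate: the mean is the replicate rate
    one <- runReplicates(sc, nDatasets = 40, nReplicates = 1,
                         baseSeed = 9, .runner = stubRandom)
    expect_equal(meanRate(one$skat), rates(one$skat)[1])
    # seed manifest covers every (replicate, dataset) cell uniquely
    expect_equal(nrow(out$seeds), 120)
    expect_equal(anyDuplicated(out$seeds$seed), 0)
    # disjoint base seeds give different replicate draws but close means
    out2 <- runReplicates(sc, nDatasets = 40, nReplicates = 3,
                          baseSeed = 10, .runner = stubRandom)
    expect_false(identical(rates(out$burden), rates(out2$burden)))
    se <- sqrt(0.05 * 0.95 / (40 * 3))
    expect_lt(abs(meanRate(out$burden) - meanRate(out2$burden)),
              5 * se)
})

test_that("the scenario grid reproduces the published design", {
    g <- scenarioGrid(mafUppers = 0.01, effects = "null",
                      includeMixed = FALSE)
    expect_length(g, 33)  # 12 balanced + 21 unbalanced
    bal <- vapply(g, function(s) s@nCases == s@nControls, logical(1))
    expect_equal(sum(bal), 12)
    expect_equal(sum(!bal), 21)
    key <- vapply(g, function(s) paste(s@nCases, s@nControls),
                  character(1))
    expect_true("7000 10000" %in% key)
    expect_false("7000 30000" %in% key)
    expect_true("1000 30000" %in% key)
    # full crossing: 2 maf bounds x 2 effects x 33 + mixed cells
    full <- scenarioGrid()
    expect_length(full, 2 * 2 * 33 + 2 * 3 * 2)
    # balanced totals go up to 20,000 as designed
    totals <- sort(unique(vapply(g[bal], function(s)
        s@nCases + s@nControls, numeric(1))))
    expect_equal(totals, c(20, 50, 100, 200, 400, 1000, 2000, 4000,
                           6000, 10000, 14000, 20000))
})

test_that("derived seeds are stable, distinct and in range", {
    sc <- Scenario(100, 100)
    s1 <- deriveSeed(1, sc, 1, 1)
    expect_identical(s1, deriveSeed(1, sc, 1, 1))
    expect_false(s1 == deriveSeed(2, sc, 1, 1))
    expect_false(s1 == deriveSeed(1, sc, 2, 1))
    expect_false(s1 == deriveSeed(1, sc, 1, 2))
    seeds <- vapply(1:500, function(i) deriveSeed(1, sc, 1, i),
                    integer(1))
    expect_equal(anyDuplicated(seeds), 0)
    expect_true(all(seeds >= 1 & seeds <= 2147483646))
})

test_that("summaries aggregate and order replicate tables", {
    sc1 <- Scenario(1000, 10000)
    sc2 <- Scenario(2000, 2000)
    pe <- function(scn, test, rr)
        new("PowerEstimate", testName = test, rates = rr,
            nDatasetsPerReplicate = 10L,
            nReplicates = length(rr), meanRate = mean(rr),
            scenario = scn)
    res <- list(pe(sc1, "burden", c(0.5, 0.7)),
                pe(sc1, "skat", c(0.8, 0.9)),
                pe(sc2, "skat", 0.4))
    out <- summarizePower(res)
    expect_equal(nrow(out$replicates), 5)
    expect_equal(nrow(out$summary), 3)
    # single replicate: quartiles collapse onto the rate
    row <- out$summary[out$summary$n_cases == 2000, ]
    expect_equal(unname(unlist(row[c("mean", "q25", "median", "q75")])),
                 rep(0.4, 4))
    # case:control percentage for 1000 / 10,000 prints as 10%
    expect_equal(unique(out$replicates$ratio_pct[
        out$replicates$n_cases == 1000]), 10)
    # aggregation oracle: the mean recomputes from the long table
    m <- with(out$replicates,
              mean(rate[n_cases == 1000 & test == "burden"]))
    expect_equal(out$summary$mean[out$summary$n_cases == 1000 &
                                  out$summary$test == "burden"], m)
})
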