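#' Construct a simulation scenario
#'
#' @param nCases,nControls ascertainment quotas.
#' @param mafUpper upper minor allele frequency bound, conventionally
#'   0.01 or 0.05 (default 0.01).
#' @param effect effect scenario (default `"uniform_or"`).
#' @param oddsRatio per-allele odds ratio for `uniform_or` (default 2.5).
#' @param nDiseaseLoci number of causal loci (default 10).
#' @param nLoci loci per bin (default 143).
#' @param alphaLevel significance level for rejection counting
#'   (default 0.05).
#' @param prevalence target population prevalence (default 0.05).
#' @param mafLower lower frequency bound (default 0.0015).
#' @param mafShape spectrum shape (default [defaultMafShape()]).
#' @return A [Scenario-class].
#' @examples
#' Scenario(2000, 2000)
#' @export
Scenario <- function(nCases, nControls, mafUpper = 0.01,
                     effect = c("uniform_or", "null", "mixed_low",
                                "mixed_moderate", "mixed_high"),
                     oddsRatio = 2.5, nDiseaseLoci = 10, nLoci = 143,
                     alphaLevel = 0.05, prevalence = 0.05,
                     mafLower = 0.0015, mafShape = defaultMafShape()) {
    effect <- match.arg(effect)
    if (effect == "null")
        nDiseaseLoci <- 0L
    new("Scenario", nCases = as.integer(nCases),
        nControls = as.integer(nControls), mafLower = mafLower,
        mafUpper = mafUpper, mafShape = mafShape, effect = effect,
        oddsRatio = oddsRatio, nDiseaseLoci = as.integer(nDiseaseLoci),
        nLoci = as.integer(nLoci), alphaLevel = alphaLevel,
        prevalence = prevalence)
}

#' Canonical string form of a scenario
#'
#' Used for seed derivation and manifests; two scenarios with equal
#' canonical strings are the same study cell.
#'
#' @param scenario a [Scenario-class].
#' @return A single character string.
#' @export
scenarioString <- function(scenario) {
    stopifnot(is(scenario, "Scenario"))
    sprintf("cases=%d;controls=%d;mafLower=%.10g;mafUpper=%.10g;shape=%.10g;effect=%s;or=%.10g;diseaseLoci=%d;loci=%d;alpha=%.10g;prevalence=%.10g",
            scenario@nCases, scenario@nControls, scenario@mafLower,
            scenario@mafUpper, scenario@mafShape, scenario@effect,
            scenario@oddsRatio, scenario@nDiseaseLoci, scenario@nLoci,
            scenario@alphaLevel, scenario@prevalence)
}

setMethod("show", "Scenario", function(object) {
    cat("Scenario:", scenarioString(object), "\n")
})

# 32-bit FNV-1a over a string, carried out in doubles with an explicit
# modular multiply so no intermediate exceeds 2^53.
.fnv1a <- function(s) {
    h <- 2166136261
    prime <- 16777619
    for (b in as.integer(charToRaw(s))) {
        low <- h %% 256
        h <- h - low + bitwXor(as.integer(low), b)
        lo <- h %% 65536
        hi <- (h - lo) / 65536
        h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
    }
    h
}

#' Derive a per-dataset seed
#'
#' Deterministically hashes the base seed, the scenario's canonical
#' string, the replicate index and the dataset index into a positive
#' 31-bit integer seed, guaranteeing reproducibility of every dataset
#' and independence across replicates.
#'
#' @param baseSeed integer base seed for the whole run.
#' @param scenario a [Scenario-class] (or its canonical string).
#' @param replicate,dataset 1-based indices.
#' @return A positive integer seed.
#' @export
deriveSeed <- function(baseSeed, scenario, replicate = 1L, dataset = 1L) {
    key <- if (is(scenario, "Scenario")) scenarioString(scenario)
           else as.character(scenario)
    h <- .fnv1a(sprintf("%d|%s|rep%d|ds%d", as.integer(baseSeed), key,
                        as.integer(replicate), as.integer(dataset)))
    as.integer(h %% 2147483646) + 1L
}

#' Simulate and test one dataset
#'
#' One full pipeline pass for a scenario: draw a fresh minor allele
#' frequency spectrum, build and calibrate the effect model, ascertain
#' the case-control cohort, compute pooled Madsen-Browning weights, and
#' run the requested tests. Fully deterministic given
#' `(scenario, datasetSeed)`.
#'
#' @param scenario a [Scenario-class].
#' @param datasetSeed integer seed for this dataset.
#' @param tests character subset of `c("burden", "skat")`.
#' @return Named list of [TestResult-class] objects, one per requested
#'   test.
#' @examples
#' r <- runDataset(Scenario(100, 100), datasetSeed = 7)
#' vapply(r, pValue, numeric(1))
#' @export
runDataset <- function(scenario, datasetSeed,
                       tests = c("burden", "skat")) {
    stopifnot(is(scenario, "Scenario"))
    tests <- match.arg(tests, several.ok = TRUE)
    set.seed(as.integer(datasetSeed))
    res <- tryCatch({
        mafs <- sampleMafSpectrum(scenario@nLoci, scenario@mafLower,
                                  scenario@mafUpper, scenario@mafShape)
        model <- buildEffectModel(scenario@nLoci, scenario@effect,
                                  scenario@nDiseaseLoci,
                                  scenario@oddsRatio,
                                  scenario@prevalence)
        model <- calibrateIntercept(mafs, model)
        cohort <- sampleCohort(scenario@nCases, scenario@nControls,
                               mafs, model)
        g <- genotypes(cohort)
        y <- caseStatus(cohort)
        w <- mbWeights(g)
        out <- list()
        if ("burden" %in% tests)
            out$burden <- .burdenTestScores(burdenScores(g, w), y)
        if ("skat" %in% tests)
            out$skat <- .skatTestMatrix(g, y, w)
        out
    }, error = function(e) {
        stop(sprintf("dataset with seed %d failed: %s",
                     as.integer(datasetSeed), conditionMessage(e)),
             call. = FALSE)
    })
    res
}

#' Estimate rejection rates for one replicate of a scenario
#'
#' Runs `nDatasets` independent datasets (seeds derived from
#' `baseSeed` via [deriveSeed()]) and reports, per test, the proportion
#' with p-value at or below the scenario's `alphaLevel` — the type I
#' error for null scenarios, power otherwise.
#'
#' @param scenario a [Scenario-class].
#' @param nDatasets number of datasets (default 1000, matching the
#'   full-size study profile).
#' @param baseSeed integer base seed.
#' @param replicate replicate index entering seed derivation.
#' @param tests character subset of `c("burden", "skat")`.
#' @param .runner dataset runner, swappable for testing; must accept
#'   `(scenario, datasetSeed, tests)` and return a named list of
#'   [TestResult-class].
#' @return A list: `rates` (named rejection proportions), `pvalues`
#'   (data frame with one row per dataset and test: `dataset`, `seed`,
#'   `test`, `p_value`, `converged`, `method`).
#' @export
estimateRejectionRate <- function(scenario, nDatasets = 1000,
                                  baseSeed = 1, replicate = 1L,
                                  tests = c("burden", "skat"),
                                  .runner = runDataset) {
    stopifnot(is(scenario, "Scenario"), nDatasets >= 1)
    tests <- match.arg(tests, several.ok = TRUE)
    key <- scenarioString(scenario)
    rows <- vector("list", nDatasets)
    for (i in seq_len(nDatasets)) {
        seed <- deriveSeed(baseSeed, key, replicate, i)
        res <- .runner(scenario, seed, tests = tests)
        rows[[i]] <- data.frame(
            dataset = i, seed = seed, test = names(res),
            p_value = vapply(res, function(r) r@pValue, numeric(1)),
            converged = vapply(res, function(r) r@converged, logical(1)),
            method = vapply(res, function(r) r@method, character(1)),
            stringsAsFactors = FALSE, row.names = NULL)
    }
    pvals <- do.call(rbind, rows)
    rates <- vapply(tests, function(tn) {
        p <- pvals$p_value[pvals$test == tn]
        mean(p <= scenario@alphaLevel)
    }, numeric(1))
    list(rates = rates, pvalues = pvals)
}

#' Run replicated rejection-rate estimation for one scenario
#'
#' Calls [estimateRejectionRate()] `nReplicates` times with independent
#' derived seeds, yielding the per-replicate rejection-rate distribution
#' (the quantity the study's boxplots display). The full-size study
#' profile is 1000 datasets times 30 replicates per scenario; the `"ci"`
#' profile (200 times 5) is a reduced budget for interactive use.
#'
#' @param scenario a [Scenario-class].
#' @param nDatasets datasets per replicate (default 1000).
#' @param nReplicates number of replicates (default 30).
#' @param baseSeed integer base seed.
#' @param tests character subset of `c("burden", "skat")`.
#' @param profile optional shortcut: `"paper"` sets 1000 x 30, `"ci"`
#'   sets 200 x 5, overriding `nDatasets`/`nReplicates`.
#' @param .runner see [estimateRejectionRate()].
#' @return Named list with one [PowerEstimate-class] per test, plus
#'   `pvalues` (long per-dataset p-value table with a `replicate`
#'   column) and `seeds` (the derived seed manifest).
#' @export
runReplicates <- function(scenario, nDatasets = 1000, nReplicates = 30,
                          baseSeed = 1, tests = c("burden", "skat"),
                          profile = NULL, .runner = runDataset) {
    stopifnot(is(scenario, "Scenario"))
    tests <- match.arg(tests, several.ok = TRUE)
    if (!is.null(profile)) {
        profile <- match.arg(profile, c("paper", "ci"))
        if (profile == "paper") {
            nDatasets <- 1000
            nReplicates <- 30
        } else {
            nDatasets <- 200
            nReplicates <- 5
        }
    }
    stopifnot(nDatasets >= 1, nReplicates >= 1)
    rateMat <- matrix(NA_real_, nReplicates, length(tests),
                      dimnames = list(NULL, tests))
    pvals <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
        est <- estimateRejectionRate(scenario, nDatasets, baseSeed,
                                     replicate = r, tests = tests,
                                     .runner = .runner)
        rateMat[r, ] <- est$rates[tests]
        est$pvalues$replicate <- r
        pvals[[r]] <- est$pvalues
    }
    pvals <- do.call(rbind, pvals)
    out <- lapply(tests, function(tn) {
        new("PowerEstimate", testName = tn,
            rates = unname(rateMat[, tn]),
            nDatasetsPerReplicate = as.integer(nDatasets),
            nReplicates = as.integer(nReplicates),
            meanRate = mean(rateMat[, tn]), scenario = scenario)
    })
    names(out) <- tests
    out$pvalues <- pvals
    out$seeds <- seedManifest(scenario, nDatasets, nReplicates, baseSeed)
    out
}

#' Seed manifest for a scenario run
#'
#' Enumerates every derived per-dataset seed for a run, sufficient to
#' reproduce any dataset in isolation with [runDataset()].
#'
#' @inheritParams runReplicates
#' @return A data frame with columns `scenario`, `replicate`, `dataset`,
#'   `seed`.
#' @export
seedManifest <- function(scenario, nDatasets, nReplicates, baseSeed) {
    key <- scenarioString(scenario)
    grid <- expand.grid(dataset = seq_len(nDatasets),
                        replicate = seq_len(nReplicates))
    data.frame(scenario = key, replicate = grid$replicate,
               dataset = grid$dataset,
               seed = mapply(function(r, i) deriveSeed(baseSeed, key, r, i),
                             grid$replicate, grid$dataset),
               stringsAsFactors = FALSE)
}

#' The published simulation design grid
#'
#' Enumerates the full study design: twelve balanced scenarios with
#' total sample sizes 20 to 20,000; twenty-one unbalanced scenarios
#' (case counts 10 to 7000 against 10,000 controls, and 10 to 1000
#' against 30,000 controls); each crossed with the requested frequency
#' bounds and effect scenarios; plus, when `includeMixed = TRUE`, the
#' three mixed risk/protective models at the two reference designs
#' (2000/2000 and 200/10,000) for each frequency bound.
#'
#' @param mafUppers frequency upper bounds to cross (default
#'   `c(0.01, 0.05)`).
#' @param effects effect scenarios to cross (default
#'   `c("null", "uniform_or")`).
#' @param includeMixed include the mixed odds-ratio cells
#'   (default `TRUE`).
#' @param ... passed to [Scenario()] (e.g. `alphaLevel`, `mafShape`).
#' @return A list of [Scenario-class] objects.
#' @examples
#' length(scenarioGrid(mafUppers = 0.01, effects = "null",
#'                     includeMixed = FALSE))  # 12 + 21 cells
#' @export
scenarioGrid <- function(mafUppers = c(0.01, 0.05),
                         effects = c("null", "uniform_or"),
                         includeMixed = TRUE, ...) {
    balancedTotals <- c(20, 50, 100, 200, 400, 1000, 2000, 4000, 6000,
                        10000, 14000, 20000)
    cases10k <- c(10, 25, 50, 75, 85, 100, 200, 500, 1000, 3000, 5000,
                  7000)
    cases30k <- c(10, 25, 50, 75, 85, 100, 200, 500, 1000)
    designs <- rbind(
        data.frame(nCases = balancedTotals / 2,
                   nControls = balancedTotals / 2, design = "balanced"),
        data.frame(nCases = cases10k, nControls = 10000,
                   design = "unbalanced"),
        data.frame(nCases = cases30k, nControls = 30000,
                   design = "unbalanced"))
    out <- list()
    for (ub in mafUppers)
        for (eff in effects)
            for (i in seq_len(nrow(designs)))
                out[[length(out) + 1L]] <-
                    Scenario(designs$nCases[i], designs$nControls[i],
                             mafUpper = ub, effect = eff, ...)
    if (includeMixed) {
        mixedDesigns <- data.frame(nCases = c(2000, 200),
                                   nControls = c(2000, 10000))
        for (ub in mafUppers)
            for (eff in c("mixed_low", "mixed_moderate", "mixed_high"))
                for (i in seq_len(nrow(mixedDesigns)))
                    out[[length(out) + 1L]] <-
                        Scenario(mixedDesigns$nCases[i],
                                 mixedDesigns$nControls[i],
                                 mafUpper = ub, effect = eff, ...)
    }
    out
}

#' @rdname rvpower-accessors
#' @export
setMethod("rates", "PowerEstimate", function(object) object@rates)

#' @rdname rvpower-accessors
#' @export
setMethod("meanRate", "PowerEstimate", function(object) object@meanRate)

#' @rdname rvpower-accessors
#' @export
setMethod("testName", "PowerEstimate", function(object) object@testName)

setMethod("show", "PowerEstimate", function(object) {
    s <- object@scenario
    kind <- if (s@effect == "null") "type I error" else "power"
    cat(sprintf(
        "PowerEstimate [%s, %s]: mean %s = %.4f over %d x %d datasets\n",
        object@testName, s@effect, kind, object@meanRate,
        object@nReplicates, object@nDatasetsPerReplicate))
    cat(sprintf("  design %d cases / %d controls, MAF <= %.3g, alpha %.3g\n",
                s@nCases, s@nControls, s@mafUpper, s@alphaLevel))
})

#' Summarize rejection-rate estimates across scenarios
#'
#' Flattens a collection of [PowerEstimate-class] objects (or results of
#' [runReplicates()]) into a long replicate-level table and a
#' per-scenario summary with mean and quartiles. The tables carry both a
#' case:control percentage (`ratio_pct`) and the raw case count, the two
#' orderings used to display unbalanced designs.
#'
#' @param results a list of [PowerEstimate-class] objects, possibly
#'   nested (e.g. several [runReplicates()] outputs).
#' @param orderBy `"ratio"` (case:control percentage) or `"cases"`.
#' @return A list of two data frames: `replicates` (one row per
#'   scenario, test and replicate) and `summary` (one row per scenario
#'   and test with `mean`, `q25`, `median`, `q75`).
#' @export
summarizePower <- function(results, orderBy = c("ratio", "cases")) {
    orderBy <- match.arg(orderBy)
    flatten <- function(x) {
        if (is(x, "PowerEstimate"))
            return(list(x))
        if (is.list(x))
            return(do.call(c, lapply(x, flatten)))
        list()
    }
    ests <- flatten(results)
    if (!length(ests))
        stop("no PowerEstimate objects found in 'results'")
    long <- do.call(rbind, lapply(ests, function(e) {
        s <- e@scenario
        data.frame(
            n_cases = s@nCases, n_controls = s@nControls,
            ratio_pct = 100 * s@nCases / max(s@nControls, 1L),
            maf_upper = s@mafUpper, effect = s@effect,
            quantity = if (s@effect == "null") "type_I_error" else "power",
            test = e@testName, replicate = seq_along(e@rates),
            rate = e@rates, stringsAsFactors = FALSE)
    }))
    agg <- aggregate(rate ~ n_cases + n_controls + ratio_pct + maf_upper +
                         effect + quantity + test,
                     data = long,
                     FUN = function(x) c(mean = mean(x),
                                         q25 = quantile(x, 0.25,
                                                        names = FALSE),
                                         median = quantile(x, 0.5,
                                                           names = FALSE),
                                         q75 = quantile(x, 0.75,
                                                        names = FALSE)))
    summ <- cbind(agg[setdiff(names(agg), "rate")],
                  as.data.frame(agg$rate))
    ord <- if (orderBy == "ratio")
        order(summ$ratio_pct, summ$n_cases, summ$test)
    else order(summ$n_cases, summ$n_controls, summ$test)
    summ <- summ[ord, , drop = FALSE]
    rownames(summ) <- NULL
    list(replicates = long, summary = summ)
}
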