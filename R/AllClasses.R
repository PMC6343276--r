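#' Minor allele frequency spectrum for a simulated variant bin
#'
#' Holds the per-locus minor allele frequencies that define one simulated
#' gene-like region, together with the frequency bounds used to draw them.
#' All frequencies are proportions in `[lowerBound, upperBound]`.
#'
#' @slot freqs numeric vector of per-locus minor allele frequencies.
#' @slot lowerBound,upperBound numeric scalars bounding the spectrum.
#'
#' @seealso [sampleMafSpectrum()]
#' @exportClass MafSpectrum
setClass("MafSpectrum",
    slots = c(freqs = "numeric", lowerBound = "numeric",
              upperBound = "numeric"))

setValidity("MafSpectrum", function(object) {
    lb <- object@lowerBound
    ub <- object@upperBound
    if (length(lb) != 1L || length(ub) != 1L || !is.finite(lb) ||
        !is.finite(ub))
        return("lowerBound and upperBound must be finite scalars")
    if (lb <= 0 || lb >= ub || ub >= 0.5)
        return("bounds must satisfy 0 < lowerBound < upperBound < 0.5")
    f <- object@freqs
    if (length(f) && (any(!is.finite(f)) || any(f < lb) || any(f > ub)))
        return("all frequencies must lie in [lowerBound, upperBound]")
    TRUE
})

#' Logistic penetrance model for a simulated variant bin
#'
#' Per-locus log odds ratios plus the intercept of the logistic disease
#' model `logit P(case) = intercept + sum_j logOdds_j * x_j`, where `x_j`
#' is the minor-allele count at locus j. The intercept is `NA` until
#' [calibrateIntercept()] has been run against a [MafSpectrum-class],
#' after which the implied population prevalence matches
#' `targetPrevalence` to within the calibration tolerance.
#'
#' @slot logOdds numeric vector of per-locus log odds ratios.
#' @slot intercept numeric scalar on the log-odds scale (`NA` before
#'   calibration).
#' @slot diseaseLoci integer indices of loci with nonzero effect.
#' @slot targetPrevalence numeric scalar, the population prevalence the
#'   intercept is calibrated to.
#' @slot calibrated logical flag.
#'
#' @seealso [buildEffectModel()], [calibrateIntercept()]
#' @exportClass EffectModel
setClass("EffectModel",
    slots = c(logOdds = "numeric", intercept = "numeric",
              diseaseLoci = "integer", targetPrevalence = "numeric",
              calibrated = "logical"))

setValidity("EffectModel", function(object) {
    nz <- which(object@logOdds != 0)
    if (!identical(sort(object@diseaseLoci), as.integer(nz)))
        return("diseaseLoci must index exactly the nonzero logOdds entries")
    tp <- object@targetPrevalence
    if (length(tp) != 1L || tp <= 0 || tp >= 1)
        return("targetPrevalence must be in (0, 1)")
    if (length(object@intercept) != 1L)
        return("intercept must be a scalar (possibly NA)")
    TRUE
})

#' Case-control cohort of rare-variant genotypes
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with one assay
#' `"genotype"` (loci in rows, individuals in columns, minor-allele counts
#' in \{0, 1, 2\}), a `status` column in `colData` (1 = case, 0 = control)
#' and the simulated per-locus minor allele frequency in `rowData$maf`.
#'
#' @seealso [RareVariantCohort()], [sampleCohort()], [genotypes()],
#'   [caseStatus()]
#' @exportClass RareVariantCohort
setClass("RareVariantCohort", contains = "SummarizedExperiment")

setValidity("RareVariantCohort", function(object) {
    if (!"genotype" %in% SummarizedExperiment::assayNames(object))
        return("assay 'genotype' is required")
    g <- SummarizedExperiment::assay(object, "genotype")
    if (length(g) && !all(g == 0L | g == 1L | g == 2L))
        return("genotype entries must be minor-allele counts in {0, 1, 2}")
    if (!"status" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData column 'status' is required")
    s <- object$status
    if (length(s) && !all(s == 0L | s == 1L))
        return("status must be binary (1 = case, 0 = control)")
    TRUE
})

#' Madsen-Browning variant weights
#'
#' Per-locus weights `1 / sqrt(n * q * (1 - q))` computed from
#' pooled-sample (cases + controls) allele frequency estimates with a
#' pseudocount, so that weights are finite and strictly positive even for
#' monomorphic loci, and invariant under exchanging case and control
#' labels.
#'
#' @slot weights numeric vector of positive per-locus weights.
#' @slot mafEstimates numeric vector of pooled frequency estimates.
#'
#' @seealso [mbWeights()]
#' @exportClass WeightVector
setClass("WeightVector",
    slots = c(weights = "numeric", mafEstimates = "numeric"))

setValidity("WeightVector", function(object) {
    if (length(object@weights) != length(object@mafEstimates))
        return("weights and mafEstimates must have equal length")
    if (length(object@weights) &&
        (any(!is.finite(object@weights)) || any(object@weights <= 0)))
        return("all weights must be finite and > 0")
    TRUE
})

#' Result of one association test on one simulated bin
#'
#' @slot statistic numeric test statistic (likelihood-ratio deviance for
#'   the burden test, the quadratic-form score statistic Q for SKAT).
#' @slot pValue numeric p-value in `[0, 1]`.
#' @slot testName `"burden"` or `"skat"`.
#' @slot dfOrEigencount integer: degrees of freedom (burden) or number of
#'   retained kernel eigenvalues (SKAT).
#' @slot converged logical; `FALSE` for degenerate inputs (zero-variance
#'   score, complete separation, all-monomorphic bin).
#' @slot method character; for SKAT, `"imhof"` when the
#'   characteristic-function inversion succeeded, `"liu"` for the
#'   moment-matching fallback.
#'
#' @exportClass TestResult
setClass("TestResult",
    slots = c(statistic = "numeric", pValue = "numeric",
              testName = "character", dfOrEigencount = "integer",
              converged = "logical", method = "character"))

setValidity("TestResult", function(object) {
    p <- object@pValue
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
        return("pValue must be a single value in [0, 1]")
    if (!object@testName %in% c("burden", "skat"))
        return("testName must be 'burden' or 'skat'")
    TRUE
})

#' One cell of the simulation study design
#'
#' A scenario fixes the cohort ascertainment (case and control quotas),
#' the variant spectrum (locus count, frequency bounds, spectrum shape),
#' the effect model, and the significance level at which rejections are
#' counted.
#'
#' @slot nCases,nControls integer ascertainment quotas.
#' @slot mafLower,mafUpper numeric minor allele frequency bounds.
#' @slot mafShape numeric shape of the truncated power-law spectrum.
#' @slot effect one of `"null"`, `"uniform_or"`, `"mixed_low"`,
#'   `"mixed_moderate"`, `"mixed_high"`.
#' @slot oddsRatio numeric per-allele odds ratio for `"uniform_or"`.
#' @slot nDiseaseLoci integer number of causal loci.
#' @slot nLoci integer number of loci in the bin.
#' @slot alphaLevel numeric significance level.
#' @slot prevalence numeric target population prevalence.
#'
#' @seealso [Scenario()], [scenarioGrid()]
#' @exportClass Scenario
setClass("Scenario",
    slots = c(nCases = "integer", nControls = "integer",
              mafLower = "numeric", mafUpper = "numeric",
              mafShape = "numeric", effect = "character",
              oddsRatio = "numeric", nDiseaseLoci = "integer",
              nLoci = "integer", alphaLevel = "numeric",
              prevalence = "numeric"))

setValidity("Scenario", function(object) {
    if (!object@effect %in% c("null", "uniform_or", "mixed_low",
                              "mixed_moderate", "mixed_high"))
        return("unknown effect scenario")
    if (object@nCases < 0L || object@nControls < 0L)
        return("case and control quotas must be non-negative")
    if (object@nDiseaseLoci > object@nLoci)
        return("nDiseaseLoci cannot exceed nLoci")
    if (object@alphaLevel <= 0 || object@alphaLevel >= 1)
        return("alphaLevel must be in (0, 1)")
    TRUE
})

#' Rejection-rate summary for one scenario and one test
#'
#' For null-effect scenarios the rate is type I error; otherwise it is
#' power. One entry of `rates` per replicate, each the proportion of
#' datasets in that replicate with p-value at or below the scenario's
#' significance level.
#'
#' @slot testName `"burden"` or `"skat"`.
#' @slot rates numeric vector (length `nReplicates`) of per-replicate
#'   rejection proportions.
#' @slot nDatasetsPerReplicate,nReplicates integer design counts.
#' @slot meanRate numeric mean of `rates`.
#' @slot scenario the [Scenario-class] the estimate belongs to.
#'
#' @seealso [runReplicates()], [summarizePower()]
#' @exportClass PowerEstimate
setClass("PowerEstimate",
    slots = c(testName = "character", rates = "numeric",
              nDatasetsPerReplicate = "integer", nReplicates = "integer",
              meanRate = "numeric", scenario = "Scenario"))

setValidity("PowerEstimate", function(object) {
    r <- object@rates
    if (length(r) != object@nReplicates)
        return("rates must have one entry per replicate")
    if (length(r) && (any(r < 0) || any(r > 1)))
        return("rates must lie in [0, 1]")
    if (length(r) && abs(object@meanRate - mean(r)) > 1e-12)
        return("meanRate must equal mean(rates)")
    TRUE
})
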