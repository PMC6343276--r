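# Printed odds-ratio sets for the mixed risk/protective designs. Each
# signal level assigns five risk odds ratios to half of the disease loci
# and the five matching protective (reciprocal, as printed) odds ratios
# to the other half.
.MIXED_OR_TABLE <- list(
    mixed_low = list(
        risk = c(2.3, 2.73, 3.15, 3.58, 4),
        protective = c(0.43, 0.37, 0.32, 0.28, 0.25)),
    mixed_moderate = list(
        risk = c(4, 5.25, 6.5, 7.75, 9),
        protective = c(0.25, 0.19, 0.15, 0.13, 0.11)),
    mixed_high = list(
        risk = c(9, 11.5, 14, 16.4, 19),
        protective = c(0.11, 0.087, 0.07, 0.06, 0.053)))

#' Mixed risk/protective odds-ratio sets
#'
#' The per-locus odds ratios used by the `mixed_low`, `mixed_moderate`
#' and `mixed_high` effect scenarios: five risk values (> 1) and the five
#' matching protective values (< 1, the reciprocals rounded as used).
#'
#' @param level one of `"mixed_low"`, `"mixed_moderate"`, `"mixed_high"`.
#' @return A list with components `risk` and `protective`.
#' @export
mixedOddsRatios <- function(level = c("mixed_low", "mixed_moderate",
                                      "mixed_high")) {
    .MIXED_OR_TABLE[[match.arg(level)]]
}

#' Build an (uncalibrated) effect model for one simulated bin
#'
#' Assigns per-locus log odds ratios according to the effect scenario:
#' \describe{
#'   \item{`null`}{all log odds ratios zero (no association signal).}
#'   \item{`uniform_or`}{`nDiseaseLoci` loci drawn uniformly without
#'     replacement all receive `log(oddsRatio)` (risk effects of equal
#'     size).}
#'   \item{`mixed_low` / `mixed_moderate` / `mixed_high`}{half of the
#'     disease loci receive the five risk odds ratios of the matching
#'     signal level, the other half the five protective reciprocals (see
#'     [mixedOddsRatios()]); values are assigned to the chosen loci in a
#'     random permutation.}
#' }
#' The intercept is left `NA`; calibrate it against a drawn spectrum
#' with [calibrateIntercept()]. Uses the current R random number
#' generator.
#'
#' @param nLoci number of loci in the bin (default 143).
#' @param effect effect scenario.
#' @param nDiseaseLoci number of causal loci (default 10; must be even
#'   for mixed scenarios).
#' @param oddsRatio per-allele odds ratio for `uniform_or` (default 2.5).
#' @param targetPrevalence population prevalence the model will be
#'   calibrated to (default 0.05).
#' @return An uncalibrated [EffectModel-class].
#' @examples
#' set.seed(1)
#' m <- buildEffectModel(143, "uniform_or")
#' length(diseaseLoci(m))
#' @export
buildEffectModel <- function(nLoci = 143,
                             effect = c("null", "uniform_or", "mixed_low",
                                        "mixed_moderate", "mixed_high"),
                             nDiseaseLoci = 10, oddsRatio = 2.5,
                             targetPrevalence = 0.05) {
    effect <- match.arg(effect)
    nLoci <- as.integer(nLoci)
    nDiseaseLoci <- as.integer(nDiseaseLoci)
    if (effect == "null")
        nDiseaseLoci <- 0L
    if (nDiseaseLoci > nLoci)
        stop("nDiseaseLoci cannot exceed nLoci")
    beta <- numeric(nLoci)
    loci <- integer(0)
    if (effect == "uniform_or" && nDiseaseLoci > 0L) {
        if (oddsRatio <= 0 || oddsRatio == 1)
            stop("oddsRatio must be positive and != 1 for uniform_or")
        loci <- sort(sample.int(nLoci, nDiseaseLoci))
        beta[loci] <- log(oddsRatio)
    } else if (startsWith(effect, "mixed_")) {
        if (nDiseaseLoci %% 2L != 0L || nDiseaseLoci == 0L)
            stop("mixed scenarios need an even, positive nDiseaseLoci")
        ors <- .MIXED_OR_TABLE[[effect]]
        half <- nDiseaseLoci %/% 2L
        vals <- c(rep_len(ors$risk, half), rep_len(ors$protective, half))
        loci <- sort(sample.int(nLoci, nDiseaseLoci))
        beta[loci] <- log(sample(vals))
    }
    new("EffectModel", logOdds = beta, intercept = NA_real_,
        diseaseLoci = loci, targetPrevalence = targetPrevalence,
        calibrated = FALSE)
}

#' Disease probability under the logistic penetrance model
#'
#' Evaluates `plogis(intercept + sum_j logOdds_j * x_j)` for one
#' genotype row or a matrix of rows. The result is strictly inside
#' (0, 1).
#'
#' @param genotypes numeric vector of minor-allele counts (one
#'   individual) or a matrix with individuals in rows.
#' @param model a calibrated [EffectModel-class] (or any model with a
#'   finite intercept).
#' @return Numeric vector of disease probabilities.
#' @examples
#' m <- buildEffectModel(3, "null")
#' m <- calibrateIntercept(MafSpectrum(c(0.01, 0.02, 0.03)), m)
#' diseaseProbability(c(0, 0, 0), m)  # = target prevalence
#' @export
diseaseProbability <- function(genotypes, model) {
    stopifnot(is(model, "EffectModel"))
    if (!is.finite(model@intercept))
        stop("model intercept is not set; run calibrateIntercept() first")
    if (is.null(dim(genotypes)))
        genotypes <- matrix(genotypes, nrow = 1L)
    if (ncol(genotypes) != length(model@logOdds))
        stop(sprintf("genotype row length (%d) does not match model (%d)",
                     ncol(genotypes), length(model@logOdds)))
    as.vector(plogis(model@intercept + genotypes %*% model@logOdds))
}

# Exact distribution of the linear predictor offset sum_j beta_j x_j over
# the disease loci, under Hardy-Weinberg genotype probabilities. Returns
# support `s` and probabilities `w`. Equal effects collapse to the
# distribution of the total disease-allele count (an exact reduction of
# the 3^d enumeration); unequal effects use the full 3^d expansion.
.linearPredictorDist <- function(mafs, model) {
    d <- length(model@diseaseLoci)
    if (d == 0L)
        return(list(s = 0, w = 1))
    if (d > 15L)
        stop("exact enumeration supports at most 15 disease loci; ",
             "use monteCarloPrevalence() instead")
    q <- freqs(mafs)[model@diseaseLoci]
    beta <- model@logOdds[model@diseaseLoci]
    hw <- function(qj) c((1 - qj)^2, 2 * qj * (1 - qj), qj^2)
    if (length(unique(beta)) == 1L) {
        # convolve allele-count distributions on the integer grid 0..2d
        w <- 1
        for (qj in q) {
            p3 <- hw(qj)
            w <- c(w, 0, 0) * p3[1L] +
                 c(0, w, 0) * p3[2L] +
                 c(0, 0, w) * p3[3L]
        }
        list(s = beta[1L] * (0:(2L * d)), w = w)
    } else {
        s <- 0
        w <- 1
        for (j in seq_len(d)) {
            p3 <- hw(q[j])
            s <- c(s, s + beta[j], s + 2 * beta[j])
            w <- c(w * p3[1L], w * p3[2L], w * p3[3L])
        }
        list(s = s, w = w)
    }
}

#' Exact population prevalence implied by a penetrance model
#'
#' Computes `E[plogis(intercept + sum_j beta_j x_j)]` exactly by
#' enumerating the Hardy-Weinberg genotype configurations of the loci
#' with nonzero effect (zero-effect loci contribute a constant factor).
#' Supports at most 15 disease loci; beyond that use
#' [monteCarloPrevalence()].
#'
#' @param mafs a [MafSpectrum-class] of the same length as the model.
#' @param model an [EffectModel-class] with a finite intercept.
#' @return The population prevalence (a single probability).
#' @export
exactPrevalence <- function(mafs, model) {
    stopifnot(is(mafs, "MafSpectrum"), is(model, "EffectModel"))
    if (length(mafs) != length(model@logOdds))
        stop("mafs and model must describe the same number of loci")
    if (!is.finite(model@intercept))
        stop("model intercept is not set")
    lp <- .linearPredictorDist(mafs, model)
    sum(lp$w * plogis(model@intercept + lp$s))
}

#' Monte Carlo estimate of the population prevalence
#'
#' Estimates the prevalence by simulating disease-locus genotypes for
#' `nSim` individuals under Hardy-Weinberg proportions and averaging the
#' penetrance. Serves as the stochastic cross-check for
#' [exactPrevalence()] and as the evaluator when there are more than 15
#' disease loci. Uses the current R random number generator.
#'
#' @inheritParams exactPrevalence
#' @param nSim number of simulated individuals (default 1e6).
#' @return Estimated prevalence.
#' @export
monteCarloPrevalence <- function(mafs, model, nSim = 1e6) {
    stopifnot(is(mafs, "MafSpectrum"), is(model, "EffectModel"))
    if (!is.finite(model@intercept))
        stop("model intercept is not set")
    d <- length(model@diseaseLoci)
    if (d == 0L)
        return(plogis(model@intercept))
    q <- freqs(mafs)[model@diseaseLoci]
    beta <- model@logOdds[model@diseaseLoci]
    g <- matrix(rbinom(nSim * d, 2L, rep(q, each = nSim)), nSim, d)
    mean(plogis(model@intercept + as.vector(g %*% beta)))
}

#' Calibrate the penetrance intercept to a target prevalence
#'
#' Finds the intercept for which [exactPrevalence()] equals
#' `targetPrevalence`. The prevalence is strictly increasing in the
#' intercept, so the root is bracketed analytically (shifting the
#' intercept past the extreme linear-predictor offsets bounds the
#' prevalence on either side of the target) and found with
#' [stats::uniroot()].
#'
#' @inheritParams exactPrevalence
#' @param targetPrevalence target population prevalence (default: the
#'   model's `targetPrevalence` slot).
#' @param tol required absolute accuracy of the achieved prevalence
#'   (default 1e-6).
#' @return The calibrated [EffectModel-class] (intercept set,
#'   `calibrated = TRUE`).
#' @examples
#' set.seed(1)
#' s <- sampleMafSpectrum(143)
#' m <- calibrateIntercept(s, buildEffectModel(143, "uniform_or"))
#' exactPrevalence(s, m)
#' @export
calibrateIntercept <- function(mafs, model,
                               targetPrevalence = NULL, tol = 1e-6) {
    stopifnot(is(mafs, "MafSpectrum"), is(model, "EffectModel"))
    if (length(mafs) != length(model@logOdds))
        stop("mafs and model must describe the same number of loci")
    if (is.null(targetPrevalence))
        targetPrevalence <- model@targetPrevalence
    if (targetPrevalence <= 0 || targetPrevalence >= 1)
        stop("targetPrevalence must be in (0, 1)")
    lp <- .linearPredictorDist(mafs, model)
    f <- function(a) sum(lp$w * plogis(a + lp$s)) - targetPrevalence
    base <- qlogis(targetPrevalence)
    lower <- base - max(c(0, lp$s)) - 1
    upper <- base - min(c(0, lp$s)) + 1
    root <- uniroot(f, c(lower, upper), tol = 1e-12, maxiter = 1000L)
    achieved <- f(root$root) + targetPrevalence
    if (abs(achieved - targetPrevalence) > tol)
        stop(sprintf(
            "intercept calibration did not reach tolerance %g in [%g, %g]",
            tol, lower, upper))
    initialize(model, intercept = root$root,
               targetPrevalence = targetPrevalence, calibrated = TRUE)
}

#' @rdname rvpower-accessors
#' @export
setMethod("logOdds", "EffectModel", function(object) object@logOdds)

#' @rdname rvpower-accessors
#' @export
setMethod("intercept", "EffectModel", function(object) object@intercept)

#' @rdname rvpower-accessors
#' @export
setMethod("diseaseLoci", "EffectModel", function(object) object@diseaseLoci)

#' @rdname rvpower-accessors
#' @export
setMethod("isCalibrated", "EffectModel", function(object) object@calibrated)

#' @rdname rvpower-accessors
#' @export
setMethod("targetPrevalence", "EffectModel",
    function(object) object@targetPrevalence)

setMethod("show", "EffectModel", function(object) {
    cat(sprintf(
        "EffectModel: %d loci, %d with nonzero effect\n",
        length(object@logOdds), length(object@diseaseLoci)))
    cat(sprintf("  intercept: %s (%scalibrated to prevalence %.4g)\n",
                format(object@intercept),
                if (object@calibrated) "" else "not ",
                object@targetPrevalence))
    if (length(object@diseaseLoci))
        cat("  odds ratios:",
            paste(format(exp(object@logOdds[object@diseaseLoci]),
                         digits = 3), collapse = " "), "\n")
})
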