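# Default shape of the truncated power-law MAF spectrum (density ~ q^-shape).
# The spectrum is the package's stand-in for an empirical exome
# rare-variant spectrum; shape 1 is the neutral site-frequency-spectrum
# shape (see the methods vignette).
.DEFAULT_MAF_SHAPE <- 1

#' Default shape of the simulated minor allele frequency spectrum
#'
#' The truncated power-law exponent used by [sampleMafSpectrum()] and
#' [Scenario()] unless overridden. See the methods vignette for how the
#' default was chosen.
#'
#' @return A numeric scalar.
#' @export
defaultMafShape <- function() .DEFAULT_MAF_SHAPE

#' Construct a MafSpectrum from known frequencies
#'
#' @param freqs numeric vector of per-locus minor allele frequencies.
#' @param lowerBound,upperBound frequency bounds; defaults are the
#'   observed range of `freqs` clipped into (0, 0.5).
#' @return A [MafSpectrum-class].
#' @export
MafSpectrum <- function(freqs, lowerBound = NULL, upperBound = NULL) {
    freqs <- as.numeric(freqs)
    if (is.null(lowerBound))
        lowerBound <- if (length(freqs)) min(freqs) else 0.0015
    if (is.null(upperBound))
        upperBound <- if (length(freqs)) max(max(freqs), lowerBound * 2)
                      else 0.01
    new("MafSpectrum", freqs = freqs, lowerBound = lowerBound,
        upperBound = upperBound)
}

#' Draw a minor allele frequency spectrum for one simulated bin
#'
#' Draws `nLoci` independent minor allele frequencies from a truncated
#' power-law density proportional to `q^(-shape)` on `[lower, upper]`,
#' by inversion of the closed-form CDF. `shape = 1` gives
#' `F(q) = log(q / lower) / log(upper / lower)`; other shapes use the
#' general truncated-Pareto inverse. Larger shapes concentrate mass near
#' the lower bound, mimicking the excess of very rare variants seen in
#' large exome panels. Uses the current R random number generator; call
#' `set.seed()` first for reproducibility.
#'
#' @param nLoci number of loci (>= 0).
#' @param lower,upper frequency bounds, `0 < lower < upper < 0.5`. The
#'   defaults are 0.0015 and 0.01 (use `upper = 0.05` for the laxer
#'   rare-variant threshold).
#' @param shape power-law exponent (default [defaultMafShape()]).
#' @return A [MafSpectrum-class] with `nLoci` frequencies.
#' @examples
#' set.seed(1)
#' s <- sampleMafSpectrum(143)
#' range(freqs(s))
#' @export
sampleMafSpectrum <- function(nLoci, lower = 0.0015, upper = 0.01,
                              shape = defaultMafShape()) {
    if (length(nLoci) != 1L || is.na(nLoci) || nLoci < 0)
        stop("nLoci must be a single non-negative count")
    if (!is.finite(lower) || !is.finite(upper) || lower <= 0 ||
        lower >= upper || upper >= 0.5)
        stop("bounds must satisfy 0 < lower < upper < 0.5")
    u <- runif(nLoci)
    q <- if (abs(shape - 1) < 1e-12) {
        lower * (upper / lower)^u
    } else {
        e <- 1 - shape
        (lower^e + u * (upper^e - lower^e))^(1 / e)
    }
    # guard against round-off just outside the bounds
    q <- pmin(pmax(q, lower), upper)
    new("MafSpectrum", freqs = q, lowerBound = lower, upperBound = upper)
}

#' CDF of the truncated power-law spectrum
#'
#' Closed-form cumulative distribution function of the density
#' proportional to `q^(-shape)` truncated to `[lower, upper]`. Used as
#' the reference law for goodness-of-fit checks of
#' [sampleMafSpectrum()].
#'
#' @param q quantiles.
#' @param lower,upper,shape as in [sampleMafSpectrum()].
#' @return Numeric vector of probabilities.
#' @export
pMafSpectrum <- function(q, lower = 0.0015, upper = 0.01,
                         shape = defaultMafShape()) {
    q <- pmin(pmax(q, lower), upper)
    if (abs(shape - 1) < 1e-12)
        return(log(q / lower) / log(upper / lower))
    e <- 1 - shape
    (q^e - lower^e) / (upper^e - lower^e)
}

#' @rdname rvpower-accessors
#' @export
setMethod("freqs", "MafSpectrum", function(object) object@freqs)

#' @describeIn MafSpectrum length = number of loci
#' @param x a `MafSpectrum`.
#' @export
setMethod("length", "MafSpectrum", function(x) length(x@freqs))

setMethod("show", "MafSpectrum", function(object) {
    cat(sprintf(
        "MafSpectrum: %d loci on [%.4g, %.4g]\n", length(object@freqs),
        object@lowerBound, object@upperBound))
    if (length(object@freqs))
        cat(sprintf("  median MAF %.4g, mean %.4g\n",
                    stats::median(object@freqs), mean(object@freqs)))
})
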