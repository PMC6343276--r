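.mbWeightsMatrix <- function(g, pseudocount = 1) {
    if (is.null(dim(g)) || nrow(g) < 1L || ncol(g) < 1L)
        stop("genotype matrix must have at least one individual and one locus")
    if (pseudocount < 0)
        stop("pseudocount must be non-negative")
    n <- nrow(g)
    counts <- colSums(g)
    qhat <- (counts + pseudocount) / (2 * n + 2 * pseudocount)
    if (any(qhat <= 0) || any(qhat >= 1))
        stop("frequency estimate outside (0, 1); use a positive pseudocount")
    w <- 1 / sqrt(n * qhat * (1 - qhat))
    new("WeightVector", weights = w, mafEstimates = qhat)
}

#' @rdname mbWeights
#' @export
setMethod("mbWeights", "matrix",
    function(object, pseudocount = 1) .mbWeightsMatrix(object, pseudocount))

#' @rdname mbWeights
#' @export
setMethod("mbWeights", "RareVariantCohort",
    function(object, pseudocount = 1)
        .mbWeightsMatrix(genotypes(object), pseudocount))

#' @rdname rvpower-accessors
#' @export
setMethod("weights", "WeightVector", function(object, ...) object@weights)

#' @rdname rvpower-accessors
#' @export
setMethod("mafEstimates", "WeightVector",
    function(object) object@mafEstimates)

#' @describeIn WeightVector number of loci
#' @param x a `WeightVector`.
#' @export
setMethod("length", "WeightVector", function(x) length(x@weights))

setMethod("show", "WeightVector", function(object) {
    cat(sprintf("WeightVector: %d loci, weight range [%.4g, %.4g]\n",
                length(object@weights), min(object@weights),
                max(object@weights)))
})

#' Per-individual weighted burden scores
#'
#' Collapses a genotype bin into one genetic score per individual,
#' `score_i = sum_j w_j g_ij`.
#'
#' @param genotypes matrix of minor-allele counts (individuals in rows)
#'   or a [RareVariantCohort-class].
#' @param weights a [WeightVector-class] or a bare numeric vector with
#'   one weight per locus.
#' @return Numeric vector of scores, one per individual.
#' @export
burdenScores <- function(genotypes, weights) {
    if (is(genotypes, "RareVariantCohort"))
        genotypes <- genotypes(genotypes)
    w <- if (is(weights, "WeightVector")) weights@weights
         else as.numeric(weights)
    if (ncol(genotypes) != length(w))
        stop("number of loci in genotypes and weights must agree")
    as.vector(genotypes %*% w)
}
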