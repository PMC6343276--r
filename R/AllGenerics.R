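#' @name rvpower-accessors
#' @title Accessors for rvpower classes
#' @description Slot accessors for the S4 classes in this package. Use
#'   these instead of `@` access.
#' @param object,x an rvpower S4 object.
#' @param ... ignored.
#' @return The corresponding slot value.
NULL

#' @rdname rvpower-accessors
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))

#' @rdname rvpower-accessors
#' @export
setGeneric("logOdds", function(object) standardGeneric("logOdds"))

#' @rdname rvpower-accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname rvpower-accessors
#' @export
setGeneric("diseaseLoci", function(object) standardGeneric("diseaseLoci"))

#' @rdname rvpower-accessors
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))

#' @rdname rvpower-accessors
#' @export
setGeneric("targetPrevalence",
    function(object) standardGeneric("targetPrevalence"))

#' @rdname rvpower-accessors
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname rvpower-accessors
#' @export
setGeneric("caseStatus", function(object) standardGeneric("caseStatus"))

#' @rdname rvpower-accessors
#' @export
setGeneric("nCases", function(object) standardGeneric("nCases"))

#' @rdname rvpower-accessors
#' @export
setGeneric("nControls", function(object) standardGeneric("nControls"))

#' @rdname rvpower-accessors
#' @export
setGeneric("variantMafs", function(object) standardGeneric("variantMafs"))

#' @rdname rvpower-accessors
#' @export
setGeneric("mafEstimates", function(object) standardGeneric("mafEstimates"))

#' @rdname rvpower-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname rvpower-accessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))

#' @rdname rvpower-accessors
#' @export
setGeneric("testName", function(object) standardGeneric("testName"))

#' @rdname rvpower-accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))

#' @rdname rvpower-accessors
#' @export
setGeneric("meanRate", function(object) standardGeneric("meanRate"))

#' Madsen-Browning weights for a genotype bin
#'
#' Computes per-locus Madsen-Browning weights
#' `w_j = 1 / sqrt(n * q_j * (1 - q_j))` where `q_j` is the pooled-sample
#' minor allele frequency estimate
#' `(c_j + pseudocount) / (2 n + 2 pseudocount)` and `c_j` the pooled
#' minor-allele count over all `n` individuals, cases and controls
#' together. The pseudocount keeps weights finite at monomorphic loci;
#' pooling makes the weights (and hence both tests) invariant under
#' exchanging case and control labels.
#'
#' @param object genotype matrix (individuals in rows, loci in columns,
#'   minor-allele counts in \{0, 1, 2\}) or a [RareVariantCohort-class].
#' @param pseudocount non-negative allele pseudocount (default 1).
#' @return A [WeightVector-class].
#' @examples
#' g <- matrix(c(0L, 1L, 1L, 0L), nrow = 2)
#' mbWeights(g)
#' @export
setGeneric("mbWeights",
    function(object, pseudocount = 1) standardGeneric("mbWeights"))

#' @rdname burdenTest
#' @export
setGeneric("burdenTest", function(object, ...) standardGeneric("burdenTest"))

#' @rdname skatTest
#' @export
setGeneric("skatTest", function(object, ...) standardGeneric("skatTest"))
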