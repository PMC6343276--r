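#' Construct a RareVariantCohort
#'
#' Wraps a genotype matrix and a binary phenotype in a
#' [SummarizedExperiment::SummarizedExperiment-class]-derived container.
#' Genotypes are given with individuals in rows (the natural orientation
#' for the association tests) and stored with loci in rows per
#' Bioconductor convention.
#'
#' @param genotypes integer matrix of minor-allele counts, individuals in
#'   rows, loci in columns.
#' @param status binary vector (1 = case, 0 = control), one entry per
#'   individual.
#' @param maf optional numeric vector of true simulated minor allele
#'   frequencies, one per locus.
#' @return A [RareVariantCohort-class].
#' @export
RareVariantCohort <- function(genotypes, status, maf = NULL) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    status <- as.integer(status)
    if (length(status) != nrow(genotypes))
        stop("status must have one entry per genotype row (individual)")
    p <- ncol(genotypes)
    if (is.null(maf))
        maf <- rep(NA_real_, p)
    if (length(maf) != p)
        stop("maf must have one entry per locus")
    sampleIds <- sprintf("S%06d", seq_len(nrow(genotypes)))
    locusIds <- sprintf("L%05d", seq_len(p))
    se <- SummarizedExperiment(
        assays = list(genotype = matrix(t(genotypes), nrow = p,
                                        dimnames = list(locusIds,
                                                        sampleIds))),
        rowData = DataFrame(maf = as.numeric(maf), row.names = locusIds),
        colData = DataFrame(status = status, row.names = sampleIds))
    new("RareVariantCohort", se)
}

#' @rdname rvpower-accessors
#' @export
setMethod("genotypes", "RareVariantCohort", function(object) {
    t(SummarizedExperiment::assay(object, "genotype"))
})

#' @rdname rvpower-accessors
#' @export
setMethod("caseStatus", "RareVariantCohort",
    function(object) object$status)

#' @rdname rvpower-accessors
#' @export
setMethod("nCases", "RareVariantCohort",
    function(object) sum(object$status == 1L))

#' @rdname rvpower-accessors
#' @export
setMethod("nControls", "RareVariantCohort",
    function(object) sum(object$status == 0L))

#' @rdname rvpower-accessors
#' @export
setMethod("variantMafs", "RareVariantCohort",
    function(object) rowData(object)$maf)

setMethod("show", "RareVariantCohort", function(object) {
    cat(sprintf("RareVariantCohort: %d loci x %d individuals (%d cases, %d controls)\n",
                nrow(object), ncol(object), nCases(object),
                nControls(object)))
    m <- variantMafs(object)
    if (length(m) && !all(is.na(m)))
        cat(sprintf("  simulated MAF range [%.4g, %.4g]\n",
                    min(m, na.rm = TRUE), max(m, na.rm = TRUE)))
})

#' Ascertain a case-control cohort under the penetrance model
#'
#' Simulates individuals from the population model — genotypes
#' `x_j ~ Binomial(2, q_j)` independently per locus (Hardy-Weinberg, no
#' linkage), case status `~ Bernoulli(diseaseProbability)` — and retains
#' each draw only while its group quota (case or control) is unfilled,
#' until both quotas are met (retrospective ascertainment). At a 5%
#' prevalence, expect roughly 20 population draws per ascertained case.
#' There is no missingness in either genotypes or phenotype. Uses the
#' current R random number generator.
#'
#' Because the neutral loci are independent of disease status, their
#' genotypes are drawn only for retained individuals; the sampled
#' distribution is identical to drawing every locus for every candidate.
#'
#' @param nCases,nControls ascertainment quotas (>= 0).
#' @param mafs a [MafSpectrum-class].
#' @param model a calibrated [EffectModel-class] of matching length.
#' @param maxDraws cap on population draws (default 1e7); exceeding it
#'   raises an error naming the unfilled quota.
#' @return A [RareVariantCohort-class] with exactly `nCases` cases and
#'   `nControls` controls, in draw order.
#' @examples
#' set.seed(1)
#' s <- sampleMafSpectrum(20)
#' m <- calibrateIntercept(s, buildEffectModel(20, "null"))
#' cohort <- sampleCohort(50, 50, s, m)
#' c(nCases(cohort), nControls(cohort))
#' @export
sampleCohort <- function(nCases, nControls, mafs, model,
                         maxDraws = 1e7) {
    stopifnot(is(mafs, "MafSpectrum"), is(model, "EffectModel"))
    if (!model@calibrated)
        stop("model must be calibrated (see calibrateIntercept())")
    if (length(mafs) != length(model@logOdds))
        stop("mafs and model must describe the same number of loci")
    nCases <- as.integer(nCases)
    nControls <- as.integer(nControls)
    if (nCases < 0L || nControls < 0L)
        stop("quotas must be non-negative")
    q <- freqs(mafs)
    p <- length(q)
    dl <- model@diseaseLoci
    d <- length(dl)
    beta <- model@logOdds[dl]
    alpha <- model@intercept
    prev <- model@targetPrevalence

    remCase <- nCases
    remCtrl <- nControls
    drawsUsed <- 0
    keptG <- vector("list", 0L)
    keptY <- vector("list", 0L)
    while (remCase > 0L || remCtrl > 0L) {
        need <- max(remCase / prev, remCtrl / (1 - prev))
        m <- ceiling(1.2 * need) + 100
        m <- min(m, maxDraws - drawsUsed)
        if (m <= 0) {
            unfilled <- if (remCase > 0L)
                sprintf("case quota (%d short)", remCase)
            else sprintf("control quota (%d short)", remCtrl)
            stop(sprintf(
                "draw cap %g reached with unfilled %s", maxDraws, unfilled))
        }
        drawsUsed <- drawsUsed + m
        gd <- if (d > 0L)
            matrix(rbinom(m * d, 2L, rep(q[dl], each = m)), m, d)
        else matrix(0L, m, 0L)
        pr <- if (d > 0L) plogis(alpha + as.vector(gd %*% beta))
              else rep(plogis(alpha), m)
        y <- as.integer(runif(m) < pr)
        # sequential quota filling: a draw is rejected only when its own
        # group's quota is already full
        caseIdx <- which(y == 1L)
        ctrlIdx <- which(y == 0L)
        takeCase <- caseIdx[seq_len(min(remCase, length(caseIdx)))]
        takeCtrl <- ctrlIdx[seq_len(min(remCtrl, length(ctrlIdx)))]
        keep <- sort(c(takeCase, takeCtrl))
        if (length(keep)) {
            keptG[[length(keptG) + 1L]] <- gd[keep, , drop = FALSE]
            keptY[[length(keptY) + 1L]] <- y[keep]
            remCase <- remCase - length(takeCase)
            remCtrl <- remCtrl - length(takeCtrl)
        }
    }
    yAll <- unlist(keptY)
    n <- length(yAll)
    G <- matrix(0L, n, p)
    if (d > 0L)
        G[, dl] <- do.call(rbind, keptG)
    neutral <- setdiff(seq_len(p), dl)
    if (length(neutral) && n > 0L)
        G[, neutral] <- rbinom(n * length(neutral), 2L,
                               rep(q[neutral], each = n))
    RareVariantCohort(G, yAll, maf = q)
}
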