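#' Write a simulated cohort as VCF plus phenotype TSV
#'
#' Emits the genotypes as an uncompressed VCF v4.2 file on one
#' pseudo-chromosome `"1"` with positions `1..nLoci`, `REF = A`,
#' `ALT = C` (the ALT allele is the minor allele by construction),
#' unphased `GT` calls and the simulated minor allele frequency in the
#' `AF` INFO field; and the phenotype as a two-column TSV
#' (`sample_id`, `status`). Sample identifiers are `S000001`, ... in
#' cohort order. The pair round-trips losslessly through
#' [readCohortVcf()] for genotypes and phenotype.
#'
#' @param cohort a [RareVariantCohort-class].
#' @param vcfPath output VCF path.
#' @param phenoPath output phenotype TSV path (default: `vcfPath` with
#'   a `.pheno.tsv` suffix appended).
#' @return Invisibly, a character vector of the two paths written.
#' @export
writeCohortVcf <- function(cohort, vcfPath,
                           phenoPath = paste0(vcfPath, ".pheno.tsv")) {
    stopifnot(is(cohort, "RareVariantCohort"))
    gt <- SummarizedExperiment::assay(cohort, "genotype")  # loci x ind
    p <- nrow(gt)
    maf <- variantMafs(cohort)
    info <- ifelse(is.na(maf), ".", sprintf("AF=%.10g", maf))
    codes <- c("0/0", "0/1", "1/1")
    gtStr <- matrix(codes[gt + 1L], nrow = p)
    sampleIds <- colnames(gt)
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=rvpower",
        "##contig=<ID=1>",
        "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Simulated minor allele frequency\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleIds), collapse = "\t"))
    body <- paste(
        "1", seq_len(p), rownames(gt), "A", "C", ".", "PASS", info, "GT",
        apply(gtStr, 1L, paste, collapse = "\t"),
        sep = "\t")
    writeLines(c(header, body), vcfPath)
    write.table(
        data.frame(sample_id = sampleIds,
                   status = caseStatus(cohort)),
        phenoPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(vcf = vcfPath, phenotype = phenoPath))
}

# Quick structural scan so malformed files fail with a line number
# before being handed to the VCF parser.
.scanVcfStructure <- function(path) {
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
        stop(sprintf("%s line 1: missing ##fileformat header", path))
    hdr <- which(startsWith(lines, "#CHROM"))
    if (length(hdr) != 1L)
        stop(sprintf("%s: expected exactly one #CHROM header line", path))
    nField <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
    body <- seq(hdr + 1L, length.out = length(lines) - hdr)
    for (i in body) {
        got <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
        if (got != nField)
            stop(sprintf("%s line %d: %d fields, expected %d",
                         path, i, got, nField))
    }
    invisible(TRUE)
}

#' Read a cohort from VCF plus phenotype TSV
#'
#' Parses the VCF with \pkg{vcfR}, converts unphased (or phased)
#' diploid `GT` calls to ALT-allele counts and joins the phenotype TSV
#' by sample identifier. The reader enforces the writer's conventions:
#' diploid calls only, and a pooled ALT allele frequency of at most 0.5
#' at every locus (ALT must be the minor allele; the reader errors
#' rather than silently flipping alleles). Missing genotype calls are
#' rejected (simulated data are complete).
#'
#' @param vcfPath VCF path (as written by [writeCohortVcf()]).
#' @param phenoPath phenotype TSV path.
#' @return A [RareVariantCohort-class].
#' @export
readCohortVcf <- function(vcfPath,
                          phenoPath = paste0(vcfPath, ".pheno.tsv")) {
    .scanVcfStructure(vcfPath)
    v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    gtStr <- vcfR::extract.gt(v, element = "GT")
    if (any(is.na(gtStr)))
        stop("missing genotype calls are not supported")
    gtStr <- gsub("|", "/", gtStr, fixed = TRUE)
    codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    bad <- !(gtStr %in% names(codes))
    if (any(bad))
        stop(sprintf(
            "unsupported genotype call '%s' (only diploid biallelic calls are accepted)",
            gtStr[which(bad)[1L]]))
    counts <- matrix(codes[gtStr], nrow = nrow(gtStr),
                     dimnames = dimnames(gtStr))
    n <- ncol(counts)
    altFreq <- rowSums(counts) / (2 * n)
    if (any(altFreq > 0.5))
        stop(sprintf(
            "locus %s has ALT allele frequency %.3f > 0.5; ALT must be the minor allele",
            rownames(counts)[which(altFreq > 0.5)[1L]],
            max(altFreq)))
    info <- vcfR::extract.info(v, element = "AF", as.numeric = TRUE)
    pheno <- read.table(phenoPath, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    if (!all(c("sample_id", "status") %in% names(pheno)))
        stop("phenotype TSV must have columns sample_id and status")
    idx <- match(colnames(counts), pheno$sample_id)
    if (any(is.na(idx)))
        stop("phenotype TSV is missing entries for some VCF samples")
    RareVariantCohort(t(counts), pheno$status[idx],
                      maf = if (all(is.na(info))) NULL else info)
}
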