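#' Sex chromosome label conventions
#'
#' Default sets of chromosome labels treated as sex chromosomes. Autosome-only
#' analyses remove these before embedding. Labels are matched as strings, so
#' both letter ("X"/"Y") and numeric PLINK conventions are covered: dog
#' datasets commonly code X/Y as 39/40, human as 23/24.
#'
#' @param species "dog" or "human"
#' @return character vector of chromosome labels
#' @export
sexChromosomes <- function(species = c("dog", "human")) {
    switch(match.arg(species),
           dog = c("X", "Y", "39", "40"),
           human = c("X", "Y", "23", "24"))
}

#' Remove markers on sex chromosomes
#'
#' @param gd a \linkS4class{GenotypeData}
#' @param sexLabels character vector of chromosome labels to drop; see
#'   \code{\link{sexChromosomes}} for species defaults.
#' @return GenotypeData with the matching markers removed; samples unchanged.
#' @export
filterSexChromosomes <- function(gd, sexLabels = sexChromosomes("human")) {
    keep <- !(SummarizedExperiment::rowData(gd)$chromosome %in% sexLabels)
    if (!any(keep))
        warning("all markers removed by sex-chromosome filter")
    gd[keep, ]
}

#' Per-marker minor allele frequency
#'
#' The alternate-allele frequency f is computed over non-missing calls as
#' sum(calls) / (2 * n_nonmissing); the MAF is min(f, 1 - f). Markers with all
#' calls missing get NA.
#'
#' @param gd a \linkS4class{GenotypeData}
#' @return numeric vector of MAFs, one per marker
#' @export
markerMAF <- function(gd) {
    m <- SummarizedExperiment::assay(gd, "calls")    # markers x samples
    obs <- m != -1L
    nObs <- rowSums(obs)
    tot <- rowSums(m * obs)
    f <- ifelse(nObs > 0, tot / (2 * nObs), NA_real_)
    pmin(f, 1 - f)
}

#' Remove markers below a minor-allele-frequency threshold
#'
#' Markers with MAF (computed over non-missing calls) strictly below
#' \code{threshold} are removed. Markers with all calls missing are always
#' removed, with a message.
#'
#' @param gd a \linkS4class{GenotypeData}
#' @param threshold MAF threshold in [0, 0.5]; the standard filter is 0.01.
#' @return filtered GenotypeData
#' @export
mafFilter <- function(gd, threshold = 0.01) {
    stopifnot(threshold >= 0, threshold <= 0.5)
    maf <- markerMAF(gd)
    if (anyNA(maf))
        message(sum(is.na(maf)), " markers with all calls missing removed")
    keep <- !is.na(maf) & maf >= threshold
    gd[keep, ]
}

#' Remove monomorphic (noninformative) markers
#'
#' Drops markers whose non-missing calls are all identical; equivalent to
#' \code{mafFilter} at any threshold > 0 for markers fixed for one allele, but
#' also drops markers fixed for the heterozygote code.
#'
#' @param gd a \linkS4class{GenotypeData}
#' @return filtered GenotypeData
#' @export
dropMonomorphic <- function(gd) {
    m <- SummarizedExperiment::assay(gd, "calls")
    keep <- apply(m, 1, function(r) length(unique(r[r != -1L])) > 1L)
    gd[keep, ]
}

#' Impute missing calls with the per-marker mode of a reference panel
#'
#' Every missing (-1) call is replaced by the most common genotype value of
#' that marker computed over non-missing calls in \code{reference}. Ties are
#' broken toward the smaller genotype value; markers entirely missing in the
#' reference are imputed as 0 (with a message).
#'
#' @param gd GenotypeData to impute
#' @param reference GenotypeData supplying the per-marker modes (defaults to
#'   \code{gd} itself); must share the marker set, in order.
#' @return imputed GenotypeData with no missing calls
#' @export
modeImpute <- function(gd, reference = gd) {
    if (!identical(rownames(gd), rownames(reference)))
        stop("reference marker set does not match")
    ref <- SummarizedExperiment::assay(reference, "calls")
    counts <- vapply(0:2, function(v) rowSums(ref == v), numeric(nrow(ref)))
    mode <- max.col(counts, ties.method = "first") - 1L   # smaller value wins
    empty <- rowSums(counts) == 0
    if (any(empty)) {
        mode[empty] <- 0L
        message(sum(empty), " markers entirely missing in reference; imputed 0")
    }
    m <- SummarizedExperiment::assay(gd, "calls")
    miss <- which(m == -1L, arr.ind = TRUE)
    if (nrow(miss)) {
        m[miss] <- mode[miss[, 1]]
        se <- as(gd, "SummarizedExperiment")
        SummarizedExperiment::assay(se, "calls") <- m
        gd <- methods::new("GenotypeData", se)
    }
    gd
}
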