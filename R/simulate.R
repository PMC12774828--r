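#' Hierarchical population design for the genotype simulator
#'
#' Parameters of a two-level Balding-Nichols drift model: per marker an
#' ancestral allele frequency p is drawn uniformly from
#' \code{ancestralMafRange}; each superpopulation frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = \code{fstSuper}; each subpopulation
#' frequency is drawn the same way around its superpopulation frequency with
#' F = \code{fstSub}; genotypes are Binomial(2, subpopulation frequency).
#'
#' Defaults give a desk-scale dataset with clear two-tier structure
#' (3 superpopulations x 3 subpopulations x 15 samples, 1,000 markers,
#' F_super = 0.25, F_sub = 0.03).
#'
#' @param nSuper,nSubPerSuper,nPerSub,nMarkers design counts (all >= 1)
#' @param fstSuper,fstSub drift parameters in (0, 1)
#' @param ancestralMafRange length-2 numeric, 0 < low <= high <= 0.5
#' @param seed integer seed governing all randomness of the simulation
#' @return a classed list of validated parameters
#' @export
populationDesign <- function(nSuper = 3, nSubPerSuper = 3, nPerSub = 15,
                             nMarkers = 1000, fstSuper = 0.25, fstSub = 0.03,
                             ancestralMafRange = c(0.1, 0.5), seed = 1L) {
    stopifnot(nSuper >= 1, nSubPerSuper >= 1, nPerSub >= 1, nMarkers >= 1,
              fstSuper > 0, fstSuper < 1, fstSub > 0, fstSub < 1,
              length(ancestralMafRange) == 2,
              ancestralMafRange[1] > 0,
              ancestralMafRange[1] <= ancestralMafRange[2],
              ancestralMafRange[2] <= 0.5)
    structure(list(nSuper = as.integer(nSuper),
                   nSubPerSuper = as.integer(nSubPerSuper),
                   nPerSub = as.integer(nPerSub),
                   nMarkers = as.integer(nMarkers),
                   fstSuper = fstSuper, fstSub = fstSub,
                   ancestralMafRange = ancestralMafRange,
                   seed = as.integer(seed)),
              class = "PopulationDesign")
}

.betaDrift <- function(p, fst) {
    ## Balding-Nichols: Beta with mean p, variance fst * p * (1 - p)
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    stats::rbeta(length(p), a, b)
}

#' Simulate genotypes under a two-level hierarchical drift model
#'
#' @param design a \code{\link{populationDesign}}
#' @return list with elements \code{genotypes} (a labeled
#'   \linkS4class{GenotypeData} with no missing calls), \code{labels}
#'   (data.frame of the generating sub/superpopulation per sample) and
#'   \code{frequencies} (list with the ancestral, superpopulation and
#'   subpopulation allele frequencies used).
#' @examples
#' sim <- simulateHierarchical(populationDesign(2, 2, 5, nMarkers = 50))
#' sim$genotypes
#' @export
simulateHierarchical <- function(design) {
    stopifnot(inherits(design, "PopulationDesign"))
    set.seed(design$seed)
    d <- design$nMarkers
    p0 <- stats::runif(d, design$ancestralMafRange[1],
                       design$ancestralMafRange[2])
    nSub <- design$nSuper * design$nSubPerSuper
    pSuper <- matrix(0, design$nSuper, d)
    for (s in seq_len(design$nSuper))
        pSuper[s, ] <- .betaDrift(p0, design$fstSuper)
    pSub <- matrix(0, nSub, d)
    subSuper <- rep(seq_len(design$nSuper), each = design$nSubPerSuper)
    for (k in seq_len(nSub))
        pSub[k, ] <- .betaDrift(pSuper[subSuper[k], ], design$fstSub)
    n <- nSub * design$nPerSub
    sampleSub <- rep(seq_len(nSub), each = design$nPerSub)
    calls <- matrix(stats::rbinom(n * d, 2L, pSub[sampleSub, ]), nrow = n)
    subNames <- sprintf("SUB%d_%d", subSuper, rep(seq_len(design$nSubPerSuper),
                                                  design$nSuper))
    superNames <- sprintf("SUPER%d", subSuper)
    ids <- sprintf("ind%04d", seq_len(n))
    labels <- data.frame(sample_id = ids,
                         subpopulation = subNames[sampleSub],
                         superpopulation = superNames[sampleSub])
    gd <- GenotypeData(calls,
                       markers = data.frame(id = sprintf("snp%05d", seq_len(d)),
                                            chromosome = "1",
                                            position = seq_len(d) * 1000L),
                       sampleIds = ids, labels = labels)
    list(genotypes = gd, labels = labels,
         frequencies = list(ancestral = p0, superpop = pSuper, subpop = pSub))
}

#' SNP-chip masking design
#'
#' Parameters of the chip-missingness experiment: a fraction of samples is
#' set aside and split evenly into groups; each group receives its own random
#' marker subset (a fraction of all markers) that is set to missing for every
#' member of the group, mimicking genotyping on a smaller shared SNP chip.
#'
#' @param fractionMaskedSamples fraction of samples to mask (default 0.2)
#' @param nGroups number of chip groups (default 4)
#' @param fractionMaskedMarkers fraction of markers masked per group (0.2)
#' @param fill "mode" to fill the masked cells with the per-marker mode of the
#'   untouched samples, "none" to leave them as -1
#' @param seed integer seed
#' @return a classed parameter list
#' @export
chipMaskDesign <- function(fractionMaskedSamples = 0.2, nGroups = 4,
                           fractionMaskedMarkers = 0.2,
                           fill = c("mode", "none"), seed = 1L) {
    stopifnot(fractionMaskedSamples > 0, fractionMaskedSamples < 1,
              fractionMaskedMarkers > 0, fractionMaskedMarkers < 1,
              nGroups >= 1)
    structure(list(fractionMaskedSamples = fractionMaskedSamples,
                   nGroups = as.integer(nGroups),
                   fractionMaskedMarkers = fractionMaskedMarkers,
                   fill = match.arg(fill), seed = as.integer(seed)),
              class = "ChipMaskDesign")
}

#' Apply the SNP-chip masking experiment to a complete genotype matrix
#'
#' @param gd a complete (no missing calls) \linkS4class{GenotypeData}
#' @param design a \code{\link{chipMaskDesign}}
#' @return list with \code{genotypes} (masked/filled GenotypeData),
#'   \code{group} (integer per sample: 0 = untouched reference, 1..nGroups =
#'   chip group) and \code{maskedMarkers} (list of masked marker index vectors
#'   per group).
#' @export
applyChipMasking <- function(gd, design = chipMaskDesign()) {
    stopifnot(inherits(design, "ChipMaskDesign"))
    calls <- genotypeCalls(gd)
    if (any(calls == -1L))
        stop("chip masking requires a complete genotype matrix")
    n <- nrow(calls); d <- ncol(calls)
    set.seed(design$seed)
    nMasked <- round(design$fractionMaskedSamples * n)
    perGroup <- nMasked %/% design$nGroups
    if (perGroup < 1)
        stop("chip groups would be empty; increase sample count")
    maskedIds <- sample.int(n, perGroup * design$nGroups)
    group <- integer(n)
    group[maskedIds] <- rep(seq_len(design$nGroups), each = perGroup)
    nMark <- round(design$fractionMaskedMarkers * d)
    maskedMarkers <- lapply(seq_len(design$nGroups),
                            function(g) sort(sample.int(d, nMark)))
    for (g in seq_len(design$nGroups))
        calls[group == g, maskedMarkers[[g]]] <- -1L
    out <- GenotypeData(calls, markers = markerInfo(gd),
                        sampleIds = sampleIds(gd))
    lab <- data.frame(sample_id = sampleIds(gd),
                      subpopulation = subpopulation(gd),
                      superpopulation = superpopulation(gd))
    if (any(!is.na(lab$subpopulation)))
        out <- setLabels(out, lab[!is.na(lab$subpopulation), ])
    if (design$fill == "mode")
        out <- modeImpute(out, gd[, group == 0L])
    list(genotypes = out, group = group, maskedMarkers = maskedMarkers)
}

#' Split samples into training and validation sets
#'
#' @param gd a \linkS4class{GenotypeData}
#' @param valFraction validation fraction in (0, 1); default 0.2
#' @param stratify stratify by subpopulation label (proportional allocation,
#'   largest-remainder rounding); subpopulations with a single sample go to
#'   the training set.
#' @param seed integer seed
#' @return list with character vectors \code{train} and \code{val} of sample
#'   ids (disjoint, exhaustive)
#' @export
splitTrainVal <- function(gd, valFraction = 0.2, stratify = TRUE, seed = 1L) {
    stopifnot(valFraction > 0, valFraction < 1)
    ids <- sampleIds(gd)
    set.seed(seed)
    if (!stratify || all(is.na(subpopulation(gd)))) {
        nVal <- round(valFraction * length(ids))
        val <- sample(ids, nVal)
        return(list(train = setdiff(ids, val), val = sort(val)))
    }
    sub <- subpopulation(gd)
    sub[is.na(sub)] <- ".unlabeled"
    val <- character(0)
    for (s in unique(sub)) {
        members <- ids[sub == s]
        if (length(members) < 2) {
            message("subpopulation ", s, " has one sample; kept in training")
            next
        }
        nVal <- round(valFraction * length(members))
        if (nVal >= 1)
            val <- c(val, sample(members, nVal))
    }
    list(train = setdiff(ids, val), val = sort(val))
}
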