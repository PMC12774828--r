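#' Run the full embedding pipeline from a configuration list
#'
#' Stages: simulate (optional) or load genotypes -> preprocess (sex-chromosome
#' and MAF filters, mode imputation) -> train/validation split -> contrastive
#' training -> spherical embedding + Equal Earth projection -> evaluation.
#' All outputs (config copy, checkpoint, embedding TSV, history TSV, metric
#' JSON) are written to \code{outDir}. Reruns with the same configuration and
#' seed reproduce the metric numbers.
#'
#' @param config nested named list (or path to a YAML file) with optional
#'   sections \code{data} (either \code{simulate}: arguments for
#'   \code{\link{populationDesign}}, or \code{plink}/\code{eigenstrat} paths
#'   plus \code{labels}), \code{preprocess} (\code{sexChromosomes},
#'   \code{mafThreshold}), \code{split} (\code{valFraction},
#'   \code{stratify}), \code{augment}, \code{encoder}, \code{loss}
#'   (\code{kind}, \code{negatives}, \code{nNeg}, \code{margin}),
#'   \code{projection} (\code{rotation}: yaw/pitch/roll), and a global
#'   \code{seed}
#' @param outDir output directory (created if needed)
#' @return invisibly, a list with the trained encoder, embeddings, split and
#'   the metric report
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed %||% 1L
    cfgData <- config$data %||% list(simulate = list())

    ## ---- load or simulate -------------------------------------------------
    if (!is.null(cfgData$simulate)) {
        design <- do.call(populationDesign,
                          utils::modifyList(as.list(cfgData$simulate),
                                            list(seed = seed)))
        sim <- simulateHierarchical(design)
        gd <- sim$genotypes
    } else if (!is.null(cfgData$plink)) {
        gd <- readPlink(cfgData$plink)
        if (is.null(cfgData$labels) && !is.null(config$evaluate))
            stop("evaluation requested but no label file configured")
        if (!is.null(cfgData$labels))
            gd <- setLabels(gd, readLabels(cfgData$labels))
    } else if (!is.null(cfgData$eigenstrat)) {
        p <- cfgData$eigenstrat
        gd <- readEigenstrat(paste0(p, ".geno"), paste0(p, ".snp"),
                             paste0(p, ".ind"))
        if (!is.null(cfgData$labels))
            gd <- setLabels(gd, readLabels(cfgData$labels))
    } else stop("config$data must give 'simulate', 'plink' or 'eigenstrat'")

    ## ---- preprocess -------------------------------------------------------
    pp <- config$preprocess %||% list()
    if (!is.null(pp$sexChromosomes))
        gd <- filterSexChromosomes(gd, pp$sexChromosomes)
    if (!is.null(pp$mafThreshold))
        gd <- mafFilter(gd, pp$mafThreshold)
    if (any(genotypeCalls(gd) == -1L))
        gd <- modeImpute(gd)

    ## ---- split ------------------------------------------------------------
    sp <- config$split %||% list()
    split <- splitTrainVal(gd, valFraction = sp$valFraction %||% 0.2,
                           stratify = sp$stratify %||% TRUE, seed = seed)
    gdTrain <- gd[, split$train]
    gdVal <- gd[, split$val]

    ## ---- train ------------------------------------------------------------
    augCfg <- do.call(augmentationConfig, config$augment %||% list())
    encArgs <- config$encoder %||% list()
    encArgs$nMarkers <- nrow(gd)
    encArgs$seed <- seed
    encCfg <- do.call(encoderConfig, encArgs)
    loss <- config$loss %||% list()
    fit <- trainEncoder(gdTrain, encCfg,
                        lossKind = loss$kind %||% "centroid",
                        augment = augCfg,
                        negatives = loss$negatives %||% "all",
                        nNeg = loss$nNeg, margin = loss$margin %||% 0.2)

    ## ---- embed + project --------------------------------------------------
    rotCfg <- (config$projection %||% list())$rotation %||% list()
    rot <- eulerRotation(rotCfg$yaw %||% 0, rotCfg$pitch %||% 0,
                         rotCfg$roll %||% 0)
    esTrain <- projectEmbedding(embedGenotypes(fit$encoder, gdTrain), rot)
    esVal <- projectEmbedding(embedGenotypes(fit$encoder, gdVal), rot)

    ## ---- evaluate ---------------------------------------------------------
    report <- metricReport(esTrain, subpopulation(gdTrain),
                           superpopulation(gdTrain),
                           valEmbedding = esVal,
                           valSubLabels = subpopulation(gdVal))

    ## ---- outputs ----------------------------------------------------------
    config$seed <- seed
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))
    digest <- unname(tools::md5sum(file.path(outDir, "config.yaml")))
    saveCheckpoint(fit$encoder, file.path(outDir, "encoder.checkpoint"))
    hist <- cbind(fit$history, configDigest = digest)
    utils::write.table(hist, file.path(outDir, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    labs <- data.frame(sample_id = sampleIds(gd),
                       subpopulation = subpopulation(gd),
                       superpopulation = superpopulation(gd))
    writeEmbedding(esTrain, file.path(outDir, "embedding_train.tsv"), labs)
    writeEmbedding(esVal, file.path(outDir, "embedding_val.tsv"), labs)
    jsonlite::write_json(c(report[c("L", "G", "GE")],
                           list(configDigest = digest)),
                         file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(encoder = fit$encoder, history = fit$history,
                   genotypes = gd, split = split,
                   trainEmbedding = esTrain, valEmbedding = esVal,
                   report = report))
}

#' Run the SNP-chip masking robustness experiment
#'
#' Starting from a complete dataset, the encoder is trained on the dense 80%
#' reference; the held-out 20% are split into chip groups whose genotypes are
#' masked on a shared per-group marker subset (and optionally mode-filled).
#' The generalization score GE is reported for the validation samples both
#' unmasked and chip-masked, along with a 3NN diagnostic asking whether the
#' masked validation samples cluster by chip group (accuracy near 1/nGroups
#' means they do not).
#'
#' @param gd complete labeled \linkS4class{GenotypeData} (or \code{NULL} to
#'   simulate from \code{design})
#' @param design a \code{\link{populationDesign}} used when \code{gd} is NULL
#' @param chip a \code{\link{chipMaskDesign}}
#' @param encoder an \code{\link{encoderConfig}}; \code{NULL} uses defaults
#'   with \code{epochs}
#' @param epochs training epochs when \code{encoder} is NULL
#' @param augment an \code{\link{augmentationConfig}}
#' @param lossKind contrastive loss to train with
#' @param seed global seed
#' @return list with \code{geUnmasked}, \code{geMasked}, \code{geDelta},
#'   \code{groupAccuracy} (3NN chip-group accuracy among masked validation
#'   samples), \code{chanceLevel} (1/nGroups), plus the fitted encoder and
#'   embeddings
#' @export
runMaskedChipExperiment <- function(gd = NULL, design = populationDesign(),
                                    chip = chipMaskDesign(),
                                    encoder = NULL, epochs = 300L,
                                    augment = augmentationConfig(),
                                    lossKind = "centroid", seed = 1L) {
    if (is.null(gd)) {
        design$seed <- as.integer(seed)
        gd <- simulateHierarchical(design)$genotypes
    }
    if (any(genotypeCalls(gd) == -1L))
        stop("chip experiment requires a complete dataset")
    ids <- sampleIds(gd)
    chip$seed <- as.integer(seed)
    masked <- applyChipMasking(gd, chip)
    trainIds <- ids[masked$group == 0L]
    valIds <- ids[masked$group > 0L]
    gdTrain <- gd[, trainIds]
    if (is.null(encoder))
        encoder <- encoderConfig(nrow(gd), epochs = epochs, seed = seed)
    fit <- trainEncoder(gdTrain, encoder, lossKind = lossKind,
                        augment = augment)
    esTrain <- embedGenotypes(fit$encoder, gdTrain)
    esValClean <- embedGenotypes(fit$encoder, gd[, valIds])
    esValMasked <- embedGenotypes(fit$encoder, masked$genotypes[, valIds])
    geU <- generalizationScore(esTrain, subpopulation(gdTrain),
                               esValClean, subpopulation(gd)[valIds])
    geM <- generalizationScore(esTrain, subpopulation(gdTrain),
                               esValMasked, subpopulation(gd)[valIds])
    grp <- masked$group[masked$group > 0L]
    grpAcc <- localScore(esValMasked, as.character(grp))
    list(geUnmasked = geU, geMasked = geM, geDelta = geU - geM,
         groupAccuracy = grpAcc, chanceLevel = 1 / chip$nGroups,
         encoder = fit$encoder, history = fit$history,
         trainEmbedding = esTrain, valEmbeddingClean = esValClean,
         valEmbeddingMasked = esValMasked, group = masked$group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
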