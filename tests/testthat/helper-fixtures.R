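## Shared fixtures and independent brute-force oracles for the test suite.

## small deterministic genotype container
makeGenotypeFixture <- function(nSamples = 6, nMarkers = 10, seed = 42,
                                missingFrac = 0) {
    set.seed(seed)
    calls <- matrix(sample(0:2, nSamples * nMarkers, replace = TRUE),
                    nrow = nSamples)
    if (missingFrac > 0)
        calls[sample(length(calls), round(missingFrac * length(calls)))] <- -1L
    GenotypeData(calls,
                 markers = data.frame(id = sprintf("m%d", seq_len(nMarkers)),
                                      chromosome = rep(c("1", "2"),
                                                       length.out = nMarkers),
                                      position = seq_len(nMarkers) * 100L),
                 sampleIds = sprintf("s%d", seq_len(nSamples)))
}

randomUnitVectors <- function(n, d = 3, seed = 1) {
    set.seed(seed)
    z <- matrix(rnorm(n * d), n, d)
    z / sqrt(rowSums(z^2))
}

## brute-force KNN: double loop, no shared code with the package internals
bruteKnn <- function(reference, refLabels, query, k, excludeSelf = FALSE) {
    sapply(seq_len(nrow(query)), function(i) {
        d <- apply(reference, 1, function(r) sqrt(sum((query[i, ] - r)^2)))
        if (excludeSelf) d[i] <- Inf
        nb <- order(d)[seq_len(k)]
        tab <- table(refLabels[nb])
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1) {
            md <- sapply(top, function(lb) mean(d[nb][refLabels[nb] == lb]))
            top <- top[order(md, top)]
        }
        top[1]
    })
}

## brute-force neighbor overlap: double loop over samples and k
bruteOverlap <- function(calls, coords, kValues) {
    n <- nrow(calls)
    sapply(kValues, function(k) {
        mean(sapply(seq_len(n), function(i) {
            dg <- sapply(seq_len(n), function(j)
                if (i == j) Inf else sum(abs(calls[i, ] - calls[j, ])))
            de <- sapply(seq_len(n), function(j)
                if (i == j) Inf else sqrt(sum((coords[i, ] - coords[j, ])^2)))
            length(intersect(order(dg)[1:k], order(de)[1:k])) / k
        }))
    })
}

## brute-force rank RMSE
bruteRankRmse <- function(calls, coords, nValues) {
    N <- nrow(calls)
    sapply(nValues, function(nv) {
        sqrt(mean(sapply(seq_len(N), function(i) {
            dg <- sapply(seq_len(N), function(j)
                if (i == j) Inf else sum(abs(calls[i, ] - calls[j, ])))
            de <- sapply(seq_len(N), function(j)
                if (i == j) Inf else sqrt(sum((coords[i, ] - coords[j, ])^2)))
            jstar <- order(dg)[nv]
            re <- which(order(de) == jstar)
            (nv - re)^2
        })))
    })
}

## cached desk-scale training run shared by the expensive tests
.popsphereTestCache <- new.env(parent = emptyenv())

recoveryRun <- function() {
    if (!is.null(.popsphereTestCache$recovery))
        return(.popsphereTestCache$recovery)
    sim <- simulateHierarchical(populationDesign())
    gd <- sim$genotypes
    sp <- splitTrainVal(gd, 0.2, stratify = TRUE, seed = 1)
    gdTrain <- gd[, sp$train]
    gdVal <- gd[, sp$val]
    ## desk-scale training parameters (see the methods vignette): batch 32,
    ## augmentation bounds 0.5 for ~10^3-marker data, 300 epochs
    fit <- trainEncoder(gdTrain,
                        encoderConfig(nrow(gd), epochs = 300L,
                                      batchSize = 32L, seed = 1),
                        augment = augmentationConfig(pflipMax = 0.5,
                                                     pmaskMax = 0.5))
    esTrain <- embedGenotypes(fit$encoder, gdTrain)
    esVal <- embedGenotypes(fit$encoder, gdVal)
    .popsphereTestCache$recovery <-
        list(gd = gd, split = sp, gdTrain = gdTrain, gdVal = gdVal,
             fit = fit, esTrain = esTrain, esVal = esVal)
    .popsphereTestCache$recovery
}
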