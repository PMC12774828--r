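#' Encoder configuration
#'
#' Architecture and training hyperparameters of the genotype encoder:
#' 2 convolutional layers (5 filters, kernel 3, stride 1, SiLU) over the
#' marker axis of the one-hot input, flatten, 3 dense layers of 256 units
#' with batch normalization and SiLU, and a final dense layer with 3 units
#' followed by L2 normalization onto the unit sphere.
#'
#' @param nMarkers number of markers D the encoder is built for
#' @param convFilters,kernelSize,denseUnits,denseLayers,embeddingDim
#'   architecture sizes (defaults match the published model)
#' @param epochs training epochs (published runs use 5000; desk-scale
#'   analyses use far fewer)
#' @param learningRate initial Adam learning rate
#' @param adamBeta1,adamBeta2 Adam moment decay rates
#' @param lrDecay,lrDecayEvery learning-rate decay factor and schedule: the
#'   rate is multiplied by \code{lrDecay} every \code{lrDecayEvery} schedule
#'   units
#' @param lrDecayUnit schedule unit, "epoch" (default) or "step"; the
#'   published description ("every 10 iterations") is ambiguous, and a
#'   per-step 0.99 decay underflows over long runs, so per-epoch is the
#'   default
#' @param convBatchNorm also apply batch normalization to the convolutional
#'   layers (per filter, over batch and marker positions); the reference
#'   description places batch normalization on the dense layers only, so
#'   this defaults to FALSE
#' @param batchSize minibatch size (default 64)
#' @param seed integer seed controlling initialization and training
#' @return a classed parameter list
#' @export
encoderConfig <- function(nMarkers, convFilters = 5L, kernelSize = 3L,
                          denseUnits = 256L, denseLayers = 3L,
                          embeddingDim = 3L, epochs = 5000L,
                          learningRate = 0.001, adamBeta1 = 0.9,
                          adamBeta2 = 0.999, lrDecay = 0.99,
                          lrDecayEvery = 10L,
                          lrDecayUnit = c("epoch", "step"),
                          convBatchNorm = FALSE,
                          batchSize = 64L, seed = 1L) {
    stopifnot(nMarkers >= kernelSize, convFilters >= 1, denseUnits >= 1,
              embeddingDim >= 2, epochs >= 1, learningRate > 0,
              batchSize >= 2)
    structure(list(nMarkers = as.integer(nMarkers),
                   convFilters = as.integer(convFilters),
                   kernelSize = as.integer(kernelSize),
                   denseUnits = as.integer(denseUnits),
                   denseLayers = as.integer(denseLayers),
                   embeddingDim = as.integer(embeddingDim),
                   epochs = as.integer(epochs),
                   learningRate = learningRate,
                   adamBeta1 = adamBeta1, adamBeta2 = adamBeta2,
                   lrDecay = lrDecay, lrDecayEvery = as.integer(lrDecayEvery),
                   lrDecayUnit = match.arg(lrDecayUnit),
                   convBatchNorm = isTRUE(convBatchNorm),
                   batchSize = as.integer(batchSize),
                   seed = as.integer(seed)),
              class = "EncoderConfig")
}

#' Build an untrained genotype encoder
#'
#' Initializes the network weights (Kaiming-uniform, deterministic given
#' \code{config$seed}) for the architecture described in
#' \code{\link{encoderConfig}}.
#'
#' @param config an \code{\link{encoderConfig}}
#' @param markerIds character vector of marker ids the encoder is tied to
#'   (checked when fine-tuning from a checkpoint); defaults to generated ids
#' @return a \linkS4class{GenotypeEncoder}
#' @export
buildEncoder <- function(config, markerIds = NULL) {
    stopifnot(inherits(config, "EncoderConfig"))
    if (is.null(markerIds))
        markerIds <- sprintf("snp%d", seq_len(config$nMarkers))
    stopifnot(length(markerIds) == config$nMarkers)
    set.seed(config$seed)
    D <- config$nMarkers; FLT <- config$convFilters
    U <- config$denseUnits; E <- config$embeddingDim
    p <- list()
    for (o in 1:3) p[[paste0("conv1.K", o)]] <- .initMat(4L * 3L, FLT)[1:4, ,
                                                                   drop = FALSE]
    p$conv1.b <- numeric(FLT)
    for (o in 1:3) p[[paste0("conv2.K", o)]] <- .initMat(FLT * 3L, FLT)[1:FLT, ,
                                                                   drop = FALSE]
    p$conv2.b <- numeric(FLT)
    dims <- c(D * FLT, rep(U, config$denseLayers))
    for (l in seq_len(config$denseLayers)) {
        p[[paste0("dense", l, ".W")]] <- .initMat(dims[l], U)
        p[[paste0("dense", l, ".b")]] <- numeric(U)
        p[[paste0("bn", l, ".gamma")]] <- rep(1, U)
        p[[paste0("bn", l, ".beta")]] <- numeric(U)
    }
    p$out.W <- .initMat(U, E)
    p$out.b <- numeric(E)
    if (config$convBatchNorm) {
        for (l in 1:2) {
            p[[paste0("bnc", l, ".gamma")]] <- rep(1, FLT)
            p[[paste0("bnc", l, ".beta")]] <- numeric(FLT)
        }
    }
    buffers <- list()
    for (l in seq_len(config$denseLayers)) {
        buffers[[paste0("bn", l, ".mean")]] <- numeric(U)
        buffers[[paste0("bn", l, ".var")]] <- rep(1, U)
    }
    if (config$convBatchNorm) {
        for (l in 1:2) {
            buffers[[paste0("bnc", l, ".mean")]] <- numeric(FLT)
            buffers[[paste0("bnc", l, ".var")]] <- rep(1, FLT)
        }
    }
    methods::new("GenotypeEncoder",
                 params = list(trainable = p, buffers = buffers),
                 config = unclass(config), markerIds = as.character(markerIds))
}

## Full forward pass. x: (B, D, 4) one-hot array. Returns embeddings and,
## if keepCache, everything the backward pass needs. In training mode batch
## statistics are used (and running statistics updated in the returned
## buffers); in inference mode the running statistics are used.
.encForward <- function(enc, x, training = FALSE, keepCache = FALSE) {
    p <- enc@params$trainable
    buf <- enc@params$buffers
    cfg <- enc@config
    cache <- list()
    convBN <- isTRUE(cfg$convBatchNorm)
    ## per-filter batch normalization of a (B, D, F) conv output
    bnConv <- function(a, l) {
        d <- dim(a)
        am <- a; dim(am) <- c(d[1] * d[2], d[3])
        bn <- .bnForward(am, p[[paste0("bnc", l, ".gamma")]],
                         p[[paste0("bnc", l, ".beta")]],
                         buf[[paste0("bnc", l, ".mean")]],
                         buf[[paste0("bnc", l, ".var")]], training)
        buf[[paste0("bnc", l, ".mean")]] <<- bn$runMean
        buf[[paste0("bnc", l, ".var")]] <<- bn$runVar
        y <- bn$y; dim(y) <- d
        if (keepCache) cache[[paste0("bnc", l)]] <<- bn
        y
    }
    k1 <- list(p$conv1.K1, p$conv1.K2, p$conv1.K3)
    c1 <- .convForward(x, k1, p$conv1.b, cache = keepCache)
    s1 <- if (convBN) bnConv(c1$y, 1) else c1$y
    h1 <- .silu(s1)
    k2 <- list(p$conv2.K1, p$conv2.K2, p$conv2.K3)
    c2 <- .convForward(h1, k2, p$conv2.b, cache = keepCache)
    s2 <- if (convBN) bnConv(c2$y, 2) else c2$y
    h2 <- .silu(s2)
    B <- dim(x)[1]
    flat <- h2; dim(flat) <- c(B, cfg$nMarkers * cfg$convFilters)
    if (keepCache) {
        cache$s1 <- s1; cache$xc1 <- c1$xc
        cache$s2 <- s2; cache$xc2 <- c2$xc
        cache$B <- B
    }
    h <- flat
    for (l in seq_len(cfg$denseLayers)) {
        W <- p[[paste0("dense", l, ".W")]]
        a <- sweep(h %*% W, 2, p[[paste0("dense", l, ".b")]], `+`)
        bn <- .bnForward(a, p[[paste0("bn", l, ".gamma")]],
                         p[[paste0("bn", l, ".beta")]],
                         buf[[paste0("bn", l, ".mean")]],
                         buf[[paste0("bn", l, ".var")]], training)
        buf[[paste0("bn", l, ".mean")]] <- bn$runMean
        buf[[paste0("bn", l, ".var")]] <- bn$runVar
        hNew <- .silu(bn$y)
        if (keepCache) {
            cache[[paste0("hIn", l)]] <- h
            cache[[paste0("a", l + 2)]] <- a
            cache[[paste0("bn", l)]] <- bn
        }
        h <- hNew
    }
    aOut <- sweep(h %*% p$out.W, 2, p$out.b, `+`)
    l2 <- .l2Forward(aOut)
    if (keepCache) {
        cache$hLast <- h
        cache$aOut <- aOut
        cache$l2 <- l2
    }
    list(z = l2$y, cache = if (keepCache) cache else NULL, buffers = buf)
}

## Backward pass: dZ is the gradient of the loss w.r.t. the unit embeddings.
.encBackward <- function(enc, cache, dZ) {
    p <- enc@params$trainable
    cfg <- enc@config
    g <- list()
    dAOut <- .l2Backward(dZ, cache$l2)
    g$out.W <- crossprod(cache$hLast, dAOut)
    g$out.b <- colSums(dAOut)
    dH <- tcrossprod(dAOut, p$out.W)
    for (l in rev(seq_len(cfg$denseLayers))) {
        bn <- cache[[paste0("bn", l)]]
        dBnY <- dH * .siluGrad(bn$y)
        bb <- .bnBackward(dBnY, bn, p[[paste0("bn", l, ".gamma")]])
        g[[paste0("bn", l, ".gamma")]] <- bb$dGamma
        g[[paste0("bn", l, ".beta")]] <- bb$dBeta
        dA <- bb$dX
        g[[paste0("dense", l, ".W")]] <- crossprod(cache[[paste0("hIn", l)]], dA)
        g[[paste0("dense", l, ".b")]] <- colSums(dA)
        dH <- tcrossprod(dA, p[[paste0("dense", l, ".W")]])
    }
    B <- cache$B
    convBN <- isTRUE(cfg$convBatchNorm)
    bnConvBack <- function(dS, l) {
        d <- dim(dS)
        dm <- dS; dim(dm) <- c(d[1] * d[2], d[3])
        bb <- .bnBackward(dm, cache[[paste0("bnc", l)]],
                          p[[paste0("bnc", l, ".gamma")]])
        g[[paste0("bnc", l, ".gamma")]] <<- bb$dGamma
        g[[paste0("bnc", l, ".beta")]] <<- bb$dBeta
        dA <- bb$dX; dim(dA) <- d
        dA
    }
    dH2 <- dH; dim(dH2) <- c(B, cfg$nMarkers, cfg$convFilters)
    dA2 <- dH2 * .siluGrad(cache$s2)
    if (convBN) dA2 <- bnConvBack(dA2, 2)
    k2 <- list(p$conv2.K1, p$conv2.K2, p$conv2.K3)
    cb2 <- .convBackward(cache$xc2, k2, dA2)
    for (o in 1:3) g[[paste0("conv2.K", o)]] <- cb2$dK[[o]]
    g$conv2.b <- cb2$dBias
    dA1 <- cb2$dX * .siluGrad(cache$s1)
    if (convBN) dA1 <- bnConvBack(dA1, 1)
    k1 <- list(p$conv1.K1, p$conv1.K2, p$conv1.K3)
    cb1 <- .convBackward(cache$xc1, k1, dA1, needDX = FALSE)
    for (o in 1:3) g[[paste0("conv1.K", o)]] <- cb1$dK[[o]]
    g$conv1.b <- cb1$dBias
    g
}

#' Embed one-hot genotype batches on the unit sphere
#'
#' @param enc a \linkS4class{GenotypeEncoder}
#' @param x one-hot input: a (batch, markers, 4) array, a single markers x 4
#'   matrix, or a \linkS4class{GenotypeData} (encoded without augmentation,
#'   missing calls routed to the missing channel)
#' @param training use batch statistics in the normalization layers (only
#'   sensible inside the training loop); default FALSE = inference mode with
#'   running statistics, deterministic
#' @return matrix of unit-norm embeddings (samples x embeddingDim), or a
#'   \linkS4class{SphereEmbedding} when \code{x} is GenotypeData
#' @export
embedGenotypes <- function(enc, x, training = FALSE) {
    asEmbedding <- FALSE
    ids <- NULL
    if (methods::is(x, "GenotypeData")) {
        ids <- sampleIds(x)
        x <- oneHotEncode(genotypeCalls(x))
        asEmbedding <- TRUE
    }
    if (is.matrix(x))
        x <- array(x, dim = c(1L, nrow(x), ncol(x)))
    d <- dim(x)
    if (length(d) != 3 || d[3] != 4L)
        stop("input must have 4 one-hot channels")
    if (d[2] != enc@config$nMarkers)
        stop("input has ", d[2], " markers but encoder expects ",
             enc@config$nMarkers)
    z <- .encForward(enc, x, training = training)$z
    if (asEmbedding) SphereEmbedding(z, sampleIds = ids) else z
}

#' Train a genotype encoder with a contrastive loss
#'
#' Each epoch shuffles the training samples into minibatches; for every batch
#' two independently augmented one-hot views of each sample are built (rates
#' drawn per sample per batch), both views are embedded, and the batch loss
#' (view 1 = anchors and negatives, view 2 = positives) is minimized with
#' Adam. Fully reproducible given \code{config$seed}.
#'
#' @param gd training \linkS4class{GenotypeData}
#' @param config an \code{\link{encoderConfig}} (its \code{nMarkers} must
#'   match \code{gd}); \code{NULL} builds a default for this data
#' @param lossKind "centroid", "npair" or "triplet"
#' @param augment an \code{\link{augmentationConfig}}
#' @param negatives "all" or "inverse_distance"
#' @param nNeg negatives per anchor when sampling by inverse distance
#' @param margin triplet margin
#' @param encoder optionally, an existing \linkS4class{GenotypeEncoder} to
#'   fine-tune (marker ids must match \code{gd})
#' @param verbose print the per-epoch mean loss every 50 epochs
#' @return list with \code{encoder} (trained \linkS4class{GenotypeEncoder})
#'   and \code{history} (data.frame: epoch, loss, learningRate)
#' @export
trainEncoder <- function(gd, config = NULL, lossKind = c("centroid", "npair",
                         "triplet"), augment = augmentationConfig(),
                         negatives = "all", nNeg = NULL, margin = 0.2,
                         encoder = NULL, verbose = FALSE) {
    lossKind <- match.arg(lossKind)
    calls <- genotypeCalls(gd)
    n <- nrow(calls)
    if (n < 2) stop("need at least 2 training samples")
    if (is.null(config))
        config <- encoderConfig(ncol(calls))
    stopifnot(config$nMarkers == ncol(calls))
    if (is.null(encoder))
        enc <- buildEncoder(config, markerIds = markerInfo(gd)$id)
    else {
        enc <- encoder
        if (!identical(enc@markerIds, markerInfo(gd)$id))
            stop("encoder marker set does not match the training data")
        enc@config <- unclass(config)
    }
    set.seed(config$seed + 1L)           # training stream, distinct from init
    ## private weight buffers: the Adam update mutates them in place
    enc@params$trainable <- lapply(enc@params$trainable, function(p) p + 0)
    adam <- .adamInit(enc@params$trainable)
    lr <- config$learningRate
    lossTrace <- numeric(config$epochs)
    lrTrace <- numeric(config$epochs)
    negCache <- vector("list", config$batchSize)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = config$batchSize)
        epochLoss <- 0; nBatches <- 0L
        for (s in starts) {
            idx <- ord[s:min(s + config$batchSize - 1L, n)]
            if (length(idx) < 2) next
            rates <- drawRates(length(idx), augment)
            x1 <- augmentView(calls[idx, , drop = FALSE],
                              rates$pflip, rates$pmask)
            rates2 <- drawRates(length(idx), augment)
            x2 <- augmentView(calls[idx, , drop = FALSE],
                              rates2$pflip, rates2$pmask)
            f1 <- .encForward(enc, x1, training = TRUE, keepCache = TRUE)
            enc@params$buffers <- f1$buffers
            f2 <- .encForward(enc, x2, training = TRUE, keepCache = TRUE)
            enc@params$buffers <- f2$buffers
            b <- length(idx)
            negIdx <- if (negatives == "all") {
                negCache[[b]] <- negCache[[b]] %||%
                    lapply(seq_len(b), function(i) seq_len(b)[-i])
                negCache[[b]]
            } else lapply(seq_len(b), function(i)
                selectNegatives(f1$z, i, mode = negatives,
                                nNeg = min(nNeg, b - 1L)))
            lb <- switch(lossKind,
                centroid = .centroidBatch(f1$z, f2$z, negIdx, grad = TRUE),
                npair = .npairBatch(f1$z, f2$z, negIdx, grad = TRUE),
                triplet = .tripletBatch(f1$z, f2$z, negIdx, margin,
                                        grad = TRUE))
            if (!is.finite(lb$loss))
                stop("non-finite loss at epoch ", epoch,
                     "; consider a smaller learning rate")
            if (lb$loss < 1e-12) {
                ## every term is in its best-case configuration: nothing to
                ## correct, and the residual gradient is rounding noise that
                ## Adam would rescale into full-size steps
                step <- step + 1L
                nBatches <- nBatches + 1L
                next
            }
            g1 <- .encBackward(enc, f1$cache, lb$dZ1)
            g2 <- .encBackward(enc, f2$cache, lb$dZ2)
            g <- g1
            for (nm in names(g2)) g[[nm]] <- g[[nm]] + g2[[nm]]
            if (config$lrDecayUnit == "step")
                lr <- config$learningRate *
                    config$lrDecay^(step %/% config$lrDecayEvery)
            upd <- .adamStep(enc@params$trainable, g, adam, lr,
                             config$adamBeta1, config$adamBeta2)
            enc@params$trainable <- upd$params
            adam <- upd$state
            step <- step + 1L
            epochLoss <- epochLoss + lb$loss
            nBatches <- nBatches + 1L
        }
        if (config$lrDecayUnit == "epoch")
            lr <- config$learningRate *
                config$lrDecay^(epoch %/% config$lrDecayEvery)
        lossTrace[epoch] <- epochLoss / max(nBatches, 1L)
        lrTrace[epoch] <- lr
        if (verbose && epoch %% 50 == 0)
            message(sprintf("epoch %d: mean batch loss %.4f (lr %.2g)",
                            epoch, epochLoss / max(nBatches, 1L), lr))
    }
    list(encoder = enc,
         history = data.frame(epoch = seq_len(config$epochs),
                              loss = lossTrace, learningRate = lrTrace))
}

#' Save / load encoder checkpoints
#'
#' The checkpoint is a single file holding the weights, the configuration and
#' the marker ids, so a model can be reloaded and fine-tuned on new data with
#' the same marker set without the original training files.
#'
#' @param enc a \linkS4class{GenotypeEncoder}
#' @param path checkpoint file path
#' @return \code{saveCheckpoint}: \code{path}, invisibly;
#'   \code{loadCheckpoint}: the restored \linkS4class{GenotypeEncoder}.
#' @export
saveCheckpoint <- function(enc, path) {
    saveRDS(list(format = "popsphere-checkpoint-1",
                 params = enc@params, config = enc@config,
                 markerIds = enc@markerIds), path)
    invisible(path)
}

#' @rdname saveCheckpoint
#' @param expectedMarkers optional character vector; if given, loading fails
#'   with a descriptive error when the checkpoint's marker set differs
#' @export
loadCheckpoint <- function(path, expectedMarkers = NULL) {
    obj <- readRDS(path)
    if (!identical(obj$format, "popsphere-checkpoint-1"))
        stop("not a popsphere checkpoint: ", path)
    if (!is.null(expectedMarkers) &&
        !identical(obj$markerIds, as.character(expectedMarkers))) {
        nOnly <- length(setdiff(expectedMarkers, obj$markerIds))
        cOnly <- length(setdiff(obj$markerIds, expectedMarkers))
        stop("marker set mismatch: ", cOnly, " markers only in checkpoint, ",
             nOnly, " only in new data")
    }
    methods::new("GenotypeEncoder", params = obj$params, config = obj$config,
                 markerIds = obj$markerIds)
}

#' @export
setMethod("show", "GenotypeEncoder", function(object) {
    cfg <- object@config
    nPar <- sum(vapply(object@params$trainable, length, numeric(1)))
    cat("GenotypeEncoder:", cfg$nMarkers, "markers ->",
        cfg$embeddingDim, "D unit sphere\n")
    cat("  ", format(nPar, big.mark = ","), "trainable parameters\n")
})
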