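#' Augmentation configuration
#'
#' Maximum flip and mask rates for the stochastic genotype augmentation used
#' to build positive pairs. For each sample, at every training iteration, the
#' actual rates are drawn as pflip ~ U(rateLow, pflipMax) and
#' pmask ~ U(rateLow, pmaskMax).
#'
#' @param pflipMax,pmaskMax maximum per-marker flip / mask probabilities; the
#'   aggressive default 0.99 matches the published training setup.
#' @param rateLow lower bound of the uniform rate draws (default 0.01).
#' @return a classed parameter list
#' @export
augmentationConfig <- function(pflipMax = 0.99, pmaskMax = 0.99,
                               rateLow = 0.01) {
    stopifnot(rateLow >= 0, pflipMax >= rateLow || pflipMax == 0,
              pmaskMax >= rateLow || pmaskMax == 0,
              pflipMax <= 1, pmaskMax <= 1)
    structure(list(pflipMax = pflipMax, pmaskMax = pmaskMax,
                   rateLow = rateLow),
              class = "AugmentationConfig")
}

#' Draw per-sample augmentation rates
#'
#' @param nSamples number of samples in the batch
#' @param config an \code{\link{augmentationConfig}}
#' @return list with numeric vectors \code{pflip} and \code{pmask}. Rates use
#'   the current RNG stream. A zero maximum disables that augmentation
#'   entirely (all rates 0).
#' @export
drawRates <- function(nSamples, config = augmentationConfig()) {
    one <- function(pmax) {
        if (pmax <= 0) rep(0, nSamples)
        else stats::runif(nSamples, min(config$rateLow, pmax), pmax)
    }
    list(pflip = one(config$pflipMax), pmask = one(config$pmaskMax))
}

#' Randomly flip genotype calls by one allele
#'
#' Each non-missing call is flipped independently with probability
#' \code{pflip}. Flips change the allele count by exactly one: 0 -> 1,
#' 2 -> 1, and 1 -> 0 or 1 -> 2 with equal probability. Missing calls (-1)
#' are never flipped.
#'
#' @param calls integer vector or matrix (rows = samples) in \{0,1,2,-1\}
#' @param pflip scalar, or vector with one rate per row of a matrix
#' @return object of the same shape with flips applied
#' @export
flipMarkers <- function(calls, pflip) {
    v <- as.vector(calls)
    p <- if (is.matrix(calls)) rep(pflip, length.out = nrow(calls)) else pflip
    pv <- if (is.matrix(calls)) rep(p, times = ncol(calls)) else p
    doFlip <- stats::runif(length(v)) < pv & v != -1L
    out <- v
    out[doFlip & v != 1L] <- 1L                  # 0 -> 1 and 2 -> 1
    het <- which(doFlip & v == 1L)
    if (length(het)) {                           # 1 -> 0 or 2, equal odds
        out[het] <- 0L
        out[het[stats::runif(length(het)) < 0.5]] <- 2L
    }
    if (is.matrix(calls)) matrix(out, nrow = nrow(calls)) else out
}

#' Randomly mask genotype calls as missing
#'
#' Each call is set to -1 independently with probability \code{pmask}.
#'
#' @inheritParams flipMarkers
#' @param pmask scalar, or one rate per row of a matrix
#' @return object of the same shape with masked calls set to -1
#' @export
maskMarkers <- function(calls, pmask) {
    v <- as.vector(calls)
    p <- if (is.matrix(calls)) rep(pmask, length.out = nrow(calls)) else pmask
    pv <- if (is.matrix(calls)) rep(p, times = ncol(calls)) else p
    v[stats::runif(length(v)) < pv] <- -1L
    if (is.matrix(calls)) matrix(v, nrow = nrow(calls)) else v
}

#' One-hot encode genotype calls
#'
#' Maps each call to one of four channels: 0 -> (1,0,0,0), 1 -> (0,1,0,0),
#' 2 -> (0,0,1,0), missing (-1) -> (0,0,0,1). For a vector input the result
#' is an nMarkers x 4 matrix; for a matrix (samples x markers) a
#' samples x markers x 4 array.
#'
#' @param calls integer vector or matrix in \{0,1,2,-1\}
#' @return one-hot matrix or array
#' @export
oneHotEncode <- function(calls) {
    v <- as.vector(calls)
    if (!all(v %in% c(0L, 1L, 2L, -1L)))
        stop("genotype values must be in {0, 1, 2, -1}")
    channel <- v + 1L
    channel[v == -1L] <- 4L
    if (is.matrix(calls)) {
        out <- array(0, dim = c(nrow(calls), ncol(calls), 4L))
        idx <- cbind(rep(seq_len(nrow(calls)), ncol(calls)),
                     rep(seq_len(ncol(calls)), each = nrow(calls)), channel)
        out[idx] <- 1
    } else {
        out <- matrix(0, nrow = length(v), ncol = 4L)
        out[cbind(seq_along(v), channel)] <- 1
    }
    out
}

#' Invert a one-hot encoding back to genotype calls
#'
#' @param oh an nMarkers x 4 matrix or samples x markers x 4 array as
#'   produced by \code{\link{oneHotEncode}}
#' @return integer vector or matrix of calls in \{0,1,2,-1\}
#' @export
oneHotDecode <- function(oh) {
    map <- c(0L, 1L, 2L, -1L)
    if (length(dim(oh)) == 3) {
        d <- dim(oh)
        m <- matrix(aperm(oh, c(3, 1, 2)), nrow = 4)
        matrix(map[max.col(t(m))], nrow = d[1])
    } else {
        map[max.col(oh)]
    }
}

#' Build an augmented one-hot view of genotype rows
#'
#' The augmentation pipeline applied in fixed order: allele flips first, then
#' masking, then one-hot encoding. Fresh randomness is consumed from the RNG
#' stream at each invocation, so repeated calls give different views.
#'
#' @param calls integer vector (one sample) or samples x markers matrix
#' @param pflip,pmask augmentation rates (scalar, or per-row for a matrix)
#' @return one-hot matrix (nMarkers x 4) or array (samples x markers x 4)
#' @export
augmentView <- function(calls, pflip, pmask) {
    if (is.matrix(calls)) {
        ## fused single-pass path; consumes the RNG stream in the same order
        ## as the composed functions, so results are identical per seed
        storage.mode(calls) <- "integer"
        .augmentOneHotCpp(calls, rep(pflip, length.out = nrow(calls)),
                          rep(pmask, length.out = nrow(calls)))
    } else {
        oneHotEncode(maskMarkers(flipMarkers(calls, pflip), pmask))
    }
}
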