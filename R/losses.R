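#' Triplet contrastive loss
#'
#' \code{max(||z - z+|| - ||z - z-|| + margin, 0)}: penalizes an anchor that
#' lies closer to its negative than to its positive by more than the margin.
#'
#' @param z,zpos,zneg numeric vectors of equal dimension (anchor, positive,
#'   negative embeddings)
#' @param margin non-negative margin (alpha); default 0.2
#' @return non-negative scalar
#' @examples
#' tripletLoss(c(0, 0), c(1, 0), c(0, 2), margin = 0.5)  # 0
#' @export
tripletLoss <- function(z, zpos, zneg, margin = 0.2) {
    stopifnot(length(z) == length(zpos), length(z) == length(zneg),
              margin >= 0)
    max(sqrt(sum((z - zpos)^2)) - sqrt(sum((z - zneg)^2)) + margin, 0)
}

#' N-pair contrastive loss
#'
#' \code{log(1 + sum_i exp(z'zi- - z'z+))} with inner products taken in the
#' global frame (about the origin); not translation invariant.
#'
#' @param z,zpos anchor and positive embedding vectors
#' @param negatives matrix with one negative embedding per row (a single
#'   vector is accepted)
#' @return scalar loss
#' @examples
#' npairLoss(c(1, 0), c(1, 0), c(-1, 0))  # log(1 + exp(-2))
#' @export
npairLoss <- function(z, zpos, negatives) {
    negatives <- rbind(negatives)
    stopifnot(nrow(negatives) >= 1, ncol(negatives) == length(z))
    s <- drop(negatives %*% z) - sum(z * zpos)
    log(1 + sum(exp(s)))
}

#' Centroid of an anchor/positive/negative triple
#'
#' \code{C = (z + 2 zneg + zpos) / 4}; the negative carries double weight
#' because anchor and positive are two views of the same individual.
#'
#' @param z,zpos,zneg embedding vectors of equal dimension
#' @return the centroid vector
#' @export
computeCentroid <- function(z, zpos, zneg) {
    stopifnot(length(z) == length(zpos), length(z) == length(zneg))
    (z + 2 * zneg + zpos) / 4
}

#' Scaling factor of the centroid frame
#'
#' The magnitude of the largest of the three centroid-shifted vectors. With
#' \code{squared = TRUE} the squared magnitudes are compared and returned
#' instead (a literal variant kept for comparison; the magnitude version is
#' the one for which the best-case normalized inner products are exactly
#' -1 and +1).
#'
#' @param zC,zposC,znegC centroid-shifted anchor, positive and negative
#' @param squared use squared magnitudes (default FALSE)
#' @param eps floor for degenerate all-zero frames
#' @return positive scalar
#' @export
scaleMu <- function(zC, zposC, znegC, squared = FALSE, eps = 1e-12) {
    m2 <- max(sum(zC^2), sum(zposC^2), sum(znegC^2))
    mu <- if (squared) m2 else sqrt(m2)
    if (mu < eps) {
        warning("degenerate centroid frame; scaling floored at eps")
        mu <- eps
    }
    mu
}

#' Centroid-based N-pair contrastive loss
#'
#' For each negative i a local frame is built: the centroid
#' \code{Ci = (z + 2 zi- + z+) / 4} is subtracted from all three points and
#' the shifted vectors are divided by the magnitude of the largest,
#' giving normalized vectors \code{z~}. The loss is
#' \code{log(1 + sum_i (exp(z~' z~i-) / exp(z~' z~i+) - exp(-2)))}.
#' The constant exp(-2) makes the best case (anchor and positive coincident,
#' any negative) contribute exactly zero, since there
#' \code{z~' z~- = -1} and \code{z~' z~+ = +1}. Because each comparison
#' happens in its own local frame, the loss is invariant to translation and
#' rotation of the embedding.
#'
#' @inheritParams npairLoss
#' @param squared compare squared magnitudes in the frame scaling (see
#'   \code{\link{scaleMu}})
#' @return non-negative scalar
#' @examples
#' centroidNpairLoss(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))  # exactly 0
#' @export
centroidNpairLoss <- function(z, zpos, negatives, squared = FALSE) {
    negatives <- rbind(negatives)
    stopifnot(nrow(negatives) >= 1, ncol(negatives) == length(z))
    terms <- vapply(seq_len(nrow(negatives)), function(i) {
        zneg <- negatives[i, ]
        C <- computeCentroid(z, zpos, zneg)
        u <- z - C; up <- zpos - C; un <- zneg - C
        if (max(abs(u), abs(up), abs(un)) < 1e-12) {
            warning("anchor, positive and negative coincide; term skipped")
            return(0)
        }
        mu <- scaleMu(u, up, un, squared = squared)
        exp(sum(u * un) / mu^2 - sum(u * up) / mu^2) - exp(-2)
    }, numeric(1))
    log(1 + sum(terms))
}

#' Select negative samples for an anchor
#'
#' @param embeddings N x d matrix of current embeddings
#' @param anchor index of the anchor sample
#' @param mode "all" returns every other sample; "inverse_distance" samples
#'   \code{nNeg} others without replacement with weights
#'   1 / (distance to anchor + eps)
#' @param nNeg number of negatives for mode "inverse_distance"
#' @param eps weight floor avoiding division by zero
#' @return integer vector of row indices (anchor excluded)
#' @export
selectNegatives <- function(embeddings, anchor, mode = c("all",
                            "inverse_distance"), nNeg = NULL, eps = 1e-12) {
    mode <- match.arg(mode)
    n <- nrow(embeddings)
    if (n < 2) stop("need at least 2 samples")
    others <- setdiff(seq_len(n), anchor)
    if (mode == "all") return(others)
    if (is.null(nNeg)) nNeg <- length(others)
    if (nNeg > length(others))
        stop("nNeg must be smaller than the batch size")
    d <- sqrt(colSums((t(embeddings[others, , drop = FALSE]) -
                       embeddings[anchor, ])^2))
    w <- 1 / (d + eps)
    others[sample.int(length(others), nNeg, prob = w)]
}

## ---- batch loss + gradients (internal training path) ----------------------

## Vectorized centroid N-pair batch loss over anchor/negative pairs.
## Z1: view-1 embeddings (anchors, and the pool negatives are drawn from),
## Z2: view-2 embeddings (positives). negIdx: list, negatives per anchor.
## Returns loss and, if grad=TRUE, gradients w.r.t. Z1 and Z2.
.centroidBatch <- function(Z1, Z2, negIdx, grad = FALSE) {
    n <- nrow(Z1)
    ai <- rep(seq_len(n), lengths(negIdx))
    nj <- unlist(negIdx, use.names = FALSE)
    Za <- Z1[ai, , drop = FALSE]
    Zp <- Z2[ai, , drop = FALSE]
    Zn <- Z1[nj, , drop = FALSE]
    C <- (Za + Zp + 2 * Zn) / 4
    U <- Za - C; Up <- Zp - C; Un <- Zn - C
    n2 <- cbind(rowSums(U^2), rowSums(Up^2), rowSums(Un^2))
    which3 <- max.col(n2, ties.method = "first")
    mu2 <- pmax(n2[cbind(seq_along(ai), which3)], 1e-24)
    f <- (rowSums(U * Un) - rowSums(U * Up)) / mu2
    ef <- exp(f)
    w <- ef - exp(-2)
    sumw <- drop(rowsum(w, ai, reorder = TRUE))          # per-anchor sums
    loss <- sum(log(1 + sumw))
    if (!grad) return(list(loss = loss))

    gf <- ef / (1 + sumw)[ai]                            # dLoss/df per pair
    gf <- as.vector(gf)
    ## partials of f w.r.t. the shifted vectors (mu fixed)
    aU <- (Un - Up) / mu2
    aUp <- -U / mu2
    aUn <- U / mu2
    ## mu chain term: f depends on mu2 through 1/mu2; d f / d v_max where
    ## v_max is the largest shifted vector: -2 f / mu2 * v_max
    coefMu <- -2 * f / mu2
    Vmax <- U
    Vmax[which3 == 2, ] <- Up[which3 == 2, , drop = FALSE]
    Vmax[which3 == 3, ] <- Un[which3 == 3, , drop = FALSE]
    add <- coefMu * Vmax
    aU[which3 == 1, ] <- aU[which3 == 1, , drop = FALSE] +
        add[which3 == 1, , drop = FALSE]
    aUp[which3 == 2, ] <- aUp[which3 == 2, , drop = FALSE] +
        add[which3 == 2, , drop = FALSE]
    aUn[which3 == 3, ] <- aUn[which3 == 3, , drop = FALSE] +
        add[which3 == 3, , drop = FALSE]
    ## map through the centroid-shift Jacobians
    gZa <- gf * (0.75 * aU - 0.25 * aUp - 0.25 * aUn)
    gZp <- gf * (-0.25 * aU + 0.75 * aUp - 0.25 * aUn)
    gZn <- gf * (-0.5 * aU - 0.5 * aUp + 0.5 * aUn)
    dZ1 <- unname(rowsum(gZa, ai, reorder = TRUE)) + .accum(gZn, nj, n)
    dZ2 <- unname(rowsum(gZp, ai, reorder = TRUE))
    list(loss = loss, dZ1 = dZ1, dZ2 = dZ2)
}

.accum <- function(vals, idx, n) {
    out <- matrix(0, n, ncol(vals))
    s <- rowsum(vals, idx, reorder = TRUE)
    out[as.integer(rownames(s)), ] <- s
    out
}

.npairBatch <- function(Z1, Z2, negIdx, grad = FALSE) {
    n <- nrow(Z1)
    ai <- rep(seq_len(n), lengths(negIdx))
    nj <- unlist(negIdx, use.names = FALSE)
    s <- rowSums(Z1[ai, , drop = FALSE] * Z1[nj, , drop = FALSE]) -
        rowSums(Z1[ai, , drop = FALSE] * Z2[ai, , drop = FALSE])
    es <- exp(s)
    sumes <- drop(rowsum(es, ai, reorder = TRUE))
    loss <- sum(log(1 + sumes))
    if (!grad) return(list(loss = loss))
    g <- as.vector(es / (1 + sumes)[ai])
    gA <- g * (Z1[nj, , drop = FALSE] - Z2[ai, , drop = FALSE])
    gN <- g * Z1[ai, , drop = FALSE]
    dZ1 <- unname(rowsum(gA, ai, reorder = TRUE)) + .accum(gN, nj, n)
    dZ2 <- unname(rowsum(-gN, ai, reorder = TRUE))
    list(loss = loss, dZ1 = dZ1, dZ2 = dZ2)
}

.tripletBatch <- function(Z1, Z2, negIdx, margin = 0.2, grad = FALSE) {
    n <- nrow(Z1)
    ai <- rep(seq_len(n), lengths(negIdx))
    nj <- unlist(negIdx, use.names = FALSE)
    Dp <- Z1[ai, , drop = FALSE] - Z2[ai, , drop = FALSE]
    Dn <- Z1[ai, , drop = FALSE] - Z1[nj, , drop = FALSE]
    dp <- pmax(sqrt(rowSums(Dp^2)), 1e-12)
    dn <- pmax(sqrt(rowSums(Dn^2)), 1e-12)
    act <- dp - dn + margin > 0
    loss <- sum(pmax(dp - dn + margin, 0))
    if (!grad) return(list(loss = loss))
    gp <- (act / dp) * Dp                   # d dp / d z etc.
    gn <- -(act / dn) * Dn
    dZ1 <- unname(rowsum(gp + gn, ai, reorder = TRUE)) + .accum(-gn, nj, n)
    dZ2 <- unname(rowsum(-gp, ai, reorder = TRUE))
    list(loss = loss, dZ1 = dZ1, dZ2 = dZ2)
}

#' Total contrastive loss of a batch
#'
#' Sums per-anchor loss contributions, using each sample of the batch as the
#' anchor once; its positive is the second view of the same sample and its
#' negatives are (by default) the view-1 embeddings of all other samples.
#' Invariant to permuting the sample order.
#'
#' @param Z1 N x d matrix of view-1 (anchor) embeddings
#' @param Z2 N x d matrix of view-2 (positive) embeddings, same sample order
#' @param kind loss kind: "centroid" (default), "npair" or "triplet"
#' @param negatives "all" or "inverse_distance" (see
#'   \code{\link{selectNegatives}})
#' @param nNeg negatives per anchor for inverse-distance sampling
#' @param margin triplet margin
#' @return scalar total loss
#' @export
batchLoss <- function(Z1, Z2, kind = c("centroid", "npair", "triplet"),
                      negatives = "all", nNeg = NULL, margin = 0.2) {
    kind <- match.arg(kind)
    Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2)
    if (nrow(Z1) < 2) stop("batch must contain at least 2 samples")
    stopifnot(identical(dim(Z1), dim(Z2)))
    negIdx <- lapply(seq_len(nrow(Z1)), function(i)
        selectNegatives(Z1, i, mode = negatives, nNeg = nNeg))
    switch(kind,
           centroid = .centroidBatch(Z1, Z2, negIdx)$loss,
           npair = .npairBatch(Z1, Z2, negIdx)$loss,
           triplet = .tripletBatch(Z1, Z2, negIdx, margin)$loss)
}
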