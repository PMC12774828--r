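test_that("triplet loss matches direct arithmetic and is non-negative", {
    expect_equal(tripletLoss(c(0, 0), c(1, 0), c(0, 2), margin = 0.5), 0)
    expect_equal(tripletLoss(c(0, 0), c(1, 0), c(0, 2), margin = 1.5), 0.5)
    v <- c(0.3, -0.2, 0.5)
    expect_equal(tripletLoss(v, v, v, margin = 0.2), 0.2)
    expect_error(tripletLoss(c(0, 0), c(1, 0, 0), c(0, 1)), "length")
    set.seed(1)
    for (i in 1:20) {
        z <- rnorm(3); zp <- rnorm(3); zn <- rnorm(3)
        expect_gte(tripletLoss(z, zp, zn), 0)
    }
})

test_that("N-pair loss matches its closed form in the global frame", {
    expect_equal(npairLoss(c(1, 0), c(1, 0), c(-1, 0)), log(1 + exp(-2)),
                 tolerance = 1e-12)
    ## equal similarity to positive and negatives gives log(N)
    z <- c(1, 0); negs <- rbind(c(0, 1), c(0, -1), c(1, 0))
    zp <- c(1, 0)
    expect_equal(npairLoss(z, zp, rbind(zp, zp, zp)), log(4))
    ## not translation invariant (inner products are about the origin)
    set.seed(2)
    v <- rnorm(2)
    expect_false(isTRUE(all.equal(npairLoss(z, c(0, 1), rbind(c(0.3, 0.1))),
                                  npairLoss(z + v, c(0, 1) + v,
                                            rbind(c(0.3, 0.1) + v)))))
})

test_that("centroid and scaling follow their definitions", {
    expect_equal(computeCentroid(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 c(0.5, 0.5, 0))
    v <- c(0.2, -0.4, 0.1)
    expect_equal(computeCentroid(v, v, v), v)
    expect_equal(computeCentroid(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)),
                 c(0.25, 0.5, 0.25))
    expect_equal(scaleMu(c(0.5, -0.5, 0), c(0.5, -0.5, 0), c(-0.5, 0.5, 0)),
                 sqrt(0.5))
    expect_equal(scaleMu(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1)
    ## positive homogeneity of degree one
    a <- c(0.3, 0.1, -0.2); b <- c(0, 0.4, 0.1); d <- c(-0.1, 0.2, 0.3)
    expect_equal(scaleMu(3 * a, 3 * b, 3 * d), 3 * scaleMu(a, b, d))
    ## literal squared variant kept for comparison
    expect_equal(scaleMu(a, b, d, squared = TRUE), scaleMu(a, b, d)^2)
})

test_that("centroid N-pair loss has the published best-case identities", {
    ## coincident anchor/positive: normalized inner products are -1 and +1,
    ## term contributes exactly zero
    z <- c(1, 0, 0); zn <- c(0, 1, 0)
    C <- computeCentroid(z, z, zn)
    mu <- scaleMu(z - C, z - C, zn - C)
    expect_equal(sum((z - C) / mu * ((zn - C) / mu)), -1)
    expect_equal(sum((z - C) / mu * ((z - C) / mu)), 1)
    expect_equal(centroidNpairLoss(z, z, zn), 0)
    ## hand-evaluated generic configuration
    expect_equal(centroidNpairLoss(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)),
                 0.4800418, tolerance = 1e-6)
    ## non-negativity on random inputs (normalized products lie in [-1, 1])
    set.seed(3)
    for (i in 1:50) {
        z <- rnorm(3); zp <- rnorm(3)
        negs <- matrix(rnorm(9), 3)
        expect_gte(centroidNpairLoss(z, zp, negs), -1e-12)
    }
})

test_that("centroid loss is translation and rotation invariant; N-pair is not", {
    set.seed(4)
    for (i in 1:10) {
        z <- rnorm(3); zp <- rnorm(3); negs <- matrix(rnorm(6), 2)
        v <- rnorm(3)
        base <- centroidNpairLoss(z, zp, negs)
        expect_equal(centroidNpairLoss(z + v, zp + v,
                                       sweep(negs, 2, -v)), base,
                     tolerance = 1e-9)
        R <- qr.Q(qr(matrix(rnorm(9), 3)))
        if (det(R) < 0) R[, 1] <- -R[, 1]
        expect_equal(centroidNpairLoss(drop(R %*% z), drop(R %*% zp),
                                       negs %*% t(R)), base,
                     tolerance = 1e-9)
        expect_equal(tripletLoss(drop(R %*% z), drop(R %*% zp),
                                 drop(R %*% negs[1, ])),
                     tripletLoss(z, zp, negs[1, ]), tolerance = 1e-9)
    }
})

test_that("batch loss sums per-anchor terms and is permutation invariant", {
    Z1 <- randomUnitVectors(6, seed = 5)
    Z2 <- randomUnitVectors(6, seed = 6)
    for (kind in c("centroid", "npair", "triplet")) {
        total <- batchLoss(Z1, Z2, kind = kind)
        perm <- sample(6)
        expect_equal(batchLoss(Z1[perm, ], Z2[perm, ], kind = kind), total,
                     tolerance = 1e-9)
    }
    ## batch of 2: sum of the 2 single-negative terms
    expect_equal(batchLoss(Z1[1:2, ], Z2[1:2, ], kind = "centroid"),
                 centroidNpairLoss(Z1[1, ], Z2[1, ], rbind(Z1[2, ])) +
                 centroidNpairLoss(Z1[2, ], Z2[2, ], rbind(Z1[1, ])),
                 tolerance = 1e-12)
    expect_error(batchLoss(Z1[1, , drop = FALSE], Z2[1, , drop = FALSE]),
                 "at least 2")
    ## positives coincident with anchors: centroid batch loss is exactly 0
    expect_equal(batchLoss(Z1, Z1, kind = "centroid"), 0, tolerance = 1e-12)
})

test_that("analytic batch gradients match finite differences", {
    Z1 <- randomUnitVectors(5, seed = 7)
    Z2 <- randomUnitVectors(5, seed = 8)
    negIdx <- lapply(1:5, function(i) setdiff(1:5, i))
    eps <- 1e-6
    for (kind in c("centroid", "npair", "triplet")) {
        fn <- switch(kind,
            centroid = function(A, B) popsphere:::.centroidBatch(A, B, negIdx)$loss,
            npair = function(A, B) popsphere:::.npairBatch(A, B, negIdx)$loss,
            triplet = function(A, B) popsphere:::.tripletBatch(A, B, negIdx,
                                                               0.2)$loss)
        an <- switch(kind,
            centroid = popsphere:::.centroidBatch(Z1, Z2, negIdx, grad = TRUE),
            npair = popsphere:::.npairBatch(Z1, Z2, negIdx, grad = TRUE),
            triplet = popsphere:::.tripletBatch(Z1, Z2, negIdx, 0.2,
                                                grad = TRUE))
        for (i in c(1, 3)) for (k in 1:3) {
            Zp <- Z1; Zp[i, k] <- Zp[i, k] + eps
            Zm <- Z1; Zm[i, k] <- Zm[i, k] - eps
            expect_equal(an$dZ1[i, k], (fn(Zp, Z2) - fn(Zm, Z2)) / (2 * eps),
                         tolerance = 1e-4)
            Zp <- Z2; Zp[i, k] <- Zp[i, k] + eps
            Zm <- Z2; Zm[i, k] <- Zm[i, k] - eps
            expect_equal(an$dZ2[i, k], (fn(Z1, Zp) - fn(Z1, Zm)) / (2 * eps),
                         tolerance = 1e-4)
        }
    }
})

test_that("a gradient step on the centroid loss improves the triple geometry", {
    ## anchor near negative, positive elsewhere: stepping along the negative
    ## gradient must decrease the loss and improve the anchor's relative
    ## placement (closer to positive or further from negative)
    Z1 <- rbind(c(1, 0, 0), c(0.95, 0.31225, 0))
    Z2 <- rbind(c(0, 1, 0), c(0.95, -0.31225, 0))
    negIdx <- list(2L, 1L)
    g <- popsphere:::.centroidBatch(Z1, Z2, negIdx, grad = TRUE)
    for (step in c(1e-3, 1e-2)) {
        newZ1 <- Z1 - step * g$dZ1
        newZ2 <- Z2 - step * g$dZ2
        expect_lt(popsphere:::.centroidBatch(newZ1, newZ2, negIdx)$loss,
                  g$loss)
    }
    dPosOld <- sqrt(sum((Z1[1, ] - Z2[1, ])^2))
    dNegOld <- sqrt(sum((Z1[1, ] - Z1[2, ])^2))
    newZ1 <- Z1 - 1e-2 * g$dZ1; newZ2 <- Z2 - 1e-2 * g$dZ2
    dPosNew <- sqrt(sum((newZ1[1, ] - newZ2[1, ])^2))
    dNegNew <- sqrt(sum((newZ1[1, ] - newZ1[2, ])^2))
    expect_true(dPosNew < dPosOld || dNegNew > dNegOld)
})

test_that("negative selection excludes the anchor and weights by distance", {
    emb <- randomUnitVectors(8, seed = 9)
    all <- selectNegatives(emb, 3, mode = "all")
    expect_identical(sort(all), setdiff(1:8, 3L))
    expect_error(selectNegatives(emb, 1, mode = "inverse_distance", nNeg = 8),
                 "smaller than the batch")
    ## a near-coincident sample dominates inverse-distance sampling
    emb2 <- rbind(c(1, 0, 0), c(1, 1e-9, 0), c(-1, 0, 0), c(0, 1, 0))
    emb2 <- emb2 / sqrt(rowSums(emb2^2))
    set.seed(10)
    picks <- replicate(400, selectNegatives(emb2, 1,
                                            mode = "inverse_distance",
                                            nNeg = 1))
    expect_gt(mean(picks == 2L), 0.95)
    ## equidistant candidates are selected uniformly
    emb3 <- rbind(c(0, 0, 1), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0))
    set.seed(11)
    picks3 <- replicate(3000, selectNegatives(emb3, 1,
                                              mode = "inverse_distance",
                                              nNeg = 1))
    freq <- table(factor(picks3, levels = 2:5)) / 3000
    expect_lt(max(abs(freq - 0.25)), 3 * sqrt(0.25 * 0.75 / 3000))
})
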