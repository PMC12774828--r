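test_that("KNN prediction matches the brute-force oracle", {
    set.seed(1)
    ref <- randomUnitVectors(10, seed = 1)
    labs <- sample(c("A", "B", "C"), 10, replace = TRUE)
    qry <- randomUnitVectors(6, seed = 2)
    for (k in c(1, 3, 5)) {
        got <- knnPredict(ref, labs, query = qry, k = k)$predicted
        expect_identical(got, bruteKnn(ref, labs, qry, k))
    }
    ## coincident query with k = 1 returns that reference's label
    got <- knnPredict(ref, labs, query = ref[4, , drop = FALSE], k = 1)
    expect_identical(got$predicted, labs[4])
    ## majority vote among equidistant references
    tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    expect_identical(knnPredict(tri, c("A", "A", "B"),
                                query = rbind(c(1, 1, 1) / sqrt(3)),
                                k = 3)$predicted, "A")
    expect_error(knnPredict(ref, labs, k = 10), "exceeds")
})

test_that("local score is the self-excluded 3NN subpopulation accuracy", {
    ## four tight, well-separated clusters of five are perfectly classified
    centers <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    set.seed(3)
    pts <- do.call(rbind, lapply(1:4, function(i)
        centers[rep(i, 5), ] + matrix(rnorm(15, sd = 0.01), 5)))
    labs <- rep(letters[1:4], each = 5)
    expect_equal(localScore(pts, labs), 1.0)
    ## matches the oracle on unstructured data
    z <- randomUnitVectors(15, seed = 4)
    labs2 <- rep(c("x", "y", "z"), each = 5)
    expect_equal(localScore(z, labs2),
                 mean(bruteKnn(z, labs2, z, 3, excludeSelf = TRUE) == labs2))
    ## permuted labels fall to roughly the frequency baseline
    set.seed(5)
    accs <- replicate(30, localScore(pts, sample(labs)))
    expect_lt(mean(accs), 0.5)
})

test_that("global score classifies subpopulation centroids by superpopulation", {
    ## 2 superpops x 4 subpops, superpops antipodal, subpops tight
    set.seed(6)
    sub <- rep(sprintf("s%d", 1:8), each = 4)
    sup <- rep(c("P", "Q"), each = 16)
    offsets <- matrix(rnorm(8 * 3, sd = 0.05), 8)
    base <- rbind(matrix(rep(c(1, 0, 0), 4), 4, byrow = TRUE),
                  matrix(rep(c(-1, 0, 0), 4), 4, byrow = TRUE))
    pts <- (base + offsets)[rep(1:8, each = 4), ] +
        matrix(rnorm(96, sd = 0.01), 32)
    expect_equal(globalScore(pts, sub, sup), 1.0)
    ## 2 x 2 perfectly separated: every centroid's 3 neighbors are majority
    ## other-superpopulation, score 0 (why the metric needs >= 4 per super)
    sub2 <- rep(c("a", "b", "c", "d"), each = 3)
    sup2 <- rep(c("P", "P", "Q", "Q"), each = 3)
    pts2 <- rbind(matrix(rep(c(1, 0.1, 0), 3), 3, byrow = TRUE),
                  matrix(rep(c(1, -0.1, 0), 3), 3, byrow = TRUE),
                  matrix(rep(c(-1, 0.1, 0), 3), 3, byrow = TRUE),
                  matrix(rep(c(-1, -0.1, 0), 3), 3, byrow = TRUE))
    expect_equal(globalScore(pts2, sub2, sup2), 0.0)
    ## centroids equal the group means
    cent <- t(sapply(c("a", "b", "c", "d"), function(s)
        colMeans(pts2[sub2 == s, ])))
    expect_equal(unname(cent[1, ]), c(1, 0.1, 0))
    expect_error(globalScore(pts2[1:6, ], sub2[1:6], sup2[1:6]), "at least")
})

test_that("generalization score scores validation queries against training", {
    z <- randomUnitVectors(20, seed = 7)
    labs <- rep(c("A", "B"), each = 10)
    ## duplicated validation points recover their training labels
    expect_equal(generalizationScore(z, labs, z[c(2, 12), ],
                                     labs[c(2, 12)]), 1.0)
    ## matches the oracle on a random 30-point instance
    val <- randomUnitVectors(10, seed = 8)
    vlabs <- rep(c("A", "B"), 5)
    expect_equal(generalizationScore(z, labs, val, vlabs),
                 mean(bruteKnn(z, labs, val, 3) == vlabs))
})

test_that("accuracy-vs-k curve is consistent with per-k KNN calls", {
    set.seed(9)
    centers <- rbind(c(0, 0, 1), c(0, 0, -1))
    pts <- centers[rep(1:2, each = 50), ] + matrix(rnorm(300, sd = 0.05), 100)
    labs <- rep(c("N", "S"), each = 50)
    curve <- accuracyVsK(pts, labs, kValues = c(1, 3, 10, 25, 49))
    ## two antipodal clusters of 50: perfect for all k <= 49
    expect_true(all(curve$accuracy == 1))
    ## k = N - 1 saturates to the majority-class accuracy
    labs2 <- c(rep("N", 60), rep("S", 40))
    z <- randomUnitVectors(100, seed = 10)
    full <- accuracyVsK(z, labs2, kValues = 99)
    expect_equal(full$accuracy, 0.6)
    ## agrees with direct knnPredict at each k
    z2 <- randomUnitVectors(20, seed = 11)
    labs3 <- rep(c("A", "B"), 10)
    curve2 <- accuracyVsK(z2, labs3, kValues = c(1, 5))
    for (i in 1:2)
        expect_equal(curve2$accuracy[i],
                     mean(knnPredict(z2, labs3, k = curve2$k[i],
                                     excludeSelf = TRUE)$predicted == labs3))
})

test_that("neighbor overlap matches the oracle and its analytic limits", {
    gm <- makeGenotypeFixture(25, 30, seed = 12)
    calls <- genotypeCalls(gm)
    z <- randomUnitVectors(25, seed = 13)
    got <- neighborOverlap(gm, z, kValues = c(3, 5, 10))
    expect_equal(got$overlap, bruteOverlap(calls, z, c(3, 5, 10)),
                 tolerance = 1e-12)
    ## a rank-preserving copy of genotype space has full overlap: for
    ## binary calls Euclidean distance is a monotone map of Manhattan
    gmBin <- GenotypeData(matrix(sample(0:1, 25 * 40, TRUE), 25))
    gotIso <- neighborOverlap(gmBin, genotypeCalls(gmBin), kValues = c(3, 7))
    expect_true(all(gotIso$overlap == 1))
    ## unrelated embedding: overlap near the hypergeometric expectation
    gm2 <- makeGenotypeFixture(200, 40, seed = 14)
    z2 <- randomUnitVectors(200, seed = 15)
    got2 <- neighborOverlap(gm2, z2, kValues = 3)
    expect_lt(got2$overlap, 0.1)          # ~ k/(N-1) = 0.015, far below 1
    ## missing genotypes are rejected with guidance
    gmMiss <- makeGenotypeFixture(10, 10, missingFrac = 0.1)
    expect_error(neighborOverlap(gmMiss, randomUnitVectors(10)), "modeImpute")
})

test_that("rank RMSE matches the oracle and vanishes for isometries", {
    gm <- makeGenotypeFixture(25, 30, seed = 16)
    calls <- genotypeCalls(gm)
    z <- randomUnitVectors(25, seed = 17)
    got <- rankRMSE(gm, z, nValues = c(1, 5, 10))
    expect_equal(got$rmse, bruteRankRmse(calls, z, c(1, 5, 10)),
                 tolerance = 1e-12)
    gmBin <- GenotypeData(matrix(sample(0:1, 25 * 40, TRUE), 25))
    gotIso <- rankRMSE(gmBin, genotypeCalls(gmBin), nValues = c(1, 2, 3))
    expect_true(all(gotIso$rmse == 0))
    ## three-point configuration with swapped first/second neighbors
    gm3 <- GenotypeData(rbind(c(0L, 0L, 0L, 0L),
                              c(1L, 0L, 0L, 0L),
                              c(2L, 2L, 0L, 0L)))
    emb3 <- rbind(0, 3, 4)                 # 1D embedding as 1-col matrix
    ## genotype ranks from sample 1: j2 (d=1) then j3 (d=4)
    ## embedding ranks from sample 1: j2 (3) then j3 (4) -> no swap for i=1
    got3 <- rankRMSE(gm3, cbind(emb3, 0, 0), nValues = 1)
    expect_equal(got3$rmse, bruteRankRmse(genotypeCalls(gm3),
                                          cbind(emb3, 0, 0), 1))
})

test_that("KNN scores are invariant to rigid rotation of the embedding", {
    z <- randomUnitVectors(30, seed = 18)
    labs <- rep(c("A", "B", "C"), each = 10)
    sup <- rep(c("P", "P", "Q"), each = 10)
    R <- eulerRotation(0.7, -0.2, 1.4)
    zR <- z %*% t(R)
    expect_equal(localScore(zR, labs), localScore(z, labs))
    expect_equal(generalizationScore(zR[1:20, ], labs[1:20], zR[21:30, ],
                                     labs[21:30]),
                 generalizationScore(z[1:20, ], labs[1:20], z[21:30, ],
                                     labs[21:30]))
})
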