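## Embedding-quality metrics. All classification metrics are built on a KNN
## classifier with deterministic tie handling; the label-agnostic metrics
## compare neighborhoods in genotype space (Manhattan distance) with
## neighborhoods in embedding space (Euclidean distance).

## Cross squared Euclidean distances, query rows x reference rows.
.crossDist2 <- function(query, reference) {
    q2 <- rowSums(query^2)
    r2 <- rowSums(reference^2)
    d2 <- outer(q2, r2, `+`) - 2 * tcrossprod(query, reference)
    pmax(d2, 0)
}

## coordinates from SphereEmbedding or plain matrix
.coords <- function(embedding, use2d = FALSE) {
    if (methods::is(embedding, "SphereEmbedding")) {
        if (use2d) {
            if (!nrow(embedding@coords2))
                stop("embedding has no 2D coordinates; project it first")
            embedding@coords2
        } else embedding@coords3
    } else as.matrix(embedding)
}

#' KNN classification in embedding space
#'
#' Majority vote over the k nearest reference samples (Euclidean distance).
#' Distance ties are broken by reference order (stable); vote ties are broken
#' by the smaller mean distance to the query, then lexicographically by
#' label.
#'
#' @param reference reference coordinates (matrix or
#'   \linkS4class{SphereEmbedding})
#' @param refLabels labels of the reference samples
#' @param query query coordinates; defaults to \code{reference}
#' @param k number of neighbors
#' @param excludeSelf drop the matching row index from each query's neighbor
#'   candidates (use when the query set is the reference set)
#' @return list with \code{predicted} labels and \code{neighbors} (matrix of
#'   reference indices, queries in rows)
#' @export
knnPredict <- function(reference, refLabels, query = NULL, k = 3L,
                       excludeSelf = is.null(query)) {
    ref <- .coords(reference)
    qry <- if (is.null(query)) ref else .coords(query)
    refLabels <- as.character(refLabels)
    stopifnot(length(refLabels) == nrow(ref))
    avail <- nrow(ref) - as.integer(excludeSelf)
    if (k > avail)
        stop("k = ", k, " exceeds the ", avail, " available references")
    d2 <- .crossDist2(qry, ref)
    if (excludeSelf)
        d2[cbind(seq_len(nrow(qry)), seq_len(nrow(qry)))] <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
    if (k == 1L) nn <- matrix(nn, ncol = 1L)
    predicted <- vapply(seq_len(nrow(qry)), function(i) {
        labs <- refLabels[nn[i, ]]
        votes <- table(labs)
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1L) {
            meanDist <- vapply(top, function(lb)
                mean(sqrt(d2[i, nn[i, ]][labs == lb])), numeric(1))
            top <- top[order(meanDist, top)]
        }
        top[1]
    }, character(1))
    list(predicted = predicted, neighbors = nn)
}

#' Local structure score (L)
#'
#' 3NN classification accuracy for the subpopulation label on the training
#' embedding, with the query sample excluded from its own neighbor set.
#'
#' @param embedding embedding coordinates (matrix or
#'   \linkS4class{SphereEmbedding})
#' @param subLabels per-sample subpopulation labels
#' @param k neighbor count (3 for the standard score)
#' @return accuracy in [0, 1]
#' @export
localScore <- function(embedding, subLabels, k = 3L) {
    pred <- knnPredict(embedding, subLabels, k = k, excludeSelf = TRUE)
    mean(pred$predicted == as.character(subLabels))
}

#' Global structure score (G)
#'
#' Mean embedding coordinates are computed per subpopulation; the
#' superpopulation of each subpopulation centroid is then predicted by 3NN
#' among the centroids (self excluded). A method that isolates
#' subpopulations but scatters them across superpopulations scores low.
#' Meaningless below 4 centroids (3NN undefined).
#'
#' @inheritParams localScore
#' @param superLabels per-sample superpopulation labels
#' @return accuracy over subpopulation centroids
#' @export
globalScore <- function(embedding, subLabels, superLabels, k = 3L) {
    co <- .coords(embedding)
    subLabels <- as.character(subLabels)
    superLabels <- as.character(superLabels)
    subs <- sort(unique(subLabels))
    if (length(subs) < k + 1L)
        stop("need at least ", k + 1L, " subpopulation centroids for ",
             k, "NN classification")
    cent <- t(vapply(subs, function(s)
        colMeans(co[subLabels == s, , drop = FALSE]), numeric(ncol(co))))
    sup <- vapply(subs, function(s) superLabels[subLabels == s][1],
                  character(1))
    if (length(unique(sup)) < 2)
        stop("need at least 2 superpopulations")
    pred <- knnPredict(cent, sup, k = k, excludeSelf = TRUE)
    mean(pred$predicted == sup)
}

#' Generalization score (GE)
#'
#' 3NN accuracy of predicting held-out (validation) sample labels from the
#' training embedding: reference = training samples, query = validation
#' samples.
#'
#' @param trainEmbedding,valEmbedding coordinates of training and validation
#'   samples
#' @param trainLabels,valLabels their labels (the tier — subpopulation or
#'   superpopulation — is the caller's choice)
#' @param k neighbor count
#' @return accuracy in [0, 1]
#' @export
generalizationScore <- function(trainEmbedding, trainLabels, valEmbedding,
                                valLabels, k = 3L) {
    pred <- knnPredict(trainEmbedding, trainLabels, query = valEmbedding,
                       k = k, excludeSelf = FALSE)
    mean(pred$predicted == as.character(valLabels))
}

#' KNN accuracy as a function of k
#'
#' @param embedding embedding coordinates
#' @param labels per-sample labels (typically the superpopulation tier)
#' @param kValues neighbor counts to evaluate (all < number of samples)
#' @return data.frame with columns \code{k} and \code{accuracy}
#' @export
accuracyVsK <- function(embedding, labels, kValues = c(1, 3, 5, 10, 20, 50)) {
    co <- .coords(embedding)
    kValues <- kValues[kValues < nrow(co)]
    acc <- vapply(kValues, function(k)
        mean(knnPredict(co, labels, k = k,
                        excludeSelf = TRUE)$predicted ==
             as.character(labels)), numeric(1))
    data.frame(k = kValues, accuracy = acc)
}

## k-nearest neighbor index sets (self excluded, stable tie-break by index)
.nnSets <- function(d, kmax) {
    n <- nrow(d)
    diag(d) <- Inf
    t(apply(d, 1, function(r) order(r)[seq_len(kmax)]))
}

#' Neighbor overlap between genotype space and embedding space
#'
#' For each sample the k nearest neighbors are found under Manhattan distance
#' on the genotypes and Euclidean distance on the embedding; the score per k
#' is the mean over samples of |intersection| / k.
#'
#' @param gd complete \linkS4class{GenotypeData} (impute missing calls first)
#' @param embedding embedding coordinates for the same samples, same order
#' @param kValues neighbor set sizes (the published curve uses 3..100)
#' @return data.frame with columns \code{k} and \code{overlap}
#' @export
neighborOverlap <- function(gd, embedding, kValues = 3:100) {
    calls <- genotypeCalls(gd)
    if (any(calls == -1L))
        stop("genotypes contain missing calls; run modeImpute() first")
    co <- .coords(embedding)
    stopifnot(nrow(co) == nrow(calls))
    n <- nrow(calls)
    kValues <- kValues[kValues < n]
    dg <- as.matrix(stats::dist(calls, method = "manhattan"))
    de <- as.matrix(stats::dist(co))
    kmax <- max(kValues)
    nnG <- .nnSets(dg, kmax)
    nnE <- .nnSets(de, kmax)
    ov <- vapply(kValues, function(k) {
        mean(vapply(seq_len(n), function(i)
            length(intersect(nnG[i, seq_len(k)], nnE[i, seq_len(k)])) / k,
            numeric(1)))
    }, numeric(1))
    data.frame(k = kValues, overlap = ov)
}

#' Neighbor rank RMSE between genotype and embedding space
#'
#' For each sample i and each n, the n-th closest neighbor j of i in genotype
#' space (Manhattan distance) is located, and j's rank among i's neighbors in
#' embedding space (Euclidean) is recorded; the score at n is the root mean
#' square of (n - embedding rank) over samples. Rank ties are resolved by a
#' stable sort on sample index.
#'
#' @inheritParams neighborOverlap
#' @param nValues genotype-space ranks to evaluate (published curve: 1..100)
#' @return data.frame with columns \code{n} and \code{rmse}
#' @export
rankRMSE <- function(gd, embedding, nValues = 1:100) {
    calls <- genotypeCalls(gd)
    if (any(calls == -1L))
        stop("genotypes contain missing calls; run modeImpute() first")
    co <- .coords(embedding)
    stopifnot(nrow(co) == nrow(calls))
    n <- nrow(calls)
    nValues <- nValues[nValues < n]
    dg <- as.matrix(stats::dist(calls, method = "manhattan"))
    de <- as.matrix(stats::dist(co))
    diag(dg) <- Inf; diag(de) <- Inf
    ordG <- t(apply(dg, 1, order))        # i-th row: neighbor ids by G-rank
    rankE <- t(apply(de, 1, function(r) {  # i-th row: id -> embedding rank
        o <- order(r)
        out <- integer(n); out[o] <- seq_len(n); out
    }))
    rmse <- vapply(nValues, function(nv) {
        re <- rankE[cbind(seq_len(n), ordG[, nv])]
        sqrt(mean((nv - re)^2))
    }, numeric(1))
    data.frame(n = nValues, rmse = rmse)
}

#' Full metric report for an embedding
#'
#' Convenience wrapper computing L, G, GE (if a validation split is given)
#' and optionally the label-agnostic curves.
#'
#' @param embedding training-sample embedding
#' @param subLabels,superLabels two-tier labels for the training samples
#' @param valEmbedding,valSubLabels optional validation embedding and labels
#' @param gd optional complete GenotypeData (training samples) enabling the
#'   neighbor-overlap and rank-RMSE curves
#' @param kValues,nValues curve grids
#' @return list of scores and curves with the settings that produced them
#' @export
metricReport <- function(embedding, subLabels, superLabels,
                         valEmbedding = NULL, valSubLabels = NULL,
                         gd = NULL, kValues = 3:100, nValues = 1:100) {
    out <- list(settings = list(k = 3L, kValues = kValues, nValues = nValues))
    out$L <- localScore(embedding, subLabels)
    out$G <- tryCatch(globalScore(embedding, subLabels, superLabels),
                      error = function(e) NA_real_)
    if (!is.null(valEmbedding))
        out$GE <- generalizationScore(embedding, subLabels, valEmbedding,
                                      valSubLabels)
    if (!is.null(gd)) {
        out$neighborOverlap <- neighborOverlap(gd, embedding, kValues)
        out$rankRMSE <- rankRMSE(gd, embedding, nValues)
    }
    out
}
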