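#' Construct a GenotypeData object
#'
#' @param calls integer matrix of alternate-allele counts, samples in rows and
#'   markers in columns; values in \{0, 1, 2\} with -1 for missing.
#' @param markers data.frame (or DataFrame) with one row per marker and columns
#'   \code{id}, \code{chromosome}, \code{position}. If \code{NULL}, marker ids
#'   are taken from \code{colnames(calls)} (or generated) with placeholder
#'   chromosome "0" and consecutive positions.
#' @param sampleIds character vector; defaults to \code{rownames(calls)} or
#'   generated ids.
#' @param labels optional data.frame with columns \code{sample_id},
#'   \code{subpopulation}, \code{superpopulation} (see \code{\link{readLabels}}).
#'
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' gm <- GenotypeData(matrix(c(0L, 1L, 2L, -1L), nrow = 2))
#' genotypeCalls(gm)
#' @export
GenotypeData <- function(calls, markers = NULL, sampleIds = NULL, labels = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    n <- nrow(calls); d <- ncol(calls)
    if (is.null(sampleIds))
        sampleIds <- rownames(calls)
    if (is.null(sampleIds))
        sampleIds <- sprintf("sample%0*d", nchar(max(n, 1L)), seq_len(n))
    if (is.null(markers)) {
        ids <- colnames(calls)
        if (is.null(ids)) ids <- sprintf("snp%d", seq_len(d))
        markers <- data.frame(id = ids, chromosome = "0",
                              position = seq_len(d))
    }
    markers <- as.data.frame(markers)
    stopifnot(all(c("id", "chromosome", "position") %in% colnames(markers)),
              nrow(markers) == d, length(sampleIds) == n)
    rd <- S4Vectors::DataFrame(chromosome = as.character(markers$chromosome),
                               position = as.integer(markers$position),
                               row.names = as.character(markers$id))
    cd <- S4Vectors::DataFrame(subpopulation = rep(NA_character_, n),
                               superpopulation = rep(NA_character_, n),
                               row.names = as.character(sampleIds))
    m <- t(calls)
    dimnames(m) <- list(rownames(rd), rownames(cd))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = m), rowData = rd, colData = cd)
    gd <- methods::new("GenotypeData", se)
    if (!is.null(labels))
        gd <- setLabels(gd, labels)
    gd
}

#' @describeIn GenotypeData genotype calls as a samples x markers integer
#'   matrix (the orientation used by the augmentation and distance code).
#' @param gd,object a GenotypeData object
#' @export
genotypeCalls <- function(gd) t(SummarizedExperiment::assay(gd, "calls"))

#' @describeIn GenotypeData marker annotation as a data.frame with columns
#'   id, chromosome, position.
#' @export
markerInfo <- function(gd) {
    rd <- SummarizedExperiment::rowData(gd)
    data.frame(id = rownames(rd), chromosome = rd$chromosome,
               position = rd$position, row.names = NULL)
}

#' @describeIn GenotypeData sample identifiers.
#' @export
sampleIds <- function(gd) colnames(gd)

#' @describeIn GenotypeData per-sample subpopulation labels (NA if unlabeled).
#' @export
subpopulation <- function(gd) {
    stats::setNames(SummarizedExperiment::colData(gd)$subpopulation, colnames(gd))
}

#' @describeIn GenotypeData per-sample superpopulation labels (NA if unlabeled).
#' @export
superpopulation <- function(gd) {
    stats::setNames(SummarizedExperiment::colData(gd)$superpopulation, colnames(gd))
}

#' Attach two-tier population labels to a GenotypeData object
#'
#' Labels are matched by sample id; samples absent from \code{labels} keep NA
#' labels and are reported via a message. Label rows for unknown samples are an
#' error, as is a subpopulation listed under two superpopulations.
#'
#' @param gd a \linkS4class{GenotypeData} object
#' @param labels data.frame with columns \code{sample_id}, \code{subpopulation},
#'   \code{superpopulation}
#' @return the updated GenotypeData object
#' @export
setLabels <- function(gd, labels) {
    labels <- as.data.frame(labels)
    stopifnot(all(c("sample_id", "subpopulation", "superpopulation") %in%
                  colnames(labels)))
    if (anyDuplicated(labels$sample_id))
        stop("duplicate sample ids in labels")
    map <- unique(labels[, c("subpopulation", "superpopulation")])
    if (anyDuplicated(map$subpopulation))
        stop("a subpopulation is listed under two superpopulations")
    unknown <- setdiff(labels$sample_id, colnames(gd))
    if (length(unknown))
        stop("labels refer to unknown samples: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    idx <- match(colnames(gd), labels$sample_id)
    cd <- SummarizedExperiment::colData(gd)
    cd$subpopulation <- labels$subpopulation[idx]
    cd$superpopulation <- labels$superpopulation[idx]
    SummarizedExperiment::colData(gd) <- cd
    if (anyNA(idx))
        message(sum(is.na(idx)), " samples have no label")
    methods::validObject(gd)
    gd
}

#' @export
setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", ncol(object), "samples x", nrow(object), "markers\n")
    miss <- mean(SummarizedExperiment::assay(object, "calls") == -1L)
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
    sub <- SummarizedExperiment::colData(object)$subpopulation
    if (any(!is.na(sub)))
        cat("  labels:", length(unique(stats::na.omit(sub))), "subpopulations,",
            length(unique(stats::na.omit(
                SummarizedExperiment::colData(object)$superpopulation))),
            "superpopulations\n")
    else cat("  labels: none\n")
})

#' Construct a SphereEmbedding
#'
#' @param coords3 samples x 3 matrix of (approximately) unit-norm coordinates;
#'   rows are re-normalized to machine precision.
#' @param sampleIds character vector of sample ids.
#' @param coords2 optional samples x 2 matrix of planar coordinates.
#' @return A \linkS4class{SphereEmbedding}.
#' @export
SphereEmbedding <- function(coords3, sampleIds = NULL, coords2 = NULL) {
    coords3 <- as.matrix(coords3)
    if (is.null(sampleIds))
        sampleIds <- rownames(coords3)
    if (is.null(sampleIds))
        sampleIds <- sprintf("sample%d", seq_len(nrow(coords3)))
    nrm <- sqrt(rowSums(coords3^2))
    if (any(nrm < 1e-12)) stop("zero-length embedding vector")
    coords3 <- coords3 / nrm
    dimnames(coords3) <- list(sampleIds, c("x3", "y3", "z3"))
    if (is.null(coords2))
        coords2 <- matrix(numeric(0), nrow = 0, ncol = 2)
    else {
        coords2 <- as.matrix(coords2)
        dimnames(coords2) <- list(sampleIds, c("x2", "y2"))
    }
    methods::new("SphereEmbedding", coords3 = coords3, coords2 = coords2,
                 sampleIds = as.character(sampleIds))
}

#' @describeIn SphereEmbedding the samples x 3 unit-sphere coordinates.
#' @param es a SphereEmbedding
#' @export
coords3 <- function(es) es@coords3

#' @describeIn SphereEmbedding the samples x 2 projected coordinates (empty
#'   matrix before \code{\link{projectEmbedding}} is applied).
#' @export
coords2 <- function(es) es@coords2

#' @export
setMethod("show", "SphereEmbedding", function(object) {
    cat("SphereEmbedding:", nrow(object@coords3), "samples on the unit sphere")
    cat(if (nrow(object@coords2)) ", 2D projection present\n" else
        ", no 2D projection\n")
})
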