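#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   colData<- rowData<-
#' @importFrom Rcpp evalCpp
#' @useDynLib popsphere, .registration = TRUE
NULL

.GENO_CODES <- c(-1L, 0L, 1L, 2L)

#' GenotypeData: diploid genotype calls with marker and sample annotation
#'
#' An S4 container for a diploid SNP genotype matrix coded as alternate-allele
#' counts 0/1/2 with -1 for missing calls. Built on
#' \linkS4class{SummarizedExperiment}: the \code{"calls"} assay holds markers in
#' rows and samples in columns, \code{rowData} carries marker annotation
#' (\code{chromosome}, \code{position}) and \code{colData} the optional
#' two-tier population labels (\code{subpopulation}, \code{superpopulation}).
#'
#' Use the \code{\link{GenotypeData}} constructor rather than \code{new()}; it
#' accepts the field-standard samples-by-markers orientation and transposes
#' internally.
#'
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- NULL
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        m <- SummarizedExperiment::assay(object, "calls")
        if (!is.numeric(m))
            msg <- c(msg, "'calls' must be numeric")
        else if (!all(m %in% .GENO_CODES))
            msg <- c(msg, "genotype calls must be in {0, 1, 2, -1}")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "marker ids must be unique")
    if (!all(c("chromosome", "position") %in%
             colnames(SummarizedExperiment::rowData(object))))
        msg <- c(msg, "rowData must have 'chromosome' and 'position'")
    sub <- SummarizedExperiment::colData(object)
    if (all(c("subpopulation", "superpopulation") %in% colnames(sub))) {
        ok <- !is.na(sub$subpopulation)
        if (any(ok)) {
            map <- unique(data.frame(sub = sub$subpopulation[ok],
                                     sup = sub$superpopulation[ok]))
            if (anyDuplicated(map$sub))
                msg <- c(msg, "each subpopulation must map to one superpopulation")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' SphereEmbedding: sample coordinates on the unit sphere
#'
#' Holds per-sample 3D unit-sphere coordinates produced by the encoder and,
#' once projected, the derived 2D Equal Earth coordinates.
#'
#' @slot coords3 numeric matrix, samples x 3, rows unit-norm.
#' @slot coords2 numeric matrix, samples x 2 (zero rows until projected).
#' @slot sampleIds character vector of sample identifiers.
#'
#' @aliases SphereEmbedding-class
#' @exportClass SphereEmbedding
setClass("SphereEmbedding",
    representation(coords3 = "matrix", coords2 = "matrix",
                   sampleIds = "character"))

setValidity("SphereEmbedding", function(object) {
    msg <- NULL
    if (ncol(object@coords3) != 3L)
        msg <- c(msg, "coords3 must have 3 columns")
    if (nrow(object@coords3) != length(object@sampleIds))
        msg <- c(msg, "coords3 rows must match sampleIds")
    if (nrow(object@coords3) > 0) {
        nrm <- sqrt(rowSums(object@coords3^2))
        if (any(abs(nrm - 1) > 1e-4))
            msg <- c(msg, "coords3 rows must be unit vectors")
    }
    if (nrow(object@coords2) > 0 && nrow(object@coords2) != nrow(object@coords3))
        msg <- c(msg, "coords2 rows must match coords3")
    if (is.null(msg)) TRUE else msg
})

#' GenotypeEncoder: convolutional encoder onto the 3D unit sphere
#'
#' Network weights and configuration for the encoder \eqn{f_E} mapping one-hot
#' genotype tensors (markers x 4 channels) to L2-normalized 3D embeddings.
#' Create with \code{\link{buildEncoder}}, train with \code{\link{trainEncoder}}.
#'
#' @slot params list of weight matrices/vectors (conv kernels, dense weights,
#'   batch-norm parameters and running statistics).
#' @slot config list, see \code{\link{encoderConfig}}.
#' @slot markerIds character, ids of the markers the encoder was built for.
#'
#' @aliases GenotypeEncoder-class
#' @exportClass GenotypeEncoder
setClass("GenotypeEncoder",
    representation(params = "list", config = "list", markerIds = "character"))
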