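#' Read two-tier population labels from a TSV file
#'
#' The file must have a header with columns \code{sample_id},
#' \code{subpopulation}, \code{superpopulation}. Duplicate sample ids and
#' subpopulations assigned to more than one superpopulation are errors.
#'
#' @param path path to the TSV file
#' @return data.frame with the three label columns.
#' @export
readLabels <- function(path) {
    labels <- utils::read.table(path, header = TRUE, sep = "\t",
                                colClasses = "character", quote = "")
    need <- c("sample_id", "subpopulation", "superpopulation")
    if (!all(need %in% colnames(labels)))
        stop("label file must have columns: ", paste(need, collapse = ", "))
    labels <- labels[, need]
    if (anyDuplicated(labels$sample_id))
        stop("duplicate sample ids in label file")
    map <- unique(labels[, c("subpopulation", "superpopulation")])
    if (anyDuplicated(map$subpopulation))
        stop("a subpopulation is listed under two superpopulations")
    labels
}

#' Write labels to TSV
#' @param labels data.frame as returned by \code{\link{readLabels}}
#' @param path output path
#' @export
writeLabels <- function(labels, path) {
    utils::write.table(labels, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an embedding (with optional labels) to TSV
#'
#' Writes one row per sample with columns \code{sample_id}, the 3D sphere
#' coordinates \code{x3,y3,z3}, the projected coordinates \code{x2,y2} (NA if
#' the embedding has not been projected) and the two label tiers (empty for
#' unlabeled samples). Coordinates are written with 12 significant digits and
#' round-trip through \code{\link{readEmbedding}} to within 1e-9.
#'
#' @param es a \linkS4class{SphereEmbedding}
#' @param path output path
#' @param labels optional data.frame with columns \code{sample_id},
#'   \code{subpopulation}, \code{superpopulation}
#' @return \code{path}, invisibly
#' @export
writeEmbedding <- function(es, path, labels = NULL) {
    n <- length(es@sampleIds)
    c2 <- if (nrow(es@coords2)) es@coords2 else
        matrix(NA_real_, nrow = n, ncol = 2)
    df <- data.frame(sample_id = es@sampleIds,
                     x3 = es@coords3[, 1], y3 = es@coords3[, 2],
                     z3 = es@coords3[, 3],
                     x2 = c2[, 1], y2 = c2[, 2],
                     subpopulation = rep("", n), superpopulation = rep("", n),
                     check.names = FALSE)
    if (!is.null(labels) && n > 0) {
        idx <- match(es@sampleIds, labels$sample_id)
        df$subpopulation <- ifelse(is.na(idx), "", labels$subpopulation[idx])
        df$superpopulation <- ifelse(is.na(idx), "", labels$superpopulation[idx])
    }
    num <- c("x3", "y3", "z3", "x2", "y2")
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 12,
                                                   format = "g"))
    df[num] <- lapply(df[num], function(x) ifelse(x == " NA" | x == "NA",
                                                  "", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an embedding TSV written by \code{\link{writeEmbedding}}
#'
#' @param path path to the TSV
#' @return list with elements \code{embedding} (a
#'   \linkS4class{SphereEmbedding}) and \code{labels} (data.frame, possibly
#'   with empty label strings).
#' @export
readEmbedding <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", rep("numeric", 5),
                                           "character", "character"),
                            quote = "", na.strings = "")
    c3 <- as.matrix(df[, c("x3", "y3", "z3")])
    c2 <- as.matrix(df[, c("x2", "y2")])
    if (nrow(df) == 0 || all(is.na(c2))) c2 <- NULL
    es <- if (nrow(df) == 0)
        methods::new("SphereEmbedding",
                     coords3 = matrix(numeric(0), 0, 3),
                     coords2 = matrix(numeric(0), 0, 2),
                     sampleIds = character(0))
    else SphereEmbedding(c3, sampleIds = df$sample_id, coords2 = c2)
    labels <- data.frame(sample_id = df$sample_id,
                         subpopulation = df$subpopulation,
                         superpopulation = df$superpopulation)
    list(embedding = es, labels = labels)
}
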