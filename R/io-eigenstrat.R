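## EIGENSTRAT unpacked text format: .geno has one row per marker, one digit
## per sample (0/1/2, 9 = missing); .snp has marker id, chromosome, genetic
## position, physical position; .ind has sample id, sex, population.

#' Read an EIGENSTRAT fileset
#'
#' Reads the unpacked text variant of the EIGENSTRAT format (one digit string
#' per marker in the .geno file, 9 coding missing calls, remapped to -1).
#'
#' @param genoPath,snpPath,indPath paths to the .geno/.snp/.ind files.
#' @return A \linkS4class{GenotypeData}.
#' @export
readEigenstrat <- function(genoPath, snpPath, indPath) {
    for (f in c(genoPath, snpPath, indPath))
        if (!file.exists(f)) stop("file not found: ", f)
    snp <- utils::read.table(snpPath, header = FALSE, colClasses = "character")
    if (ncol(snp) < 4) stop("malformed .snp file")
    ind <- utils::read.table(indPath, header = FALSE, colClasses = "character")
    rows <- readLines(genoPath)
    rows <- rows[nzchar(rows)]
    n <- nrow(ind); d <- nrow(snp)
    if (length(rows) != d)
        stop("dimension mismatch: ", length(rows), " genotype rows for ",
             d, " markers in .snp")
    if (any(nchar(rows) != n))
        stop("dimension mismatch: genotype row length differs from the ",
             n, " samples in .ind")
    flat <- unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE)
    if (!all(flat %in% c("0", "1", "2", "9")))
        stop("non-genotype characters in .geno (expected digits 0/1/2/9)")
    vals <- c(`0` = 0L, `1` = 1L, `2` = 2L, `9` = -1L)[flat]
    calls <- matrix(vals, nrow = n)             # samples x markers (col-major)
    GenotypeData(calls,
                 markers = data.frame(id = snp[[1]], chromosome = snp[[2]],
                                      position = as.integer(snp[[4]])),
                 sampleIds = ind[[1]])
}

#' Write a GenotypeData object in EIGENSTRAT format
#'
#' @param gd a \linkS4class{GenotypeData}
#' @param prefix output path prefix; \code{<prefix>.geno/.snp/.ind} are written.
#' @return \code{prefix}, invisibly.
#' @export
writeEigenstrat <- function(gd, prefix) {
    calls <- genotypeCalls(gd)
    calls[calls == -1L] <- 9L
    rows <- apply(calls, 2, paste, collapse = "")  # one row per marker
    writeLines(rows, paste0(prefix, ".geno"))
    mk <- markerInfo(gd)
    utils::write.table(data.frame(mk$id, mk$chromosome, 0, mk$position),
                       paste0(prefix, ".snp"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(sampleIds(gd), "U", "Ignore"),
                       paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(prefix)
}
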