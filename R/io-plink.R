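## PLINK 1.9 binary trio (.bed SNP-major / .bim / .fam).
## Two-bit codes in the .bed: 00 = homozygous A1, 01 = missing, 10 = het,
## 11 = homozygous A2. A1 is taken as the alternate allele, so calls are
## 00 -> 2, 10 -> 1, 11 -> 0, 01 -> -1.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))

#' Read a PLINK binary fileset
#'
#' Reads a SNP-major PLINK 1.9 binary trio into a
#' \linkS4class{GenotypeData} object. The two-bit genotype codes are mapped to
#' alternate-allele (A1) counts, with missing calls set to -1. Marker order
#' follows the .bim file.
#'
#' @param bedPath,bimPath,famPath paths to the .bed/.bim/.fam files. If
#'   \code{bimPath}/\code{famPath} are missing they are derived from
#'   \code{bedPath} by extension replacement.
#' @return A \linkS4class{GenotypeData}.
#' @seealso \code{\link{writePlink}}
#' @export
readPlink <- function(bedPath, bimPath = NULL, famPath = NULL) {
    if (is.null(bimPath)) bimPath <- sub("\\.bed$", ".bim", bedPath)
    if (is.null(famPath)) famPath <- sub("\\.bed$", ".fam", bedPath)
    for (f in c(bedPath, bimPath, famPath))
        if (!file.exists(f)) stop("file not found: ", f)
    bim <- utils::read.table(bimPath, header = FALSE,
                             colClasses = c("character", "character", "numeric",
                                            "integer", "character", "character"))
    colnames(bim) <- c("chromosome", "id", "cm", "position", "a1", "a2")
    fam <- utils::read.table(famPath, header = FALSE, colClasses = "character")
    if (ncol(fam) < 2) stop("malformed .fam file")
    n <- nrow(fam); d <- nrow(bim)
    raw <- readBin(bedPath, "raw", n = file.size(bedPath))
    if (length(raw) < 3 || !identical(raw[1:2], .BED_MAGIC))
        stop("not a PLINK .bed file (bad magic bytes)")
    if (as.integer(raw[3]) != 1L)
        stop("only SNP-major .bed files are supported")
    bpm <- ceiling(n / 4)                       # bytes per marker
    body <- raw[-(1:3)]
    if (length(body) != bpm * d)
        stop("dimension mismatch: .bed payload is ", length(body),
             " bytes but .bim/.fam imply ", bpm * d)
    ## decode all two-bit fields at once via a 256 x 4 lookup table
    lut <- sapply(0:3, function(s) {
        code <- bitwAnd(bitwShiftR(0:255, 2L * s), 3L)
        c(2L, -1L, 1L, 0L)[code + 1L]
    })
    vals <- matrix(lut[cbind(rep(as.integer(body) + 1L, each = 4L),
                             rep(1:4, length(body)))], nrow = 4L * bpm)
    calls <- vals[seq_len(n), , drop = FALSE]      # samples x markers
    GenotypeData(calls,
                 markers = bim[, c("id", "chromosome", "position")],
                 sampleIds = fam[[2]])
}

#' Write a GenotypeData object as a PLINK binary fileset
#'
#' @param gd a \linkS4class{GenotypeData}
#' @param prefix output path prefix; \code{<prefix>.bed/.bim/.fam} are written.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(gd, prefix) {
    calls <- genotypeCalls(gd)                  # samples x markers
    n <- nrow(calls); d <- ncol(calls)
    mk <- markerInfo(gd)
    utils::write.table(
        data.frame(mk$chromosome, mk$id, 0, mk$position, "A", "B"),
        paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    utils::write.table(
        data.frame(sampleIds(gd), sampleIds(gd), 0, 0, 0, -9),
        paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    code <- matrix(c(3L, 2L, 0L, 1L)[match(calls, c(0L, 1L, 2L, -1L))],
                   nrow = n)                    # two-bit codes per sample
    bpm <- ceiling(n / 4)
    pad <- matrix(0L, nrow = 4L * bpm, ncol = d)
    pad[seq_len(n), ] <- code
    shift <- rep(c(1L, 4L, 16L, 64L), bpm)
    bytes <- rowsum(pad * shift, group = rep(seq_len(bpm), each = 4L))
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(c(.BED_MAGIC, as.raw(1L)), con)
    writeBin(as.raw(bytes), con)
    invisible(prefix)
}
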