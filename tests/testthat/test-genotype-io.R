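test_that("GenotypeData validates calls and label consistency", {
    expect_error(GenotypeData(matrix(c(0L, 3L), 1)), "0, 1, 2, -1")
    gm <- makeGenotypeFixture(4, 6)
    expect_identical(dim(genotypeCalls(gm)), c(4L, 6L))
    labs <- data.frame(sample_id = c("s1", "s2"),
                       subpopulation = c("a", "a"),
                       superpopulation = c("A", "B"))
    expect_error(setLabels(gm, labs), "two superpopulations")
    labs$superpopulation <- "A"
    expect_message(gm2 <- setLabels(gm, labs), "no label")
    expect_identical(unname(subpopulation(gm2)[1:2]), c("a", "a"))
})

test_that("PLINK binary trio round-trips, including missing calls", {
    gm <- makeGenotypeFixture(5, 7, missingFrac = 0.2)
    prefix <- file.path(tempdir(), "rt")
    writePlink(gm, prefix)
    back <- readPlink(paste0(prefix, ".bed"))
    expect_identical(genotypeCalls(back), genotypeCalls(gm))
    expect_identical(markerInfo(back)$chromosome, markerInfo(gm)$chromosome)
    expect_identical(sampleIds(back), sampleIds(gm))
    expect_true(any(genotypeCalls(back) == -1L))
})

test_that("PLINK reader rejects malformed filesets", {
    gm <- makeGenotypeFixture(4, 5)
    prefix <- file.path(tempdir(), "bad")
    writePlink(gm, prefix)
    ## corrupt magic bytes
    raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
    writeBin(c(as.raw(c(0, 0)), raw[-(1:2)]), paste0(prefix, "m.bed"))
    file.copy(paste0(prefix, ".bim"), paste0(prefix, "m.bim"), overwrite = TRUE)
    file.copy(paste0(prefix, ".fam"), paste0(prefix, "m.fam"), overwrite = TRUE)
    expect_error(readPlink(paste0(prefix, "m.bed")), "magic")
    ## sample count inconsistent with payload
    fam <- read.table(paste0(prefix, ".fam"))
    write.table(rbind(fam, fam), paste0(prefix, ".fam"), row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    expect_error(readPlink(paste0(prefix, ".bed")), "dimension mismatch")
})

test_that("EIGENSTRAT text format round-trips and maps 9 to missing", {
    gm <- makeGenotypeFixture(4, 6, missingFrac = 0.25)
    prefix <- file.path(tempdir(), "es")
    writeEigenstrat(gm, prefix)
    back <- readEigenstrat(paste0(prefix, ".geno"), paste0(prefix, ".snp"),
                           paste0(prefix, ".ind"))
    expect_identical(genotypeCalls(back), genotypeCalls(gm))

    ## literal row decoding: "0129" over 4 samples
    writeLines(c("0129"), paste0(prefix, "2.geno"))
    write.table(data.frame("m1", "1", 0, 10), paste0(prefix, "2.snp"),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    write.table(data.frame(paste0("i", 1:4), "U", "pop"),
                paste0(prefix, "2.ind"), row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    g <- readEigenstrat(paste0(prefix, "2.geno"), paste0(prefix, "2.snp"),
                        paste0(prefix, "2.ind"))
    expect_identical(as.vector(genotypeCalls(g)), c(0L, 1L, 2L, -1L))

    ## ragged rows and non-digit characters are format errors
    writeLines(c("012x"), paste0(prefix, "2.geno"))
    expect_error(readEigenstrat(paste0(prefix, "2.geno"),
                                paste0(prefix, "2.snp"),
                                paste0(prefix, "2.ind")), "non-genotype")
    writeLines(c("012"), paste0(prefix, "2.geno"))
    expect_error(readEigenstrat(paste0(prefix, "2.geno"),
                                paste0(prefix, "2.snp"),
                                paste0(prefix, "2.ind")), "dimension")
})

test_that("label TSV reading enforces uniqueness and tier consistency", {
    path <- file.path(tempdir(), "labels.tsv")
    labs <- data.frame(sample_id = c("s1", "s2", "s3"),
                       subpopulation = c("PoodleToy", "PoodleToy", "Boxer"),
                       superpopulation = c("Poodle", "Poodle", "Working"))
    writeLabels(labs, path)
    expect_identical(readLabels(path), labs)
    writeLabels(labs[c(1, 1, 3), ], path)
    expect_error(readLabels(path), "duplicate")
    labs$superpopulation[2] <- "Working"
    writeLabels(labs, path)
    expect_error(readLabels(path), "two superpopulations")
})

test_that("sex-chromosome filter removes exactly the named chromosomes", {
    calls <- matrix(0L, 2, 5)
    gm <- GenotypeData(calls, markers = data.frame(
        id = paste0("m", 1:5), chromosome = c("1", "1", "2", "X", "Y"),
        position = 1:5))
    out <- filterSexChromosomes(gm, c("X", "Y"))
    expect_identical(markerInfo(out)$chromosome, c("1", "1", "2"))
    expect_identical(sampleIds(out), sampleIds(gm))
    ## empty label set is the identity
    expect_identical(dim(filterSexChromosomes(gm, character(0))), dim(gm))
    expect_identical(sexChromosomes("dog"), c("X", "Y", "39", "40"))
})

test_that("MAF filter uses allele frequency over non-missing calls", {
    ## column (0,0,0,0,1): f = 1/10, MAF 0.1, kept at threshold 0.01
    calls <- cbind(c(0L, 0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L, 0L),
                   c(1L, 1L, 1L, 1L, 1L), c(2L, 2L, -1L, -1L, -1L))
    gm <- GenotypeData(calls)
    expect_equal(unname(markerMAF(gm)), c(0.1, 0, 0.5, 0))
    kept <- mafFilter(gm, 0.01)
    expect_identical(markerInfo(kept)$id, c("snp1", "snp3"))
    ## threshold 0 keeps every marker with at least one non-missing call
    expect_identical(nrow(mafFilter(gm, 0)), 4L)
    ## all-missing markers are always dropped
    calls2 <- cbind(calls, rep(-1L, 5))
    expect_message(out <- mafFilter(GenotypeData(calls2), 0),
                   "all calls missing")
    expect_identical(nrow(out), 4L)
})

test_that("sex and MAF filters commute on complete data", {
    set.seed(9)
    gm <- makeGenotypeFixture(20, 40, seed = 9)
    a <- mafFilter(filterSexChromosomes(gm, "2"), 0.1)
    b <- filterSexChromosomes(mafFilter(gm, 0.1), "2")
    expect_identical(markerInfo(a), markerInfo(b))
    expect_true(all(markerMAF(a) >= 0.1))
})

test_that("mode imputation fills from the reference with ties toward 0", {
    gm <- GenotypeData(rbind(c(-1L, -1L, 2L), c(0L, -1L, -1L)))
    ref <- GenotypeData(rbind(c(0L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 0L),
                              c(2L, 0L, 0L)))
    ## marker modes: col1 -> 0; col2 tie (0,0 vs 1,1) -> 0; col3 tie -> 0
    out <- modeImpute(gm, ref)
    expect_identical(genotypeCalls(out),
                     matrix(c(0L, 0L, 0L, 0L, 2L, 0L), nrow = 2,
                            dimnames = dimnames(genotypeCalls(gm))))
    ## no missing calls: identity
    expect_identical(genotypeCalls(modeImpute(ref)), genotypeCalls(ref))
    ## entirely missing reference marker imputes 0 with a message
    ref2 <- GenotypeData(rbind(c(-1L, 0L, 1L), c(-1L, 1L, 1L)))
    gm2 <- GenotypeData(rbind(c(-1L, 0L, 1L), c(0L, 0L, 1L)))
    expect_message(out2 <- modeImpute(gm2, ref2), "imputed 0")
    expect_identical(unname(genotypeCalls(out2)[1, 1]), 0L)
})

test_that("embedding TSV round-trips coordinates and labels", {
    z <- randomUnitVectors(4, seed = 3)
    es <- projectEmbedding(SphereEmbedding(z, sampleIds = paste0("s", 1:4)))
    labs <- data.frame(sample_id = c("s1", "s2"),
                       subpopulation = c("a", "b"),
                       superpopulation = c("A", "B"))
    path <- file.path(tempdir(), "emb.tsv")
    writeEmbedding(es, path, labs)
    back <- readEmbedding(path)
    expect_lt(max(abs(coords3(back$embedding) - coords3(es))), 1e-9)
    expect_lt(max(abs(coords2(back$embedding) - coords2(es))), 1e-9)
    expect_identical(back$labels$subpopulation[3], NA_character_)
    ## empty embedding writes a header-only file
    es0 <- new("SphereEmbedding", coords3 = matrix(numeric(0), 0, 3),
               coords2 = matrix(numeric(0), 0, 2), sampleIds = character(0))
    writeEmbedding(es0, path)
    expect_identical(length(readLines(path)), 1L)
})
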