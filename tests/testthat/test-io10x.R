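write_trio <- function(dir, mtxLines, genes, barcodes, meta = NULL) {
    dir.create(dir, showWarnings = FALSE)
    writeLines(mtxLines, file.path(dir, "matrix.mtx"))
    writeLines(genes, file.path(dir, "features.tsv"))
    writeLines(barcodes, file.path(dir, "barcodes.tsv"))
    if (is.null(meta))
        meta <- data.frame(barcode = barcodes, sample = "s1",
                           condition = "c1")
    utils::write.table(meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                     "cell_meta.tsv"))
}

read_trio <- function(paths) readTenx(paths[1], paths[2], paths[3], paths[4])

test_that("triplet entries land at their coordinates, absent entries are zero", {
    header <- c("%%MatrixMarket matrix coordinate integer general", "3 2 2")
    paths <- write_trio(withr::local_tempdir(),
                        c(header, "1 1 5", "3 2 2"),
                        c("gA", "gB", "gC"), c("b1", "b2"))
    sce <- read_trio(paths)
    expect_identical(unname(as.matrix(assay(sce, "counts"))),
                     matrix(c(5, 0, 0, 0, 0, 2), nrow = 3))
    expect_identical(rownames(sce), c("gA", "gB", "gC"))
    expect_identical(colData(sce)$condition, rep("c1", 2))

    empty <- write_trio(withr::local_tempdir(),
                        c("%%MatrixMarket matrix coordinate integer general",
                          "3 2 0"),
                        c("gA", "gB", "gC"), c("b1", "b2"))
    expect_true(all(assay(read_trio(empty), "counts") == 0))
})

test_that("malformed inputs are rejected with format errors", {
    hdr <- "%%MatrixMarket matrix coordinate integer general"
    d <- withr::local_tempdir()
    expect_error(read_trio(write_trio(d, c(hdr, "3 2 0"),
                                      c("gA", "gB"), c("b1", "b2"))),
                 "features")
    expect_error(read_trio(write_trio(d, c(hdr, "2 2 0"),
                                      c("gA", "gB"), c("b1"))),
                 "barcodes")
    expect_error(read_trio(write_trio(d, c(hdr, "2 2 1", "1 1 -3"),
                                      c("gA", "gB"), c("b1", "b2"))),
                 "negative")
    expect_error(read_trio(write_trio(
        d, c("%%MatrixMarket matrix coordinate real general",
             "2 2 1", "1 1 2.5"),
        c("gA", "gB"), c("b1", "b2"))), "non-integer")
    expect_error(read_trio(write_trio(d, c(hdr, "2 2 0"),
                                      c("gA", "gB"), c("b1", "b1"))),
                 "[Dd]uplicate")
    meta <- data.frame(barcode = "b1", sample = "s1", condition = "c1")
    expect_error(read_trio(write_trio(d, c(hdr, "2 2 0"),
                                      c("gA", "gB"), c("b1", "b2"),
                                      meta = meta)),
                 "without metadata")
})

test_that("write/read round trip is the identity and conserves mass", {
    cfg <- test_sim_config(seed = 5, nCells = c(young_sham = 60L,
                                                aged_stroke = 40L))
    sce <- simulateCells(cfg)
    d <- withr::local_tempdir()
    paths <- writeTenx(sce, d)
    back <- readTenx(paths["matrix"], paths["features"],
                     paths["barcodes"], paths["meta"])
    expect_identical(as.matrix(assay(back, "counts")),
                     as.matrix(assay(sce, "counts")))
    expect_identical(rownames(back), rownames(sce))
    expect_identical(colnames(back), colnames(sce))
    expect_identical(colData(back)$condition, colData(sce)$condition)
    expect_identical(colData(back)$sample, colData(sce)$sample)

    # conservation: total mass equals the sum of the triplet values
    body <- readLines(paths["matrix"])[-(1:2)]
    expect_equal(sum(as.numeric(vapply(strsplit(body, " "), `[`, "", 3))),
                 sum(assay(sce, "counts")))

    # nnz bookkeeping: one data line per nonzero entry
    one <- toy_sce(matrix(c(0, 7, 0, 0), nrow = 2))
    p1 <- writeTenx(one, file.path(d, "one"))
    lines1 <- readLines(p1["matrix"])
    expect_length(lines1, 3L)
    expect_identical(lines1[2], "2 2 1")
    zero <- toy_sce(matrix(0L, nrow = 2, ncol = 2))
    p0 <- writeTenx(zero, file.path(d, "zero"))
    expect_identical(readLines(p0["matrix"])[2], "2 2 0")
})

test_that("signature tables round trip and reject duplicates", {
    d <- withr::local_tempdir()
    path <- file.path(d, "sigs.tsv")
    writeLines(c("set_name\tgene", "DAM\tLpl", "DAM\tSpp1", "homeo\tHexb"),
               path)
    s <- readSignatures(path)
    expect_identical(names(s), c("DAM", "homeo"))
    expect_identical(s[["DAM"]], c("Lpl", "Spp1"))

    out <- file.path(d, "roundtrip.tsv")
    writeSignatures(s, out)
    expect_identical(geneSets(readSignatures(out)), geneSets(s))

    writeLines(c("set_name\tgene", "DAM\tLpl", "DAM\tLpl"), path)
    expect_error(readSignatures(path), "duplicated")
    writeLines("set_name\tgene", path)
    expect_error(readSignatures(path), "empty")
})
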