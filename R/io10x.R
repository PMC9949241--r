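#' @importFrom Matrix readMM sparseMatrix colSums rowSums t which
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assay<- colData colData<- rowData
NULL

.open_maybe_gz <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else path
}

.read_lines_maybe_gz <- function(path) {
    con <- .open_maybe_gz(path)
    if (is.character(con)) return(readLines(con))
    on.exit(close(con))
    readLines(con)
}

#' Read a 10x-convention count matrix triplet plus cell metadata
#'
#' Reads a MatrixMarket coordinate integer matrix (genes as rows, cells as
#' columns), one-entry-per-line feature and barcode files, and a
#' tab-delimited cell metadata table with columns \code{barcode},
#' \code{sample} and \code{condition}. All files may be gzip-compressed.
#' Entries absent from the triplet file are zero.
#'
#' @param matrixPath Path to the \code{.mtx} (or \code{.mtx.gz}) file.
#' @param featuresPath Path to the feature (gene symbol) file, one per line.
#' @param barcodesPath Path to the barcode file, one per line.
#' @param metaPath Path to the cell metadata TSV. Every barcode must appear
#'   exactly once; unmatched barcodes are an error, not a silent drop.
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   sparse integer \code{counts} assay, gene symbols as row names,
#'   barcodes as column names, and \code{sample}/\code{condition} columns
#'   in \code{colData}.
#' @seealso \code{\link{writeTenx}} for the inverse operation.
#' @export
readTenx <- function(matrixPath, featuresPath, barcodesPath, metaPath) {
    m <- Matrix::readMM(.open_maybe_gz(matrixPath))
    genes <- .read_lines_maybe_gz(featuresPath)
    barcodes <- .read_lines_maybe_gz(barcodesPath)
    genes <- genes[nzchar(genes)]
    barcodes <- barcodes[nzchar(barcodes)]
    if (nrow(m) != length(genes))
        stop("matrix has ", nrow(m), " rows but ", length(genes),
             " features were supplied", call. = FALSE)
    if (ncol(m) != length(barcodes))
        stop("matrix has ", ncol(m), " columns but ", length(barcodes),
             " barcodes were supplied", call. = FALSE)
    if (anyDuplicated(barcodes))
        stop("duplicate barcodes in ", barcodesPath, call. = FALSE)
    v <- m@x
    if (any(v < 0))
        stop("count matrix contains negative entries", call. = FALSE)
    if (any(v != round(v)))
        stop("count matrix contains non-integer entries", call. = FALSE)
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, barcodes)

    meta <- utils::read.delim(metaPath, header = TRUE,
                              colClasses = "character")
    need <- c("barcode", "sample", "condition")
    if (!all(need %in% colnames(meta)))
        stop("cell metadata must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
    if (anyDuplicated(meta$barcode))
        stop("duplicate barcodes in cell metadata", call. = FALSE)
    idx <- match(barcodes, meta$barcode)
    if (anyNA(idx)) {
        missing <- barcodes[is.na(idx)]
        stop("barcodes without metadata: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ..." else "", call. = FALSE)
    }
    cd <- DataFrame(sample = meta$sample[idx],
                    condition = meta$condition[idx],
                    row.names = barcodes)
    SingleCellExperiment(assays = list(counts = m), colData = cd)
}

.write_mtx_int <- function(m, path) {
    tm <- methods::as(m, "TsparseMatrix")
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 paste(nrow(m), ncol(m), length(tm@x))), con)
    if (length(tm@x)) {
        o <- order(tm@j, tm@i)
        writeLines(paste(tm@i[o] + 1L, tm@j[o] + 1L,
                         format(tm@x[o], scientific = FALSE, trim = TRUE)),
                   con)
    }
    invisible(path)
}

#' Write a count experiment as a 10x-convention triplet plus metadata
#'
#' Writes \code{matrix.mtx} (MatrixMarket coordinate integer, genes as
#' rows), \code{features.tsv}, \code{barcodes.tsv} and \code{cell_meta.tsv}
#' into a directory. The round trip through \code{\link{readTenx}} is
#' lossless (values, gene order, barcode order, metadata).
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay and
#'   \code{sample}/\code{condition} columns in \code{colData}.
#' @param dirPath Output directory; created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
writeTenx <- function(sce, dirPath) {
    if (!dir.exists(dirPath))
        dir.create(dirPath, recursive = TRUE)
    if (!dir.exists(dirPath))
        stop("cannot create output directory ", dirPath, call. = FALSE)
    m <- assay(sce, "counts")
    paths <- c(matrix = file.path(dirPath, "matrix.mtx"),
               features = file.path(dirPath, "features.tsv"),
               barcodes = file.path(dirPath, "barcodes.tsv"),
               meta = file.path(dirPath, "cell_meta.tsv"))
    .write_mtx_int(m, paths["matrix"])
    writeLines(rownames(sce), paths["features"])
    writeLines(colnames(sce), paths["barcodes"])
    meta <- data.frame(barcode = colnames(sce),
                       sample = colData(sce)$sample,
                       condition = colData(sce)$condition)
    utils::write.table(meta, paths["meta"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}

#' Read gene signatures from a two-column table
#'
#' The file is tab-delimited with header columns \code{set_name} and
#' \code{gene}; within-set gene order is preserved.
#'
#' @param path Path to the signatures TSV.
#' @return A \linkS4class{SignatureSet}.
#' @export
readSignatures <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
    if (!all(c("set_name", "gene") %in% colnames(tab)))
        stop("signature table must have columns set_name, gene",
             call. = FALSE)
    if (nrow(tab) == 0L)
        stop("signature table is empty", call. = FALSE)
    if (anyDuplicated(tab[, c("set_name", "gene")]))
        stop("duplicated (set_name, gene) pair in signature table",
             call. = FALSE)
    sets <- split(tab$gene, factor(tab$set_name, levels = unique(tab$set_name)))
    SignatureSet(as.list(sets))
}

#' Write gene signatures to a two-column table
#'
#' @param sigs A \linkS4class{SignatureSet}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSignatures <- function(sigs, path) {
    sets <- geneSets(sigs)
    tab <- data.frame(
        set_name = rep(names(sets), lengths(sets)),
        gene = unlist(sets, use.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
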