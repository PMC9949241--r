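#' @importFrom Matrix Diagonal rowMeans
NULL

.logcounts <- function(sce) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
        stop("no 'logcounts' assay; run logNormalizeCells() first",
             call. = FALSE)
    assay(sce, "logcounts")
}

#' Score cells against marker-gene signatures
#'
#' A cell's score for a signature is the mean, over the signature's genes
#' present in the matrix, of the gene's z-scored log-normalized expression
#' (z computed across all cells, so scores are comparable between
#' condition groups). Genes with zero variance contribute 0; signature
#' genes absent from the matrix are dropped with a warning; a signature
#' with no present genes is an error naming the signature.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param sigs A \linkS4class{SignatureSet}.
#' @return Numeric matrix, cells x signatures.
#' @export
scoreSignatures <- function(sce, sigs) {
    stopifnot(is(sigs, "SignatureSet"))
    v <- .logcounts(sce)
    sets <- geneSets(sigs)
    present <- lapply(sets, intersect, rownames(v))
    empty <- names(sets)[lengths(present) == 0L]
    if (length(empty))
        stop("signature(s) with no genes in the matrix: ",
             paste(empty, collapse = ", "), call. = FALSE)
    dropped <- sum(lengths(sets)) - sum(lengths(present))
    if (dropped > 0L)
        warning(dropped, " signature gene(s) absent from the matrix were dropped")

    used <- unique(unlist(present, use.names = FALSE))
    x <- as.matrix(v[used, , drop = FALSE])
    mu <- rowMeans(x)
    sd <- sqrt(rowMeans((x - mu)^2) * ncol(x) / max(1L, ncol(x) - 1L))
    z <- (x - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0

    scores <- vapply(present,
                     function(g) colMeans(z[g, , drop = FALSE]),
                     numeric(ncol(x)))
    rownames(scores) <- colnames(v)
    scores
}

#' Assign a cell-type label from signature scores
#'
#' Each cell is labelled with the signature of its maximal score, provided
#' that score reaches \code{minScore}; otherwise the cell is
#' \code{"Unassigned"}. Ties are broken by the lexicographically smallest
#' signature name so the assignment is deterministic.
#'
#' @param scores Cells x signatures score matrix from
#'   \code{\link{scoreSignatures}}.
#' @param minScore Minimum winning score for assignment (default 0).
#' @return A \code{DataFrame} with per-cell \code{label}, winning
#'   \code{score} and \code{margin} over the runner-up.
#' @export
assignTypes <- function(scores, minScore = 0) {
    sigNames <- colnames(scores)
    ord <- order(sigNames)
    s <- scores[, ord, drop = FALSE]
    best <- max.col(s, ties.method = "first")  # columns sorted, so first = lexicographic
    win <- s[cbind(seq_len(nrow(s)), best)]
    runner <- vapply(seq_len(nrow(s)), function(i) {
        if (ncol(s) == 1L) return(-Inf)
        max(s[i, -best[i]])
    }, numeric(1))
    label <- colnames(s)[best]
    label[win < minScore] <- "Unassigned"
    DataFrame(label = label, score = win, margin = win - runner,
              row.names = rownames(scores))
}

#' Cell-type composition per condition
#'
#' Counts and percentages of each label within each condition; the
#' percentages of a condition sum to 100 (conditions without cells yield
#' zero-count rows with NA percentages rather than a division error).
#'
#' @param labels Character vector of per-cell labels (or the
#'   \code{DataFrame} returned by \code{\link{assignTypes}}).
#' @param condition Character or factor vector of per-cell conditions;
#'   factor levels define the reported condition set.
#' @return A \code{data.frame} with columns \code{condition}, \code{label},
#'   \code{n} and \code{pct}.
#' @export
cellComposition <- function(labels, condition) {
    if (is(labels, "DataFrame")) labels <- labels$label
    stopifnot(length(labels) == length(condition))
    condition <- as.factor(condition)
    labels <- factor(labels, levels = sort(unique(labels)))
    tab <- table(condition = condition, label = labels)
    out <- as.data.frame(tab, responseName = "n",
                         stringsAsFactors = FALSE)
    totals <- rowSums(tab)[out$condition]
    out$pct <- ifelse(totals > 0, 100 * out$n / totals, NA_real_)
    out[order(out$condition, out$label), , drop = FALSE]
}

#' Write cell annotations to a TSV
#'
#' @param ann \code{DataFrame} from \code{\link{assignTypes}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotations <- function(ann, path) {
    tab <- data.frame(barcode = rownames(ann), label = ann$label,
                      score = sprintf("%.6g", ann$score),
                      margin = sprintf("%.6g", ann$margin))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
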