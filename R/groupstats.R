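.resolve_cells <- function(sce, cells) {
    if (is.logical(cells)) {
        stopifnot(length(cells) == ncol(sce))
        which(cells)
    } else if (is.character(cells)) {
        idx <- match(cells, colnames(sce))
        if (anyNA(idx)) stop("unknown barcodes in cell selection",
                             call. = FALSE)
        idx
    } else {
        as.integer(cells)
    }
}

.check_gene <- function(sce, gene) {
    if (!all(gene %in% rownames(sce)))
        stop("gene(s) not in matrix: ",
             paste(setdiff(gene, rownames(sce)), collapse = ", "),
             call. = FALSE)
    gene
}

#' Group means of log-normalized expression
#'
#' Arithmetic mean of the log-normalized values over each group's cells,
#' per gene. Groups must be disjoint and non-empty.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param cellsA,cellsB Logical masks, barcodes or indices selecting the
#'   two groups.
#' @param genes Genes to report (default: all).
#' @return A \code{data.frame} with columns \code{gene}, \code{mean_a},
#'   \code{mean_b}.
#' @export
groupMeans <- function(sce, cellsA, cellsB, genes = rownames(sce)) {
    a <- .resolve_cells(sce, cellsA)
    b <- .resolve_cells(sce, cellsB)
    if (!length(a) || !length(b))
        stop("both groups must be non-empty", call. = FALSE)
    if (length(intersect(a, b)))
        stop("groups must be disjoint", call. = FALSE)
    v <- .logcounts(sce)[.check_gene(sce, genes), , drop = FALSE]
    data.frame(gene = genes,
               mean_a = Matrix::rowMeans(v[, a, drop = FALSE]),
               mean_b = Matrix::rowMeans(v[, b, drop = FALSE]),
               row.names = NULL)
}

#' Fraction of cells expressing a gene
#'
#' The dot-plot convention: the fraction of cells in the group with a raw
#' count greater than zero.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param cells Logical mask, barcodes or indices selecting the group
#'   (must be non-empty).
#' @param gene Gene symbol(s).
#' @return Numeric vector of fractions in [0, 1], one per gene.
#' @export
pctExpressing <- function(sce, cells, gene) {
    idx <- .resolve_cells(sce, cells)
    if (!length(idx)) stop("cell group is empty", call. = FALSE)
    m <- assay(sce, "counts")[.check_gene(sce, gene), idx, drop = FALSE]
    Matrix::rowSums(m > 0) / length(idx)
}

#' Fold change from an average log2 fold change
#'
#' The output convention pairing an \code{avg_logfc} column with a linear
#' fold change: \code{fc = 2^avg_logfc}.
#'
#' @param avgLogFC Numeric vector of average log fold changes (base 2).
#' @return \code{2^avgLogFC}.
#' @examples
#' foldChange(c(0.84, 0.65))  # 1.79, 1.57 at two decimals
#' @export
foldChange <- function(avgLogFC) 2^avgLogFC

#' Wilcoxon rank-sum test (Mann-Whitney U)
#'
#' Computes the U statistic for the first sample via midranks. For small
#' tie-free samples (\code{min(n, m) <= 8}) the two-sided p-value is exact
#' (from the exact U distribution); otherwise it uses the normal
#' approximation with tie correction and continuity correction. Identical
#' samples give p = 1.
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @return A list with elements \code{statistic} (U for \code{x}) and
#'   \code{p.value}.
#' @examples
#' wilcoxRankSum(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
#' @export
wilcoxRankSum <- function(x, y) {
    n <- length(x); m <- length(y)
    stopifnot(n >= 1L, m >= 1L)
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    ties <- table(pooled)
    hasTies <- any(ties > 1L)

    if (!hasTies && min(n, m) <= 8L) {
        p <- 2 * min(stats::pwilcox(U, n, m),
                     stats::pwilcox(U - 1, n, m, lower.tail = FALSE))
        return(list(statistic = U, p.value = min(1, p)))
    }
    N <- n + m
    mu <- n * m / 2
    sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0)
        return(list(statistic = U, p.value = 1))
    z <- U - mu
    z <- z - sign(z) * 0.5  # continuity correction
    p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
    list(statistic = U, p.value = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin wrapper around
#' \code{stats::p.adjust(..., method = "BH")} kept as the package's single
#' named multiple-testing entry point.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, capped at 1.
#' @export
bhAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    stats::p.adjust(p, method = "BH")
}

#' Differential-expression statistics between two cell groups
#'
#' The FindMarkers-style per-gene table behind the pipeline's contrasts:
#' group means of log-normalized expression, fractions of cells
#' expressing, \code{avg_logfc = mean_b - mean_a}, the paired linear fold
#' change \code{2^avg_logfc}, a two-sided Wilcoxon rank-sum p-value on the
#' log-normalized values, and its Benjamini-Hochberg adjustment.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param cellsA,cellsB Disjoint, non-empty cell selections (reference
#'   group A, comparison group B).
#' @param genes Genes to test (default: all).
#' @return A \code{data.frame} with columns \code{gene}, \code{mean_a},
#'   \code{mean_b}, \code{pct_a}, \code{pct_b}, \code{avg_logfc},
#'   \code{fold_change}, \code{p}, \code{p_adj}.
#' @export
groupStats <- function(sce, cellsA, cellsB, genes = rownames(sce)) {
    a <- .resolve_cells(sce, cellsA)
    b <- .resolve_cells(sce, cellsB)
    gm <- groupMeans(sce, a, b, genes)
    v <- .logcounts(sce)
    pv <- vapply(genes, function(g) {
        wilcoxRankSum(as.numeric(v[g, a]), as.numeric(v[g, b]))$p.value
    }, numeric(1))
    out <- data.frame(
        gene = genes,
        mean_a = gm$mean_a, mean_b = gm$mean_b,
        pct_a = pctExpressing(sce, a, genes),
        pct_b = pctExpressing(sce, b, genes),
        avg_logfc = gm$mean_b - gm$mean_a,
        p = unname(pv),
        row.names = NULL)
    out$fold_change <- foldChange(out$avg_logfc)
    out$p_adj <- bhAdjust(out$p)
    out[, c("gene", "mean_a", "mean_b", "pct_a", "pct_b",
            "avg_logfc", "fold_change", "p", "p_adj")]
}

#' Rank marker genes of a cluster against all other cells
#'
#' Runs \code{\link{groupStats}} with the cluster as group B and its
#' complement as group A, keeps genes expressed in at least
#' \code{minPct} of the cluster's cells, and orders rows by decreasing
#' \code{avg_logfc} with alphabetical gene-name tie-break.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param labels Per-cell annotation labels.
#' @param cluster The label whose markers are ranked.
#' @param minPct Minimum fraction of cluster cells expressing (default 0.1).
#' @param genes Candidate genes (default: all).
#' @return A \code{data.frame} as \code{\link{groupStats}}, filtered and
#'   sorted; \code{avg_logfc > 0} means up in the cluster.
#' @export
rankMarkers <- function(sce, labels, cluster, minPct = 0.1,
                        genes = rownames(sce)) {
    if (is(labels, "DataFrame")) labels <- labels$label
    stopifnot(length(labels) == ncol(sce))
    inCluster <- labels == cluster
    if (!any(inCluster)) stop("cluster ", sQuote(cluster), " is empty",
                              call. = FALSE)
    if (all(inCluster)) stop("cluster complement is empty", call. = FALSE)
    tab <- groupStats(sce, !inCluster, inCluster, genes)
    tab <- tab[tab$pct_b >= minPct & tab$pct_b > 0, , drop = FALSE]
    tab[order(-tab$avg_logfc, tab$gene), , drop = FALSE]
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Fold change of a target gene in a treated sample relative to a control
#' sample, each normalized to a reference gene (e.g. Gapdh):
#' \code{2^-((ctTargetTrt - ctRefTrt) - (ctTargetCtl - ctRefCtl))}.
#'
#' @param ctTargetTrt,ctRefTrt Ct values of target and reference gene in
#'   the treated sample.
#' @param ctTargetCtl,ctRefCtl Ct values in the control sample.
#' @return The fold change.
#' @examples
#' ddctFold(24, 18, 26, 18)  # ddCt = -2 -> fold 4
#' @export
ddctFold <- function(ctTargetTrt, ctRefTrt, ctTargetCtl, ctRefCtl) {
    ddct <- (ctTargetTrt - ctRefTrt) - (ctTargetCtl - ctRefCtl)
    2^(-ddct)
}

#' Write a differential-expression table to a TSV
#'
#' @param tab Output of \code{\link{groupStats}} or
#'   \code{\link{rankMarkers}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGroupStats <- function(tab, path) {
    out <- tab
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) sprintf("%.6g", x))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Linear fold change of depth-normalized expression between two groups
#'
#' Ratio of group means of \code{expm1(logcounts)}, i.e. of expression on
#' the depth-normalized linear scale (counts per \code{scale_factor}).
#' Because the per-cell depth is divided out by the normalization, this
#' ratio estimates the underlying mean-expression ratio between the two
#' groups directly, which makes it the natural estimator for recovering a
#' planted induction multiplier from a simulation.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param cellsA,cellsB Disjoint, non-empty cell selections (A = reference).
#' @param gene Gene symbol.
#' @return \code{mean_b / mean_a} on the linear scale; NA when the
#'   reference mean is zero.
#' @export
linearFoldChange <- function(sce, cellsA, cellsB, gene) {
    a <- .resolve_cells(sce, cellsA)
    b <- .resolve_cells(sce, cellsB)
    if (!length(a) || !length(b))
        stop("both groups must be non-empty", call. = FALSE)
    v <- .logcounts(sce)[.check_gene(sce, gene), ]
    ma <- mean(expm1(v[a])); mb <- mean(expm1(v[b]))
    if (ma == 0) return(NA_real_)
    mb / ma
}
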