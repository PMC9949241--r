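#' Bin cells by the normalized expression of one gene
#'
#' Left-closed, right-open bins on the log-normalized expression of
#' \code{gene}; the last bin is unbounded above. Cells below the first
#' edge get the \code{"excluded"} label. The default edges
#' \code{c(0.3, 1, 2, 3)} produce the bins [0.3, 1), [1, 2), [2, 3) and
#' [3, Inf).
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param gene Gene to bin on (default \code{"Ifi27l2a"}).
#' @param edges Strictly increasing numeric bin edges.
#' @param cells Cell selection to bin (default: all cells).
#' @return A factor over the selected cells with level \code{"excluded"}
#'   followed by one level per bin, named like \code{"[1,2)"}; names are
#'   the barcodes.
#' @export
binCells <- function(sce, gene = "Ifi27l2a", edges = c(0.3, 1, 2, 3),
                     cells = seq_len(ncol(sce))) {
    if (any(diff(edges) <= 0) || length(edges) < 1L)
        stop("bin edges must be strictly increasing", call. = FALSE)
    idx <- .resolve_cells(sce, cells)
    v <- as.numeric(.logcounts(sce)[.check_gene(sce, gene), idx])
    lab <- c("excluded",
             sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
             sprintf("[%g,Inf)", edges[length(edges)]))
    bin <- findInterval(v, edges) + 1L  # 1 = below first edge
    out <- factor(lab[bin], levels = lab)
    names(out) <- colnames(sce)[idx]
    out
}

#' Per-bin mean expression profile
#'
#' Arithmetic mean of log-normalized expression per bin per gene, over the
#' non-excluded bins. Empty bins are dropped with a warning; all bins
#' empty is an error.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param bins Factor from \code{\link{binCells}} (names are barcodes).
#' @param genes Genes to profile.
#' @return Numeric matrix, bins x genes, with bin-occupancy counts in
#'   \code{attr(, "n_cells")}.
#' @export
binProfile <- function(sce, bins, genes) {
    keep <- !is.na(bins) & bins != "excluded"
    useLevels <- setdiff(levels(bins), "excluded")
    counts <- table(factor(bins[keep], levels = useLevels))
    if (all(counts == 0L))
        stop("all bins are empty", call. = FALSE)
    if (any(counts == 0L)) {
        warning("dropping empty bin(s): ",
                paste(names(counts)[counts == 0L], collapse = ", "))
        useLevels <- names(counts)[counts > 0L]
    }
    v <- .logcounts(sce)[.check_gene(sce, genes),
                         names(bins)[keep], drop = FALSE]
    binned <- factor(bins[keep], levels = useLevels)
    prof <- matrix(NA_real_, nrow = length(useLevels), ncol = length(genes),
                   dimnames = list(useLevels, genes))
    for (b in useLevels)
        prof[b, ] <- Matrix::rowMeans(v[, binned == b, drop = FALSE])
    attr(prof, "n_cells") <- as.integer(counts[useLevels])
    prof
}

.spearman_exact_p <- function(rho, n) {
    # exact null distribution of rho by enumerating all n! rank permutations
    perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
        out
    }
    ref <- seq_len(n)
    rhos <- vapply(perms(ref), function(p) stats::cor(ref, p), numeric(1))
    mean(abs(rhos) >= abs(rho) - 1e-12)
}

#' Spearman correlation between two genes over a cell subset
#'
#' Spearman's rho with midranks over the selected cells. The p-value uses
#' the t approximation, except for tie-free samples with n <= 9 where the
#' exact permutation null is used. Zero-variance input yields an NA rho
#' with a note instead of an error.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param geneX,geneY Gene symbols.
#' @param cells Cell selection (>= 3 cells).
#' @return A list with \code{rho}, \code{p.value}, \code{n} and
#'   (when degenerate) \code{note}.
#' @export
trendCorrelation <- function(sce, geneX, geneY, cells = seq_len(ncol(sce))) {
    idx <- .resolve_cells(sce, cells)
    if (length(idx) < 3L)
        stop("need at least 3 cells for a correlation", call. = FALSE)
    v <- .logcounts(sce)
    x <- as.numeric(v[.check_gene(sce, geneX), idx])
    y <- as.numeric(v[.check_gene(sce, geneY), idx])
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(rho = NA_real_, p.value = NA_real_, n = length(idx),
                    note = "zero variance"))
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    n <- length(idx)
    noTies <- !anyDuplicated(x) && !anyDuplicated(y)
    if (n <= 9L && noTies) {
        p <- .spearman_exact_p(rho, n)
    } else if (abs(rho) >= 1) {
        p <- 0
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    list(rho = rho, p.value = p, n = n)
}

#' Dichotomize cells into high and low expressers of a gene
#'
#' Among cells expressing \code{gene} (normalized value > 0), the high
#' group has values at or above \code{threshold} and the low group values
#' in (0, threshold). Reports per-group mean expression for the requested
#' genes and, for each gene set, how many member genes have a lower mean
#' in the high group.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param gene Gene defining the dichotomy (default \code{"Ifi27l2a"}).
#' @param threshold Normalized-expression split point (default 1).
#' @param cells Cell selection the dichotomy applies within.
#' @param sets Optional \linkS4class{SignatureSet} of gene programs to
#'   summarize.
#' @param genes Genes to report means for (default: union of the sets, or
#'   all genes when no sets are given).
#' @return A list with \code{threshold}, \code{n_high}, \code{n_low},
#'   \code{means} (genes x c(low, high) matrix, plus \code{diff} = high -
#'   low) and \code{set_summary} (per set: size and number of genes with
#'   mean(high) < mean(low)).
#' @export
splitHighLow <- function(sce, gene = "Ifi27l2a", threshold = 1,
                         cells = seq_len(ncol(sce)), sets = NULL,
                         genes = NULL) {
    idx <- .resolve_cells(sce, cells)
    v <- .logcounts(sce)
    expr <- as.numeric(v[.check_gene(sce, gene), idx])
    keep <- expr > 0
    idx <- idx[keep]; expr <- expr[keep]
    high <- expr >= threshold
    if (!any(high))
        stop(sprintf(
            "no cells at or above threshold %g (max expressing value %g)",
            threshold, if (length(expr)) max(expr) else NA_real_),
            call. = FALSE)
    if (all(high))
        stop(sprintf(
            "no cells below threshold %g (min expressing value %g)",
            threshold, min(expr)), call. = FALSE)
    if (is.null(genes)) {
        genes <- if (is.null(sets)) rownames(sce)
                 else unique(unlist(geneSets(sets), use.names = FALSE))
    }
    genes <- .check_gene(sce, intersect(genes, rownames(sce)))
    sub <- v[genes, idx, drop = FALSE]
    means <- cbind(low = Matrix::rowMeans(sub[, !high, drop = FALSE]),
                   high = Matrix::rowMeans(sub[, high, drop = FALSE]))
    means <- cbind(means, diff = means[, "high"] - means[, "low"])
    setSummary <- NULL
    if (!is.null(sets)) {
        sl <- geneSets(sets)
        setSummary <- data.frame(
            set = names(sl),
            n_genes = vapply(sl, function(g)
                sum(g %in% genes), integer(1)),
            n_lower_in_high = vapply(sl, function(g) {
                g <- intersect(g, genes)
                sum(means[g, "high"] < means[g, "low"])
            }, integer(1)),
            row.names = NULL)
    }
    list(threshold = threshold, n_high = sum(high), n_low = sum(!high),
         means = means, set_summary = setSummary)
}

#' Per-subcluster fold change of one gene between two conditions
#'
#' For each subcluster, the mean log-normalized expression of \code{gene}
#' in each condition and their plain ratio \code{fc = mean_b / mean_a}
#' (the convention of per-subcluster induction tables; contrast with the
#' \code{2^avg_logfc} convention of \code{\link{groupStats}}). A zero
#' \code{mean_a} yields an NA fold change; a subcluster empty in either
#' condition is an error.
#'
#' @param sce A log-normalized \code{SingleCellExperiment}.
#' @param subLabels Per-cell subcluster labels (over all cells of
#'   \code{sce}).
#' @param gene Gene to summarize.
#' @param conditionA,conditionB The two condition labels (A = reference).
#' @param condition Per-cell condition labels (default: colData).
#' @return A \code{data.frame} with columns \code{subcluster},
#'   \code{mean_a}, \code{mean_b}, \code{fc}.
#' @export
subclusterFoldChange <- function(sce, subLabels, gene,
                                 conditionA, conditionB,
                                 condition = colData(sce)$condition) {
    stopifnot(length(subLabels) == ncol(sce),
              length(condition) == ncol(sce))
    v <- .logcounts(sce)[.check_gene(sce, gene), ]
    subs <- sort(unique(subLabels[!is.na(subLabels)]))
    rows <- lapply(subs, function(s) {
        a <- subLabels == s & condition == conditionA
        b <- subLabels == s & condition == conditionB
        if (!any(a) || !any(b))
            stop("subcluster ", sQuote(s),
                 " is empty in one of the conditions", call. = FALSE)
        ma <- mean(v[a]); mb <- mean(v[b])
        data.frame(subcluster = s, mean_a = ma, mean_b = mb,
                   fc = if (ma > 0) mb / ma else NA_real_)
    })
    do.call(rbind, rows)
}
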