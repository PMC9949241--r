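#' Gate disease-associated microglia by compound count thresholds
#'
#' A cell is flagged DAM when it carries the gate's population label
#' (default \code{MG}) and its raw count reaches the per-gene threshold
#' for every gate gene simultaneously. The default gate requires
#' \code{Aif1}, \code{Spp1}, \code{Cst7} and \code{Lpl} all detected
#' (count >= 1). The gate works on raw counts, not normalized values.
#'
#' Raising any single threshold can only shrink the flagged set, and
#' gating on a subset of the gate genes yields a superset of the full
#' gate's flags.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param labels Per-cell annotation labels (character vector or the
#'   \code{DataFrame} from \code{\link{assignTypes}}).
#' @param config A \linkS4class{GateConfig}.
#' @return A \code{DataFrame} keyed by barcode with logical columns
#'   \code{in_population} and \code{dam}.
#' @examples
#' sce <- logNormalizeCells(simulateCells(defaultSimConfig(1, cellScale = 0.05)))
#' ann <- assignTypes(scoreSignatures(sce, defaultCellTypeSignatures()))
#' res <- gateDAM(sce, ann, gateConfig())
#' sum(res$dam)
#' @export
gateDAM <- function(sce, labels, config = gateConfig()) {
    stopifnot(is(config, "GateConfig"))
    methods::validObject(config)
    if (is(labels, "DataFrame")) labels <- labels$label
    stopifnot(length(labels) == ncol(sce))
    missing <- setdiff(config@gateGenes, rownames(sce))
    if (length(missing))
        stop("gate gene(s) missing from matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (!any(labels == config@population))
        stop("no cells carry the gate population label ",
             sQuote(config@population), call. = FALSE)
    m <- assay(sce, "counts")[config@gateGenes, , drop = FALSE]
    pass <- as.matrix(m) >= config@thresholds  # thresholds recycle down rows
    flag <- labels == config@population & colSums(pass) == length(config@gateGenes)
    DataFrame(in_population = labels == config@population,
              dam = unname(flag), row.names = colnames(sce))
}

#' Per-condition DAM percentages
#'
#' Summarizes a gate result into, for each condition, the number of
#' population (MG) cells, the number of flagged DAM cells, and
#' \code{pct_DAM = 100 * n_DAM / n_MG}. Conditions with no MG cells
#' report \code{NA} rather than 0.
#'
#' @param gate \code{DataFrame} from \code{\link{gateDAM}}.
#' @param condition Per-cell condition labels; factor levels define the
#'   reported condition order.
#' @return A \code{data.frame} with columns \code{condition}, \code{n_MG},
#'   \code{n_DAM}, \code{pct_DAM}.
#' @export
damSummary <- function(gate, condition) {
    stopifnot(length(condition) == nrow(gate))
    condition <- as.factor(condition)
    nMG <- tapply(gate$in_population, condition, sum, default = 0L)
    nDAM <- tapply(gate$dam, condition, sum, default = 0L)
    data.frame(condition = levels(condition),
               n_MG = as.integer(nMG),
               n_DAM = as.integer(nDAM),
               pct_DAM = ifelse(nMG > 0, 100 * nDAM / nMG, NA_real_),
               row.names = NULL)
}

#' Write DAM gate outputs
#'
#' Writes \code{dam_summary.tsv} (condition, n_MG, n_DAM, pct_DAM) and
#' \code{dam_flags.tsv} (barcode, dam).
#'
#' @param gate \code{DataFrame} from \code{\link{gateDAM}}.
#' @param summary Table from \code{\link{damSummary}}.
#' @param dirPath Output directory.
#' @return Invisibly, the paths written.
#' @export
writeDamResults <- function(gate, summary, dirPath) {
    paths <- c(summary = file.path(dirPath, "dam_summary.tsv"),
               flags = file.path(dirPath, "dam_flags.tsv"))
    s <- summary
    s$pct_DAM <- ifelse(is.na(s$pct_DAM), "NA", sprintf("%.4f", s$pct_DAM))
    utils::write.table(s, paths["summary"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
        data.frame(barcode = rownames(gate), dam = gate$dam),
        paths["flags"], sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}
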