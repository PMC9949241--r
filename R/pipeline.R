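.write_tsv <- function(tab, path, digits = 6) {
    out <- tab
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x)
        ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.config_hash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    con <- file(tmp, open = "wb")
    serialize(config, con, version = 2)
    close(con)
    unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis end to end in the study's order: simulate
#' (or accept) a count experiment, log-normalize, annotate cell types
#' from marker signatures, compute differential-expression tables within
#' MG for each condition contrast, apply the DAM gate, and run the
#' Ifi27l2a-stratified analysis. All outputs are plain TSV files plus a
#' machine-readable JSON manifest; identical configuration and seed give
#' byte-identical outputs.
#'
#' @param outDir Output directory (created if needed).
#' @param simConfig \linkS4class{SimConfig} used when \code{sce} is NULL.
#' @param sce Optionally, an existing \code{SingleCellExperiment} with a
#'   \code{counts} assay and condition metadata (skips simulation).
#' @param contrasts List of length-2 character vectors of condition
#'   labels, each \code{c(reference, comparison)}; differential expression
#'   is computed within annotated MG cells.
#' @param gate A \linkS4class{GateConfig}.
#' @param typeSignatures \linkS4class{SignatureSet} of cell-type markers.
#' @param programSets \linkS4class{SignatureSet} of gene programs for the
#'   stratified analysis.
#' @param stratConditions Conditions pooled for the stratified Ifi27l2a
#'   analysis (default: the aged pair).
#' @param binEdges Bin edges for \code{\link{binCells}}.
#' @param highLowThreshold Split point for \code{\link{splitHighLow}}.
#' @param scaleFactor Normalization scale factor.
#' @return Invisibly, a list with the \code{sce}, annotation, gate result
#'   and the manifest.
#' @export
runPipeline <- function(outDir,
                        simConfig = defaultSimConfig(),
                        sce = NULL,
                        contrasts = list(c("young_stroke", "aged_stroke")),
                        gate = gateConfig(),
                        typeSignatures = defaultCellTypeSignatures(),
                        programSets = defaultGeneSets(),
                        stratConditions = c("aged_sham", "aged_stroke"),
                        binEdges = c(0.3, 1, 2, 3),
                        highLowThreshold = 1,
                        scaleFactor = 10000) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    manifest <- list(
        package = "MicrogliaStates",
        version = as.character(utils::packageVersion("MicrogliaStates")),
        seed = if (is.null(sce)) simConfig@seed else metadata(sce)$seed,
        config_hash = .config_hash(list(simConfig, gate, contrasts,
                                        stratConditions, binEdges,
                                        highLowThreshold, scaleFactor)),
        stages = list(), outputs = character(0))
    flush_manifest <- function() {
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    stage <- function(name, expr) {
        res <- tryCatch(expr, error = function(e) {
            manifest$stages[[name]] <<- "failed"
            flush_manifest()
            stop("stage ", sQuote(name), ": ", conditionMessage(e),
                 call. = FALSE)
        })
        manifest$stages[[name]] <<- "done"
        res
    }

    # validate contrasts before any compute
    conds <- if (is.null(sce)) simConfig@conditions
             else unique(colData(sce)$condition)
    for (ct in contrasts) {
        if (length(ct) != 2L || ct[1] == ct[2])
            stop("each contrast must name two distinct conditions",
                 call. = FALSE)
        unknown <- setdiff(ct, conds)
        if (length(unknown))
            stop("contrast references unknown condition(s): ",
                 paste(unknown, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(stratConditions, conds)
    if (length(unknown))
        stop("stratification references unknown condition(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)

    sce <- stage("simulate", {
        if (is.null(sce)) sce <- simulateCells(simConfig)
        writeTenx(sce, file.path(outDir, "counts"))
        if (!is.null(metadata(sce)$truth))
            writeTruth(sce, file.path(outDir, "truth.tsv"))
        sce
    })
    sce <- stage("normalize", logNormalizeCells(sce, scaleFactor))
    ann <- stage("annotate", {
        ann <- assignTypes(scoreSignatures(sce, typeSignatures))
        writeAnnotations(ann, file.path(outDir, "annotations.tsv"))
        comp <- cellComposition(ann, colData(sce)$condition)
        .write_tsv(comp, file.path(outDir, "composition.tsv"))
        ann
    })
    condition <- colData(sce)$condition
    mg <- ann$label == gate@population

    stage("dge", {
        for (ct in contrasts) {
            a <- mg & condition == ct[1]
            b <- mg & condition == ct[2]
            tab <- groupStats(sce, a, b)
            tab <- tab[order(-tab$avg_logfc, tab$gene), ]
            writeGroupStats(tab, file.path(
                outDir, sprintf("dge_%s_vs_%s.tsv", ct[1], ct[2])))
        }
    })
    gateRes <- stage("dam", {
        res <- gateDAM(sce, ann, gate)
        writeDamResults(res, damSummary(res, condition), outDir)
        res
    })
    stage("stratify", {
        strat <- mg & condition %in% stratConditions
        damGenes <- programSets[["DAM"]]
        bins <- binCells(sce, edges = binEdges, cells = strat)
        prof <- suppressWarnings(binProfile(sce, bins, damGenes))
        profTab <- data.frame(bin = rownames(prof),
                              n_cells = attr(prof, "n_cells"),
                              as.data.frame(prof, check.names = FALSE))
        .write_tsv(profTab, file.path(outDir, "strat_profile.tsv"))

        sets <- geneSets(programSets)
        corrTab <- do.call(rbind, lapply(names(sets), function(sn) {
            do.call(rbind, lapply(setdiff(sets[[sn]], "Ifi27l2a"),
                function(g) {
                    tc <- trendCorrelation(sce, "Ifi27l2a", g, strat)
                    data.frame(gene = g, set = sn, rho = tc$rho,
                               p = tc$p.value, n = tc$n)
                }))
        }))
        .write_tsv(corrTab, file.path(outDir, "strat_corr.tsv"))

        hl <- splitHighLow(sce, threshold = highLowThreshold,
                           cells = strat, sets = programSets)
        hlTab <- data.frame(gene = rownames(hl$means),
                            mean_low = hl$means[, "low"],
                            mean_high = hl$means[, "high"],
                            diff = hl$means[, "diff"])
        .write_tsv(hlTab, file.path(outDir, "highlow.tsv"))
        .write_tsv(hl$set_summary, file.path(outDir, "highlow_sets.tsv"))
    })

    manifest$outputs <- sort(list.files(outDir, recursive = TRUE))
    flush_manifest()
    invisible(list(sce = sce, annotation = ann, gate = gateRes,
                   manifest = manifest))
}

#' Summarize a pipeline result directory
#'
#' Produces a short human-readable (markdown) summary: the top induced
#' gene of each differential-expression contrast, DAM percentages per
#' condition, and the signs of the stratified correlations. Missing
#' tables are listed as absent rather than raising an error.
#'
#' @param dirPath A directory written by \code{\link{runPipeline}}.
#' @return Character vector of report lines (also printed).
#' @export
pipelineReport <- function(dirPath) {
    manifestPath <- file.path(dirPath, "manifest.json")
    if (!file.exists(manifestPath))
        stop("no manifest.json in ", dirPath, call. = FALSE)
    manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    lines <- c(sprintf("# Pipeline report (%s %s, seed %s)",
                       manifest$package, manifest$version, manifest$seed))

    dge <- list.files(dirPath, pattern = "^dge_.*\\.tsv$")
    if (!length(dge)) {
        lines <- c(lines, "- differential expression tables: absent")
    } else for (f in dge) {
        tab <- utils::read.delim(file.path(dirPath, f))
        top <- tab$gene[which.max(tab$avg_logfc)]
        lines <- c(lines, sprintf(
            "- %s: top induced gene %s (avg_logfc %.2f, fold %.2f)",
            sub("\\.tsv$", "", f), top, max(tab$avg_logfc),
            tab$fold_change[which.max(tab$avg_logfc)]))
    }

    damPath <- file.path(dirPath, "dam_summary.tsv")
    if (!file.exists(damPath)) {
        lines <- c(lines, "- DAM summary: absent")
    } else {
        dam <- utils::read.delim(damPath)
        if (nrow(dam) == 0L || sum(dam$n_DAM) == 0L) {
            lines <- c(lines, "- no DAM detected")
        } else {
            lines <- c(lines, sprintf("- DAM: %s", paste(
                sprintf("%s %.1f%%", dam$condition,
                        suppressWarnings(as.numeric(dam$pct_DAM))),
                collapse = ", ")))
        }
    }

    corrPath <- file.path(dirPath, "strat_corr.tsv")
    if (!file.exists(corrPath)) {
        lines <- c(lines, "- stratified correlations: absent")
    } else {
        corr <- utils::read.delim(corrPath)
        for (sn in unique(corr$set)) {
            sub <- corr[corr$set == sn, ]
            lines <- c(lines, sprintf(
                "- Ifi27l2a vs %s: %d/%d genes negatively correlated",
                sn, sum(sub$rho < 0, na.rm = TRUE), nrow(sub)))
        }
    }
    cat(lines, sep = "\n")
    invisible(lines)
}
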