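# Fixture builders shared across the test files. Everything is generated
# in code; no data files are read.

library(Matrix)
library(SingleCellExperiment)

# SingleCellExperiment from a dense count matrix (genes x cells)
toy_sce <- function(counts, condition = rep("c1", ncol(counts)),
                    genes = rownames(counts), barcodes = colnames(counts)) {
    counts <- as.matrix(counts)
    if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(counts)))
    if (is.null(barcodes)) barcodes <- sprintf("b%02d", seq_len(ncol(counts)))
    dimnames(counts) <- list(genes, barcodes)
    SingleCellExperiment(
        assays = list(counts = as(counts, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(sample = condition,
                                       condition = condition,
                                       row.names = barcodes))
}

# SingleCellExperiment whose logcounts are set directly (for arithmetic
# operations defined on the normalized scale)
toy_logcounts_sce <- function(values, condition = rep("c1", ncol(values))) {
    values <- as.matrix(values)
    sce <- toy_sce(ceiling(values), condition,
                   genes = rownames(values), barcodes = colnames(values))
    v <- values
    dimnames(v) <- dimnames(assay(sce, "counts"))
    SummarizedExperiment::assay(sce, "logcounts") <-
        as(v, "CsparseMatrix")
    sce
}

# Minimal custom simulator configuration; defaults give a single-type,
# single-condition microglial population.
test_sim_config <- function(seed = 1L,
                            nCells = c(young_sham = 1000L),
                            cellTypes = "MG",
                            typeProportions = NULL,
                            genes = c("Ifi27l2a", "Lpl", "Bkg01"),
                            baseMean = NULL,
                            dispersion = 0.1,
                            libsizeSigma = 0.3,
                            ifiGene = NULL,
                            ifiMultipliers = c(aging = 1, stroke = 1,
                                               synergy = 1),
                            mgType = "MG",
                            damFraction = 0,
                            damMultipliers = numeric(0)) {
    conds <- names(nCells)
    age <- ifelse(grepl("aged", conds), "aged", "young")
    injury <- ifelse(grepl("stroke", conds), "stroke", "sham")
    names(age) <- names(injury) <- conds
    if (is.null(typeProportions))
        typeProportions <- matrix(1 / length(cellTypes),
                                  nrow = length(cellTypes),
                                  ncol = length(conds),
                                  dimnames = list(cellTypes, conds))
    if (is.null(baseMean))
        baseMean <- matrix(5, nrow = length(genes), ncol = length(cellTypes),
                           dimnames = list(genes, cellTypes))
    if (length(dispersion) == 1L)
        dispersion <- stats::setNames(rep(dispersion, length(genes)), genes)
    if (is.null(ifiGene))
        ifiGene <- if ("Ifi27l2a" %in% genes) "Ifi27l2a" else genes[1]
    if (length(damFraction) == 1L)
        damFraction <- stats::setNames(rep(damFraction, length(conds)), conds)
    methods::new("SimConfig",
        seed = as.integer(seed), conditions = conds,
        conditionAge = age, conditionInjury = injury,
        nCells = as.integer(nCells) |> stats::setNames(conds),
        cellTypes = cellTypes, typeProportions = typeProportions,
        genes = genes, baseMean = baseMean, dispersion = dispersion,
        libsizeSigma = libsizeSigma, ifiGene = ifiGene,
        ifiMultipliers = ifiMultipliers, mgType = mgType,
        damFraction = damFraction, damMultipliers = damMultipliers)
}

# MG-only population with a planted DAM subpopulation carrying opposing
# fold shifts: DAM program genes up `fold`, Ifi27l2a down 1/fold.
planted_mg_config <- function(seed, nCells = 2000L, fold = 4,
                              damFraction = 0.3) {
    genes <- c("Ifi27l2a", "Lpl", "Spp1", "Itgax", "Cst7", "Tyrobp",
               "Aif1", "C1qc", "Hexb", "Gapdh",
               sprintf("Bkg%02d", 1:12))
    bm <- matrix(0, nrow = length(genes), ncol = 1,
                 dimnames = list(genes, "MG"))
    bm["Ifi27l2a", ] <- 4
    bm[c("Lpl", "Spp1", "Itgax", "Cst7", "Tyrobp"), ] <- 1
    bm[c("Aif1", "C1qc", "Hexb"), ] <- 4
    bm["Gapdh", ] <- 20
    bm[sprintf("Bkg%02d", 1:12), ] <- seq(1500, 400, length.out = 12)
    dam <- c(Lpl = fold, Spp1 = fold, Itgax = fold, Cst7 = fold,
             Tyrobp = fold, Ifi27l2a = 1 / fold)
    if (damFraction == 0) dam <- numeric(0)
    test_sim_config(seed = seed, nCells = c(aged_stroke = as.integer(nCells)),
                    cellTypes = "MG", genes = genes, baseMean = bm,
                    damFraction = damFraction, damMultipliers = dam)
}

sim_norm <- function(config) logNormalizeCells(simulateCells(config))
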