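#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SignatureSet: named gene sets
#'
#' Container for named, ordered gene lists such as conserved cell-type
#' markers, the DAM (disease-associated microglia) program, or homeostatic
#' microglial genes. Gene symbols are case-sensitive exact strings; no
#' alias resolution is attempted.
#'
#' @slot sets Named list of character vectors. Set names are unique, every
#'   set is non-empty, and genes within a set are unique (order preserved).
#' @export
setClass("SignatureSet", representation(sets = "list"))

setValidity("SignatureSet", function(object) {
    s <- object@sets
    if (length(s) == 0L)
        return("a SignatureSet must contain at least one set")
    nm <- names(s)
    if (is.null(nm) || any(!nzchar(nm)))
        return("every signature set must be named")
    if (anyDuplicated(nm))
        return("signature set names must be unique")
    for (i in seq_along(s)) {
        g <- s[[i]]
        if (!is.character(g) || length(g) == 0L)
            return(sprintf("set '%s' must be a non-empty character vector", nm[i]))
        if (anyDuplicated(g))
            return(sprintf("set '%s' contains duplicated genes", nm[i]))
    }
    TRUE
})

#' Construct a SignatureSet
#'
#' @param ... Named character vectors, or a single named list of them.
#' @return A \linkS4class{SignatureSet}.
#' @examples
#' SignatureSet(DAM = c("Lpl", "Spp1", "Cst7", "Itgax"),
#'              homeostatic = c("Aif1", "C1qc", "Hexb", "Gapdh"))
#' @export
SignatureSet <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1]]) && !is.character(args[[1]]))
        args <- args[[1]]
    new("SignatureSet", sets = args)
}

#' @describeIn SignatureSet Names of the gene sets.
#' @param x A SignatureSet.
#' @export
setMethod("names", "SignatureSet", function(x) names(x@sets))

#' @describeIn SignatureSet Number of gene sets.
#' @export
setMethod("length", "SignatureSet", function(x) length(x@sets))

#' @describeIn SignatureSet Extract one gene set by name or index.
#' @param i Set name or index.
#' @export
setMethod("[[", "SignatureSet", function(x, i) x@sets[[i]])

#' Gene sets as a plain named list
#'
#' @param x A \linkS4class{SignatureSet}.
#' @return Named list of character vectors.
#' @export
geneSets <- function(x) {
    stopifnot(is(x, "SignatureSet"))
    x@sets
}

setMethod("show", "SignatureSet", function(object) {
    cat("SignatureSet with", length(object@sets), "sets\n")
    for (nm in names(object@sets)) {
        g <- object@sets[[nm]]
        shown <- paste(utils::head(g, 6L), collapse = ", ")
        if (length(g) > 6L) shown <- paste0(shown, ", ...")
        cat(sprintf("  %s (%d): %s\n", nm, length(g), shown))
    }
})

#' SimConfig: configuration of the synthetic scRNA-seq generator
#'
#' Describes a negative-binomial count simulator for a brain single-cell
#' experiment with four condition groups (a 2x2 aging-by-stroke design),
#' a fixed gene panel, per-type mean profiles, a latent DAM subpopulation
#' inside the microglial (MG) compartment, and condition-dependent
#' induction of one interferon-stimulated gene (by default Ifi27l2a) in MG.
#'
#' The Ifi27l2a mean in MG is scaled by 1, \code{aging}, \code{stroke} and
#' \code{aging * stroke * synergy} across young-sham, aged-sham,
#' young-stroke and aged-stroke cells, so the aging-by-stroke synergy is a
#' single recoverable parameter.
#'
#' @slot seed Integer RNG seed; identical configurations and seeds yield
#'   bit-identical output.
#' @slot conditions Character vector of condition labels.
#' @slot conditionAge,conditionInjury Named character vectors mapping each
#'   condition to "young"/"aged" and "sham"/"stroke".
#' @slot nCells Named integer vector: cells per condition.
#' @slot cellTypes Character vector of cell-type labels.
#' @slot typeProportions Numeric matrix (type x condition); columns sum to 1.
#' @slot genes Character vector: the simulated gene panel.
#' @slot baseMean Numeric matrix (gene x type) of negative-binomial means
#'   in counts, before depth, induction and DAM-program scaling.
#' @slot dispersion Named numeric vector, per-gene NB dispersion (1/size); > 0.
#' @slot libsizeSigma Log-normal sigma of the per-cell depth factor (>= 0).
#' @slot ifiGene Name of the induced gene (default "Ifi27l2a").
#' @slot ifiMultipliers Named numeric c(aging, stroke, synergy), each >= 1.
#' @slot mgType Label of the microglial type the DAM fraction and the
#'   induction apply to.
#' @slot damFraction Named numeric vector per condition in [0, 1]: fraction
#'   of MG cells carrying the latent DAM program.
#' @slot damMultipliers Named numeric vector: per-gene fold applied in DAM
#'   cells (fold-ups > 1 for the DAM program, folds < 1 for genes
#'   suppressed in DAM, including the induced gene).
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    conditions = "character",
    conditionAge = "character",
    conditionInjury = "character",
    nCells = "integer",
    cellTypes = "character",
    typeProportions = "matrix",
    genes = "character",
    baseMean = "matrix",
    dispersion = "numeric",
    libsizeSigma = "numeric",
    ifiGene = "character",
    ifiMultipliers = "numeric",
    mgType = "character",
    damFraction = "numeric",
    damMultipliers = "numeric"
))

setValidity("SimConfig", function(object) {
    cond <- object@conditions
    if (length(cond) == 0L || anyDuplicated(cond))
        return("conditions must be non-empty and unique")
    for (slot in c("conditionAge", "conditionInjury", "nCells",
                   "damFraction")) {
        v <- slot(object, slot)
        if (!identical(sort(names(v)), sort(cond)))
            return(sprintf("'%s' must be named by the conditions", slot))
    }
    if (!all(object@conditionAge %in% c("young", "aged")))
        return("conditionAge values must be 'young' or 'aged'")
    if (!all(object@conditionInjury %in% c("sham", "stroke")))
        return("conditionInjury values must be 'sham' or 'stroke'")
    if (any(object@nCells < 0L))
        return("nCells must be non-negative")
    p <- object@typeProportions
    if (!identical(rownames(p), object@cellTypes) ||
        !identical(colnames(p), cond))
        return("typeProportions must be a cellTypes x conditions matrix")
    if (any(p < 0) || any(abs(colSums(p) - 1) > 1e-9))
        return("type proportions must be non-negative and sum to 1 per condition")
    bm <- object@baseMean
    if (!identical(rownames(bm), object@genes) ||
        !identical(colnames(bm), object@cellTypes))
        return("baseMean must be a genes x cellTypes matrix")
    if (any(bm < 0)) return("baseMean entries must be >= 0")
    if (anyDuplicated(object@genes)) return("gene panel must be unique")
    d <- object@dispersion
    if (!identical(names(d), object@genes) || any(d <= 0))
        return("dispersion must be > 0 and named by the gene panel")
    if (length(object@libsizeSigma) != 1L || object@libsizeSigma < 0)
        return("libsizeSigma must be a single value >= 0")
    if (!all(c("aging", "stroke", "synergy") %in% names(object@ifiMultipliers)))
        return("ifiMultipliers must contain aging, stroke and synergy")
    if (any(object@ifiMultipliers < 0))
        return("ifiMultipliers must be >= 0")
    if (!(object@ifiGene %in% object@genes))
        return("ifiGene must be part of the gene panel")
    if (any(object@damFraction < 0 | object@damFraction > 1))
        return("damFraction must lie in [0, 1]")
    if (any(object@damFraction > 0) && !(object@mgType %in% object@cellTypes))
        return("damFraction > 0 requires the MG type to be declared")
    if (any(object@damMultipliers < 0))
        return("damMultipliers must be >= 0")
    if (!all(names(object@damMultipliers) %in% object@genes))
        return("damMultipliers reference genes outside the panel")
    TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", sum(object@nCells), "cells,",
        length(object@genes), "genes,",
        length(object@cellTypes), "cell types\n")
    cat("  conditions:", paste(sprintf("%s (%d)", object@conditions,
        object@nCells[object@conditions]), collapse = ", "), "\n")
    cat("  induced gene:", object@ifiGene, " multipliers:",
        paste(sprintf("%s=%.2f", names(object@ifiMultipliers),
                      object@ifiMultipliers), collapse = ", "), "\n")
    cat("  DAM fraction:", paste(sprintf("%s=%.3f",
        object@conditions, object@damFraction[object@conditions]),
        collapse = ", "), "\n")
    cat("  seed:", object@seed, "\n")
})

#' GateConfig: compound count-threshold DAM gate
#'
#' The DAM gate classifies a cell as disease-associated microglia when the
#' cell carries the MG annotation label and its raw count meets or exceeds
#' a per-gene integer threshold for every gate gene simultaneously
#' (a boolean conjunction).
#'
#' @slot gateGenes Ordered character vector of gate genes.
#' @slot thresholds Named integer vector of per-gene minimum raw counts
#'   (>= 1), aligned with \code{gateGenes}.
#' @slot population Annotation label the gate applies within (default "MG").
#' @export
setClass("GateConfig", representation(
    gateGenes = "character",
    thresholds = "integer",
    population = "character"
))

setValidity("GateConfig", function(object) {
    if (length(object@gateGenes) == 0L || anyDuplicated(object@gateGenes))
        return("gateGenes must be non-empty and unique")
    if (!identical(names(object@thresholds), object@gateGenes))
        return("thresholds must be named by gateGenes, in order")
    if (any(object@thresholds < 1L))
        return("thresholds must be integers >= 1")
    if (length(object@population) != 1L || !nzchar(object@population))
        return("population must be a single non-empty label")
    TRUE
})

#' Construct a GateConfig
#'
#' Defaults encode the weakest faithful reading of a "high by count"
#' filter: a cell is DAM when all four canonical gate genes are detected
#' (raw count >= 1) and the cell is annotated MG. Stricter integer
#' thresholds can be supplied per gene.
#'
#' @param gateGenes Character vector of gate genes.
#' @param thresholds Integer vector (recycled if length 1) of per-gene
#'   minimum raw counts.
#' @param population Annotation label the gate applies within.
#' @return A \linkS4class{GateConfig}.
#' @examples
#' gateConfig()
#' gateConfig(thresholds = c(Aif1 = 2L, Spp1 = 1L, Cst7 = 1L, Lpl = 1L))
#' @export
gateConfig <- function(gateGenes = c("Aif1", "Spp1", "Cst7", "Lpl"),
                       thresholds = 1L, population = "MG") {
    if (length(thresholds) == 1L)
        thresholds <- rep(thresholds, length(gateGenes))
    nm <- names(thresholds)
    thresholds <- as.integer(thresholds)
    names(thresholds) <- if (is.null(nm)) gateGenes else nm
    thresholds <- thresholds[gateGenes]
    if (anyNA(thresholds))
        stop("a threshold is required for every gate gene", call. = FALSE)
    names(thresholds) <- gateGenes
    new("GateConfig", gateGenes = gateGenes, thresholds = thresholds,
        population = population)
}

setMethod("show", "GateConfig", function(object) {
    cat("GateConfig on population", sQuote(object@population), "\n")
    cat(" ", paste(sprintf("%s >= %d", object@gateGenes,
                           object@thresholds), collapse = " AND "), "\n")
})
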