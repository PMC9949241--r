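test_that("group means and the logFC/FC conventions match the table arithmetic", {
    # two MG groups whose mean log-normalized expression is fixed exactly
    vals <- rbind(Lgals3   = c(0.99, 0.99, 1.83, 1.83),
                  Lgals3bp = c(1.43, 1.43, 2.08, 2.08))
    sce <- toy_logcounts_sce(vals)
    gm <- groupMeans(sce, 1:2, 3:4)
    lfc <- gm$mean_b - gm$mean_a
    expect_equal(lfc, c(0.84, 0.65), tolerance = 1e-12)
    expect_equal(round(foldChange(lfc), 2), c(1.79, 1.57))

    # single-cell groups reduce to the cell's own value
    one <- groupMeans(sce, 1, 4, genes = "Lgals3")
    expect_identical(c(one$mean_a, one$mean_b), c(0.99, 1.83))

    expect_error(groupMeans(sce, 1:2, 2:3), "disjoint")
    expect_error(groupMeans(sce, integer(0), 3:4), "non-empty")
})

test_that("foldChange is the base-2 exponential and antisymmetric", {
    expect_identical(foldChange(0), 1)
    expect_equal(round(foldChange(0.83), 2), 1.78)
    for (x in c(-1.3, 0, 0.42, 2))
        expect_equal(foldChange(x) * foldChange(-x), 1, tolerance = 1e-12)
})

test_that("percent expressing follows the count > 0 rule", {
    m <- rbind(all0 = rep(0, 10), all1 = rep(3, 10),
               some = c(rep(1, 3), rep(0, 7)))
    sce <- toy_sce(m)
    expect_identical(unname(pctExpressing(sce, 1:10, "all0")), 0)
    expect_identical(unname(pctExpressing(sce, 1:10, "all1")), 1)
    expect_identical(unname(pctExpressing(sce, 1:10, "some")), 0.3)
    expect_error(pctExpressing(sce, 1:10, "nope"), "not in matrix")
})

test_that("rank-sum p-values are exact for small tie-free samples", {
    r <- wilcoxRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_identical(r$statistic, 0)
    expect_equal(r$p.value, 0.1, tolerance = 1e-12)

    # identical multisets: dead-centre statistic, p = 1
    expect_identical(wilcoxRankSum(c(1, 2, 2), c(1, 2, 2))$p.value, 1)

    # invariance under strictly monotone transforms of the pooled data
    x <- c(0.3, 2.1, 5, 0.01); y <- c(1.4, 0.2, 7)
    expect_identical(wilcoxRankSum(x, y)$p.value,
                     wilcoxRankSum(exp(x), exp(y))$p.value)

    # agreement with the reference implementation, with and without ties
    for (i in 1:5) {
        x <- round(rgamma(2 + i, 2), 1)
        y <- round(rgamma(9, 2), 1)
        expect_equal(wilcoxRankSum(x, y)$p.value,
                     suppressWarnings(stats::wilcox.test(x, y)$p.value),
                     tolerance = 1e-9)
    }
})

test_that("BH adjustment is the step-up procedure, order-independent", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_identical(bhAdjust(0.37), 0.37)
    expect_identical(bhAdjust(rep(1, 5)), rep(1, 5))

    p <- c(0.001, 0.2, 0.013, 1, 0.04, 0.04)
    perm <- c(3, 1, 6, 2, 5, 4)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]), tolerance = 1e-15)
    expect_true(all(bhAdjust(p) >= p))
})

test_that("marker ranking surfaces planted markers and applies the pct filter", {
    genes <- c("Trem2", "Plp1", "Silent", "Bkg01")
    bm <- cbind(MG = c(8, 0.02, 0, 2), Oligo = c(0.02, 8, 0, 2))
    rownames(bm) <- genes
    cfg <- test_sim_config(seed = 12, nCells = c(young_sham = 600L),
                           cellTypes = c("MG", "Oligo"), genes = genes,
                           baseMean = bm)
    sce <- sim_norm(cfg)
    tt <- truthTable(sce)
    tab <- rankMarkers(sce, tt$cell_type, "MG")
    expect_identical(tab$gene[1], "Trem2")
    # never-expressed genes cannot appear in the table
    expect_false("Silent" %in% tab$gene)
    expect_error(rankMarkers(sce, tt$cell_type, "Astro"), "empty")

    # equal logFC resolves alphabetically
    vals <- rbind(b_gene = c(1, 1, 2, 2), a_gene = c(1, 1, 2, 2))
    tsce <- toy_logcounts_sce(vals)
    ttab <- rankMarkers(tsce, c("x", "x", "y", "y"), "y")
    expect_identical(ttab$gene, c("a_gene", "b_gene"))
})

test_that("groupStats assembles a coherent table", {
    cfg <- test_sim_config(seed = 8, nCells = c(young_sham = 80L,
                                                aged_stroke = 80L))
    sce <- sim_norm(cfg)
    cond <- colData(sce)$condition
    tab <- groupStats(sce, cond == "young_sham", cond == "aged_stroke")
    expect_identical(tab$gene, rownames(sce))
    expect_equal(tab$fold_change, 2^tab$avg_logfc, tolerance = 1e-15)
    expect_true(all(tab$p_adj >= tab$p - 1e-15))
    expect_true(all(tab$pct_a >= 0 & tab$pct_a <= 1))
    expect_true(all(tab$p_adj > 0 & tab$p_adj <= 1))
})

test_that("ddCt fold change follows the 2^-ddCt rule", {
    expect_identical(ddctFold(20, 20, 20, 20), 1)
    expect_identical(ddctFold(19, 18, 20, 18), 2)  # ddCt = -1
    expect_identical(ddctFold(21, 18, 19, 18), 0.25)
    expect_identical(ddctFold(17, 18, 20, 20), 2)
})

test_that("linear fold change recovers a known mean ratio exactly", {
    # two cells with depth-normalized expression 3 and 6 per 10k
    sce <- toy_logcounts_sce(rbind(g = log1p(c(3, 6))))
    expect_equal(linearFoldChange(sce, 1, 2, "g"), 2, tolerance = 1e-12)
    zero <- toy_logcounts_sce(rbind(g = c(0, 1)))
    expect_true(is.na(linearFoldChange(zero, 1, 2, "g")))
})
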