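test_that("binning follows the half-open convention with an open top bin", {
    sce <- toy_logcounts_sce(rbind(Ifi27l2a = c(0.5, 1.0, 0.2, 7.3, 2.9)))
    b <- binCells(sce)
    expect_identical(as.character(b),
                     c("[0.3,1)", "[1,2)", "excluded", "[3,Inf)", "[2,3)"))
    expect_error(binCells(sce, edges = c(1, 1, 2)), "increasing")

    # partition invariant: bins + excluded account for every masked cell
    sim <- sim_norm(planted_mg_config(seed = 14, nCells = 800L))
    bb <- binCells(sim)
    expect_identical(sum(table(bb)), 800L)
})

test_that("bin profiles are plain means with empty bins dropped", {
    vals <- rbind(Ifi27l2a = c(0.5, 1.5, 2.5, 3.5),
                  Lpl = c(4, 3, 2, 1),
                  flat = c(2, 2, 2, 2))
    sce <- toy_logcounts_sce(vals)
    bins <- binCells(sce)
    prof <- binProfile(sce, bins, c("Lpl", "flat"))
    expect_equal(unname(prof[, "Lpl"]), c(4, 3, 2, 1))
    expect_equal(unname(prof[, "flat"]), rep(2, 4))

    # a hole in the occupied bins triggers a warning, not an error
    holed <- toy_logcounts_sce(rbind(Ifi27l2a = c(0.5, 3.5), Lpl = c(1, 2)))
    expect_warning(p2 <- binProfile(holed, binCells(holed), "Lpl"),
                   "empty bin")
    expect_identical(rownames(p2), c("[0.3,1)", "[3,Inf)"))

    allout <- toy_logcounts_sce(rbind(Ifi27l2a = c(0.1, 0.2), Lpl = c(1, 2)))
    expect_error(binProfile(allout, binCells(allout), "Lpl"), "empty")
})

test_that("a planted DAM program makes the DAM-gene profile fall across bins", {
    sce <- sim_norm(planted_mg_config(seed = 31, nCells = 3000L))
    # edges chosen to spread the planted gradient across all three bins
    bins <- binCells(sce, edges = c(0.3, 0.8, 1.3))
    prof <- suppressWarnings(
        binProfile(sce, bins, c("Lpl", "Spp1", "Cst7")))
    for (g in colnames(prof))
        expect_true(all(diff(prof[, g]) < 0))
})

test_that("trend correlation is rank-based with sane degenerate handling", {
    inc <- toy_logcounts_sce(rbind(x = 1:6, y = c(2, 4, 5, 7, 8, 11)))
    expect_equal(trendCorrelation(inc, "x", "y")$rho, 1)
    dec <- toy_logcounts_sce(rbind(x = 1:6, y = -(1:6)))
    r <- trendCorrelation(dec, "x", "y")
    expect_equal(r$rho, -1)
    expect_lt(r$p.value, 0.01)

    # invariance under strictly monotone transforms of either gene
    curved <- toy_logcounts_sce(rbind(x = c(0.3, 1.2, 0.9, 2.4, 5),
                                      y = c(4, 2.2, 3, 1.8, 0.5)))
    curved2 <- toy_logcounts_sce(rbind(x = exp(c(0.3, 1.2, 0.9, 2.4, 5)),
                                       y = sqrt(c(4, 2.2, 3, 1.8, 0.5))))
    expect_identical(trendCorrelation(curved, "x", "y")$rho,
                     trendCorrelation(curved2, "x", "y")$rho)

    flat <- toy_logcounts_sce(rbind(x = c(1, 1, 1), y = c(1, 2, 3)))
    expect_true(is.na(trendCorrelation(flat, "x", "y")$rho))
    expect_error(trendCorrelation(flat, "x", "y", cells = 1:2), "3 cells")

    # exact small-sample p agrees with the reference implementation
    set.seed(4)
    for (i in 1:3) {
        x <- rnorm(7); y <- rnorm(7)
        mine <- trendCorrelation(toy_logcounts_sce(rbind(x = x, y = y)),
                                 "x", "y")
        ref <- stats::cor.test(x, y, method = "spearman")
        expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
    }
})

test_that("the high/low dichotomy partitions expressing cells", {
    sce <- toy_logcounts_sce(rbind(Ifi27l2a = c(0.5, 1.5, 0, 2),
                                   Lpl = c(3, 1, 2, 0.5)))
    hl <- splitHighLow(sce, genes = "Lpl")
    expect_identical(hl$n_low, 1L)
    expect_identical(hl$n_high, 2L)   # the zero-expressing cell is excluded
    expect_equal(unname(hl$means["Lpl", ]),
                 c(3, 0.75, -2.25), tolerance = 1e-12)

    expect_error(splitHighLow(sce, threshold = 99, genes = "Lpl"),
                 "threshold 99")
})

test_that("planted anti-correlation shows as reduced DAM genes in Ifi-high MG", {
    sce <- sim_norm(planted_mg_config(seed = 77, nCells = 3000L))
    hl <- splitHighLow(sce, sets = defaultGeneSets())
    ss <- hl$set_summary
    expect_identical(ss$n_lower_in_high[ss$set == "DAM"], 5L)
    # homeostatic genes sit within a +/- 10% noise band instead
    homeo <- intersect(defaultGeneSets()[["homeostatic"]],
                       rownames(hl$means))
    rel <- abs(hl$means[homeo, "diff"]) /
        pmax(hl$means[homeo, "low"], 1e-9)
    expect_true(all(rel < 0.1))
})

test_that("subcluster fold changes are plain ratios of group means", {
    # printed-table arithmetic: 1.815 / 1.279 = 1.419 at three decimals
    vals <- rbind(Ifi27l2a = c(1.279, 1.279, 1.815, 1.815,
                               2.272, 2.272, 6.276, 6.276))
    cond <- rep(c("aged_sham", "aged_stroke"), each = 2, times = 2)[c(1:4, 5:8)]
    sub <- rep(c("P2ry12_homeostatic", "Activated_2"), each = 4)
    sce <- toy_logcounts_sce(vals, condition = cond)
    tab <- subclusterFoldChange(sce, sub, "Ifi27l2a",
                                "aged_sham", "aged_stroke")
    expect_equal(round(tab$fc[tab$subcluster == "P2ry12_homeostatic"], 3),
                 1.419)
    expect_equal(tab$fc[tab$subcluster == "Activated_2"],
                 6.276 / 2.272, tolerance = 1e-12)

    eq <- toy_logcounts_sce(rbind(g = c(2, 2)),
                            condition = c("aged_sham", "aged_stroke"))
    expect_identical(
        subclusterFoldChange(eq, c("s", "s"), "g",
                             "aged_sham", "aged_stroke")$fc, 1)
    z <- toy_logcounts_sce(rbind(g = c(0, 1)),
                           condition = c("aged_sham", "aged_stroke"))
    expect_true(is.na(subclusterFoldChange(z, c("s", "s"), "g",
                                           "aged_sham", "aged_stroke")$fc))
    expect_error(subclusterFoldChange(eq, c("s", "t"), "g",
                                      "aged_sham", "aged_stroke"),
                 "empty")
})
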