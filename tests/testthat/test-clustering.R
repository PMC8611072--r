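## five archetype temporal shapes over a 13-day grid
archetypes <- function(days = 0:12) {
    rbind(1 - plogis((days - 2) / 0.8), 1 - plogis((days - 6) / 0.8),
          plogis((days - 4) / 0.7) - plogis((days - 8) / 0.7),
          plogis((days - 6.5) / 0.8), plogis((days - 10) / 0.8))
}

plantedProfiles <- function(nPer = 20, noise = 0.01, seed = 2) {
    withr::with_seed(seed, {
        arch <- archetypes()
        m <- arch[rep(1:5, each = nPer), ] +
            matrix(rnorm(5 * nPer * ncol(arch), 0, noise), 5 * nPer)
        rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
        colnames(m) <- 0:12
        list(z = zscoreProfiles(m), truth = rep(1:5, each = nPer))
    })
}

test_that("k-means recovers planted profile classes and orders them by peak", {
    pp <- plantedProfiles()
    cl <- kmeansProfiles(pp$z, k = 5, seed = 7)
    expect_equal(mclust::adjustedRandIndex(cl$cluster, pp$truth), 1)
    ## labels follow peak time: archetype 1 peaks first
    expect_equal(unique(cl$label[pp$truth == 1]), "E1")
    expect_equal(unique(cl$label[pp$truth == 5]), "E5")
    peaks <- apply(attr(cl, "centers"), 1L, which.max)
    expect_true(all(diff(peaks) >= 0))
})

test_that("k-means is deterministic, duplicate-consistent and best-of-restarts", {
    pp <- plantedProfiles(nPer = 8, noise = 0.3)
    a <- kmeansProfiles(pp$z, k = 5, seed = 11)
    b <- kmeansProfiles(pp$z, k = 5, seed = 11)
    expect_identical(a, b)
    expect_lte(attr(a, "tot.withinss"),
               min(attr(a, "restart_objectives")) + 1e-9)

    dup <- rbind(pp$z, `rownames<-`(pp$z, paste0(rownames(pp$z), "_dup")))
    cl <- kmeansProfiles(dup, k = 5, seed = 11)
    n <- nrow(pp$z)
    expect_equal(cl$cluster[seq_len(n)], cl$cluster[n + seq_len(n)])

    expect_error(kmeansProfiles(pp$z[1:3, ], k = 5), "k exceeds")
})

## small constructed geography: 2 gene clusters x 2 DHS clusters
enrichFixture <- function() {
    tss <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1e6, 2e6, 8e6, 9e6) + 1, width = 1),
        strand = "+")
    names(tss) <- c("gA1", "gA2", "gB1", "gB2")
    ## E1 DHSs sit near GA genes, E2 DHSs near GB genes; an E3 background
    ## keeps each cluster's marginal share well below the window share
    pos <- c(1e6 + 1e4, 1e6 - 2e4, 2e6 + 3e4, 2e6 - 1e4,      # E1 near GA
             8e6 + 1e4, 8e6 - 2e4, 9e6 + 3e4, 9e6 - 1e4,      # E2 near GB
             5e6, 5.2e6,                                       # strays
             seq(2e7, 2.7e7, by = 1e6))                        # E3 desert
    iv <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = pos - 99, width = 200))
    names(iv) <- sprintf("d%02d", seq_along(pos))
    geneClusters <- data.frame(feature_id = names(tss),
                               cluster = c(1, 1, 2, 2),
                               label = c("G1", "G1", "G2", "G2"))
    dhsClusters <- data.frame(feature_id = names(iv),
                              cluster = c(rep(1, 4), rep(2, 4), 1, 2,
                                          rep(3, 8)),
                              label = c(rep("E1", 4), rep("E2", 4),
                                        "E1", "E2", rep("E3", 8)))
    list(tss = tss, iv = iv, g = geneClusters, d = dhsClusters)
}

test_that("enrichment matrix counts, pseudocounts and chi-square behave", {
    fx <- enrichFixture()
    em <- clusterEnrichmentMatrix(fx$g, fx$d, fx$tss, fx$iv, window = 5e4)
    ## co-located cluster pairs enriched, crossed pairs depleted
    g1e1 <- em[em$gene_cluster == "G1" & em$dhs_cluster == "E1", ]
    expect_equal(g1e1$observed, 4L)
    expect_equal(g1e1$expected, 4 * 5 / 18)
    expect_gt(g1e1$log2_ratio, 1)
    expect_equal(g1e1$log2_ratio,
                 log2((g1e1$observed + 0.5) / (g1e1$expected + 0.5)))
    g1e2 <- em[em$gene_cluster == "G1" & em$dhs_cluster == "E2", ]
    expect_equal(g1e2$observed, 0L)
    ## the documented pseudocount arithmetic
    expect_equal(log2((10 + 0.5) / (5 + 0.5)), 0.9328858,
                 tolerance = 1e-6)
    ## every cell recomputes consistently
    expect_equal(em$log2_ratio,
                 log2((em$observed + 0.5) / (em$expected + 0.5)))
    ## chi-square matches stats::chisq.test without continuity correction
    total <- nrow(fx$d)
    nWin <- sum(em$observed[em$gene_cluster == "G1"])
    a <- g1e1$observed; b <- nWin - a
    c0 <- sum(fx$d$label == "E1") - a; d0 <- total - a - b - c0
    ref <- suppressWarnings(chisq.test(matrix(c(a, b, c0, d0), 2),
                                       correct = FALSE))$p.value
    expect_equal(g1e1$chi2_p, ref, tolerance = 1e-12)
})

test_that("relabeling clusters permutes the enrichment matrix rows", {
    fx <- enrichFixture()
    em <- clusterEnrichmentMatrix(fx$g, fx$d, fx$tss, fx$iv, window = 5e4)
    gSwap <- fx$g
    gSwap$label <- c("G2", "G2", "G1", "G1")[match(fx$g$feature_id,
                                                   fx$g$feature_id)]
    gSwap$label <- ifelse(fx$g$label == "G1", "G2", "G1")
    em2 <- clusterEnrichmentMatrix(gSwap, fx$d, fx$tss, fx$iv,
                                   window = 5e4)
    for (e in c("E1", "E2"))
        expect_equal(
            em2$log2_ratio[em2$gene_cluster == "G2" &
                           em2$dhs_cluster == e],
            em$log2_ratio[em$gene_cluster == "G1" & em$dhs_cluster == e])
})

test_that("uniformly scattered DHS clusters show no enrichment signal", {
    bad <- 0L; totalCells <- 0L
    for (s in 1:10) {
        withr::with_seed(400 + s, {
            nD <- 2000
            pos <- sort(round(runif(nD, 1e5, 2e8)))
            iv <- GenomicRanges::GRanges("chr1",
                IRanges::IRanges(start = pos, width = 200))
            names(iv) <- sprintf("d%04d", seq_len(nD))
            tssPos <- round(seq(2e6, 1.98e8, length.out = 40))
            tss <- GenomicRanges::GRanges("chr1",
                IRanges::IRanges(start = tssPos, width = 1), strand = "+")
            names(tss) <- sprintf("g%02d", seq_along(tssPos))
            g <- data.frame(feature_id = names(tss),
                            cluster = rep(1:2, 20),
                            label = paste0("G", rep(1:2, 20)))
            d <- data.frame(feature_id = names(iv),
                            cluster = sample(1:5, nD, replace = TRUE))
            d$label <- paste0("E", d$cluster)
            em <- clusterEnrichmentMatrix(g, d, tss, iv, window = 2e6)
            ok <- abs(em$log2_ratio) <= 0.2 & em$chi2_p > 0.05
            bad <- bad + sum(!ok); totalCells <- totalCells + nrow(em)
        })
    }
    expect_gte(1 - bad / totalCells, 0.9)
})
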