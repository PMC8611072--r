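test_that("the generator is a deterministic function of its config", {
    a <- generateDataset(simulationConfig(n_dhs = 60, n_genes = 20,
                                          seed = 1))
    b <- generateDataset(simulationConfig(n_dhs = 60, n_genes = 20,
                                          seed = 1))
    expect_identical(SummarizedExperiment::assay(a$dhs),
                     SummarizedExperiment::assay(b$dhs))
    expect_identical(SummarizedExperiment::assay(a$gene),
                     SummarizedExperiment::assay(b$gene))
    expect_identical(a$motifHits, b$motifHits)
    expect_identical(a$truth$effects, b$truth$effects)
    c <- generateDataset(simulationConfig(n_dhs = 60, n_genes = 20,
                                          seed = 2))
    expect_false(identical(SummarizedExperiment::assay(a$dhs),
                           SummarizedExperiment::assay(c$dhs)))
})

test_that("config invariants are enforced", {
    expect_error(simulationConfig(frac_changing_dhs = 1.2), "frac")
    expect_error(simulationConfig(noise_sd = -1), "noise_sd")
    expect_error(simulationConfig(n_dhs = 0), "positive")
    expect_error(simulationConfig(n_tf = 5, n_modules = 5), "n_modules")
})

test_that("noiseless single-TF DHS tracks the TF curve almost linearly", {
    sim <- generateDataset(simulationConfig(n_modules = 1, n_tf = 3,
                                            n_dhs = 10, n_genes = 4,
                                            frac_changing_dhs = 1,
                                            noise_sd = 0, seed = 3))
    dm <- dayMeans(sim$dhs)
    gm <- dayMeans(sim$gene)
    eff <- sim$truth$effects
    one <- names(which(table(eff$dhs_id) == 1L))
    expect_gt(length(one), 0)
    for (d in one) {
        tf <- eff$tf_name[eff$dhs_id == d]
        r <- cor(dm[d, ], gm[tf, ])
        expect_gt(abs(r), 1 - 1e-4)
    }
})

test_that("noiseless changing profiles are monotone (ramps) or unimodal", {
    sim <- generateDataset(simulationConfig(noise_sd = 0, seed = 5))
    classes <- chronet:::moduleClasses(5)
    daily <- sim$truth$dhsDaily
    chg <- sim$truth$dhs[sim$truth$dhs$changing, ]
    unimodal <- function(x, tol = 1e-9) {
        d <- diff(x)
        rises <- which(d > tol); falls <- which(d < -tol)
        !length(rises) || !length(falls) || max(rises) < min(falls)
    }
    for (i in seq_len(nrow(chg))) {
        prof <- daily[chg$dhs_id[i], ]
        cls <- classes[chg$cluster[i]]
        if (cls == 1L) expect_true(all(diff(prof) >= -1e-8))
        else if (cls == -1L) expect_true(all(diff(prof) <= 1e-8))
        else expect_true(unimodal(prof))
    }
})

test_that("a null simulation yields no regulated calls in nearly all seeds", {
    hits <- 0L
    pAll <- numeric()
    for (s in 1:20) {
        sim <- generateDataset(simulationConfig(n_dhs = 150, n_genes = 10,
                                                frac_changing_dhs = 0,
                                                frac_changing_gene = 0,
                                                seed = 100 + s))
        fits <- callRegulated(
            fitDevelopmentalModel(quantileNormalize(sim$dhs), "ols"),
            featureKind = "dhs")
        if (sum(fits$regulated) == 0L) hits <- hits + 1L
        pAll <- c(pAll, fits$p_raw)
    }
    expect_gte(hits, 19L)                     # >= 95% of 20 seeds
    ## flat DHS day means carry no day effect: raw p roughly uniform
    expect_gte(mean(pAll > 0.01), 0.95)
})

test_that("recovery scoring returns exact metrics on constructed results", {
    sim <- generateDataset(simulationConfig(n_dhs = 100, n_genes = 30,
                                            seed = 8))
    tr <- sim$truth
    perfect <- scoreRecovery(tr, list(
        dhsRegulated = tr$dhs$dhs_id[tr$dhs$changing],
        geneRegulated = tr$gene$gene_id[tr$gene$changing],
        links = tr$links,
        dhsClusters = data.frame(
            feature_id = tr$dhs$dhs_id[tr$dhs$changing],
            cluster = tr$dhs$cluster[tr$dhs$changing]),
        tfModules = data.frame(
            tf_name = tr$tf$tf_name[!is.na(tr$tf$module)],
            module = tr$tf$module[!is.na(tr$tf$module)])))
    expect_equal(unname(perfect$dhs_changing["f1"]), 1)
    expect_equal(unname(perfect$links["f1"]), 1)
    expect_equal(perfect$cluster_ari, 1)
    expect_equal(perfect$module_ari, 1)

    ## half the links dropped, none added
    half <- tr$links[seq_len(floor(nrow(tr$links) / 2)), ]
    sc <- scoreRecovery(tr, list(links = half))
    expect_equal(unname(sc$links["precision"]), 1)
    expect_equal(unname(sc$links["recall"]),
                 nrow(half) / nrow(tr$links))

    ## random label permutations have ARI centred on 0
    withr::with_seed(13, {
        lab <- tr$dhs$cluster[tr$dhs$changing]
        ids <- tr$dhs$dhs_id[tr$dhs$changing]
        aris <- vapply(1:100, function(i)
            scoreRecovery(tr, list(dhsClusters = data.frame(
                feature_id = ids, cluster = sample(lab))))$cluster_ari,
            numeric(1))
        expect_lt(abs(mean(aris)), 0.1)
    })

    expect_error(scoreRecovery(tr, list(dhsRegulated = "nope")),
                 "unknown DHS")
})

test_that("simulated inputs written to disk reproduce the dataset", {
    sim <- generateDataset(simulationConfig(n_dhs = 40, n_genes = 12,
                                            seed = 4))
    dir <- withr::local_tempdir()
    files <- writeSimulatedInputs(sim, dir)
    tc <- readMatrixWithSamples(files["dhs_matrix"], files["samples"])
    expect_equal(SummarizedExperiment::assay(tc),
                 SummarizedExperiment::assay(sim$dhs), tolerance = 1e-11)
    iv <- readHotspotsBed(files["hotspots"])
    expect_setequal(names(iv), names(sim$intervals))
    hits <- readFimoHits(files["motif_hits"], iv)
    expect_equal(hits, sim$motifHits, ignore_attr = TRUE)
    tss <- readTssBed(files["tss"])
    expect_setequal(names(tss), names(sim$annotation))
})
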