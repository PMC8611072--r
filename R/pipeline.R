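#' Full pipeline configuration
#'
#' Gathers every stage threshold with the analysis defaults: adjusted
#' p < 1e-5, fold-range >= 1 (log2), minimum maximum density 30 (DHS) /
#' 2 FPKM (gene), k = 5 temporal clusters, +/-1 Mb linking window with
#' |r| > 0.7, +/-50 kb enrichment window, elastic-net grids, and >= 200
#' positively associated DHSs for module TFs. Inputs are either a
#' \code{\link{simulationConfig}} (\code{simulation}) or file paths
#' (\code{inputs}: dhs_matrix, gene_matrix, samples, hotspots, tss,
#' motif_hits) as written by \code{\link{writeSimulatedInputs}}.
#'
#' @param simulation a \code{\link{simulationConfig}}, or NULL when
#'   reading from files.
#' @param inputs named list/vector of input paths (ignored when
#'   \code{simulation} is given).
#' @param tfNames character vector naming which gene-matrix rows are TFs;
#'   defaults, for simulated input, to the generator's TF names.
#' @param mode regression mode for the developmental fits.
#' @param pAdjMax,minLog2Range,minMaxDensity,minMaxFpkm regulated-call
#'   thresholds.
#' @param k temporal cluster count (and module count).
#' @param enrichmentWindow,linkWindow bp windows.
#' @param minAbsR correlation threshold for links.
#' @param enet an \code{\link{enetConfig}} (reduced grids keep small runs
#'   fast; pass the full grids for a complete search).
#' @param requireRegulatedTf restrict TF candidates to regulated TFs.
#' @param minPositiveDhs module-TF selection threshold.
#' @param topN top targets kept per TF in the stage networks.
#' @param seed global seed.
#' @return list of class \code{chronetConfig}.
#' @export
chronetConfig <- function(simulation = simulationConfig(), inputs = NULL,
                          tfNames = NULL, mode = c("ols", "robust"),
                          pAdjMax = 1e-5, minLog2Range = 1,
                          minMaxDensity = 30, minMaxFpkm = 2, k = 5L,
                          enrichmentWindow = 5e4, linkWindow = 1e6,
                          minAbsR = 0.7,
                          enet = enetConfig(
                              alphaGrid = seq(0, 1, by = 0.1),
                              lambdaGrid = 10^seq(-5, 5, length.out = 20),
                              nRepeats = 20L),
                          requireRegulatedTf = TRUE,
                          minPositiveDhs = 200, topN = 50L, seed = 1L) {
    mode <- match.arg(mode)
    if (is.null(simulation) && is.null(inputs))
        stop("provide either a simulation config or input paths")
    structure(list(simulation = simulation, inputs = inputs,
                   tfNames = tfNames, mode = mode, pAdjMax = pAdjMax,
                   minLog2Range = minLog2Range,
                   minMaxDensity = minMaxDensity,
                   minMaxFpkm = minMaxFpkm, k = as.integer(k),
                   enrichmentWindow = enrichmentWindow,
                   linkWindow = linkWindow, minAbsR = minAbsR,
                   enet = enet,
                   requireRegulatedTf = requireRegulatedTf,
                   minPositiveDhs = minPositiveDhs,
                   topN = as.integer(topN), seed = as.integer(seed)),
              class = "chronetConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the \code{\link{chronetConfig}} arguments;
#' \code{simulation} and \code{enet} are nested maps passed to
#' \code{\link{simulationConfig}} / \code{\link{enetConfig}}.
#'
#' @param path YAML file.
#' @return a \code{chronetConfig}.
#' @export
readConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$simulation))
        y$simulation <- do.call(simulationConfig, y$simulation)
    if (!is.null(y$enet)) y$enet <- do.call(enetConfig, y$enet)
    do.call(chronetConfig, y)
}

#' Run the full inference pipeline
#'
#' Stages, in dependency order: developmental regulation calls for DHSs
#' and genes, temporal clustering (with the gene-cluster x DHS-cluster
#' enrichment matrix), DHS-gene linking, motif-cluster enrichment,
#' elastic-net TF modeling, regulatory-module resolution, and per-module
#' stage-specific TF-to-gene networks. When the inputs are simulated, the
#' planted truth is scored automatically.
#'
#' @param config a \code{\link{chronetConfig}}.
#' @param outDir optional directory; when given, every stage table, the
#'   networks (GraphML + edge list) and a JSON manifest are written there.
#' @param quiet suppress per-stage progress messages.
#' @return list with all stage results (\code{dhsFits}, \code{geneFits},
#'   \code{dhsClusters}, \code{geneClusters}, \code{enrichment},
#'   \code{links}, \code{linkSummary}, \code{motifEnrichment},
#'   \code{tfModel}, \code{modules}, \code{networks}, \code{recovery},
#'   \code{counts}).
#' @export
runPipeline <- function(config, outDir = NULL, quiet = FALSE) {
    stopifnot(inherits(config, "chronetConfig"))
    say <- function(...) if (!quiet) message("[chronet] ", ...)
    res <- list(config = config)

    ## ---- inputs ----------------------------------------------------------
    if (!is.null(config$simulation)) {
        say("simulating dataset (seed ", config$simulation$seed, ")")
        sim <- generateDataset(config$simulation)
        truth <- sim$truth
        tfNames <- truth$tf$tf_name
    } else {
        p <- config$inputs
        sim <- list(dhs = readMatrixWithSamples(p$dhs_matrix, p$samples),
                    gene = readMatrixWithSamples(p$gene_matrix, p$samples),
                    intervals = readHotspotsBed(p$hotspots),
                    annotation = readTssBed(p$tss))
        sim$motifHits <- readFimoHits(p$motif_hits, sim$intervals)
        truth <- NULL
        tfNames <- config$tfNames
        if (is.null(tfNames))
            stop("tfNames must name the TF rows of the gene matrix")
    }

    res$motifHits <- sim$motifHits

    ## ---- developmental regulation ---------------------------------------
    say("normalizing and fitting developmental models (", config$mode, ")")
    dhsN <- quantileNormalize(sim$dhs)
    geneN <- quantileNormalize(sim$gene)
    dhsFits <- callRegulated(fitDevelopmentalModel(dhsN, config$mode),
                             pAdjMax = config$pAdjMax,
                             minLog2Range = config$minLog2Range,
                             minMaxLevel = config$minMaxDensity,
                             featureKind = "dhs")
    geneFits <- callRegulated(fitDevelopmentalModel(geneN, config$mode),
                              pAdjMax = config$pAdjMax,
                              minLog2Range = config$minLog2Range,
                              minMaxLevel = config$minMaxFpkm,
                              featureKind = "gene")
    res$dhsFits <- dhsFits
    res$geneFits <- geneFits
    regDhs <- dhsFits$feature_id[dhsFits$regulated]
    regGene <- geneFits$feature_id[geneFits$regulated]
    say(length(regDhs), " regulated DHSs, ", length(regGene),
        " regulated genes")

    ## ---- temporal clustering ---------------------------------------------
    dhsDm <- dayMeans(dhsN)
    geneDm <- dayMeans(geneN)
    res$dhsClusters <- res$geneClusters <- res$enrichment <- NULL
    if (length(regDhs) >= config$k && length(regGene) >= config$k) {
        say("k-means temporal clustering (k = ", config$k, ")")
        res$dhsClusters <- kmeansProfiles(
            zscoreProfiles(dhsDm[regDhs, , drop = FALSE]), k = config$k,
            seed = childSeed(config$seed, "kmeans_dhs"), prefix = "E")
        res$geneClusters <- kmeansProfiles(
            zscoreProfiles(geneDm[regGene, , drop = FALSE]), k = config$k,
            seed = childSeed(config$seed, "kmeans_gene"), prefix = "G")
        res$enrichment <- clusterEnrichmentMatrix(
            res$geneClusters, res$dhsClusters, sim$annotation,
            sim$intervals, window = config$enrichmentWindow)
    } else say("too few regulated features to cluster; skipping")

    ## ---- linking ----------------------------------------------------------
    say("linking DHSs to genes (window ", config$linkWindow, " bp)")
    res$links <- linkDhsToGenes(geneDm[regGene, , drop = FALSE],
                                dhsDm[regDhs, , drop = FALSE],
                                sim$annotation, sim$intervals,
                                window = config$linkWindow,
                                minAbsR = config$minAbsR)
    res$linkSummary <- linkStats(res$links, regGene, regDhs,
                                 sim$annotation, sim$intervals,
                                 window = config$linkWindow)
    res$linksPositive <- linkDhsToGenes(geneDm[regGene, , drop = FALSE],
                                        dhsDm[regDhs, , drop = FALSE],
                                        sim$annotation, sim$intervals,
                                        window = config$linkWindow,
                                        minAbsR = config$minAbsR,
                                        requirePositive = TRUE)

    ## ---- motif enrichment --------------------------------------------------
    res$motifEnrichment <- NULL
    if (!is.null(res$dhsClusters) && nrow(sim$motifHits)) {
        say("motif-cluster enrichment")
        res$motifEnrichment <- motifClusterEnrichment(sim$motifHits,
                                                      res$dhsClusters)
    }

    ## ---- TF modeling -------------------------------------------------------
    res$tfModel <- NULL
    tfInMatrix <- intersect(tfNames, rownames(geneDm))
    if (!is.null(res$dhsClusters) && length(tfInMatrix)) {
        say("elastic-net TF modeling (", length(regDhs), " DHSs)")
        regTfs <- intersect(tfInMatrix, regGene)
        enet <- config$enet
        enet$seed <- childSeed(config$seed, "enet_cv")
        res$tfModel <- fitTfModels(
            dhsDm[regDhs, , drop = FALSE], res$dhsClusters,
            sim$motifHits, geneDm[tfInMatrix, , drop = FALSE],
            config = enet, minMaxFpkm = config$minMaxFpkm,
            requireRegulatedTf = config$requireRegulatedTf,
            regulatedTfs = regTfs)
        res$modelSummary <- modelSummary(res$tfModel)
    }

    ## ---- modules -----------------------------------------------------------
    res$modules <- NULL
    if (!is.null(res$tfModel)) {
        tfSel <- selectConnectedTfs(res$tfModel,
                                    minPositiveDhs = config$minPositiveDhs)
        if (length(tfSel) >= config$k) {
            say("resolving ", length(tfSel), " TFs into ", config$k,
                " modules")
            res$modules <- clusterTfsCosine(res$tfModel, tfSel,
                                            k = config$k,
                                            dhsDayMeans = dhsDm)
            res$moduleFractions <- moduleDhsFraction(res$tfModel, tfSel,
                                                     res$dhsClusters)
        } else say("no (or too few) TFs pass minPositiveDhs (",
                   length(tfSel), " of ", config$k,
                   " needed); skipping modules")
    }

    ## ---- stage networks ----------------------------------------------------
    res$networks <- NULL
    if (!is.null(res$modules)) {
        say("building stage-specific networks")
        mm <- res$modules$membership
        res$networks <- lapply(sort(unique(mm$module)), function(m)
            topTargets(buildNetwork(mm$tf_name[mm$module == m],
                                    res$tfModel, res$linksPositive),
                       n = config$topN))
        names(res$networks) <- paste0("module", sort(unique(mm$module)))
    }

    ## ---- recovery scoring --------------------------------------------------
    if (!is.null(truth)) {
        scored <- list(dhsRegulated = regDhs, geneRegulated = regGene,
                       links = res$links)
        if (!is.null(res$dhsClusters))
            scored$dhsClusters <- res$dhsClusters
        if (!is.null(res$modules))
            scored$tfModules <- data.frame(
                tf_name = res$modules$membership$tf_name,
                module = res$modules$membership$module,
                stringsAsFactors = FALSE)
        if (!is.null(res$tfModel))
            scored$coefficients <- coefMatrix(res$tfModel)
        res$recovery <- scoreRecovery(truth, scored)
        res$truth <- truth
    }
    res$counts <- c(n_dhs = nrow(sim$dhs), n_gene = nrow(sim$gene),
                    regulated_dhs = length(regDhs),
                    regulated_gene = length(regGene),
                    links = nrow(res$links),
                    module_tfs = if (is.null(res$modules)) 0L
                                 else nrow(res$modules$membership))
    if (!is.null(outDir)) res$manifest <- writeOutputs(res, outDir)
    res
}

#' Write pipeline results and a machine-readable manifest
#'
#' Emits one TSV per stage (fixed column order, 12-significant-digit
#' numeric convention), the stage networks as GraphML plus edge-list TSV,
#' and \code{manifest.json} recording the package version, seed,
#' parameters, per-stage output files with MD5 checksums, and feature
#' counts. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param results a \code{\link{runPipeline}} result.
#' @param outDir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
writeOutputs <- function(results, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(outDir, mode = 2L) != 0L)
        stop("output directory is not writable: ", outDir)
    files <- character()
    put <- function(df, name) {
        path <- file.path(outDir, name)
        writeTable(df, path)
        files[[name]] <<- path
    }
    stages <- list()
    addStage <- function(stage, ...) {
        stages[[stage]] <<- unname(unlist(list(...)))
    }
    if (!is.null(results$dhsFits)) {
        put(results$dhsFits, "dhs_fits.tsv")
        addStage("devreg_dhs", "dhs_fits.tsv")
    }
    if (!is.null(results$geneFits)) {
        put(results$geneFits, "gene_fits.tsv")
        addStage("devreg_gene", "gene_fits.tsv")
    }
    clFiles <- character()
    if (!is.null(results$dhsClusters)) {
        put(results$dhsClusters, "dhs_clusters.tsv")
        clFiles <- c(clFiles, "dhs_clusters.tsv")
    }
    if (!is.null(results$geneClusters)) {
        put(results$geneClusters, "gene_clusters.tsv")
        clFiles <- c(clFiles, "gene_clusters.tsv")
    }
    if (!is.null(results$enrichment)) {
        put(results$enrichment, "cluster_enrichment.tsv")
        clFiles <- c(clFiles, "cluster_enrichment.tsv")
    }
    if (length(clFiles)) addStage("temporal_clustering", clFiles)
    if (!is.null(results$links)) {
        put(results$links, "links.tsv")
        addStage("linking", "links.tsv")
    }
    if (!is.null(results$motifEnrichment)) {
        put(results$motifEnrichment, "motif_enrichment.tsv")
        addStage("motif_enrichment", "motif_enrichment.tsv")
    }
    if (!is.null(results$tfModel)) {
        co <- coefMatrix(results$tfModel)
        nz <- which(co != 0, arr.ind = TRUE)
        long <- data.frame(dhs_id = rownames(co)[nz[, 1L]],
                           tf_name = colnames(co)[nz[, 2L]],
                           coefficient = co[nz],
                           stringsAsFactors = FALSE)
        long <- long[order(long$dhs_id, long$tf_name), , drop = FALSE]
        put(long, "tf_coefficients.tsv")
        put(clusterParams(results$tfModel), "cluster_params.tsv")
        addStage("tfmodel", "tf_coefficients.tsv", "cluster_params.tsv")
    }
    if (!is.null(results$modules)) {
        put(results$modules$membership, "modules.tsv")
        fr <- results$moduleFractions
        if (!is.null(fr))
            put(data.frame(tf_name = rownames(fr), fr,
                           check.names = FALSE, stringsAsFactors = FALSE),
                "module_fractions.tsv")
        addStage("regmodules", "modules.tsv",
                 if (!is.null(fr)) "module_fractions.tsv")
    }
    if (!is.null(results$networks)) {
        nf <- character()
        for (nm in names(results$networks)) {
            gml <- file.path(outDir, paste0("network_", nm, ".graphml"))
            tsv <- paste0("network_", nm, "_edges.tsv")
            writeNetwork(results$networks[[nm]], gml,
                         file.path(outDir, tsv))
            files[[basename(gml)]] <- gml
            files[[tsv]] <- file.path(outDir, tsv)
            nf <- c(nf, basename(gml), tsv)
            cent <- nodeCentrality(results$networks[[nm]])
            cn <- paste0("network_", nm, "_centrality.tsv")
            put(cent, cn)
            nf <- c(nf, cn)
        }
        addStage("network", nf)
    }
    if (!is.null(results$recovery))
        files[["recovery.json"]] <- local({
            path <- file.path(outDir, "recovery.json")
            jsonlite::write_json(results$recovery, path,
                                 auto_unbox = TRUE, digits = NA)
            path
        })
    manifest <- list(
        package = "chronet",
        version = as.character(utils::packageVersion("chronet")),
        seed = results$config$seed,
        parameters = configForManifest(results$config),
        counts = as.list(results$counts),
        stages = stages,
        files = lapply(files, function(f)
            list(file = basename(f),
                 md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

configForManifest <- function(cfg) {
    out <- unclass(cfg)
    out$enet <- unclass(out$enet)
    if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
    out
}
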