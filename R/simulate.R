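#' Configuration for the synthetic differentiation time course
#'
#' Defaults emulate the design of a 13-day (days 0..12), 3-donor ex vivo
#' differentiation time course: five sequential regulatory modules (two
#' silencing ramps, one transient bump, two activation ramps), DHS densities
#' driven by module TF activities through a softplus response, gene FPKM
#' profiles driven by planted enhancer DHSs, and a motif-hit table with
#' degenerate background ("decoy") motifs.
#'
#' @param n_days number of sampled days (days are 0..n_days-1).
#' @param n_donors replicates per day.
#' @param n_tf number of transcription factors (two of them are flat,
#'   non-regulated decoy TFs exercising the expression filters).
#' @param n_modules number of planted regulatory modules (temporal classes).
#' @param n_dhs number of DHSs.
#' @param n_genes number of non-TF genes (TF genes are appended to the gene
#'   matrix under their TF names).
#' @param frac_changing_dhs fraction of DHSs with planted temporal structure.
#' @param frac_changing_gene fraction of non-TF genes with planted enhancers.
#' @param noise_sd replicate noise, as a fraction of each feature's dynamic
#'   range (normalized-signal scale).
#' @param effect_scale magnitude of planted TF-to-DHS effects.
#' @param decoy_motif_rate Poisson mean of background motif hits per
#'   (DHS, TF) pair; 0.5 makes roughly 39\% of TF motifs appear in a DHS
#'   without any causal effect, emulating degenerate motif vocabularies.
#' @param link_window bp window within which planted enhancers are placed
#'   around their target gene's TSS.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration.
#' @return a list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(n_days = 13L, n_donors = 3L, n_tf = 40L,
                             n_modules = 5L, n_dhs = 400L, n_genes = 100L,
                             frac_changing_dhs = 0.3,
                             frac_changing_gene = 0.4,
                             noise_sd = 0.1, effect_scale = 1,
                             decoy_motif_rate = 0.5, link_window = 1e6,
                             seed = 1L) {
    cfg <- list(n_days = as.integer(n_days), n_donors = as.integer(n_donors),
                n_tf = as.integer(n_tf), n_modules = as.integer(n_modules),
                n_dhs = as.integer(n_dhs), n_genes = as.integer(n_genes),
                frac_changing_dhs = frac_changing_dhs,
                frac_changing_gene = frac_changing_gene,
                noise_sd = noise_sd, effect_scale = effect_scale,
                decoy_motif_rate = decoy_motif_rate,
                link_window = link_window, seed = as.integer(seed))
    counts <- c("n_days", "n_donors", "n_tf", "n_modules", "n_dhs", "n_genes")
    if (any(unlist(cfg[counts]) <= 0))
        stop("all counts must be positive")
    if (frac_changing_dhs < 0 || frac_changing_dhs > 1)
        stop("frac_changing_dhs must be in [0, 1]")
    if (frac_changing_gene < 0 || frac_changing_gene > 1)
        stop("frac_changing_gene must be in [0, 1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (cfg$n_modules > cfg$n_tf - 2L)
        stop("need at least n_modules + 2 TFs")
    class(cfg) <- "simulationConfig"
    cfg
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

logisticCurve <- function(d, mid, scale) 1 / (1 + exp(-(d - mid) / scale))

## class of each module: -1 down ramp, 0 transient bump, +1 up ramp
moduleClasses <- function(k) {
    if (k == 1L) return(1L)
    nDown <- max(1L, floor((k - 1L) / 2L))
    hasTransient <- k >= 3L
    nUp <- k - nDown - as.integer(hasTransient)
    c(rep(-1L, nDown), if (hasTransient) 0L, rep(1L, nUp))
}

## noiseless activity curve in [0, 1]. The temporal position (logistic
## midpoint) is a property of the MODULE -- modules of the same ramp class
## are spread across distinct midpoints -- while individual TFs only jitter
## around their module's curve (shift in days, steepness factor), keeping
## modules separable but members distinguishable.
moduleCurve <- function(class, classRank, nClassModules, days, shift = 0,
                        steep = 1) {
    dmax <- max(days)
    spread <- function(i, n, lo, hi)
        if (n == 1L) (lo + hi) / 2 else lo + (hi - lo) * (i - 1) / (n - 1)
    if (class == -1L) {
        mid <- spread(classRank, nClassModules, 0.18, 0.48) * dmax + shift
        y <- 1 - logisticCurve(days, mid, 0.8 / steep)
    } else if (class == 1L) {
        mid <- spread(classRank, nClassModules, 0.55, 0.8) * dmax + shift
        y <- logisticCurve(days, mid, 0.8 / steep)
    } else {
        y <- logisticCurve(days, 0.3 * dmax + shift, 0.7 / steep) -
             logisticCurve(days, 0.68 * dmax + shift, 0.7 / steep)
    }
    (y - min(y)) / (max(y) - min(y))
}

rescaleTo <- function(y, lo, hi) {
    r <- max(y) - min(y)
    if (r == 0) return(rep((lo + hi) / 2, length(y)))
    lo + (hi - lo) * (y - min(y)) / r
}

#' Generate a synthetic differentiation time course with planted structure
#'
#' See \code{\link{simulationConfig}} for the generative model. The returned
#' truth ledger records every planted fact needed for recovery scoring:
#' per-TF module labels and activity curves, per-DHS changing flags, cluster
#' labels and true TF effects, per-gene changing flags and enhancer links,
#' and all genomic coordinates (one synthetic chromosome, \code{chrS}).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{dhs} and \code{gene}
#'   (\linkS4class{TimeCourseExperiment}s), \code{motifHits} (data.frame),
#'   \code{intervals} and \code{annotation} (\link[GenomicRanges]{GRanges}),
#'   and \code{truth} (list).
#' @export
generateDataset <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "simulationConfig"))
    withSeed(config$seed, generateDatasetImpl(config))
}

generateDatasetImpl <- function(cfg) {
    days <- 0:(cfg$n_days - 1L)
    D <- cfg$n_days
    sampleDay <- rep(days, each = cfg$n_donors)
    donors <- sprintf("donor%d", seq_len(cfg$n_donors))
    sampleDonor <- rep(donors, times = D)
    sampleId <- sprintf("d%02d_%s", sampleDay, sampleDonor)
    nS <- length(sampleId)

    ## ---- transcription factors -------------------------------------------
    classes <- moduleClasses(cfg$n_modules)
    nReg <- cfg$n_tf - 2L                      # last two TFs are flat decoys
    tfModule <- rep(seq_len(cfg$n_modules), length.out = nReg)
    tfName <- sprintf("TF%02d", seq_len(cfg$n_tf))
    tfAct <- matrix(0, cfg$n_tf, D, dimnames = list(tfName, days))
    classRank <- integer(cfg$n_modules)
    for (cl in unique(classes)) {
        same <- which(classes == cl)
        classRank[same] <- seq_along(same)
    }
    for (m in seq_len(cfg$n_modules)) {
        idx <- which(tfModule == m)
        for (j in seq_along(idx))
            tfAct[idx[j], ] <- moduleCurve(classes[m], classRank[m],
                                           sum(classes == classes[m]), days,
                                           shift = runif(1, -0.4, 0.4),
                                           steep = runif(1, 0.85, 1.2))
    }
    tfGain <- runif(cfg$n_tf, 5, 60)
    tfGain[nReg + 2L] <- 20
    tfExpr <- matrix(0, cfg$n_tf, nS, dimnames = list(tfName, sampleId))
    for (t in seq_len(nReg))
        tfExpr[t, ] <- pmax(0, tfGain[t] * (0.05 + 0.95 * tfAct[t, sampleDay + 1L]) +
                                rnorm(nS, 0, cfg$noise_sd * tfGain[t]))
    tfExpr[nReg + 1L, ] <- pmax(0, 0.5 + rnorm(nS, 0, 0.05))   # below FPKM 2
    tfExpr[nReg + 2L, ] <- pmax(0, 20 + rnorm(nS, 0, cfg$noise_sd * 20))
    tfModuleFull <- c(tfModule, NA_integer_, NA_integer_)

    ## ---- DHSs -------------------------------------------------------------
    nChg <- round(cfg$frac_changing_dhs * cfg$n_dhs)
    dhsId <- sprintf("dhs%05d", seq_len(cfg$n_dhs))
    changing <- seq_len(cfg$n_dhs) <= nChg
    dhsModule <- rep(NA_integer_, cfg$n_dhs)
    if (nChg > 0)
        dhsModule[seq_len(nChg)] <- rep(seq_len(cfg$n_modules),
                                        length.out = nChg)
    effects <- vector("list", cfg$n_dhs)
    dhsDaily <- matrix(0, cfg$n_dhs, D, dimnames = list(dhsId, days))
    dhsSignal <- matrix(0, cfg$n_dhs, nS, dimnames = list(dhsId, sampleId))
    mirror <- function(m) {      # a module of the opposite ramp direction
        opp <- if (classes[m] == 1L) which(classes == -1L)
               else if (classes[m] == -1L) which(classes == 1L) else integer()
        if (length(opp)) opp[1L] else NA_integer_
    }
    for (i in seq_len(cfg$n_dhs)) {
        if (changing[i]) {
            m <- dhsModule[i]
            pool <- which(tfModule == m)
            nEff <- sample(1:2, 1L)
            tfs <- sample(pool, min(nEff, length(pool)))
            eff <- cfg$effect_scale * runif(length(tfs), 0.7, 1.3)
            mm <- mirror(m)
            if (!is.na(mm) && runif(1) < 0.2) {
                ## weak repressive input from the opposite ramp class; its
                ## negated curve runs in the DHS's own direction, so the
                ## class shape stays dominated by the module program
                negTf <- sample(which(tfModule == mm), 1L)
                tfs <- c(tfs, negTf)
                eff <- c(eff, -cfg$effect_scale * runif(1, 0.25, 0.5))
            }
            effects[[i]] <- data.frame(dhs_id = dhsId[i],
                                       tf_name = tfName[tfs],
                                       effect = eff,
                                       stringsAsFactors = FALSE)
            z <- as.vector(eff %*% tfAct[tfs, , drop = FALSE])
            lo <- runif(1, 2, 8); hi <- runif(1, 40, 150)
            daily <- rescaleTo(softplus(4 + 2 * z), lo, hi)
            dhsDaily[i, ] <- daily
            dhsSignal[i, ] <- pmax(0, daily[sampleDay + 1L] +
                rnorm(nS, 0, cfg$noise_sd * (hi - lo)))
        } else {
            lev <- runif(1, 5, 80)
            dhsDaily[i, ] <- lev
            dhsSignal[i, ] <- pmax(0, lev + rnorm(nS, 0, cfg$noise_sd * 20))
        }
    }

    ## ---- genes ------------------------------------------------------------
    nChgGene <- round(cfg$frac_changing_gene * cfg$n_genes)
    geneId <- sprintf("gene%04d", seq_len(cfg$n_genes))
    geneChanging <- seq_len(cfg$n_genes) <= nChgGene
    geneModule <- rep(NA_integer_, cfg$n_genes)
    if (nChgGene > 0)
        geneModule[seq_len(nChgGene)] <- rep(seq_len(cfg$n_modules),
                                             length.out = nChgGene)
    ## exclusive enhancer assignment from same-module changing DHSs; each
    ## gene draws 1-3, capped by a fair share of its module's pool so a
    ## valid config can never exhaust the pool mid-assignment
    pools <- split(which(changing), dhsModule[changing])
    if (nChgGene > 0) {
        genesPerModule <- table(factor(geneModule[seq_len(nChgGene)],
                                       levels = seq_len(cfg$n_modules)))
        poolSizes <- vapply(as.character(seq_len(cfg$n_modules)),
                            function(m) length(pools[[m]]), numeric(1))
        if (any(poolSizes < as.numeric(genesPerModule)))
            stop("not enough changing DHSs to plant enhancers; ",
                 "increase n_dhs or frac_changing_dhs")
        fairShare <- pmax(1, floor(poolSizes / pmax(1,
            as.numeric(genesPerModule))))
        names(fairShare) <- as.character(seq_len(cfg$n_modules))
    }
    geneEnh <- vector("list", cfg$n_genes)
    geneDaily <- matrix(0, cfg$n_genes, D, dimnames = list(geneId, days))
    geneSignal <- matrix(0, cfg$n_genes, nS, dimnames = list(geneId, sampleId))
    for (g in seq_len(cfg$n_genes)) {
        if (geneChanging[g]) {
            m <- as.character(geneModule[g])
            avail <- pools[[m]]
            nEnh <- min(sample(1:3, 1L), fairShare[[m]], length(avail))
            enh <- avail[seq_len(nEnh)]           # deterministic draw order
            pools[[m]] <- setdiff(avail, enh)
            w <- runif(nEnh, 0.5, 1.5)
            geneEnh[[g]] <- data.frame(gene_id = geneId[g],
                                       dhs_id = dhsId[enh], weight = w,
                                       stringsAsFactors = FALSE)
            prof <- as.vector(w %*% dhsDaily[enh, , drop = FALSE])
            lo <- runif(1, 0.5, 2); hi <- runif(1, 8, 60)
            daily <- rescaleTo(prof, lo, hi)
            geneDaily[g, ] <- daily
            geneSignal[g, ] <- pmax(0, daily[sampleDay + 1L] +
                rnorm(nS, 0, cfg$noise_sd * (hi - lo)))
        } else {
            lev <- runif(1, 0.5, 30)
            geneDaily[g, ] <- lev
            geneSignal[g, ] <- pmax(0, lev + rnorm(nS, 0, cfg$noise_sd * 5))
        }
    }

    ## ---- motif hits: one per true effect + per-pair Poisson decoys --------
    trueHits <- do.call(rbind, effects[!vapply(effects, is.null, TRUE)])
    decoyCount <- matrix(rpois(cfg$n_dhs * cfg$n_tf, cfg$decoy_motif_rate),
                         cfg$n_dhs, cfg$n_tf, dimnames = list(dhsId, tfName))
    dec <- which(decoyCount > 0, arr.ind = TRUE)
    hits <- data.frame(dhs_id = dhsId[dec[, 1L]], tf_name = tfName[dec[, 2L]],
                       hit_count = as.integer(decoyCount[dec]),
                       stringsAsFactors = FALSE)
    if (!is.null(trueHits) && nrow(trueHits)) {
        th <- data.frame(dhs_id = trueHits$dhs_id, tf_name = trueHits$tf_name,
                         hit_count = sample(1:3, nrow(trueHits),
                                            replace = TRUE),
                         stringsAsFactors = FALSE)
        hits <- rbind(hits, th)
    }
    if (nrow(hits)) {
        hits <- aggregate(hit_count ~ dhs_id + tf_name, hits, sum)
        hits$hit_count <- as.integer(hits$hit_count)
        hits <- hits[order(hits$dhs_id, hits$tf_name), , drop = FALSE]
        rownames(hits) <- NULL
    }

    ## ---- coordinates on one synthetic chromosome --------------------------
    W <- cfg$link_window
    spacing <- 4.2 * W
    geneTss <- (seq_len(cfg$n_genes)) * spacing
    tfTssStart <- max(geneTss) + 3 * W
    tfTss <- tfTssStart + (seq_len(cfg$n_tf)) * 3 * W
    dhsPos <- rep(NA_real_, cfg$n_dhs)
    allLinks <- do.call(rbind, geneEnh[!vapply(geneEnh, is.null, TRUE)])
    if (!is.null(allLinks) && nrow(allLinks)) {
        for (r in seq_len(nrow(allLinks))) {
            g <- match(allLinks$gene_id[r], geneId)
            d <- match(allLinks$dhs_id[r], dhsId)
            off <- sample(c(-1, 1), 1L) *
                min(2000 + stats::rexp(1, rate = 1 / (W / 8)), 0.8 * W)
            dhsPos[d] <- geneTss[g] + off
        }
    }
    ## outside-window decoys: changing DHSs at 1.2-2x the window from a
    ## changing gene, same module where possible so the decoy is a DHS the
    ## correlation filter alone would link
    chgGenes <- which(geneChanging)
    for (g in chgGenes) {
        leftover <- which(changing & is.na(dhsPos))
        if (!length(leftover)) break
        same <- leftover[dhsModule[leftover] == geneModule[g]]
        d <- if (length(same)) same[1L] else leftover[1L]
        dhsPos[d] <- geneTss[g] + sample(c(-1, 1), 1L) * runif(1, 1.2, 2) * W
    }
    ## inside-window non-changing decoys near gene TSSs
    ncIdx <- which(!changing)
    nIn <- min(length(ncIdx), cfg$n_genes)
    if (nIn > 0)
        dhsPos[ncIdx[seq_len(nIn)]] <-
            geneTss[seq_len(nIn)] + sample(c(-1, 1), nIn, replace = TRUE) *
                runif(nIn, 5000, 0.9 * W)
    ## everything else lands in a distal zone clear of all gene windows
    rest <- which(is.na(dhsPos))
    distalStart <- max(tfTss) + 3 * W
    if (length(rest))
        dhsPos[rest] <- distalStart + seq_along(rest) * 1e4
    dhsPos <- round(dhsPos)

    intervals <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = dhsPos - 99, width = 200))
    names(intervals) <- dhsId
    allGeneIds <- c(geneId, tfName)
    annotation <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = c(geneTss, tfTss) + 1, width = 1),
        strand = rep(c("+", "-"), length.out = length(allGeneIds)))
    names(annotation) <- allGeneIds

    ## ---- assemble ---------------------------------------------------------
    sheet <- data.frame(sample_id = sampleId, donor = sampleDonor,
                        day = sampleDay, stringsAsFactors = FALSE)
    dhsTc <- TimeCourseExperiment(dhsSignal, sheet)
    geneTc <- TimeCourseExperiment(rbind(geneSignal, tfExpr), sheet)

    effectsDf <- if (is.null(trueHits)) {
        data.frame(dhs_id = character(), tf_name = character(),
                   effect = numeric(), stringsAsFactors = FALSE)
    } else trueHits
    linksDf <- if (is.null(allLinks)) {
        data.frame(gene_id = character(), dhs_id = character(),
                   weight = numeric(), stringsAsFactors = FALSE)
    } else allLinks

    truth <- list(
        tf = data.frame(tf_name = tfName, module = tfModuleFull,
                        gain = tfGain, stringsAsFactors = FALSE),
        tfActivity = tfAct,
        dhs = data.frame(dhs_id = dhsId, changing = changing,
                         cluster = dhsModule, stringsAsFactors = FALSE),
        dhsDaily = dhsDaily,
        effects = effectsDf,
        gene = data.frame(gene_id = allGeneIds,
                          changing = c(geneChanging,
                                       !is.na(tfModuleFull)),
                          module = c(geneModule, tfModuleFull),
                          stringsAsFactors = FALSE),
        links = linksDf,
        config = unclass(cfg))
    list(dhs = dhsTc, gene = geneTc, motifHits = hits,
         intervals = intervals, annotation = annotation, truth = truth)
}

#' Write a simulated dataset in the pipeline's on-disk input formats
#'
#' Emits the DHS and gene matrices with a shared sample sheet (TSV), the DHS
#' hotspot intervals and gene TSS annotation (BED), and the motif-hit table
#' (pre-intersected TSV), so a run can start from files.
#'
#' @param sim result of \code{\link{generateDataset}}.
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulatedInputs <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeMatrixTsv <- function(tc, path) {
        m <- SummarizedExperiment::assay(tc)
        df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        writeTable(df, path)
    }
    writeMatrixTsv(sim$dhs, p("dhs_matrix.tsv"))
    writeMatrixTsv(sim$gene, p("gene_matrix.tsv"))
    cd <- SummarizedExperiment::colData(sim$dhs)
    writeTable(data.frame(sample_id = rownames(cd), donor = cd$donor,
                          day = cd$day, stringsAsFactors = FALSE),
               p("samples.tsv"))
    bed <- function(gr, path, strand = FALSE) {
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr),
                         id = names(gr))
        if (strand) {
            df$score <- 0L
            df$strand <- as.character(GenomicRanges::strand(gr))
        }
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    bed(sim$intervals, p("hotspots.bed"))
    bed(sim$annotation, p("tss.bed"), strand = TRUE)
    writeTable(sim$motifHits, p("motif_hits.tsv"))
    files <- c(dhs_matrix = p("dhs_matrix.tsv"),
               gene_matrix = p("gene_matrix.tsv"),
               samples = p("samples.tsv"), hotspots = p("hotspots.bed"),
               tss = p("tss.bed"), motif_hits = p("motif_hits.tsv"))
    invisible(files)
}
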