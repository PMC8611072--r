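#' z-score per-day mean profiles
#'
#' @param x a \linkS4class{TimeCourseExperiment} or a features-x-days
#'   matrix of per-day means.
#' @param featureIds optional subset of features.
#' @return matrix of row-wise z-scored profiles (mean 0, sd 1 per feature).
#' @export
zscoreProfiles <- function(x, featureIds = NULL) {
    dm <- if (is(x, "TimeCourseExperiment")) dayMeans(x) else as.matrix(x)
    if (!is.null(featureIds)) {
        missing <- setdiff(featureIds, rownames(dm))
        if (length(missing))
            stop("unknown feature id(s): ",
                 paste(head(missing, 5L), collapse = ", "))
        dm <- dm[featureIds, , drop = FALSE]
    }
    zscoreRows(dm)
}

#' K-means clustering of temporal profiles into sequential classes
#'
#' Euclidean k-means on z-scored per-day profiles, best of
#' \code{nRestarts} random starts by total within-cluster sum of squares.
#' Cluster labels are renumbered so that cluster mean-profile peak days are
#' non-decreasing (ties broken by the profile's center of mass), making
#' label 1 the earliest-peaking class.
#'
#' @param zprofiles features-x-days matrix of z-scored profiles.
#' @param k number of clusters.
#' @param nRestarts random restarts.
#' @param seed integer seed; the assignment is deterministic given it.
#' @param prefix label prefix (\code{"E"} for DHSs, \code{"G"} for genes).
#' @return data.frame with columns \code{feature_id}, \code{cluster}
#'   (integer 1..k), \code{label}; attributes \code{centers} (k x days) and
#'   \code{restart_objectives}.
#' @export
kmeansProfiles <- function(zprofiles, k = 5L, nRestarts = 50L, seed = 1L,
                           prefix = "E") {
    z <- as.matrix(zprofiles)
    if (k > nrow(z)) stop("k exceeds the number of features")
    if (any(!is.finite(z))) stop("non-finite profile values")
    withSeed(seed, {
        best <- NULL
        objectives <- numeric(nRestarts)
        for (r in seq_len(nRestarts)) {
            km <- suppressWarnings(
                kmeans(z, centers = k, iter.max = 100L, nstart = 1L))
            objectives[r] <- km$tot.withinss
            if (is.null(best) || km$tot.withinss < best$tot.withinss)
                best <- km
        }
        centers <- best$centers
        peak <- apply(centers, 1L, which.max)
        ndays <- ncol(centers)
        com <- apply(centers, 1L, function(p) {
            w <- p - min(p)
            if (sum(w) == 0) return(ndays / 2)
            sum(seq_len(ndays) * w) / sum(w)
        })
        ord <- order(peak, com)
        relabel <- match(seq_len(k), ord)
        cluster <- relabel[best$cluster]
        out <- data.frame(feature_id = rownames(z), cluster = cluster,
                          label = paste0(prefix, cluster),
                          stringsAsFactors = FALSE)
        attr(out, "centers") <- centers[ord, , drop = FALSE]
        attr(out, "tot.withinss") <- best$tot.withinss
        attr(out, "restart_objectives") <- objectives
        out
    })
}

#' Gene-cluster by DHS-cluster enrichment matrix
#'
#' For each gene cluster Gi and DHS cluster Ej, counts the regulated DHSs of
#' Ej whose midpoint lies within \code{window} bp of the TSS of any gene in
#' Gi. Expected counts assume Ej membership is independent of window
#' occupancy: expected = (in-window DHSs for Gi) x (share of Ej among all
#' regulated DHSs). The enrichment score is
#' log2((observed + 0.5) / (expected + 0.5)); each cell also carries a
#' chi-square test (no continuity correction) on the 2x2 table
#' membership-in-Ej by presence-in-Gi-windows, with cells of expected
#' count < 5 flagged.
#'
#' @param geneClusters,dhsClusters data.frames from
#'   \code{\link{kmeansProfiles}}.
#' @param annotation TSS \link[GenomicRanges]{GRanges} (names = gene ids).
#' @param intervals DHS \link[GenomicRanges]{GRanges} (names = DHS ids).
#' @param window half-width of the TSS-centered window in bp.
#' @return data.frame with columns gene_cluster, dhs_cluster, observed,
#'   expected, log2_ratio, chi2_p, low_expected.
#' @export
clusterEnrichmentMatrix <- function(geneClusters, dhsClusters, annotation,
                                    intervals, window = 50000) {
    gLabs <- sort(unique(geneClusters$label))
    eLabs <- sort(unique(dhsClusters$label))
    dhsIds <- dhsClusters$feature_id
    miss <- setdiff(dhsIds, names(intervals))
    if (length(miss))
        stop("DHS id(s) missing coordinates: ",
             paste(head(miss, 5L), collapse = ", "))
    mid <- intervalMidpoint(intervals[dhsIds])
    midGr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(intervals[dhsIds]),
        IRanges::IRanges(start = mid + 1L, width = 1L))
    total <- length(dhsIds)
    eOf <- dhsClusters$label
    nE <- table(factor(eOf, levels = eLabs))
    rows <- list()
    for (g in gLabs) {
        genes <- geneClusters$feature_id[geneClusters$label == g]
        genes <- intersect(genes, names(annotation))
        if (!length(genes)) {
            warning("gene cluster ", g, " has no annotated genes; NA row")
            rows[[g]] <- data.frame(gene_cluster = g, dhs_cluster = eLabs,
                                    observed = NA_integer_,
                                    expected = NA_real_,
                                    log2_ratio = NA_real_,
                                    chi2_p = NA_real_, low_expected = NA,
                                    stringsAsFactors = FALSE)
            next
        }
        tss <- annotation[genes]
        win <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(tss),
            IRanges::IRanges(
                start = pmax(1L, GenomicRanges::start(tss) - as.integer(window)),
                end = GenomicRanges::end(tss) + as.integer(window)))
        inWin <- GenomicRanges::countOverlaps(midGr, win,
                                              ignore.strand = TRUE) > 0
        nWin <- sum(inWin)
        obs <- as.integer(table(factor(eOf[inWin], levels = eLabs)))
        expd <- nWin * as.numeric(nE) / total
        l2r <- log2((obs + 0.5) / (expd + 0.5))
        chi2p <- vapply(seq_along(eLabs), function(j) {
            a <- obs[j]; b <- nWin - a
            c0 <- as.numeric(nE[j]) - a; d0 <- total - a - b - c0
            tot <- a + b + c0 + d0
            denom <- (a + b) * (c0 + d0) * (a + c0) * (b + d0)
            if (denom == 0) return(NA_real_)
            stat <- tot * (a * d0 - b * c0)^2 / denom
            pchisq(stat, df = 1, lower.tail = FALSE)
        }, numeric(1))
        lowExp <- expd < 5
        rows[[g]] <- data.frame(gene_cluster = g, dhs_cluster = eLabs,
                                observed = obs, expected = expd,
                                log2_ratio = l2r, chi2_p = chi2p,
                                low_expected = lowExp,
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
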