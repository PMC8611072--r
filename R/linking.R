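#' Link regulated DHSs to regulated genes by temporal correlation
#'
#' Candidate pairs are (DHS, gene) on the same chromosome with the DHS
#' midpoint within \code{window} bp of the gene TSS. A candidate becomes a
#' link when the Pearson correlation of the per-day mean profiles passes
#' the threshold: \code{|r| > minAbsR} for discovery links
#' (\code{requirePositive = FALSE}) or \code{r >= minAbsR} for the
#' positive-only network variant. Distances are signed, strand-aware
#' (upstream of the TSS is negative). Zero-variance profiles are skipped
#' and counted in \code{attr(x, "skipped_zero_variance")}.
#'
#' @param geneProfiles,dhsProfiles features-x-days matrices of per-day
#'   means (e.g. \code{dayMeans} of the regulated subsets); day grids must
#'   match.
#' @param annotation TSS \link[GenomicRanges]{GRanges} (names = gene ids).
#' @param intervals DHS \link[GenomicRanges]{GRanges} (names = DHS ids).
#' @param window candidate window in bp around the TSS.
#' @param minAbsR correlation threshold.
#' @param requirePositive if TRUE keep only r >= minAbsR.
#' @return data.frame with columns dhs_id, gene_id, r, distance.
#' @export
linkDhsToGenes <- function(geneProfiles, dhsProfiles, annotation, intervals,
                           window = 1e6, minAbsR = 0.7,
                           requirePositive = FALSE) {
    if (window <= 0) stop("window must be positive")
    gp <- as.matrix(geneProfiles)
    dp <- as.matrix(dhsProfiles)
    if (!identical(colnames(gp), colnames(dp)))
        stop("gene and DHS profiles are on different day grids")
    geneIds <- intersect(rownames(gp), names(annotation))
    dhsIds <- intersect(rownames(dp), names(intervals))
    empty <- data.frame(dhs_id = character(), gene_id = character(),
                        r = numeric(), distance = numeric(),
                        stringsAsFactors = FALSE)
    if (!length(geneIds) || !length(dhsIds)) {
        attr(empty, "skipped_zero_variance") <- 0L
        return(empty)
    }
    tss <- annotation[geneIds]
    dhs <- intervals[dhsIds]
    mid <- intervalMidpoint(dhs)
    midGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(dhs),
        IRanges::IRanges(start = mid + 1L, width = 1L))
    win <- GenomicRanges::GRanges(GenomicRanges::seqnames(tss),
        IRanges::IRanges(
            start = pmax(1L, GenomicRanges::start(tss) - as.integer(window)),
            end = GenomicRanges::end(tss) + as.integer(window)))
    ov <- GenomicRanges::findOverlaps(midGr, win, ignore.strand = TRUE)
    if (!length(ov)) {
        attr(empty, "skipped_zero_variance") <- 0L
        return(empty)
    }
    di <- S4Vectors::queryHits(ov)
    gi <- S4Vectors::subjectHits(ov)
    dz <- apply(dp[dhsIds, , drop = FALSE], 1L, sd) == 0
    gz <- apply(gp[geneIds, , drop = FALSE], 1L, sd) == 0
    skip <- dz[di] | gz[gi]
    nSkip <- sum(skip)
    di <- di[!skip]; gi <- gi[!skip]
    r <- vapply(seq_along(di), function(j)
        cor(dp[dhsIds[di[j]], ], gp[geneIds[gi[j]], ]), numeric(1))
    tss0 <- GenomicRanges::start(tss) - 1L
    dist <- mid[di] - tss0[gi]
    neg <- as.character(GenomicRanges::strand(tss))[gi] == "-"
    dist[neg] <- -dist[neg]
    keep <- if (requirePositive) r >= minAbsR else abs(r) > minAbsR
    out <- data.frame(dhs_id = dhsIds[di[keep]], gene_id = geneIds[gi[keep]],
                      r = r[keep], distance = dist[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_id, out$dhs_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "skipped_zero_variance") <- nSkip
    out
}

#' Summary statistics for a set of DHS-gene links
#'
#' @param links output of \code{\link{linkDhsToGenes}}.
#' @param geneIds,dhsIds the regulated feature sets the links were computed
#'   on.
#' @param annotation,intervals coordinates, as in
#'   \code{\link{linkDhsToGenes}}.
#' @param window the candidate window used.
#' @return list with fraction of genes / DHSs with at least one link, mean
#'   and SD of links per gene, mean candidate (in-window) DHSs per gene,
#'   and a histogram of |distance| in 10 kb bins.
#' @export
linkStats <- function(links, geneIds, dhsIds, annotation, intervals,
                      window = 1e6) {
    linksPerGene <- table(factor(links$gene_id, levels = geneIds))
    dhsLinked <- unique(links$dhs_id)
    cand <- rep(0L, length(geneIds))
    gKnown <- intersect(geneIds, names(annotation))
    dKnown <- intersect(dhsIds, names(intervals))
    if (length(gKnown) && length(dKnown)) {
        tss <- annotation[gKnown]
        dhs <- intervals[dKnown]
        mid <- intervalMidpoint(dhs)
        midGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(dhs),
            IRanges::IRanges(start = mid + 1L, width = 1L))
        win <- GenomicRanges::GRanges(GenomicRanges::seqnames(tss),
            IRanges::IRanges(
                start = pmax(1L, GenomicRanges::start(tss) -
                                 as.integer(window)),
                end = GenomicRanges::end(tss) + as.integer(window)))
        cnt <- GenomicRanges::countOverlaps(win, midGr,
                                            ignore.strand = TRUE)
        cand <- setNames(rep(0L, length(geneIds)), geneIds)
        cand[gKnown] <- cnt
    }
    histBins <- if (nrow(links)) {
        b <- floor(abs(links$distance) / 1e4)
        tb <- table(b)
        data.frame(bin_start = as.numeric(names(tb)) * 1e4,
                   count = as.integer(tb))
    } else data.frame(bin_start = numeric(), count = integer())
    list(frac_genes_linked = if (length(geneIds))
             mean(linksPerGene > 0) else 0,
         frac_dhs_linked = if (length(dhsIds))
             length(intersect(dhsLinked, dhsIds)) / length(dhsIds) else 0,
         mean_links_per_gene = if (length(geneIds))
             mean(linksPerGene) else 0,
         sd_links_per_gene = if (length(geneIds) > 1)
             sd(linksPerGene) else 0,
         mean_candidates_per_gene = if (length(geneIds))
             mean(cand) else 0,
         distance_histogram = histBins)
}
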