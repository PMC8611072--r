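#' Motif over/under-representation per temporal DHS cluster
#'
#' Presence/absence testing: a TF is "present" in a DHS when it has at
#' least one motif hit there. For each (TF, cluster) pair the
#' over-representation p-value is the upper hypergeometric tail
#' \eqn{P[X \ge k]} with population size N (the universe), K
#' motif-carrying DHSs in the universe, n DHSs in the cluster and k
#' motif-carrying DHSs in the cluster; under-representation is the
#' complementary tail \eqn{P[X \le k]}. Benjamini-Hochberg adjustment is
#' applied to the over-representation p-values across all pairs.
#'
#' @param hits motif-hit data.frame (dhs_id, tf_name, hit_count).
#' @param clusters data.frame from \code{\link{kmeansProfiles}} (the
#'   changing DHSs).
#' @param universe \code{"changing"} (the clustered set; default) or
#'   \code{"all"} (requires \code{allIds}).
#' @param allIds character vector of all detected DHS ids, for
#'   \code{universe = "all"}.
#' @param groupMap optional data.frame (tf_name, group) collapsing motifs
#'   into archetype groups before testing; presence of a group = presence
#'   of any member motif.
#' @return data.frame with columns tf_name, cluster_label, n_universe,
#'   n_cluster, n_with_motif_universe, n_with_motif_cluster, p_over,
#'   p_under, p_adj.
#' @export
motifClusterEnrichment <- function(hits, clusters,
                                   universe = c("changing", "all"),
                                   allIds = NULL, groupMap = NULL) {
    universe <- match.arg(universe)
    uniIds <- if (universe == "changing") clusters$feature_id else allIds
    if (!length(uniIds)) stop("empty universe")
    if (!all(clusters$feature_id %in% uniIds))
        stop("cluster ids must be a subset of the universe")
    h <- hits[hits$hit_count >= 1 & hits$dhs_id %in% uniIds, , drop = FALSE]
    if (!is.null(groupMap)) {
        idx <- match(h$tf_name, groupMap$tf_name)
        if (anyNA(idx))
            stop("groupMap missing TF(s): ",
                 paste(head(unique(h$tf_name[is.na(idx)]), 5L),
                       collapse = ", "))
        h$tf_name <- groupMap$group[idx]
    }
    tfs <- sort(unique(h$tf_name))
    labs <- sort(unique(clusters$label))
    N <- length(uniIds)
    presence <- split(h$dhs_id, h$tf_name)   # unique ids per tf/group
    presence <- lapply(presence, unique)
    clMembers <- split(clusters$feature_id, clusters$label)
    rows <- vector("list", length(tfs) * length(labs))
    i <- 0L
    for (tf in tfs) {
        withMotif <- presence[[tf]]
        K <- length(withMotif)
        for (lab in labs) {
            mem <- clMembers[[lab]]
            n <- length(mem)
            k <- length(intersect(withMotif, mem))
            i <- i + 1L
            rows[[i]] <- data.frame(
                tf_name = tf, cluster_label = lab, n_universe = N,
                n_cluster = n, n_with_motif_universe = K,
                n_with_motif_cluster = k,
                p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                p_under = phyper(k, K, N - K, n),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p_over, method = "BH")
    rownames(out) <- NULL
    out
}
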