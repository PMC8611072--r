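#' Build a stage-specific TF-to-gene regulatory network
#'
#' Each stage TF reaches its positively associated DHSs (strictly positive
#' elastic-net coefficient); each such DHS reaches its positively
#' correlated target genes (links computed with
#' \code{requirePositive = TRUE}). Multi-DHS (TF, gene) paths are
#' aggregated by summing the per-DHS products coefficient x correlation;
#' the standardized weight rescales the raw weights to mean 0 and
#' (sample) SD 1 across the network's edges, 0 by convention for a
#' single-edge network.
#'
#' @param stageTfs character vector of stage-specific TFs (must be
#'   modeled TFs).
#' @param coefs a \linkS4class{TFCoefficientMatrix} or DHS x TF matrix.
#' @param links positive-only links from \code{\link{linkDhsToGenes}}.
#' @param aggregate \code{"sum"} (default) or \code{"max"} over multi-DHS
#'   paths.
#' @return a \linkS4class{TFNetwork}.
#' @export
buildNetwork <- function(stageTfs, coefs, links,
                         aggregate = c("sum", "max")) {
    aggregate <- match.arg(aggregate)
    co <- if (is(coefs, "TFCoefficientMatrix")) coefMatrix(coefs)
          else as.matrix(coefs)
    unknown <- setdiff(stageTfs, colnames(co))
    if (length(unknown))
        stop("unknown TF(s): ", paste(unknown, collapse = ", "))
    edges <- list()
    isolated <- character()
    for (tf in stageTfs) {
        posDhs <- rownames(co)[co[, tf] > 0]
        li <- links[links$dhs_id %in% posDhs, , drop = FALSE]
        if (!nrow(li)) { isolated <- c(isolated, tf); next }
        prod <- co[li$dhs_id, tf] * li$r
        agg <- if (aggregate == "sum")
            tapply(prod, li$gene_id, sum)
        else tapply(prod, li$gene_id, max)
        via <- tapply(li$dhs_id, li$gene_id,
                      function(d) paste(sort(d), collapse = ","))
        edges[[tf]] <- data.frame(tf = tf, gene = names(agg),
                                  via_dhs = as.character(via[names(agg)]),
                                  raw_weight = as.numeric(agg),
                                  stringsAsFactors = FALSE)
    }
    edges <- if (length(edges)) do.call(rbind, edges)
        else data.frame(tf = character(), gene = character(),
                        via_dhs = character(), raw_weight = numeric(),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
    edges$std_weight <- standardizeWeights(edges$raw_weight)
    nodes <- data.frame(
        node = c(stageTfs, setdiff(unique(edges$gene), stageTfs)),
        type = c(rep("TF", length(stageTfs)),
                 rep("gene", length(setdiff(unique(edges$gene),
                                            stageTfs)))),
        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
        edges[, c("tf", "gene", "raw_weight", "std_weight")],
        directed = TRUE, vertices = nodes)
    new("TFNetwork", graph = g, edges = edges, nodes = nodes)
}

standardizeWeights <- function(w) {
    if (length(w) < 2L) return(rep(0, length(w)))
    s <- sd(w)
    if (s == 0) return(rep(0, length(w)))
    (w - mean(w)) / s
}

#' Recompute standardized edge weights after an edge-set change
#' @param network a \linkS4class{TFNetwork}.
#' @return the network with \code{std_weight} restored to mean 0 / SD 1.
#' @export
restandardizeEdges <- function(network) {
    network@edges$std_weight <- standardizeWeights(network@edges$raw_weight)
    if (nrow(network@edges))
        igraph::E(network@graph)$std_weight <- network@edges$std_weight
    network
}

#' Node centrality of a regulatory network
#'
#' Degree centrality (normalized by n - 1) by default; betweenness
#' (normalized) and eigenvector centrality selectable. Centralities are
#' computed on the undirected skeleton; eigenvector centrality on a
#' disconnected graph is computed per component with a warning.
#'
#' @param network a \linkS4class{TFNetwork}.
#' @param method centrality flavor.
#' @return data.frame with columns node, centrality.
#' @export
nodeCentrality <- function(network,
                           method = c("degree", "betweenness",
                                      "eigenvector")) {
    method <- match.arg(method)
    g <- igraph::as_undirected(network@graph, mode = "collapse")
    n <- igraph::vcount(g)
    if (n == 0)
        return(data.frame(node = character(), centrality = numeric()))
    score <- switch(method,
        degree = igraph::degree(g) / max(1L, n - 1L),
        betweenness = igraph::betweenness(g, normalized = TRUE),
        eigenvector = {
            comp <- igraph::components(g)
            if (comp$no > 1L) {
                warning("disconnected graph: eigenvector centrality ",
                        "computed per component")
                out <- numeric(n)
                names(out) <- igraph::V(g)$name
                for (cc in seq_len(comp$no)) {
                    sub <- igraph::induced_subgraph(
                        g, which(comp$membership == cc))
                    ev <- igraph::eigen_centrality(sub)$vector
                    out[names(ev)] <- ev
                }
                out
            } else igraph::eigen_centrality(g)$vector
        })
    data.frame(node = names(score), centrality = as.numeric(score),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep each TF's strongest targets
#'
#' Per TF, retains the \code{n} edges with the largest absolute
#' standardized weight; ties at the cutoff are broken toward the
#' lexicographically smaller gene id.
#'
#' @param network a \linkS4class{TFNetwork}.
#' @param n targets kept per TF.
#' @param restandardize recompute std weights on the filtered edge set.
#' @return the filtered \linkS4class{TFNetwork}.
#' @export
topTargets <- function(network, n = 50L, restandardize = FALSE) {
    ed <- network@edges
    keep <- unlist(lapply(split(seq_len(nrow(ed)), ed$tf), function(idx) {
        o <- idx[order(-abs(ed$std_weight[idx]), ed$gene[idx])]
        head(o, n)
    }), use.names = FALSE)
    ed <- ed[sort(keep), , drop = FALSE]
    rownames(ed) <- NULL
    tfs <- unique(network@edges$tf)
    nodes <- data.frame(
        node = c(tfs, setdiff(unique(ed$gene), tfs)),
        type = c(rep("TF", length(tfs)),
                 rep("gene", length(setdiff(unique(ed$gene), tfs)))),
        stringsAsFactors = FALSE)
    out <- new("TFNetwork",
               graph = igraph::graph_from_data_frame(
                   ed[, c("tf", "gene", "raw_weight", "std_weight")],
                   directed = TRUE, vertices = nodes),
               edges = ed, nodes = nodes)
    if (restandardize) restandardizeEdges(out) else out
}

#' Write a network as GraphML and edge-list TSV
#'
#' @param network a \linkS4class{TFNetwork}.
#' @param graphmlPath,edgesPath output paths (either may be NULL).
#' @return invisibly, the written paths.
#' @export
writeNetwork <- function(network, graphmlPath = NULL, edgesPath = NULL) {
    if (!is.null(graphmlPath))
        igraph::write_graph(network@graph, graphmlPath, format = "graphml")
    if (!is.null(edgesPath))
        writeTable(network@edges, edgesPath)
    invisible(c(graphml = graphmlPath, edges = edgesPath))
}
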