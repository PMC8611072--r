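prf <- function(called, truthSet, universe) {
    tp <- length(intersect(called, truthSet))
    precision <- if (length(called)) tp / length(called) else NA_real_
    recall <- if (length(truthSet)) tp / length(truthSet) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
        2 * precision * recall / (precision + recall) else NA_real_
    c(precision = precision, recall = recall, f1 = f1)
}

#' Score recovery of the planted structure
#'
#' Compares downstream results with the truth ledger of
#' \code{\link{generateDataset}}: precision/recall/F1 for changing-feature
#' calls and enhancer-gene links, adjusted Rand index for temporal clusters
#' and TF modules, and sign accuracy plus recovery rate for planted
#' TF-to-DHS effects.
#'
#' @param truth the \code{truth} element of a generated dataset.
#' @param results named list; any subset of \code{dhsRegulated} /
#'   \code{geneRegulated} (character ids called changing),
#'   \code{dhsClusters} (data.frame feature_id, cluster), \code{links}
#'   (data.frame dhs_id, gene_id), \code{tfModules} (data.frame tf_name,
#'   module), \code{coefficients} (DHS x TF matrix).
#' @return named list of metrics (only those computable from
#'   \code{results}).
#' @export
scoreRecovery <- function(truth, results) {
    out <- list()
    checkIds <- function(ids, known, what) {
        bad <- setdiff(ids, known)
        if (length(bad))
            stop("unknown ", what, " id(s): ",
                 paste(head(bad, 5L), collapse = ", "))
    }
    if (!is.null(results$dhsRegulated)) {
        checkIds(results$dhsRegulated, truth$dhs$dhs_id, "DHS")
        out$dhs_changing <- prf(results$dhsRegulated,
                                truth$dhs$dhs_id[truth$dhs$changing],
                                truth$dhs$dhs_id)
    }
    if (!is.null(results$geneRegulated)) {
        checkIds(results$geneRegulated, truth$gene$gene_id, "gene")
        out$gene_changing <- prf(results$geneRegulated,
                                 truth$gene$gene_id[truth$gene$changing],
                                 truth$gene$gene_id)
    }
    if (!is.null(results$links)) {
        checkIds(results$links$dhs_id, truth$dhs$dhs_id, "DHS")
        checkIds(results$links$gene_id, truth$gene$gene_id, "gene")
        called <- paste(results$links$dhs_id, results$links$gene_id)
        planted <- paste(truth$links$dhs_id, truth$links$gene_id)
        out$links <- prf(called, planted, NULL)
    }
    if (!is.null(results$dhsClusters)) {
        cl <- results$dhsClusters
        checkIds(cl$feature_id, truth$dhs$dhs_id, "DHS")
        tr <- truth$dhs$cluster[match(cl$feature_id, truth$dhs$dhs_id)]
        keep <- !is.na(tr)
        out$cluster_ari <- mclust::adjustedRandIndex(cl$cluster[keep],
                                                     tr[keep])
    }
    if (!is.null(results$tfModules)) {
        mo <- results$tfModules
        checkIds(mo$tf_name, truth$tf$tf_name, "TF")
        tr <- truth$tf$module[match(mo$tf_name, truth$tf$tf_name)]
        keep <- !is.na(tr)
        out$module_ari <- mclust::adjustedRandIndex(mo$module[keep], tr[keep])
    }
    if (!is.null(results$coefficients) && nrow(truth$effects)) {
        co <- results$coefficients
        eff <- truth$effects
        keep <- eff$dhs_id %in% rownames(co) & eff$tf_name %in% colnames(co)
        eff <- eff[keep, , drop = FALSE]
        got <- co[cbind(match(eff$dhs_id, rownames(co)),
                        match(eff$tf_name, colnames(co)))]
        nz <- got != 0
        out$effect_recovery <- mean(nz)
        out$effect_sign_accuracy <-
            if (any(nz)) mean(sign(got[nz]) == sign(eff$effect[nz]))
            else NA_real_
    }
    out
}
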