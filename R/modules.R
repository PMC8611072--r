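#' Select TFs positively associated with many DHSs
#'
#' @param coefs a \linkS4class{TFCoefficientMatrix} or DHS x TF matrix.
#' @param minPositiveDhs threshold on the count of strictly positive
#'   coefficients.
#' @param strict if TRUE require strictly more than the threshold
#'   (\code{>}), else at least (\code{>=}, default).
#' @return character vector of TF names.
#' @export
selectConnectedTfs <- function(coefs, minPositiveDhs = 200,
                               strict = FALSE) {
    co <- if (is(coefs, "TFCoefficientMatrix")) coefMatrix(coefs)
          else as.matrix(coefs)
    if (!length(co)) return(character())
    nPos <- colSums(co > 0)
    names(nPos)[if (strict) nPos > minPositiveDhs
                else nPos >= minPositiveDhs]
}

#' Resolve TFs into sequential regulatory modules
#'
#' Hierarchical clustering (agglomerative, average linkage by default) of
#' the TFs' coefficient vectors over all modeled DHSs (zeros included)
#' under cosine distance, cut into \code{k} modules. Modules are numbered
#' by the mean peak day of the DHS profiles positively associated with
#' their member TFs, so module 1 is the earliest program. Each module's
#' DHS set is the union of its member TFs' positively associated DHSs
#' (sets may overlap between modules).
#'
#' @param coefs a \linkS4class{TFCoefficientMatrix} or DHS x TF matrix.
#' @param tfList TFs to cluster (e.g. \code{\link{selectConnectedTfs}}).
#' @param k number of modules.
#' @param linkage \code{hclust} agglomeration method.
#' @param dhsDayMeans DHS x days per-day mean profiles (for temporal
#'   ordering of the modules).
#' @return list with \code{membership} (data.frame tf_name, module),
#'   \code{dhsMembers} (list of DHS id vectors per module), \code{tree}
#'   (the hclust object), \code{modulePeak} (mean peak day per module).
#' @export
clusterTfsCosine <- function(coefs, tfList, k = 5L, linkage = "average",
                             dhsDayMeans = NULL) {
    co <- if (is(coefs, "TFCoefficientMatrix")) coefMatrix(coefs)
          else as.matrix(coefs)
    if (k > length(tfList)) stop("k exceeds the number of TFs")
    miss <- setdiff(tfList, colnames(co))
    if (length(miss))
        stop("unknown TF(s): ", paste(head(miss, 5L), collapse = ", "))
    V <- t(co[, tfList, drop = FALSE])          # TF x DHS vectors
    zero <- rowSums(V != 0) == 0
    if (any(zero)) {
        warning("excluding all-zero coefficient vector(s): ",
                paste(rownames(V)[zero], collapse = ", "))
        V <- V[!zero, , drop = FALSE]
        tfList <- rownames(V)
        if (k > length(tfList)) stop("k exceeds the number of usable TFs")
    }
    d <- cosineDist(V)
    tree <- hclust(as.dist(d), method = linkage)
    raw <- cutree(tree, k = k)
    ## temporal ordering of modules by the mean peak day of associated DHSs
    tfPeak <- rep(NA_real_, length(tfList))
    if (!is.null(dhsDayMeans)) {
        dayVals <- as.numeric(colnames(dhsDayMeans))
        if (anyNA(dayVals)) dayVals <- seq_len(ncol(dhsDayMeans))
        for (i in seq_along(tfList)) {
            pos <- rownames(co)[co[, tfList[i]] > 0]
            pos <- intersect(pos, rownames(dhsDayMeans))
            if (length(pos))
                tfPeak[i] <- mean(dayVals[apply(
                    dhsDayMeans[pos, , drop = FALSE], 1L, which.max)])
        }
        modPeak <- vapply(seq_len(k), function(m)
            mean(tfPeak[raw == m], na.rm = TRUE), numeric(1))
    } else modPeak <- seq_len(k)
    ord <- order(modPeak)
    relabel <- match(seq_len(k), ord)
    module <- relabel[raw]
    membership <- data.frame(tf_name = tfList, module = module,
                             stringsAsFactors = FALSE)
    dhsMembers <- lapply(seq_len(k), function(m) {
        tfs <- tfList[module == m]
        sort(unique(rownames(co)[rowSums(
            co[, tfs, drop = FALSE] > 0) > 0]))
    })
    list(membership = membership, dhsMembers = dhsMembers, tree = tree,
         modulePeak = sort(modPeak))
}

#' Fraction of each DHS cluster positively associated with each TF
#'
#' fraction(t, c) = |{DHS in cluster c with coefficient(t, DHS) > 0}| /
#' |cluster c|.
#'
#' @param coefs a \linkS4class{TFCoefficientMatrix} or DHS x TF matrix.
#' @param tfList TFs (rows of the result).
#' @param dhsClusters data.frame from \code{\link{kmeansProfiles}}.
#' @return TF x cluster matrix of fractions (NA for empty clusters).
#' @export
moduleDhsFraction <- function(coefs, tfList, dhsClusters) {
    co <- if (is(coefs, "TFCoefficientMatrix")) coefMatrix(coefs)
          else as.matrix(coefs)
    labs <- sort(unique(dhsClusters$label))
    out <- matrix(NA_real_, length(tfList), length(labs),
                  dimnames = list(tfList, labs))
    for (lab in labs) {
        mem <- intersect(dhsClusters$feature_id[dhsClusters$label == lab],
                         rownames(co))
        if (!length(mem)) next
        out[, lab] <- colSums(co[mem, tfList, drop = FALSE] > 0) /
            length(mem)
    }
    out
}
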