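#' Elastic-net search configuration
#'
#' Defaults follow the full search design: a mixing grid of 0..1 in 0.01
#' steps, 100 log-spaced penalties between 1e-5 and 1e5, and 100 random
#' repeats of leave-4-days-out validation. Tests and small runs pass
#' reduced grids.
#'
#' @param alphaGrid mixing parameters in [0, 1].
#' @param lambdaGrid penalty strengths (> 0).
#' @param nHeldoutDays days held out per validation repeat.
#' @param nRepeats random held-out day sets.
#' @param seed integer seed for the held-out draws.
#' @param cvTol,cvMaxit coordinate-descent tolerance (relative to the
#'   response SD) and sweep cap for the validation fits; the final refits
#'   always use the full tolerance (1e-7).
#' @return list of class \code{enetConfig}.
#' @export
enetConfig <- function(alphaGrid = seq(0, 1, by = 0.01),
                       lambdaGrid = 10^seq(-5, 5, length.out = 100),
                       nHeldoutDays = 4L, nRepeats = 100L, seed = 1L,
                       cvTol = 1e-4, cvMaxit = 200L) {
    if (!length(alphaGrid) || !length(lambdaGrid)) stop("empty grid")
    if (any(alphaGrid < 0 | alphaGrid > 1)) stop("alpha must be in [0, 1]")
    if (any(lambdaGrid <= 0)) stop("lambda must be > 0")
    structure(list(alphaGrid = sort(alphaGrid),
                   lambdaGrid = sort(lambdaGrid),
                   nHeldoutDays = as.integer(nHeldoutDays),
                   nRepeats = as.integer(nRepeats),
                   seed = as.integer(seed), cvTol = cvTol,
                   cvMaxit = as.integer(cvMaxit)),
              class = "enetConfig")
}

## z-scored TF predictor matrix (days x TFs) from per-day mean expression;
## constant TFs dropped with a warning, low/unregulated TFs filtered out
prepTfPredictors <- function(tfDayMeans, minMaxFpkm = 2,
                             regulatedTfs = NULL) {
    tm <- as.matrix(tfDayMeans)
    keep <- apply(tm, 1L, max) > minMaxFpkm
    if (!is.null(regulatedTfs))
        keep <- keep & rownames(tm) %in% regulatedTfs
    tm <- tm[keep, , drop = FALSE]
    s <- apply(tm, 1L, sd)
    if (any(s == 0)) {
        warning("dropping constant TF profile(s): ",
                paste(head(rownames(tm)[s == 0], 5L), collapse = ", "))
        tm <- tm[s > 0, , drop = FALSE]
    }
    t(zscoreRows(tm))                       # days x TFs
}

#' Build the per-DHS elastic-net design
#'
#' Candidate TFs for a DHS are those with at least one motif hit in it,
#' maximum daily mean expression above \code{minMaxFpkm}, and (optionally)
#' a developmental-regulation call. Predictors are the TF per-day mean
#' expression profiles z-scored across days; the response is the DHS
#' per-day mean density, centered.
#'
#' @param dhsId the DHS.
#' @param motifHits motif-hit data.frame (dhs_id, tf_name, hit_count).
#' @param tfDayMeans TFs-x-days matrix of per-day mean expression.
#' @param dhsProfile named per-day mean density vector for the DHS.
#' @param minMaxFpkm expression floor for candidate TFs.
#' @param requireRegulatedTf restrict candidates to regulated TFs.
#' @param regulatedTfs character vector of regulated TF names (used when
#'   \code{requireRegulatedTf}).
#' @return list with \code{X} (days x candidate TFs, z-scored), \code{y}
#'   (centered response), \code{candidates}, \code{modelable}.
#' @export
buildDesign <- function(dhsId, motifHits, tfDayMeans, dhsProfile,
                        minMaxFpkm = 2, requireRegulatedTf = TRUE,
                        regulatedTfs = NULL) {
    Z <- prepTfPredictors(tfDayMeans, minMaxFpkm,
                          if (requireRegulatedTf) regulatedTfs)
    hitTfs <- unique(motifHits$tf_name[motifHits$dhs_id == dhsId &
                                       motifHits$hit_count >= 1])
    cand <- intersect(colnames(Z), hitTfs)
    if (!length(cand))
        return(list(X = Z[, 0, drop = FALSE], y = dhsProfile -
                        mean(dhsProfile), candidates = character(),
                    modelable = FALSE))
    list(X = Z[, cand, drop = FALSE], y = dhsProfile - mean(dhsProfile),
         candidates = cand, modelable = TRUE)
}

#' Select per-cluster elastic-net hyperparameters by repeated
#' leave-days-out validation
#'
#' For each repeat, \code{nHeldoutDays} days are held out at random; every
#' modelable DHS in the cluster is fit on the remaining days for every
#' (alpha, lambda) on the grid (warm-started along the lambda path) and
#' scored by held-out mean squared error. Per DHS, the MSE is averaged
#' over repeats and its standard error taken across repeats; the cluster
#' objective is the sum over DHSs of (mean MSE + SE), and the grid point
#' minimizing it is chosen, ties broken toward larger lambda then larger
#' alpha (the sparser model).
#'
#' @param designs list of \code{\link{buildDesign}} results (one cluster).
#' @param config an \code{\link{enetConfig}}.
#' @param seObjective include the SE term in the objective (default TRUE);
#'   FALSE gives a pure-MSE objective.
#' @return list with \code{alpha}, \code{lambda}, and the objective
#'   \code{surface} (alpha x lambda).
#' @export
cvSelectClusterParams <- function(designs, config = enetConfig(),
                                  seObjective = TRUE) {
    designs <- designs[vapply(designs, function(d) isTRUE(d$modelable),
                              TRUE)]
    if (!length(designs)) stop("no modelable DHS in cluster")
    days <- length(designs[[1L]]$y)
    H <- config$nHeldoutDays
    if (days - H < 6L)
        stop("holding out ", H, " days leaves fewer than 6 training days")
    alphas <- config$alphaGrid
    lambdas <- config$lambdaGrid      # increasing; path solved decreasing
    nA <- length(alphas); nL <- length(lambdas); R <- config$nRepeats
    nD <- length(designs)
    heldSets <- withSeed(config$seed, t(vapply(seq_len(R), function(r)
        sample(days, H), integer(H))))
    lamDec <- rev(lambdas)
    surface <- matrix(0, nA, nL)
    for (d in seq_len(nD)) {
        mse <- enetCvCpp(designs[[d]]$X, designs[[d]]$y, alphas, lamDec,
                         heldSets, config$cvTol, config$cvMaxit)
        mse <- mse[, rev(seq_len(nL)), , drop = FALSE]  # back to increasing
        meanMse <- apply(mse, c(1L, 2L), mean)
        se <- if (R > 1)
            apply(mse, c(1L, 2L), sd) / sqrt(R)
        else matrix(0, nA, nL)
        surface <- surface + meanMse + if (seObjective) se else 0
    }
    dimnames(surface) <- list(alpha = alphas, lambda = lambdas)
    best <- min(surface)
    ## ties toward larger lambda, then larger alpha
    cand <- which(surface <= best + 1e-12, arr.ind = TRUE)
    pick <- cand[order(-cand[, 2L], -cand[, 1L])[1L], ]
    list(alpha = alphas[pick[1L]], lambda = lambdas[pick[2L]],
         surface = surface)
}

#' Final elastic-net fit of one DHS design
#'
#' @param design a \code{\link{buildDesign}} result.
#' @param alpha,lambda the cluster-selected penalty.
#' @param tol coordinate-descent tolerance.
#' @return list with named \code{beta}, \code{b0}, \code{mse} (training).
#' @export
fitElasticNetFinal <- function(design, alpha, lambda, tol = 1e-7) {
    fit <- enetFit(design$X, design$y, alpha, lambda, tol = tol)
    beta <- fit$beta[, 1L]
    names(beta) <- colnames(design$X)
    pred <- as.vector(design$X %*% fit$beta[, 1L]) + fit$b0[1L]
    list(beta = beta, b0 = fit$b0[1L], mse = mean((design$y - pred)^2))
}

#' Model every regulated DHS from motif-compatible TF expression
#'
#' Orchestrates the two-step procedure: builds a design per DHS, selects
#' (alpha, lambda) per temporal cluster by repeated leave-days-out
#' validation, then refits every DHS of the cluster on all days at the
#' chosen penalty.
#'
#' @param dhsDayMeans regulated-DHS x days matrix of per-day mean density.
#' @param dhsClusters data.frame from \code{\link{kmeansProfiles}} for the
#'   same DHSs.
#' @param motifHits motif-hit table.
#' @param tfDayMeans TF x days per-day mean expression.
#' @param config an \code{\link{enetConfig}}.
#' @param minMaxFpkm,requireRegulatedTf,regulatedTfs candidate filters, as
#'   in \code{\link{buildDesign}}.
#' @return a \linkS4class{TFCoefficientMatrix}.
#' @export
fitTfModels <- function(dhsDayMeans, dhsClusters, motifHits, tfDayMeans,
                        config = enetConfig(), minMaxFpkm = 2,
                        requireRegulatedTf = TRUE, regulatedTfs = NULL) {
    Z <- prepTfPredictors(tfDayMeans, minMaxFpkm,
                          if (requireRegulatedTf) regulatedTfs)
    tfs <- colnames(Z)
    dhsIds <- dhsClusters$feature_id
    miss <- setdiff(dhsIds, rownames(dhsDayMeans))
    if (length(miss))
        stop("no profile for DHS id(s): ",
             paste(head(miss, 5L), collapse = ", "))
    hitsByDhs <- split(motifHits$tf_name[motifHits$hit_count >= 1],
                       motifHits$dhs_id[motifHits$hit_count >= 1])
    designs <- lapply(dhsIds, function(id) {
        cand <- intersect(tfs, unique(hitsByDhs[[id]]))
        y <- dhsDayMeans[id, ]
        if (!length(cand))
            list(X = Z[, 0, drop = FALSE], y = y - mean(y),
                 candidates = character(), modelable = FALSE)
        else list(X = Z[, cand, drop = FALSE], y = y - mean(y),
                  candidates = cand, modelable = TRUE)
    })
    names(designs) <- dhsIds

    coefs <- matrix(0, length(dhsIds), length(tfs),
                    dimnames = list(dhsIds, tfs))
    mask <- matrix(FALSE, length(dhsIds), length(tfs),
                   dimnames = list(dhsIds, tfs))
    for (i in seq_along(designs))
        mask[i, designs[[i]]$candidates] <- TRUE
    intercepts <- setNames(numeric(length(dhsIds)), dhsIds)
    trainMse <- setNames(rep(NA_real_, length(dhsIds)), dhsIds)
    labs <- sort(unique(dhsClusters$label))
    cp <- data.frame(cluster = labs, alpha = NA_real_, lambda = NA_real_,
                     stringsAsFactors = FALSE)
    for (ci in seq_along(labs)) {
        mem <- which(dhsClusters$label == labs[ci])
        memDesigns <- designs[mem]
        modelable <- vapply(memDesigns, function(d) d$modelable, TRUE)
        if (!any(modelable)) next
        clCfg <- config
        clCfg$seed <- childSeed(config$seed, labs[ci])
        sel <- cvSelectClusterParams(memDesigns[modelable], clCfg)
        cp$alpha[ci] <- sel$alpha
        cp$lambda[ci] <- sel$lambda
        for (d in mem[modelable]) {
            fit <- fitElasticNetFinal(designs[[d]], sel$alpha, sel$lambda)
            coefs[d, names(fit$beta)] <- fit$beta
            intercepts[d] <- fit$b0
            trainMse[d] <- fit$mse
        }
    }
    unmod <- dhsIds[!vapply(designs, function(d) d$modelable, TRUE)]
    new("TFCoefficientMatrix", coefficients = coefs,
        intercepts = intercepts, trainMse = trainMse, clusterParams = cp,
        candidateMask = mask, unmodelable = unmod)
}

#' Summarize a fitted coefficient matrix
#'
#' @param object a \linkS4class{TFCoefficientMatrix} or plain coefficient
#'   matrix.
#' @return list with per-DHS nonzero and positive coefficient counts, the
#'   fraction of DHSs with at least one explanatory TF, the mean number of
#'   positively associated TFs per modeled DHS, and per-TF counts of
#'   positively associated DHSs.
#' @export
modelSummary <- function(object) {
    co <- if (is(object, "TFCoefficientMatrix")) coefMatrix(object)
          else as.matrix(object)
    nz <- rowSums(co != 0)
    pos <- rowSums(co > 0)
    list(nonzero_per_dhs = nz, positive_per_dhs = pos,
         frac_dhs_modeled = if (nrow(co)) mean(nz > 0) else 0,
         mean_positive_tfs = if (any(nz > 0)) mean(pos[nz > 0]) else 0,
         positive_dhs_per_tf = colSums(co > 0))
}
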