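nbTrain <- function(feat, labels, mode) {
    classes <- sort(unique(labels))
    prior <- vapply(classes, function(cl) mean(labels == cl), numeric(1))
    params <- lapply(classes, function(cl) {
        m <- feat[labels == cl, , drop = FALSE]
        if (mode == "poisson") {
            list(rate = colMeans(m) + 0.1)      # pseudorate against zeros
        } else {
            list(mu = colMeans(m),
                 v = pmax(apply(m, 2L, var), 1e-6))
        }
    })
    names(params) <- classes
    list(classes = classes, prior = prior, params = params, mode = mode)
}

nbPredict <- function(model, feat, returnLog = FALSE) {
    ll <- vapply(model$classes, function(cl) {
        p <- model$params[[cl]]
        if (model$mode == "poisson") {
            lam <- p$rate
            rowSums(sweep(feat, 2L, log(lam), `*`)) - sum(lam) -
                rowSums(lfactorial(feat))
        } else {
            rowSums(-0.5 * log(2 * pi * rep(1, nrow(feat)) %o% p$v) -
                    sweep(feat, 2L, p$mu)^2 /
                        (2 * rep(1, nrow(feat)) %o% p$v))
        }
    }, numeric(nrow(feat)))
    if (nrow(feat) == 1L) ll <- matrix(ll, nrow = 1L)
    ll <- sweep(ll, 2L, log(model$prior), `+`)
    colnames(ll) <- model$classes
    if (returnLog) return(ll)
    model$classes[apply(ll, 1L, which.max)]     # ties -> lowest class index
}

stratifiedFolds <- function(labels, k, seed) {
    withSeed(seed, {
        fold <- integer(length(labels))
        for (cl in unique(labels)) {
            idx <- sample(which(labels == cl))
            fold[idx] <- rep(seq_len(k), length.out = length(idx))
        }
        fold
    })
}

#' Benchmark motif counts against elastic-net coefficients with naive Bayes
#'
#' Predicts each DHS's temporal cluster from either its discrete motif
#' counts (per-class Poisson likelihood, rate = class mean + 0.1) or its
#' elastic-net TF coefficients (per-class Gaussian likelihood, variance
#' floored at 1e-6), using stratified cross-validation. The accuracy ratio
#' (coefficients over counts) quantifies how much the fitted temporal
#' associations add over raw motif composition.
#'
#' @param motifHits motif-hit table (dhs_id, tf_name, hit_count).
#' @param coefs a \linkS4class{TFCoefficientMatrix} or DHS x TF matrix.
#' @param clusterLabels named vector or data.frame
#'   (\code{feature_id, label}) of cluster labels for the modeled DHSs.
#' @param tfSubset TFs used as features; defaults to TFs with at least one
#'   nonzero coefficient.
#' @param cvFolds stratified folds (use \code{resubstitution = TRUE} to
#'   score on the training data instead).
#' @param seed fold-assignment seed.
#' @param resubstitution train and score on the full data.
#' @return list with \code{counts} and \code{coefs} results (per-fold
#'   accuracy, mean accuracy, confusion matrix) and
#'   \code{accuracy_ratio}.
#' @export
naiveBayesClusterBenchmark <- function(motifHits, coefs, clusterLabels,
                                       tfSubset = NULL, cvFolds = 5L,
                                       seed = 1L, resubstitution = FALSE) {
    co <- if (is(coefs, "TFCoefficientMatrix")) coefMatrix(coefs)
          else as.matrix(coefs)
    if (is.data.frame(clusterLabels))
        clusterLabels <- setNames(clusterLabels$label,
                                  clusterLabels$feature_id)
    ids <- intersect(rownames(co), names(clusterLabels))
    if (!length(ids)) stop("no DHS shared between coefficients and labels")
    labels <- as.character(clusterLabels[ids])
    if (is.null(tfSubset))
        tfSubset <- colnames(co)[colSums(co[ids, , drop = FALSE] != 0) > 0]
    if (!length(tfSubset)) stop("no TFs with a nonzero coefficient")
    counts <- matrix(0, length(ids), length(tfSubset),
                     dimnames = list(ids, tfSubset))
    h <- motifHits[motifHits$dhs_id %in% ids &
                   motifHits$tf_name %in% tfSubset, , drop = FALSE]
    if (nrow(h))
        counts[cbind(match(h$dhs_id, ids), match(h$tf_name, tfSubset))] <-
            h$hit_count
    coefFeat <- co[ids, tfSubset, drop = FALSE]

    runMode <- function(feat, mode) {
        classes <- sort(unique(labels))
        if (resubstitution) {
            pred <- nbPredict(nbTrain(feat, labels, mode), feat)
            acc <- mean(pred == labels)
            conf <- table(truth = factor(labels, classes),
                          predicted = factor(pred, classes))
            return(list(feature_mode = mode, fold_accuracy = acc,
                        mean_accuracy = acc, confusion = conf))
        }
        small <- names(which(table(labels) < cvFolds))
        if (length(small))
            stop("class(es) with fewer members than cvFolds: ",
                 paste(small, collapse = ", "),
                 "; use fewer folds")
        fold <- stratifiedFolds(labels, cvFolds, seed)
        foldAcc <- numeric(cvFolds)
        predAll <- character(length(labels))
        for (f in seq_len(cvFolds)) {
            tr <- fold != f
            model <- nbTrain(feat[tr, , drop = FALSE], labels[tr], mode)
            pred <- nbPredict(model, feat[!tr, , drop = FALSE])
            foldAcc[f] <- mean(pred == labels[!tr])
            predAll[!tr] <- pred
        }
        conf <- table(truth = factor(labels, classes),
                      predicted = factor(predAll, classes))
        list(feature_mode = mode, fold_accuracy = foldAcc,
             mean_accuracy = mean(foldAcc), confusion = conf)
    }
    resCounts <- runMode(counts, "poisson")
    resCoefs <- runMode(coefFeat, "gaussian")
    list(counts = resCounts, coefs = resCoefs,
         accuracy_ratio = resCoefs$mean_accuracy /
             resCounts$mean_accuracy)
}
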