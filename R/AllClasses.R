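#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TimeCourseExperiment: a feature-by-sample matrix with (donor, day) design
#'
#' Extends \linkS4class{SummarizedExperiment}. Columns are samples from a
#' differentiation time course; \code{colData} must carry a \code{donor}
#' factor and a non-negative integer \code{day}. Columns are kept ordered by
#' (day, donor) so that per-day summaries are reproducible.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    msg <- character()
    if (!all(c("donor", "day") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'donor' and 'day'")
    else {
        day <- cd$day
        if (!is.numeric(day) || any(!is.finite(day)) || any(day < 0))
            msg <- c(msg, "'day' must be finite, non-negative numeric")
        else if (length(unique(day)) < 2L)
            msg <- c(msg, "need samples from at least 2 distinct days")
    }
    if (ncol(object) > 0 && anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    if (nrow(object) > 0 && anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a TimeCourseExperiment
#'
#' @param counts numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param sampleData data.frame with columns \code{sample_id}, \code{donor},
#'   \code{day}; one row per matrix column.
#' @return a \linkS4class{TimeCourseExperiment} with columns ordered by
#'   (day, donor).
#' @examples
#' m <- matrix(1:12, 2, 6, dimnames = list(c("f1", "f2"), paste0("s", 1:6)))
#' sd <- data.frame(sample_id = paste0("s", 1:6),
#'                  donor = rep(c("d1", "d2"), 3), day = rep(0:2, each = 2))
#' TimeCourseExperiment(m, sd)
#' @export
TimeCourseExperiment <- function(counts, sampleData) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        stop("matrix must have sample ids as colnames")
    if (is.null(rownames(counts)))
        stop("matrix must have feature ids as rownames")
    if (!all(c("sample_id", "donor", "day") %in% colnames(sampleData)))
        stop("sampleData needs columns sample_id, donor, day")
    orphan <- setdiff(colnames(counts), sampleData$sample_id)
    if (length(orphan))
        stop("samples missing from sample sheet: ",
             paste(orphan, collapse = ", "))
    sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), ,
                             drop = FALSE]
    ord <- order(sampleData$day, as.character(sampleData$donor))
    counts <- counts[, ord, drop = FALSE]
    sampleData <- sampleData[ord, , drop = FALSE]
    cd <- S4Vectors::DataFrame(donor = as.character(sampleData$donor),
                               day = as.numeric(sampleData$day),
                               row.names = sampleData$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(signal = counts), colData = cd)
    new("TimeCourseExperiment", se)
}

#' Per-DHS-by-TF elastic-net coefficients with per-cluster hyperparameters
#'
#' @slot coefficients numeric matrix, DHS x TF, final elastic-net
#'   coefficients (zero where a TF was not selected or not a candidate).
#' @slot intercepts per-DHS intercept of the final fit.
#' @slot trainMse per-DHS training mean squared error of the final fit.
#' @slot clusterParams data.frame with columns cluster, alpha, lambda.
#' @slot candidateMask logical matrix, DHS x TF; TRUE where the TF passed the
#'   motif + expression candidacy filter for that DHS.
#' @slot unmodelable character vector of DHS ids with no candidate TFs.
#' @export
setClass("TFCoefficientMatrix",
    representation(coefficients = "matrix", intercepts = "numeric",
                   trainMse = "numeric", clusterParams = "data.frame",
                   candidateMask = "matrix", unmodelable = "character"))

setValidity("TFCoefficientMatrix", function(object) {
    msg <- character()
    co <- object@coefficients
    if (!identical(dim(co), dim(object@candidateMask)))
        msg <- c(msg, "coefficients and candidateMask dims differ")
    else if (any(co != 0 & !object@candidateMask))
        msg <- c(msg, "nonzero coefficient outside the candidate mask")
    if (length(object@intercepts) != nrow(co))
        msg <- c(msg, "one intercept per DHS required")
    if (length(msg)) msg else TRUE
})

#' Weighted TF-to-gene regulatory network
#'
#' @slot graph an igraph directed graph; vertices carry a \code{type}
#'   attribute ("TF" or "gene").
#' @slot edges data.frame with columns tf, gene, via_dhs, raw_weight,
#'   std_weight.
#' @slot nodes data.frame with columns node, type.
#' @export
setClass("TFNetwork",
    representation(graph = "ANY", edges = "data.frame", nodes = "data.frame"))
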