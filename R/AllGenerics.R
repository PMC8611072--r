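#' Sampling days of a time course
#' @param x a TimeCourseExperiment
#' @return numeric vector of per-sample days
#' @export
setGeneric("sampleDays", function(x) standardGeneric("sampleDays"))

#' Donors of a time course
#' @param x a TimeCourseExperiment
#' @return character vector of per-sample donor ids
#' @export
setGeneric("sampleDonors", function(x) standardGeneric("sampleDonors"))

#' Per-day replicate means
#'
#' Averages the signal across donors within each day.
#'
#' @param x a TimeCourseExperiment
#' @return numeric matrix, features x unique days (column names are days)
#' @export
setGeneric("dayMeans", function(x) standardGeneric("dayMeans"))

#' Final elastic-net coefficient matrix (DHS x TF)
#' @param object a TFCoefficientMatrix
#' @return numeric matrix
#' @export
setGeneric("coefMatrix", function(object) standardGeneric("coefMatrix"))

#' Chosen per-cluster elastic-net hyperparameters
#' @param object a TFCoefficientMatrix
#' @return data.frame with columns cluster, alpha, lambda
#' @export
setGeneric("clusterParams", function(object) standardGeneric("clusterParams"))

#' @export
#' @describeIn TimeCourseExperiment-methods per-sample days
setMethod("sampleDays", "TimeCourseExperiment", function(x)
    SummarizedExperiment::colData(x)$day)

#' @export
#' @describeIn TimeCourseExperiment-methods per-sample donors
setMethod("sampleDonors", "TimeCourseExperiment", function(x)
    SummarizedExperiment::colData(x)$donor)

#' Methods for TimeCourseExperiment
#'
#' @param x a TimeCourseExperiment
#' @name TimeCourseExperiment-methods
NULL

#' @export
#' @describeIn TimeCourseExperiment-methods per-day replicate means
setMethod("dayMeans", "TimeCourseExperiment", function(x) {
    day <- sampleDays(x)
    m <- SummarizedExperiment::assay(x)
    ud <- sort(unique(day))
    out <- vapply(ud, function(d)
        rowMeans(m[, day == d, drop = FALSE]), numeric(nrow(m)))
    if (nrow(m) == 1L) out <- matrix(out, nrow = 1L)
    dimnames(out) <- list(rownames(m), as.character(ud))
    out
})

setMethod("show", "TimeCourseExperiment", function(object) {
    d <- sampleDays(object)
    cat("TimeCourseExperiment:", nrow(object), "features x",
        ncol(object), "samples\n")
    cat("  days:", paste(range(d), collapse = ".."),
        sprintf("(%d distinct), donors: %d\n", length(unique(d)),
                length(unique(sampleDonors(object)))))
})

#' @export
#' @describeIn TFCoefficientMatrix-methods coefficient matrix accessor
setMethod("coefMatrix", "TFCoefficientMatrix", function(object)
    object@coefficients)

#' Methods for TFCoefficientMatrix
#' @param object a TFCoefficientMatrix
#' @name TFCoefficientMatrix-methods
NULL

#' @export
#' @describeIn TFCoefficientMatrix-methods per-cluster (alpha, lambda)
setMethod("clusterParams", "TFCoefficientMatrix", function(object)
    object@clusterParams)

setMethod("show", "TFCoefficientMatrix", function(object) {
    co <- object@coefficients
    cat("TFCoefficientMatrix:", nrow(co), "DHSs x", ncol(co), "TFs\n")
    cat("  nonzero coefficients:", sum(co != 0),
        "| unmodelable DHSs:", length(object@unmodelable), "\n")
    cp <- object@clusterParams
    if (nrow(cp))
        cat("  clusters:", paste(sprintf("%s(a=%.2f,l=%.3g)", cp$cluster,
            cp$alpha, cp$lambda), collapse = " "), "\n")
})

setMethod("show", "TFNetwork", function(object) {
    cat("TFNetwork:", sum(object@nodes$type == "TF"), "TFs,",
        sum(object@nodes$type == "gene"), "genes,",
        nrow(object@edges), "edges\n")
})
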