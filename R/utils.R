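#' @importFrom stats sd cor pchisq phyper p.adjust kmeans hclust cutree
#'   as.dist rnorm runif rpois quantile var lm.fit aggregate rexp
#'   predict coef fitted residuals setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib chronet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## number formatting used by every table writer: 12 significant digits,
## plain notation down to 1e-4 (the %g switch point), '.' decimal
fmtNum <- function(x) {
    out <- sprintf("%.12g", x)
    out[is.na(x)] <- "NA"
    out
}

## z-score rows of a matrix; constant rows -> error unless drop = TRUE
zscoreRows <- function(m, drop = FALSE) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    if (any(s == 0)) {
        if (!drop) stop("constant profile(s) cannot be z-scored: ",
                        paste(head(rownames(m)[s == 0], 5L), collapse = ", "))
        keep <- s > 0
        m <- m[keep, , drop = FALSE]; mu <- mu[keep]; s <- s[keep]
    }
    (m - mu) / s
}

## cosine distance matrix between rows; d = 1 - u.v/(|u||v|), in [0, 2]
#' Cosine distance between row vectors
#' @param m numeric matrix; distances computed between rows
#' @return symmetric matrix of distances in [0, 2]
#' @export
cosineDist <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("all-zero vector has no cosine direction")
    s <- (m / nrm) %*% t(m / nrm)
    d <- 1 - s
    d[d < 0] <- 0
    diag(d) <- 0
    d
}

## midpoint of a BED half-open interval [start0, end0): 0-based position
intervalMidpoint <- function(gr) {
    s0 <- GenomicRanges::start(gr) - 1L   # GRanges is 1-based inclusive
    e0 <- GenomicRanges::end(gr)
    as.integer(floor((s0 + e0 - 1L) / 2L))
}

## deterministic child seed (< 2^31) derived from a base seed and a tag
childSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}
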