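#' Quantile-normalize a feature-by-sample matrix
#'
#' Forces every column onto the cross-sample mean reference distribution:
#' after normalization each column's sorted values equal the mean of the
#' per-rank sorted values across samples. A group of tied values receives
#' the mean of every reference slot the group occupies (so a constant
#' column maps to the mean of the whole reference distribution).
#'
#' @param x numeric matrix (features x samples, non-negative) or a
#'   \linkS4class{TimeCourseExperiment}.
#' @return object of the same class with normalized values.
#' @export
quantileNormalize <- function(x) {
    m <- if (is(x, "TimeCourseExperiment"))
        SummarizedExperiment::assay(x) else as.matrix(x)
    if (ncol(m) < 2L) stop("need at least 2 samples")
    if (any(m < 0)) stop("negative values are not allowed")
    ref <- rowMeans(apply(m, 2L, sort))
    refCum <- c(0, cumsum(ref))
    qn <- apply(m, 2L, function(col) {
        rmin <- rank(col, ties.method = "min")
        rmax <- rank(col, ties.method = "max")
        ## mean of the occupied reference slots via cumulative sums
        (refCum[rmax + 1L] - refCum[rmin]) / (rmax - rmin + 1L)
    })
    dimnames(qn) <- dimnames(m)
    if (is(x, "TimeCourseExperiment")) {
        SummarizedExperiment::assay(x) <- qn
        x
    } else qn
}

## natural cubic spline basis of day with 3 df: boundary knots at the day
## range, 2 internal knots at the day tertiles
splineBasis <- function(day, newday = day) {
    ud <- sort(unique(day))
    knots <- quantile(day, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    splines::ns(newday, knots = knots, Boundary.knots = range(ud))
}

bisquareRho <- function(u, c = 4.685) {
    r <- rep(c^2 / 6, length(u))
    inside <- abs(u) <= c
    r[inside] <- c^2 / 6 * (1 - (1 - (u[inside] / c)^2)^3)
    r
}

#' Fit the developmental time model to every feature
#'
#' For each feature, the (quantile-normalized) per-sample values are
#' mean-centered and regressed on a natural cubic spline of day (3 df;
#' boundary knots at the day range, internal knots at the day tertiles).
#' Significance of developmental time is a likelihood-ratio test against an
#' intercept-only null: in \code{ols} mode the statistic is
#' \eqn{n \log(RSS_0 / RSS_1)} referred to \eqn{\chi^2_3}; in \code{robust}
#' mode both models are fit by iteratively reweighted least squares
#' (bisquare psi, tuning 4.685, via \code{MASS::rlm}) and the statistic is
#' twice the robustified deviance difference evaluated at the full-model
#' scale, referred to the same \eqn{\chi^2_3} reference.
#'
#' Fold-range and abundance summaries are computed from the raw
#' (uncentered) per-day replicate means; the fold-range uses a pseudocount
#' of 0.5 against zero minima.
#'
#' @param x a \linkS4class{TimeCourseExperiment}; needs >= 8 samples
#'   spanning >= 4 distinct days.
#' @param mode \code{"ols"} (exact, vectorized) or \code{"robust"}.
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{lrt_stat}, \code{p_raw}, \code{log2_range},
#'   \code{max_daily_mean}, and fitted per-day values in columns
#'   \code{fit_day<d>}.
#' @export
fitDevelopmentalModel <- function(x, mode = c("ols", "robust")) {
    mode <- match.arg(mode)
    stopifnot(is(x, "TimeCourseExperiment"))
    day <- sampleDays(x)
    if (length(day) < 8L) stop("need at least 8 samples")
    if (length(unique(day)) < 4L)
        stop("need at least 4 distinct days for a 3-df spline")
    Y <- SummarizedExperiment::assay(x)
    n <- ncol(Y)
    ud <- sort(unique(day))
    B <- splineBasis(day)
    X <- cbind(1, B)
    Bd <- splineBasis(day, ud)
    Yc <- Y - rowMeans(Y)

    if (mode == "ols") {
        qrX <- qr(X)
        resid <- qr.resid(qrX, t(Yc))
        rssFull <- colSums(resid^2)
        rssRed <- rowSums(Yc^2)
        cf <- qr.coef(qrX, t(Yc))               # (1 + 3df) x features
        fitDaily <- t(cbind(1, Bd) %*% cf) + rowMeans(Y)
        lrt <- ifelse(rssRed <= .Machine$double.eps, 0,
                      n * log(rssRed / pmax(rssFull, 1e-300)))
    } else {
        nf <- nrow(Y)
        lrt <- numeric(nf)
        fitDaily <- matrix(0, nf, length(ud))
        for (i in seq_len(nf)) {
            y <- Yc[i, ]
            if (var(y) <= .Machine$double.eps) {
                lrt[i] <- 0
                fitDaily[i, ] <- mean(Y[i, ])
                next
            }
            fitFull <- tryCatch(
                MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
                          maxit = 100),
                error = function(e) NULL)
            if (is.null(fitFull)) {             # fall back to ols statistic
                cf <- qr.coef(qr(X), y)
                fullRes <- y - X %*% cf
                lrt[i] <- n * log(sum(y^2) / max(sum(fullRes^2), 1e-300))
                fitDaily[i, ] <- cbind(1, Bd) %*% cf + mean(Y[i, ])
                next
            }
            s <- fitFull$s
            if (!is.finite(s) || s <= 0) s <- sd(y)
            fitRed <- tryCatch(
                MASS::rlm(matrix(1, n, 1L), y, psi = MASS::psi.bisquare,
                          c = 4.685, maxit = 100),
                error = function(e) NULL)
            redRes <- if (is.null(fitRed)) y - stats::median(y)
                      else residuals(fitRed)
            dFull <- sum(bisquareRho(residuals(fitFull) / s))
            dRed <- sum(bisquareRho(redRes / s))
            lrt[i] <- max(0, 2 * (dRed - dFull))
            fitDaily[i, ] <- cbind(1, Bd) %*% coef(fitFull) + mean(Y[i, ])
        }
    }
    p <- pchisq(lrt, df = 3, lower.tail = FALSE)
    p[lrt == 0] <- 1

    dm <- dayMeans(x)
    log2Range <- log2((apply(dm, 1L, max) + 0.5) /
                      (apply(dm, 1L, min) + 0.5))
    out <- data.frame(feature_id = rownames(Y), lrt_stat = lrt, p_raw = p,
                      log2_range = log2Range,
                      max_daily_mean = apply(dm, 1L, max),
                      stringsAsFactors = FALSE)
    fitCols <- as.data.frame(fitDaily)
    colnames(fitCols) <- sprintf("fit_day%g", ud)
    out <- cbind(out, fitCols)
    rownames(out) <- NULL
    out
}

#' Call developmentally regulated features and their direction
#'
#' Applies Benjamini-Hochberg adjustment across all tested features and the
#' three filters: adjusted p below \code{pAdjMax}, fold-range
#' (\code{log2_range}) of at least \code{minLog2Range}, and maximum daily
#' mean of at least \code{minMaxLevel} (defaults: 30 normalized counts for
#' DHSs, 2 FPKM for genes). Direction compares the mean fitted value over
#' the last two days with the first two: \code{activated} if it rose,
#' \code{silenced} if it fell, \code{other} if the difference is below 5\%
#' of the fitted range.
#'
#' @param fits output of \code{\link{fitDevelopmentalModel}}.
#' @param pAdjMax,minLog2Range,minMaxLevel filter thresholds.
#' @param featureKind \code{"dhs"} or \code{"gene"}; sets the default
#'   \code{minMaxLevel}.
#' @return \code{fits} with added columns \code{p_adj}, \code{regulated},
#'   \code{direction}.
#' @export
callRegulated <- function(fits, pAdjMax = 1e-5, minLog2Range = 1,
                          minMaxLevel = NULL,
                          featureKind = c("dhs", "gene")) {
    featureKind <- match.arg(featureKind)
    if (is.null(minMaxLevel))
        minMaxLevel <- switch(featureKind, dhs = 30, gene = 2)
    fits$p_adj <- p.adjust(fits$p_raw, method = "BH")
    fits$regulated <- fits$p_adj < pAdjMax &
        fits$log2_range >= minLog2Range &
        fits$max_daily_mean >= minMaxLevel
    fitCols <- grep("^fit_day", colnames(fits))
    fd <- as.matrix(fits[, fitCols, drop = FALSE])
    nd <- ncol(fd)
    first2 <- rowMeans(fd[, 1:min(2L, nd), drop = FALSE])
    last2 <- rowMeans(fd[, max(1L, nd - 1L):nd, drop = FALSE])
    rng <- apply(fd, 1L, max) - apply(fd, 1L, min)
    diffv <- last2 - first2
    fits$direction <- ifelse(rng == 0 | abs(diffv) < 0.05 * rng, "other",
                             ifelse(diffv > 0, "activated", "silenced"))
    fits
}
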