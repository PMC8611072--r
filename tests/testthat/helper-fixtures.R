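## shared fixture builders -------------------------------------------------

## tiny time course: nf features x (days x donors), constant + ramp rows
tinyTce <- function(nf = 4L, days = 0:3, donors = c("a", "b"),
                    seed = 42L) {
    withr::with_seed(seed, {
        sampleDay <- rep(days, each = length(donors))
        sampleDonor <- rep(donors, times = length(days))
        id <- sprintf("d%d_%s", sampleDay, sampleDonor)
        m <- matrix(abs(rnorm(nf * length(id), 10, 2)), nf,
                    dimnames = list(sprintf("f%d", seq_len(nf)), id))
        TimeCourseExperiment(m, data.frame(sample_id = id,
                                           donor = sampleDonor,
                                           day = sampleDay))
    })
}

writeLinesTmp <- function(lines, ext = ".tsv") {
    path <- withr::local_tempfile(fileext = ext,
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

## brute-force LRT oracle: explicit normal-equation least squares for the
## spline-full and intercept-only models
oracleLrt <- function(y, day) {
    yc <- y - mean(y)
    B <- splines::ns(day, knots = quantile(day, c(1/3, 2/3), names = FALSE),
                     Boundary.knots = range(day))
    X <- cbind(1, B)
    bhat <- solve(t(X) %*% X, t(X) %*% yc)
    rssFull <- sum((yc - X %*% bhat)^2)
    rssRed <- sum(yc^2)
    n <- length(y)
    lrt <- n * log(rssRed / rssFull)
    list(lrt = lrt, p = pchisq(lrt, 3, lower.tail = FALSE))
}

## dynamic-programming hypergeometric tail oracle: pmf by the standard
## ratio recurrence from the lower support end, then tail sums
dpHyperTails <- function(k, K, N, n) {
    kmin <- max(0L, n - (N - K))
    kmax <- min(n, K)
    pmf <- numeric(kmax - kmin + 1L)
    ## P(X = kmin) via log-factorial-free products would overflow; build it
    ## from the recurrence seeded by an unnormalized 1 and renormalize
    u <- numeric(length(pmf))
    u[1L] <- 1
    if (length(u) > 1L)
        for (i in seq_len(length(u) - 1L)) {
            kk <- kmin + i - 1L
            u[i + 1L] <- u[i] * ((K - kk) * (n - kk)) /
                ((kk + 1) * (N - K - n + kk + 1))
        }
    pmf <- u / sum(u)
    idx <- k - kmin + 1L
    list(p_over = sum(pmf[idx:length(pmf)]),
         p_under = sum(pmf[1L:idx]),
         pmf = pmf[idx])
}

## random hypergeometric enrichment instance (one TF, two clusters)
randomEnrichmentCase <- function(seed) {
    withr::with_seed(seed, {
        N <- sample(20:200, 1)
        ids <- sprintf("d%03d", seq_len(N))
        K <- sample(1:N, 1)
        n <- sample(1:N, 1)
        hits <- data.frame(dhs_id = sample(ids, K), tf_name = "TF1",
                           hit_count = 1L)
        clusters <- data.frame(feature_id = ids,
                               cluster = c(rep(1, n), rep(2, N - n)),
                               label = c(rep("E1", n), rep("E2", N - n)))
        list(hits = hits, clusters = clusters, N = N, K = K, n = n)
    })
}

## random sparse regression problem for solver checks
randomProblem <- function(n = 13, p = 6, seed = 1, sparse = 2) {
    withr::with_seed(seed, {
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("x", seq_len(p))))
        beta <- c(rnorm(sparse), rep(0, p - sparse))
        y <- as.vector(X %*% beta) + rnorm(n, 0, 0.3)
        list(X = X, y = y, beta = beta)
    })
}

## simple quantile-normalization oracle: rank-mean reference with ties
## receiving the mean of their reference slots
oracleQuantileNormalize <- function(m) {
    ref <- rowMeans(apply(m, 2L, sort))
    out <- m
    for (j in seq_len(ncol(m))) {
        rmin <- rank(m[, j], ties.method = "min")
        rmax <- rank(m[, j], ties.method = "max")
        ## a tied group takes the mean of every reference slot it occupies
        out[, j] <- vapply(seq_along(rmin), function(i)
            mean(ref[rmin[i]:rmax[i]]), numeric(1))
    }
    out
}
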