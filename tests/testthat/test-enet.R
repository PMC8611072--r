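test_that("solver hits the OLS limit, the null threshold and closed-form ridge", {
    withr::with_seed(2, {
        x <- rnorm(13)
        y <- x
        X <- matrix(x, ncol = 1, dimnames = list(NULL, "x1"))
    })
    fit <- enetFit(X, y, alpha = 0.37, lambda = 1e-9)
    expect_equal(unname(fit$beta[1, 1]), 1, tolerance = 1e-4)

    ## lasso null threshold: lambda >= max|Xc'yc|/(n alpha) zeroes all
    pb <- randomProblem(seed = 3)
    for (alpha in c(0.3, 1)) {
        lam0 <- chronet:::lassoNullLambda(pb$X, pb$y, alpha)
        z <- enetFit(pb$X, pb$y, alpha, lam0 * 1.0000001)
        expect_true(all(z$beta == 0))
        nz <- enetFit(pb$X, pb$y, alpha, lam0 * 0.99)
        expect_gt(sum(nz$beta != 0), 0)
    }

    ## alpha = 0 equals the closed-form ridge solution
    for (lam in c(1e-3, 0.1, 10)) {
        fit <- enetFit(pb$X, pb$y, alpha = 0, lambda = lam, tol = 1e-10)
        Xc <- scale(pb$X, scale = FALSE)
        yc <- pb$y - mean(pb$y)
        n <- nrow(pb$X)
        ref <- solve(crossprod(Xc) / n + lam * diag(ncol(Xc)),
                     crossprod(Xc, yc) / n)
        expect_equal(unname(fit$beta[, 1]), as.vector(ref),
                     tolerance = 1e-6)
    }
})

test_that("KKT conditions hold at every solved grid point", {
    for (s in 1:5) {
        pb <- randomProblem(p = 8, seed = 10 + s, sparse = 3)
        for (alpha in c(0.1, 0.5, 0.95)) {
            lams <- 10^seq(-4, 1, length.out = 8)
            fit <- enetFit(pb$X, pb$y, alpha, lams)
            for (l in seq_along(lams)) {
                kkt <- enetKkt(pb$X, pb$y, fit$beta[, l], fit$b0[l],
                               alpha, lams[l])
                if (length(kkt$inactive))
                    expect_lt(max(kkt$inactive), 1e-5)
                if (length(kkt$active))
                    expect_lt(max(abs(kkt$active)), 1e-5)
            }
        }
    }
})

test_that("solutions agree with glmnet on shared problems", {
    library(glmnet)
    for (s in 1:3) {
        pb <- randomProblem(n = 20, p = 7, seed = 30 + s, sparse = 3)
        ## glmnet standardizes y internally for gaussian fits, so compare
        ## on a unit-variance response where both objectives coincide
        sy <- sqrt(mean((pb$y - mean(pb$y))^2))
        pb$y <- pb$y / sy
        for (alpha in c(0.2, 0.8)) {
            lams <- c(0.5, 0.1, 0.02)
            ours <- enetFit(pb$X, pb$y, alpha, lams, tol = 1e-9)
            gfit <- glmnet(pb$X, pb$y, alpha = alpha, lambda = lams,
                           standardize = FALSE, intercept = TRUE,
                           thresh = 1e-14)
            for (l in seq_along(lams)) {
                ref <- as.vector(coef(gfit, s = lams[l]))
                expect_equal(unname(c(ours$b0[l], ours$beta[, l])), ref,
                             tolerance = 1e-4)
            }
        }
    }
})

test_that("the coordinate-descent objective never increases across sweeps", {
    pb <- randomProblem(n = 13, p = 10, seed = 44, sparse = 4)
    fit <- enetFit(pb$X, pb$y, alpha = 0.5,
                   lambda = 10^seq(1, -4, length.out = 6), trace = TRUE)
    for (tr in fit$objective_trace)
        if (length(tr) > 1)
            expect_true(all(diff(tr) <= 1e-12))
})

test_that("sparsity is monotone along the penalty path on average", {
    withr::with_seed(55, {
        nzByLambda <- matrix(0, 20, 12)
        for (d in 1:20) {
            pb <- randomProblem(n = 13, p = 9, seed = 500 + d, sparse = 3)
            lams <- 10^seq(-4, 1, length.out = 12)
            fit <- enetFit(pb$X, pb$y, alpha = 0.9, lams)
            nzByLambda[d, ] <- colSums(fit$beta != 0)
        }
        avg <- colMeans(nzByLambda)
        expect_true(all(diff(avg) <= 1e-9))
    })
})

test_that("designs apply the motif, expression and variance filters", {
    days <- 0:6
    tfDm <- rbind(TFa = 10 + days, TFb = 1 + 0.05 * days,  # max < 2 FPKM
                  TFc = 20 - days, TFd = rep(5, 7))        # constant
    colnames(tfDm) <- days
    hits <- data.frame(dhs_id = "d1", tf_name = c("TFa", "TFb", "TFc"),
                       hit_count = 1L)
    y <- 3 + days
    names(y) <- days
    expect_warning(des <- buildDesign("d1", hits, tfDm, y,
                                      requireRegulatedTf = FALSE),
                   "constant")
    expect_setequal(des$candidates, c("TFa", "TFc"))   # TFb under 2 FPKM
    expect_equal(unname(colMeans(des$X)), c(0, 0))
    expect_equal(unname(apply(des$X, 2, sd)), c(1, 1))
    expect_equal(mean(des$y), 0)

    none <- suppressWarnings(
        buildDesign("d9", hits, tfDm, y, requireRegulatedTf = FALSE))
    expect_false(none$modelable)

    reg <- suppressWarnings(
        buildDesign("d1", hits, tfDm, y, requireRegulatedTf = TRUE,
                    regulatedTfs = "TFc"))
    expect_equal(reg$candidates, "TFc")
})

test_that("cluster-level CV selects sane penalties deterministically", {
    days <- 0:12
    withr::with_seed(66, {
        tfCurve <- plogis((days - 6) / 1.2)
        X <- matrix(c(scale(tfCurve), scale(rnorm(13))), 13, 2,
                    dimnames = list(days, c("TFtrue", "TFnoise")))
        y <- 10 * as.vector(scale(tfCurve))
        des <- list(list(X = X, y = y, candidates = colnames(X),
                         modelable = TRUE))
        cfg <- enetConfig(alphaGrid = seq(0, 1, 0.25),
                          lambdaGrid = 10^seq(-4, 2, length.out = 10),
                          nRepeats = 10, seed = 5)
        sel <- cvSelectClusterParams(des, cfg)
        fit <- fitElasticNetFinal(des[[1]], sel$alpha, sel$lambda)
        expect_lt(fit$mse, 1e-3 * var(y))
        expect_gt(fit$beta["TFtrue"], 0)
        sel2 <- cvSelectClusterParams(des, cfg)
        expect_identical(sel, sel2)

        ## a pure-noise design ties across the null region; the tie-break
        ## takes the sparsest corner (largest lambda, then largest alpha)
        desN <- list(list(X = X, y = rnorm(13), candidates = colnames(X),
                          modelable = TRUE))
        selN <- cvSelectClusterParams(desN, cfg)
        expect_equal(selN$lambda, max(cfg$lambdaGrid))
        expect_equal(selN$alpha, max(cfg$alphaGrid))

        cfgBad <- enetConfig(nHeldoutDays = 8)
        expect_error(cvSelectClusterParams(des, cfgBad), "fewer than 6")
    })
})

test_that("model summaries count explanatory TFs", {
    co <- rbind(d1 = c(TFa = 0.5, TFb = -0.2, TFc = 0),
                d2 = c(TFa = 0, TFb = 0, TFc = 0),
                d3 = c(TFa = 0.1, TFb = 0.3, TFc = -0.4))
    s <- modelSummary(co)
    expect_equal(unname(s$nonzero_per_dhs), c(2, 0, 3))
    expect_equal(unname(s$positive_per_dhs), c(1, 0, 2))
    expect_equal(s$frac_dhs_modeled, 2 / 3)
    expect_equal(unname(s$positive_dhs_per_tf), c(2, 1, 0))
    expect_equal(modelSummary(co * 0)$frac_dhs_modeled, 0)
})
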