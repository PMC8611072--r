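test_that("quantile normalization maps columns onto the rank-mean reference", {
    ## two identical columns are a fixed point
    m <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
    expect_equal(quantileNormalize(m), m)

    ## hand-computed rank-mean reference
    m2 <- cbind(a = c(1, 2, 3), b = c(10, 20, 30))
    qn <- quantileNormalize(m2)
    expect_equal(unname(qn[, "a"]), c(5.5, 11, 16.5))
    expect_equal(unname(qn[, "b"]), c(5.5, 11, 16.5))

    ## ties take the mean of their reference slots (constant column)
    m3 <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
    expect_equal(quantileNormalize(m3), oracleQuantileNormalize(m3),
                 ignore_attr = TRUE)
    expect_equal(unname(quantileNormalize(m3)[, "a"]), rep(3.5, 3))

    expect_error(quantileNormalize(cbind(c(-1, 2), c(1, 2))), "negative")
    ## random matrices agree with the independent oracle; tie-free data
    ## also matches limma's quantile normalization
    withr::with_seed(3, {
        r <- matrix(rpois(60, 20), 10, 6)
        expect_equal(quantileNormalize(r), oracleQuantileNormalize(r),
                     ignore_attr = TRUE)
        u <- matrix(runif(60, 0, 100), 10, 6)     # ties a.s. absent
        expect_equal(quantileNormalize(u),
                     limma::normalizeQuantiles(u), ignore_attr = TRUE)
    })
})

test_that("spline LRT matches the explicit normal-equation oracle", {
    withr::with_seed(21, {
        day <- rep(0:12, each = 3)
        for (i in 1:100) {
            y <- rnorm(length(day), 10, 2) +
                runif(1, 0, 3) * day / 12        # random mild trend
            tc <- TimeCourseExperiment(
                matrix(y, 1, dimnames = list("f", paste0("s", seq_along(day)))),
                data.frame(sample_id = paste0("s", seq_along(day)),
                           donor = rep(c("a", "b", "c"), 13), day = day))
            fit <- fitDevelopmentalModel(tc, "ols")
            orc <- oracleLrt(y, day)
            expect_equal(fit$lrt_stat, orc$lrt, tolerance = 1e-8)
        }
    })
})

test_that("degenerate and strong-signal profiles behave sensibly", {
    day <- rep(0:12, each = 3)
    sheet <- data.frame(sample_id = paste0("s", seq_along(day)),
                        donor = rep(c("a", "b", "c"), 13), day = day)
    m <- rbind(const = rep(7, length(day)),
               ramp = 10 + day + rnorm(length(day), 0, 0.1))
    colnames(m) <- sheet$sample_id
    withr::with_seed(5, m["ramp", ] <- 10 + day + rnorm(length(day), 0, 0.1))
    tc <- TimeCourseExperiment(m, sheet)
    fit <- fitDevelopmentalModel(tc, "ols")
    expect_equal(fit$lrt_stat[fit$feature_id == "const"], 0)
    expect_equal(fit$p_raw[fit$feature_id == "const"], 1)
    ramp <- fit[fit$feature_id == "ramp", ]
    expect_lt(ramp$p_raw, 1e-10)
    orc <- oracleLrt(m["ramp", ], day)
    expect_lt(abs(log10(ramp$p_raw) - log10(orc$p)) /
                  abs(log10(orc$p)), 0.1)

    ## too few distinct days
    short <- tinyTce(days = 0:2, donors = c("a", "b", "c"))
    expect_error(fitDevelopmentalModel(short), "4 distinct days")
})

test_that("robust mode agrees with ols on clean data and resists outliers", {
    withr::with_seed(9, {
        day <- rep(0:12, each = 3)
        sheet <- data.frame(sample_id = paste0("s", seq_along(day)),
                            donor = rep(c("a", "b", "c"), 13), day = day)
        clean <- 20 + 5 * sin(day / 4) + rnorm(length(day), 0, 0.3)
        dirty <- clean
        dirty[5] <- dirty[5] + 50            # single gross outlier
        m <- rbind(clean = clean, dirty = dirty, null = rnorm(39, 20, 1))
        colnames(m) <- sheet$sample_id
        tc <- TimeCourseExperiment(m, sheet)
        rob <- fitDevelopmentalModel(tc, "robust")
        ols <- fitDevelopmentalModel(tc, "ols")
        ## strong signal highly significant under both
        expect_lt(rob$p_raw[rob$feature_id == "clean"], 1e-8)
        ## the outlier wrecks the ols statistic far more than the robust one
        expect_gt(rob$lrt_stat[rob$feature_id == "dirty"],
                  ols$lrt_stat[ols$feature_id == "dirty"])
        expect_gt(rob$p_raw[rob$feature_id == "null"], 1e-4)
    })
})

test_that("signal injection never decreases the LRT statistic", {
    withr::with_seed(31, {
        day <- rep(0:12, each = 3)
        sheet <- data.frame(sample_id = paste0("s", seq_along(day)),
                            donor = rep(c("a", "b", "c"), 13), day = day)
        worse <- 0L
        for (i in 1:100) {
            noise <- rnorm(length(day), 30, 1)
            signal <- noise + runif(1, 2, 4) * day / 6
            m <- rbind(null = noise, sig = signal)
            colnames(m) <- sheet$sample_id
            fit <- fitDevelopmentalModel(TimeCourseExperiment(m, sheet),
                                         "ols")
            if (fit$lrt_stat[fit$feature_id == "sig"] <
                fit$lrt_stat[fit$feature_id == "null"])
                worse <- worse + 1L
        }
        expect_equal(worse, 0L)
    })
})

test_that("regulated calls apply BH and the abundance/fold filters", {
    ## hand-checked BH on three p-values
    expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

    fits <- data.frame(feature_id = c("a", "b", "c", "d"),
                       lrt_stat = 50, p_raw = c(1e-8, 1e-8, 0.5, 1e-8),
                       log2_range = c(1.3, 1.3, 1.3, 0.8),
                       max_daily_mean = c(35, 29, 35, 35),
                       fit_day0 = c(1, 1, 1, 5), fit_day1 = c(2, 2, 2, 5),
                       fit_day2 = c(8, 8, 8, 5), fit_day3 = c(9, 9, 9, 5),
                       stringsAsFactors = FALSE)
    out <- callRegulated(fits, featureKind = "dhs")
    expect_equal(out$regulated, c(TRUE, FALSE, FALSE, FALSE))
    expect_equal(out$p_adj, p.adjust(fits$p_raw, "BH"))
    expect_equal(out$direction[1], "activated")
    expect_equal(out$direction[4], "other")        # flat fitted profile
    ## gene kind lowers the abundance floor to 2
    outG <- callRegulated(transform(fits, max_daily_mean = 2.5),
                          featureKind = "gene")
    expect_true(outG$regulated[1])
    expect_error(callRegulated(fits, featureKind = "rna"))
})
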