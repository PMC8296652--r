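test_that("trapezoidal AUC matches closed forms", {
    ## constant function
    r <- traitAuc(c(6, 9, 12), c(5, 5, 5), c(6, 12))
    expect_equal(r$auc, 30)
    expect_equal(r$yearly, 5)
    ## linear ramp value = age: integral of x over [6,12] = 54
    r2 <- traitAuc(c(6, 12), c(6, 12), c(6, 12))
    expect_equal(r2$auc, 54)
    expect_equal(r2$yearly, 9)
    ## single measurement: missing with a reason
    r3 <- traitAuc(10, 5, c(6, 12))
    expect_true(is.na(r3$auc))
    expect_identical(r3$reason, "insufficient_points")
    ## duplicate ages averaged
    r4 <- traitAuc(c(6, 6, 12), c(4, 6, 5), c(6, 12))
    expect_equal(r4$yearly, 5)
})

test_that("AUC is additive over contiguous windows", {
    set.seed(61)
    ages <- c(6, 12, 18, 24)
    vals <- rnorm(4, 10, 3)
    a1 <- traitAuc(ages, vals, c(6, 12))$auc
    a2 <- traitAuc(ages, vals, c(12, 18))$auc
    a3 <- traitAuc(ages, vals, c(18, 24))$auc
    atot <- traitAuc(ages, vals, c(6, 24))$auc
    expect_equal(atot, a1 + a2 + a3)
})

test_that("dense-grid trapezoid converges to analytic integrals", {
    ## quadratic f(x) = 2 + 0.5 x - 0.01 x^2 over [6, 24]
    f <- function(x) 2 + 0.5 * x - 0.01 * x^2
    F <- function(x) 2 * x + 0.25 * x^2 - 0.01 * x^3 / 3
    ages <- seq(5, 25, by = 0.001)
    r <- traitAuc(ages, f(ages), c(6, 24))
    expect_equal(r$auc, F(24) - F(6), tolerance = 1e-6)
    ## yearly estimate bounded by the interpolated extrema in the window
    xs <- seq(6, 24, by = 0.001)
    expect_gte(r$yearly, min(f(xs)))
    expect_lte(r$yearly, max(f(xs)))
})

test_that("coverage and boundary rules control missingness", {
    ## measured only at 20-24: windows 6-12, 6-18, 12-18 missing, 18-24
    ## present (20 is within 3 years of the 18 boundary -> anchored)
    panel <- TraitPanel(data.frame(
        sample = "s1", trait = "glucose",
        age = c(20, 22, 24), value = c(5, 5.2, 5.4)))
    est <- as.data.frame(estimateByAge(panel))
    expect_identical(nrow(est), 5L)
    present <- est$window[!is.na(est$yearly)]
    expect_identical(present, "18-24")
    ## full coverage: all 5 default windows
    panel2 <- TraitPanel(data.frame(
        sample = "s1", trait = "glucose",
        age = c(6, 12, 18, 24), value = c(5, 5, 5, 5)))
    est2 <- as.data.frame(estimateByAge(panel2))
    expect_true(all(!is.na(est2$yearly)))
    expect_true(all(est2$yearly == 5))
})

test_that("log-flagged traits are integrated on the log scale", {
    panel <- TraitPanel(
        data.frame(sample = "s1", trait = "tg",
                   age = c(6, 12), value = c(exp(1), exp(3))),
        traitInfo = data.frame(trait = "tg", log_transform = TRUE))
    est <- as.data.frame(estimateByAge(panel, windows = list(c(6, 12))))
    expect_equal(est$yearly, 2)  # mean of log-values 1 and 3
})

test_that("status-trait regression recovers constructed effects", {
    set.seed(62)
    n <- 200
    ids <- sprintf("s%03d", 1:n)
    st <- rep(c("non", "hemi"), each = n / 2)
    names(st) <- ids
    calls <- makeCalls(st)
    ## outcome equal to the status indicator: maximal separation
    est <- S4Vectors::DataFrame(
        sample = ids, trait = "t", window = "6-24",
        yearly = as.numeric(st == "non") + rnorm(n, sd = 1e-8))
    res <- associateStatusTraits(est, calls)
    expect_lt(res$p, 1e-100)
    expect_gt(res$ci_lo, 0)
    ## beta in SD units: two equal groups separated by delta have outcome
    ## SD = delta/2 (delta/2 * sqrt(n/(n-1)) with the sample SD), so the
    ## standardized difference is 2 * sqrt((n-1)/n)
    expect_equal(res$beta, 2 * sqrt((n - 1) / n), tolerance = 1e-6)
    ## degenerate outcome rejected with reason
    est2 <- est
    est2$yearly <- rep(1, n)
    res2 <- associateStatusTraits(est2, calls)
    expect_identical(res2$reason, "degenerate_outcome")
    ## too-small groups rejected with reason
    st3 <- c(rep("non", 5), rep("hemi", 50))
    names(st3) <- sprintf("s%03d", seq_along(st3))
    est3 <- S4Vectors::DataFrame(sample = names(st3), trait = "t",
                                 window = "6-24", yearly = rnorm(55))
    res3 <- associateStatusTraits(est3, makeCalls(st3))
    expect_identical(res3$reason, "group_too_small")
})

test_that("null status-trait regressions keep the nominal type-I rate", {
    set.seed(63)
    n <- 150
    ids <- sprintf("s%03d", 1:n)
    st <- rep(c("non", "hemi"), c(50, 100))
    names(st) <- ids
    calls <- makeCalls(st)
    n_rep <- 400
    ps <- vapply(seq_len(n_rep), function(i) {
        est <- S4Vectors::DataFrame(sample = ids, trait = "t",
                                    window = "6-24", yearly = rnorm(n))
        associateStatusTraits(est, calls)$p
    }, numeric(1))
    rate <- mean(ps < 0.05)
    se <- sqrt(0.05 * 0.95 / n_rep)
    expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("sex stratification runs the three strata", {
    coh <- simulateCohort(cohortConfig(n_samples = 400, seed = 64,
                                       n_timepoints = 1))
    calls <- makeCalls(trueStatus(coh))
    est <- estimateByAge(cohortTraits(coh), windows = list(c(6, 24)))
    cov <- as.data.frame(cohortCovariates(coh))
    res <- associateStatusTraits(est, calls, covariates = cov,
                                 stratify_by_sex = TRUE)
    expect_setequal(unique(res$stratum), c("all", "men", "women"))
    ## the simulated insulin effect (0.25 SD, non > hemi) is detected overall
    ins <- res[res$trait == "insulin" & res$stratum == "all", ]
    expect_gt(ins$beta, 0)
    expect_lt(ins$p, 0.05)
})

test_that("a 0.3 SD status effect is covered by its own 95% CI", {
    set.seed(65)
    n <- 1600
    ids <- sprintf("s%04d", seq_len(n))
    st <- rep(c("non", "hemi"), c(400, 1200))
    names(st) <- ids
    calls <- makeCalls(st)
    n_rep <- 200
    covered <- vapply(seq_len(n_rep), function(i) {
        y <- 0.3 * as.numeric(st == "non") + rnorm(n)
        est <- S4Vectors::DataFrame(sample = ids, trait = "t",
                                    window = "6-24", yearly = y)
        res <- associateStatusTraits(est, calls)
        ## the estimate is on the standardized-outcome scale; so is the truth
        truth <- 0.3 / sd(y)
        res$ci_lo <= truth && truth <= res$ci_hi
    }, logical(1))
    expect_gte(mean(covered), 0.90)
})

test_that("chi-squared worked cases are exact", {
    ## counts [[10,40],[40,10]]: statistic 36.0 uncorrected
    st <- c(rep("non", 10), rep("hemi", 40), rep("non", 40), rep("hemi", 10))
    names(st) <- sprintf("s%03d", seq_along(st))
    fac <- rep(c("A", "B"), each = 50)
    names(fac) <- names(st)
    res <- testCategoricalAssociation(makeCalls(st), fac)
    expect_equal(res$overall$statistic, 36)
    expect_lt(res$overall$p, 1e-8)
    expect_equal(res$pairwise$statistic, 36)
    ## perfect independence: statistic 0, p 1
    st0 <- rep(c("non", "hemi"), 60)
    names(st0) <- sprintf("s%03d", seq_along(st0))
    fac0 <- rep(c("A", "A", "B", "B"), 30)
    names(fac0) <- names(st0)
    res0 <- testCategoricalAssociation(makeCalls(st0), fac0)
    expect_equal(res0$overall$statistic, 0)
    expect_equal(res0$overall$p, 1)
    ## single factor level rejected; intermediates excluded
    fac1 <- rep("A", length(st0))
    names(fac1) <- names(st0)
    expect_error(testCategoricalAssociation(makeCalls(st0), fac1),
                 ">= 2")
    st2 <- c(st, setNames(rep("intermediate", 4),
                          sprintf("x%02d", 1:4)))
    fac2 <- c(fac, setNames(rep("A", 4), sprintf("x%02d", 1:4)))
    res2 <- testCategoricalAssociation(makeCalls(st2), fac2)
    expect_identical(res2$excluded, 4L)
    expect_equal(res2$overall$statistic, 36)
})
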