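test_that("config validation rejects bad inputs", {
    expect_error(cohortConfig(n_samples = 0), "positive")
    expect_error(cohortConfig(status_weights = c(non = 0.5, hemi = 0.6)),
                 "sum to 1")
    expect_error(cohortConfig(rna_fold_changes = c("x" = -1)), "> 0")
    expect_error(cohortConfig(beta_means = c(non = 0, intermediate = 0.35,
                                             hemi = 0.5, full = 0.7)),
                 "\\(0, 1\\)")
    expect_error(simulateBetaMatrix(c("hemi", "weird")), "unknown status")
})

test_that("degenerate mixtures hit their configured means exactly", {
    ## all-hemi, noise-free: every median beta is exactly 0.50
    cfg <- cohortConfig(n_samples = 20,
                        status_weights = c(hemi = 1),
                        beta_sd = 0, sample_level_sd = 0, seed = 3)
    coh <- simulateCohort(cfg)
    b <- betaValues(betaMatrices(coh)[[1]])
    med <- apply(b[sprintf("cgB%02d", 1:14), ], 2, median)
    expect_true(all(med == 0.50))
    ## all-full, noise-free: bimodal betas 0.70, above the 0.60 rule
    bm <- simulateBetaMatrix(rep("full", 5),
                             params = cohortConfig(beta_sd = 0,
                                                   sample_level_sd = 0),
                             seed = 1)
    bb <- betaValues(bm)[sprintf("cgB%02d", 1:14), ]
    expect_true(all(bb == 0.70))
    expect_true(all(bb > 0.60))
})

test_that("status sampling follows the configured weights", {
    cfg <- cohortConfig(n_samples = 10000,
                        status_weights = c(non = 0.25, hemi = 0.75),
                        covariate_assoc = list(),   # no tilts
                        n_timepoints = 1, seed = 1)
    coh <- simulateCohort(cfg)
    frac_non <- mean(trueStatus(coh) == "non")
    se <- sqrt(0.25 * 0.75 / 10000)
    expect_lt(abs(frac_non - 0.25), 3 * se)
})

test_that("noise-free expression reproduces the fold change exactly", {
    cfg <- cohortConfig(n_samples = 40,
                        status_weights = c(non = 0.5, hemi = 0.5),
                        rna_fold_changes = c("nc886-5p" = 2.0),
                        rna_cv = 0, n_timepoints = 1, seed = 5)
    coh <- simulateCohort(cfg)
    v <- exprValues(cohortExpression(coh)[[1]])["nc886-5p", ]
    st <- trueStatus(coh)
    expect_equal(median(v[st == "non"]) / median(v[st == "hemi"]), 2.0)
})

test_that("per-CpG means and flanking independence behave as constructed", {
    bm <- simulateBetaMatrix(rep("hemi", 1000), seed = 11)
    means <- rowMeans(betaValues(bm)[sprintf("cgB%02d", 1:14), ])
    expect_true(all(abs(means - 0.50) < 0.02))
    ## flanking CpGs carry no status signal
    st <- rep(c("non", "hemi"), each = 500)
    bm2 <- simulateBetaMatrix(st, seed = 12)
    fl <- betaValues(bm2)[sprintf("cgF%02d", 1:6), ]
    rr <- apply(fl, 1, function(z) cor(z, as.numeric(st == "hemi")))
    expect_true(all(abs(rr) < 0.05))
    ## and the bimodal ones do
    bb <- betaValues(bm2)["cgB01", ]
    expect_gt(cor(bb, as.numeric(st == "hemi")), 0.9)
})

test_that("simulation is deterministic and labelled consistently", {
    cfg <- cohortConfig(n_samples = 60, seed = 9)
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(betaValues(betaMatrices(c1)[[1]]),
                     betaValues(betaMatrices(c2)[[1]]))
    expect_identical(trueStatus(c1), trueStatus(c2))
    expect_identical(exprValues(cohortExpression(c1)[[1]]),
                     exprValues(cohortExpression(c2)[[1]]))
    expect_identical(as.data.frame(traitRecords(cohortTraits(c1))),
                     as.data.frame(traitRecords(cohortTraits(c2))))
    ## identical ids across all components (class validity enforces too)
    expect_identical(colnames(betaMatrices(c1)[[1]]),
                     rownames(cohortCovariates(c1)))
})

test_that("group-wise median betas are ordered non < intermediate < hemi < full", {
    set.seed(31)
    for (s in c(101, 202)) {
        coh <- simulateCohort(cohortConfig(n_samples = 500, seed = s))
        b <- betaValues(betaMatrices(coh)[[1]])[sprintf("cgB%02d", 1:14), ]
        med <- apply(b, 2, median)
        gm <- tapply(med, trueStatus(coh), median)
        gm <- gm[!is.na(gm)]
        expect_true(all(diff(gm) > 0))
    }
})

test_that("longitudinal median betas correlate above 0.95 with no switching", {
    coh <- simulateCohort(cohortConfig(n_samples = 250, seed = 17))
    cp <- sprintf("cgB%02d", 1:14)
    m1 <- apply(betaValues(betaMatrices(coh)[[1]])[cp, ], 2, median)
    m2 <- apply(betaValues(betaMatrices(coh)[[2]])[cp, ], 2, median)
    expect_gt(cor(m1, m2, method = "spearman"), 0.95)
})

test_that("covariate strata tilt the non-methylated prevalence", {
    coh <- simulateCohort(cohortConfig(n_samples = 8000, seed = 19,
                                       n_timepoints = 1))
    cov <- cohortCovariates(coh)
    st <- trueStatus(coh)
    prev <- tapply(st == "non", cov$maternal_age_group, mean)
    ## young and old mothers enriched for non-methylated offspring
    expect_gt(prev[["<=20"]], prev[["21-35"]] + 0.03)
    expect_gt(prev[[">=36"]], prev[["21-35"]] + 0.03)
    prev_inc <- tapply(st == "non", cov$income_quartile, mean)
    expect_lt(prev_inc[["III"]], prev_inc[["I"]] - 0.03)
})

test_that("cohort round-trips through plain-text files", {
    dir <- withr::local_tempdir()
    coh <- simulateCohort(cohortConfig(n_samples = 25, seed = 13))
    writeCohort(coh, dir)
    bm <- readBetaMatrix(file.path(dir, "beta_t1.tsv"),
                         file.path(dir, "cpg_annotation.csv"))
    expect_equal(betaValues(bm), betaValues(betaMatrices(coh)[[1]]))
    expect_equal(as.data.frame(cpgAnnotation(bm))$position,
                 as.data.frame(cpgAnnotation(betaMatrices(coh)[[1]]))$position)
})

test_that("yaml config mirrors cohortConfig", {
    path <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("n_samples: 30",
                 "status_weights:", "  non: 0.3", "  hemi: 0.7",
                 "beta_sd: 0.01", "seed: 4"), path)
    cfg <- readCohortConfig(path)
    expect_s3_class(cfg, "CohortConfig")
    expect_identical(cfg$n_samples, 30L)
    expect_equal(unname(cfg$status_weights[c("non", "hemi")]), c(0.3, 0.7))
    writeLines("nonsense_field: 1", path)
    expect_error(readCohortConfig(path), "unknown config field")
})
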