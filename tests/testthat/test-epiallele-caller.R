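test_that("association scan recovers a constructed linear effect", {
    set.seed(21)
    n <- 50
    b <- matrix(runif(3 * n, 0.05, 0.95), nrow = 3,
                dimnames = list(c("cgA", "cgB", "cgC"),
                                sprintf("s%03d", 1:n)))
    bm <- makeBetaMatrix(b)
    rna <- 10 * b["cgA", ] + rnorm(n, sd = 1e-6)
    res <- scanCpgAssociations(bm, rna)
    expect_equal(res["cgA", "estimate"], 10, tolerance = 1e-4)
    expect_true(res["cgA", "genome_wide"])
    expect_false(any(res[c("cgB", "cgC"), "genome_wide"]))
})

test_that("association scan guards its preconditions", {
    b <- matrix(0.5, nrow = 2, ncol = 1,
                dimnames = list(c("cgA", "cgB"), "s1"))
    bm <- makeBetaMatrix(b)
    expect_error(scanCpgAssociations(bm, c(s1 = 1.0)),
                 "insufficient observations")
    ## constant beta column: missing p, excluded from flags
    set.seed(22)
    b2 <- rbind(cgA = rep(0.4, 20), cgB = runif(20))
    colnames(b2) <- sprintf("s%03d", 1:20)
    bm2 <- makeBetaMatrix(b2)
    rna <- rnorm(20)
    names(rna) <- colnames(b2)
    res <- scanCpgAssociations(bm2, rna)
    expect_true(is.na(res["cgA", "p"]))
    expect_false(res["cgA", "genome_wide"])
    ## rank-deficient covariates rejected
    cov <- data.frame(a = 1:20, b = 2 * (1:20), row.names = colnames(b2))
    expect_error(scanCpgAssociations(bm2, rna, covariates = cov),
                 "rank-deficient")
})

test_that("null association scan keeps its nominal type-I rate", {
    set.seed(23)
    n <- 60
    ncpg <- 400
    b <- matrix(runif(ncpg * n), nrow = ncpg,
                dimnames = list(sprintf("cg%04d", 1:ncpg),
                                sprintf("s%03d", 1:n)))
    bm <- makeBetaMatrix(b)
    rna <- rnorm(n)
    names(rna) <- colnames(b)
    res <- scanCpgAssociations(bm, rna)
    rate <- mean(res$p < 0.05, na.rm = TRUE)
    se <- sqrt(0.05 * 0.95 / ncpg)
    expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("bimodality detection separates constructed shapes", {
    set.seed(24)
    n <- 400
    bimodal <- c(rnorm(n / 2, 0.10, 0.03), rnorm(n / 2, 0.50, 0.03))
    unimodal <- rnorm(n, 0.45, 0.02)
    b <- rbind(cgMix = bimodal, cgFlat = unimodal)
    b <- pmin(pmax(b, 0), 1)
    colnames(b) <- sprintf("s%03d", 1:n)
    bm <- makeBetaMatrix(b)
    region <- GenomicRanges::GRanges("chr5",
        IRanges::IRanges(135415000, 135416000))
    rep <- detectBimodalCpgs(bm, region, B = 200)
    expect_true(rep["cgMix", "bimodal"])
    expect_equal(rep["cgMix", "separation"], 0.40, tolerance = 0.04)
    expect_false(rep["cgFlat", "bimodal"])
    ## empty-overlap region
    far <- GenomicRanges::GRanges("chr5", IRanges::IRanges(1, 100))
    expect_warning(out <- detectBimodalCpgs(bm, far, B = 50),
                   "no annotated CpG")
    expect_identical(nrow(out), 0L)
    ## too few samples
    expect_error(detectBimodalCpgs(bm[, 1:10], region), ">= 30 samples")
})

test_that("status calling labels exact prototypes and applies the full rule", {
    b <- cbind(s_non = rep(0.10, 5), s_int = rep(0.35, 5),
               s_hemi = rep(0.50, 5), s_full = rep(0.70, 5))
    rownames(b) <- sprintf("cg%03d", 1:5)
    bm <- makeBetaMatrix(b)
    calls <- callStatus(bm, rownames(b), k = 3)
    st <- sampleStatus(calls)
    expect_identical(as.character(st[c("s_non", "s_int", "s_hemi", "s_full")]),
                     c("non", "intermediate", "hemi", "full"))
    ## the fully methylated sample never enters clustering
    expect_true(is.na(statusCalls(calls)["s_full", "cluster"]))
    ## boundary: median exactly at the threshold is NOT full (strict >)
    b2 <- cbind(s_a = rep(0.60, 5), s_b = rep(0.10, 5), s_c = rep(0.35, 5),
                s_d = rep(0.50, 5))
    rownames(b2) <- sprintf("cg%03d", 1:5)
    st2 <- sampleStatus(callStatus(makeBetaMatrix(b2), rownames(b2)))
    expect_false(as.character(st2["s_a"]) == "full")
})

test_that("status calling recovers simulated truth and orders group medians", {
    coh <- simulateCohort(cohortConfig(n_samples = 600, seed = 25,
                                       n_timepoints = 1))
    bm <- betaMatrices(coh)[[1]]
    calls <- callStatus(bm, sprintf("cgB%02d", 1:14))
    truth <- trueStatus(coh)[rownames(statusCalls(calls))]
    expect_gte(mean(as.character(sampleStatus(calls)) ==
                    as.character(truth)), 0.95)
    gm <- tapply(medianBeta(calls), sampleStatus(calls), median)
    gm <- gm[!is.na(gm)]
    expect_true(all(diff(gm) > 0))
    ## permutation invariance: shuffling sample order changes no call
    perm <- sample(ncol(bm))
    calls_p <- callStatus(bm[, perm], sprintf("cgB%02d", 1:14))
    expect_identical(
        as.character(sampleStatus(calls_p)[names(sampleStatus(calls))]),
        as.character(sampleStatus(calls)))
})

test_that("clustering matches the exhaustive minimum-diameter partition", {
    ## on well-separated data the complete-linkage cut is the unique
    ## minimum-diameter 3-partition
    set.seed(26)
    for (i in 1:5) {
        st <- sample(c("non", "intermediate", "hemi"), 8, replace = TRUE)
        while (length(unique(st)) < 3)
            st <- sample(c("non", "intermediate", "hemi"), 8, replace = TRUE)
        bm <- simulateBetaMatrix(st, seed = 100 + i)
        b <- betaValues(bm)[sprintf("cgB%02d", 1:14), ]
        calls <- callStatus(bm, sprintf("cgB%02d", 1:14))
        oracle <- minDiameterPartition(dist(t(b)), k = 3)$assignment
        got <- as.integer(factor(as.character(sampleStatus(calls))))
        ## same partition up to label names
        expect_equal(length(unique(paste(oracle, got))),
                     length(unique(oracle)))
    }
})

test_that("recovery accuracy does not increase with noise", {
    cp <- sprintf("cgB%02d", 1:14)
    acc <- vapply(c(0.01, 0.05, 0.12), function(sdv) {
        coh <- simulateCohort(cohortConfig(
            n_samples = 300, seed = 77, beta_sd = sdv, n_timepoints = 1))
        calls <- callStatus(betaMatrices(coh)[[1]], cp)
        truth <- trueStatus(coh)[rownames(statusCalls(calls))]
        mean(as.character(sampleStatus(calls)) == as.character(truth))
    }, numeric(1))
    expect_true(all(diff(acc) <= 0.005 + 1e-9))
})

test_that("missing-beta policy imputes moderately missing samples", {
    set.seed(27)
    coh <- simulateCohort(cohortConfig(n_samples = 50, seed = 28,
                                       n_timepoints = 1))
    b <- betaValues(betaMatrices(coh)[[1]])
    b["cgB01", 1:3] <- NA            # light missingness: imputed
    b[sprintf("cgB%02d", 1:10), 4] <- NA   # heavy: dropped
    bm <- makeBetaMatrix(b, bimodal = grepl("^cgB", rownames(b)))
    expect_warning(calls <- callStatus(bm, sprintf("cgB%02d", 1:14)),
                   "dropped")
    expect_false(colnames(b)[4] %in% rownames(statusCalls(calls)))
    expect_true(all(colnames(b)[1:3] %in% rownames(statusCalls(calls))))
})

test_that("stability report handles identity, flips and null calls", {
    coh <- simulateCohort(cohortConfig(n_samples = 100, seed = 29,
                                       n_timepoints = 1))
    calls <- callStatus(betaMatrices(coh)[[1]], sprintf("cgB%02d", 1:14))
    ## identity
    rep0 <- assessStability(calls, calls)
    expect_equal(rep0@rho, 1)
    expect_equal(concordance(rep0), 1)
    expect_length(discordantSamples(rep0), 0)
    ## one constructed flip in 100
    df <- statusCalls(calls)
    flip_id <- rownames(df)[which(df$status == "non")[1]]
    df$status[rownames(df) == flip_id] <-
        factor("hemi", levels = statusLevels())
    calls2 <- epistatus:::.StatusCalls(df, calls@cpgIds, 0.60, 3L)
    rep1 <- assessStability(calls, calls2)
    expect_equal(concordance(rep1), 0.99)
    expect_identical(discordantSamples(rep1), flip_id)
    ## independent random call sets: negligible correlation
    set.seed(30)
    mk <- function() {
        st <- sample(c("non", "hemi"), 200, replace = TRUE)
        names(st) <- sprintf("s%03d", 1:200)
        makeCalls(st, median_beta = runif(200))
    }
    repn <- assessStability(mk(), mk())
    expect_lt(abs(repn@rho), 0.2)
    expect_gt(repn@pValue, 0.05)
    ## empty intersection rejected
    stA <- c(sA = "non")
    stB <- c(sB = "hemi")
    expect_error(assessStability(makeCalls(stA), makeCalls(stB)),
                 "no overlapping")
})
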