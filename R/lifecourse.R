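#' @include AllClasses.R
NULL

.defaultWindows <- function()
    list(c(6, 12), c(6, 18), c(12, 18), c(18, 24), c(6, 24))

#' Age-window AUC of repeated trait measurements
#'
#' Integrates the piecewise-linear age-value curve of one sample's repeated
#' measurements over an age window by the trapezoidal rule, interpolating
#' linearly at the window boundaries.  Measurements outside the window are
#' used only to anchor the boundary interpolation, and only when they lie
#' within \code{boundary_tol} years of the boundary; otherwise the window
#' is truncated to the observed span and the AUC is rescaled from the
#' time-averaged level.  The yearly estimate is AUC divided by the window
#' width, i.e. the time-averaged trait level in the trait's own units.
#'
#' The estimate is missing (with a reason code) when fewer than 2 distinct
#' ages are usable or when the usable measurements span less than
#' \code{coverage_min_frac} of the window.
#'
#' @param ages,values numeric vectors of measurement ages (years) and trait
#'   values; duplicate ages are averaged.
#' @param window numeric length-2 (start age, end age).
#' @param boundary_tol years beyond the boundary within which an outside
#'   point may anchor interpolation.
#' @param coverage_min_frac minimum fraction of the window that must be
#'   covered by usable measurements.
#' @return A one-row \code{data.frame}: \code{start}, \code{end},
#'   \code{auc}, \code{yearly}, \code{n_points}, \code{reason}
#'   (\code{NA} when the estimate is valid).
#' @export
#' @examples
#' traitAuc(c(6, 9, 12), c(5, 5, 5), c(6, 12))   # AUC 30, yearly 5
#' traitAuc(c(6, 12), c(6, 12), c(6, 12))        # AUC 54, yearly 9
traitAuc <- function(ages, values, window, boundary_tol = 3,
                     coverage_min_frac = 0.5) {
    stopifnot(length(window) == 2, window[2] > window[1])
    ok <- !is.na(ages) & !is.na(values)
    ages <- ages[ok]
    values <- values[ok]
    if (anyDuplicated(ages)) {
        values <- as.numeric(tapply(values, ages, mean))
        ages <- sort(unique(ages))
    }
    o <- order(ages)
    ages <- ages[o]
    values <- values[o]
    miss <- function(reason, npt = length(ages))
        data.frame(start = window[1], end = window[2], auc = NA_real_,
                   yearly = NA_real_, n_points = npt, reason = reason,
                   stringsAsFactors = FALSE)
    if (length(ages) < 2) return(miss("insufficient_points"))

    inside <- ages >= window[1] & ages <= window[2]
    ## nearest outside anchors, admissible within boundary_tol
    left_anchor <- which(ages < window[1] & ages >= window[1] - boundary_tol)
    right_anchor <- which(ages > window[2] & ages <= window[2] + boundary_tol)
    use <- which(inside)
    if (length(left_anchor)) use <- c(max(left_anchor), use)
    if (length(right_anchor)) use <- c(use, min(right_anchor))
    if (length(use) < 2) return(miss("insufficient_points"))
    a <- ages[use]
    v <- values[use]

    ## effective integration bounds: full window if anchored/covered on that
    ## side, otherwise truncate to the observed span
    lo_eff <- max(window[1], min(a))
    hi_eff <- min(window[2], max(a))
    if (hi_eff <= lo_eff) return(miss("coverage"))
    if ((hi_eff - lo_eff) < coverage_min_frac * (window[2] - window[1]))
        return(miss("coverage"))

    grid <- sort(unique(c(lo_eff, hi_eff, a[a > lo_eff & a < hi_eff])))
    y <- stats::approx(a, v, xout = grid)$y
    auc_eff <- sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    yearly <- auc_eff / (hi_eff - lo_eff)
    data.frame(start = window[1], end = window[2],
               auc = yearly * (window[2] - window[1]), yearly = yearly,
               n_points = length(use), reason = NA_character_,
               stringsAsFactors = FALSE)
}

#' Age-window estimates for a whole trait panel
#'
#' Applies \code{\link{traitAuc}} to every (sample, trait, window)
#' combination.  Traits flagged \code{log_transform} in the panel metadata
#' are log-transformed before integration (their estimates are on the log
#' scale).
#'
#' @param panel A \linkS4class{TraitPanel}.
#' @param windows list of length-2 numeric windows; defaults to ages 6-12,
#'   6-18, 12-18, 18-24 and 6-24.
#' @param boundary_tol,coverage_min_frac see \code{\link{traitAuc}}.
#' @return A \code{DataFrame} with columns \code{sample}, \code{trait},
#'   \code{window}, \code{start}, \code{end}, \code{auc}, \code{yearly},
#'   \code{n_points}, \code{reason}.
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 20, seed = 4))
#' est <- estimateByAge(cohortTraits(coh))
#' head(est)
estimateByAge <- function(panel, windows = .defaultWindows(),
                          boundary_tol = 3, coverage_min_frac = 0.5) {
    stopifnot(is(panel, "TraitPanel"))
    rec <- as.data.frame(traitRecords(panel))
    info <- as.data.frame(traitInfo(panel))
    logt <- stats::setNames(info$log_transform, info$trait)
    out <- list()
    for (tr in unique(rec$trait)) {
        sub <- rec[rec$trait == tr, ]
        vals <- if (isTRUE(logt[[tr]])) log(sub$value) else sub$value
        by_sample <- split(seq_len(nrow(sub)), sub$sample)
        for (sm in names(by_sample)) {
            ii <- by_sample[[sm]]
            for (w in windows) {
                r <- traitAuc(sub$age[ii], vals[ii], w,
                              boundary_tol = boundary_tol,
                              coverage_min_frac = coverage_min_frac)
                out[[length(out) + 1L]] <- cbind(
                    data.frame(sample = sm, trait = tr,
                               window = sprintf("%g-%g", w[1], w[2]),
                               stringsAsFactors = FALSE), r)
            }
        }
    }
    as(do.call(rbind, out), "DataFrame")
}

#' Associate epiallele status with lifecourse trait estimates
#'
#' For each (trait, window), regresses the standardized yearly estimate on
#' the status indicator (non-methylated = 1, hemi-methylated = 0) plus
#' covariates, reporting the effect in SD units with a Wald 95\% confidence
#' interval.  Intermediately and fully methylated samples are excluded.
#' Optionally repeated within sex strata.
#'
#' @param estimates output of \code{\link{estimateByAge}} (rows with
#'   missing \code{yearly} are ignored).
#' @param calls A \linkS4class{StatusCalls}.
#' @param covariates optional data.frame (rownames = sample ids).  A
#'   \code{sex} column is used both for adjustment (when unstratified) and
#'   for stratification; additional numeric columns are adjusted for.
#' @param stratify_by_sex repeat the analysis within men and women.
#' @param min_group_n minimum samples per status group.
#' @return A \code{DataFrame} with columns \code{trait}, \code{window},
#'   \code{stratum}, \code{n_non}, \code{n_hemi}, \code{beta},
#'   \code{ci_lo}, \code{ci_hi}, \code{p}, \code{reason}.
#' @export
associateStatusTraits <- function(estimates, calls, covariates = NULL,
                                  stratify_by_sex = FALSE, min_group_n = 10) {
    stopifnot(is(calls, "StatusCalls"))
    est <- as.data.frame(estimates)
    st <- sampleStatus(calls)
    keep_status <- st[st %in% c("non", "hemi")]
    strata <- list(all = names(keep_status))
    if (stratify_by_sex) {
        if (is.null(covariates) || !"sex" %in% colnames(covariates))
            stop("sex stratification requires a 'sex' covariate column")
        sx <- stats::setNames(as.character(covariates$sex),
                              rownames(covariates))
        strata$men <- names(keep_status)[sx[names(keep_status)] == "male"]
        strata$women <- names(keep_status)[sx[names(keep_status)] == "female"]
    }
    adj <- NULL
    if (!is.null(covariates)) {
        num <- vapply(as.data.frame(covariates), is.numeric, logical(1))
        adj_df <- as.data.frame(covariates)[, num, drop = FALSE]
        if ("sex" %in% colnames(covariates))
            adj_df$sex_male <-
                as.numeric(as.character(covariates$sex) == "male")
        if (ncol(adj_df)) adj <- adj_df
    }
    rows <- list()
    for (tr in unique(est$trait)) for (w in unique(est$window)) {
        sub <- est[est$trait == tr & est$window == w & !is.na(est$yearly), ]
        for (sname in names(strata)) {
            ids <- intersect(sub$sample, strata[[sname]])
            y <- stats::setNames(sub$yearly, sub$sample)[ids]
            g <- as.numeric(st[ids] == "non")
            n_non <- sum(g == 1)
            n_hemi <- sum(g == 0)
            fail <- function(reason)
                DataFrame(trait = tr, window = w, stratum = sname,
                          n_non = n_non, n_hemi = n_hemi, beta = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                          reason = reason)
            if (n_non < min_group_n || n_hemi < min_group_n) {
                rows[[length(rows) + 1L]] <- fail("group_too_small")
                next
            }
            if (stats::sd(y) == 0) {
                rows[[length(rows) + 1L]] <- fail("degenerate_outcome")
                next
            }
            z <- (y - mean(y)) / stats::sd(y)
            dat <- data.frame(z = z, status = g)
            if (!is.null(adj)) {
                extra <- adj[ids, , drop = FALSE]
                if (sname %in% c("men", "women"))
                    extra$sex_male <- NULL
                ## drop constant adjustment columns within the stratum
                extra <- extra[, vapply(extra, function(cl)
                    length(unique(cl[!is.na(cl)])) > 1, logical(1)),
                    drop = FALSE]
                if (ncol(extra)) dat <- cbind(dat, extra)
            }
            fit <- stats::lm(z ~ ., data = dat)
            sm <- summary(fit)$coefficients
            if (!"status" %in% rownames(sm)) {
                rows[[length(rows) + 1L]] <- fail("collinear_model")
                next
            }
            bhat <- sm["status", "Estimate"]
            se <- sm["status", "Std. Error"]
            tcrit <- stats::qt(0.975, fit$df.residual)
            rows[[length(rows) + 1L]] <-
                DataFrame(trait = tr, window = w, stratum = sname,
                          n_non = n_non, n_hemi = n_hemi, beta = bhat,
                          ci_lo = bhat - tcrit * se,
                          ci_hi = bhat + tcrit * se,
                          p = sm["status", "Pr(>|t|)"],
                          reason = NA_character_)
        }
    }
    do.call(rbind, rows)
}

#' Chi-squared tests of a categorical factor against status
#'
#' Cross-tabulates epiallele status (non- vs hemi-methylated; intermediate
#' and full samples are excluded) against a categorical early-life factor
#' and tests independence with the uncorrected chi-squared statistic:
#' overall over all factor levels, and pairwise between every pair of
#' levels (2x2 tables).
#'
#' @param calls A \linkS4class{StatusCalls}.
#' @param factor_values named character/factor of per-sample categories
#'   (e.g. maternal age group).
#' @param correct apply Yates continuity correction (default FALSE, the
#'   classic statistic).
#' @return A list of class \code{"CategoricalAssociation"}: \code{counts}
#'   (levels x status table), \code{overall} (statistic, df, p),
#'   \code{pairwise} \code{DataFrame} (level_a, level_b, statistic, p,
#'   expected_ok), \code{excluded} (number of intermediate/full samples
#'   dropped).
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 400, seed = 9))
#' cpgs <- grep("^cgB", rownames(betaMatrices(coh)[[1]]), value = TRUE)
#' calls <- callStatus(betaMatrices(coh)[[1]], cpgs)
#' fac <- setNames(cohortCovariates(coh)$maternal_age_group,
#'                 rownames(cohortCovariates(coh)))
#' testCategoricalAssociation(calls, fac)
testCategoricalAssociation <- function(calls, factor_values,
                                       correct = FALSE) {
    stopifnot(is(calls, "StatusCalls"))
    st <- sampleStatus(calls)
    if (is.null(names(factor_values)))
        stop("'factor_values' must be named by sample id")
    ids <- intersect(names(st), names(factor_values))
    st <- st[ids]
    fv <- as.character(factor_values[ids])
    keep <- st %in% c("non", "hemi") & !is.na(fv)
    excluded <- sum(!keep)
    st <- droplevels(st[keep])
    fv <- factor(fv[keep])
    if (nlevels(fv) < 2)
        stop("factor must have >= 2 observed levels, got ", nlevels(fv))
    counts <- table(level = fv, status = st)
    ov <- suppressWarnings(stats::chisq.test(counts, correct = correct))
    lv <- levels(fv)
    pairs <- utils::combn(lv, 2)
    pw <- lapply(seq_len(ncol(pairs)), function(i) {
        tab <- counts[pairs[, i], , drop = FALSE]
        ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
        DataFrame(level_a = pairs[1, i], level_b = pairs[2, i],
                  statistic = unname(ct$statistic), p = ct$p.value,
                  expected_ok = all(ct$expected >= 5))
    })
    structure(list(counts = counts,
                   overall = list(statistic = unname(ov$statistic),
                                  df = unname(ov$parameter),
                                  p = ov$p.value,
                                  expected_ok = all(ov$expected >= 5)),
                   pairwise = do.call(rbind, pw),
                   excluded = excluded),
              class = "CategoricalAssociation")
}

#' @export
print.CategoricalAssociation <- function(x, ...) {
    cat("CategoricalAssociation (non vs hemi;", x$excluded,
        "samples excluded)\n")
    print(x$counts)
    cat(sprintf("overall chi-squared = %.3f (df = %d, p = %.3g)%s\n",
                x$overall$statistic, x$overall$df, x$overall$p,
                if (!x$overall$expected_ok) " [low expected counts]" else ""))
    cat("pairwise:\n")
    print(as.data.frame(x$pairwise))
    invisible(x)
}
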