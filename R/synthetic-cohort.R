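#' @include AllClasses.R
NULL

## Default CpG panel emulating the nc886 DMR neighbourhood on 5q31.1:
## 14 bimodal CpGs within ~2 kb around the coding region plus flanking
## non-bimodal CpGs outside it.  Positions are synthetic but placed at
## hg19-like coordinates so range operations behave realistically.
.defaultCpgPanel <- function(n_bimodal = 14L, n_flanking = 6L) {
    bim_pos <- as.integer(seq(135415200L, 135416800L, length.out = n_bimodal))
    fl_pos <- as.integer(seq(135410500L, 135413500L,
                             length.out = max(n_flanking, 1L)))[seq_len(n_flanking)]
    data.frame(
        cpg = c(sprintf("cgB%02d", seq_len(n_bimodal)),
                sprintf("cgF%02d", seq_len(n_flanking))),
        chromosome = "chr5",
        position = c(bim_pos, fl_pos),
        in_dmr = rep(c(TRUE, FALSE), c(n_bimodal, n_flanking)),
        bimodal = rep(c(TRUE, FALSE), c(n_bimodal, n_flanking)),
        stringsAsFactors = FALSE)
}

.defaultTraitParams <- function() {
    list(
        insulin = list(baseline = 4.0, slope = 0.35, curvature = -0.004,
                       sd = 1.2, status_effect = 0.25, sex_effect = -0.30,
                       log_transform = FALSE),
        glucose = list(baseline = 4.6, slope = 0.045, curvature = -5e-4,
                       sd = 0.45, status_effect = -0.20, sex_effect = 0.10,
                       log_transform = FALSE))
}

.defaultCovariateAssoc <- function() {
    ## multiplicative tilts on the weight of the non-methylated state per
    ## covariate stratum; chosen to give roughly 10-percentage-point
    ## prevalence differences between extreme strata
    list(
        maternal_age_group = c("<=20" = 1.5, "21-35" = 0.85, ">=36" = 1.5),
        income_quartile = c(I = 1.10, II = 1.05, III = 0.70),
        occupation_class = c(I = 0.70, II = 1.00, III = 1.05, IV = 1.10,
                             F = 1.05),
        education_class = c(I = 1.0, II = 1.0, III = 1.0))
}

.covariateFreqs <- function() {
    list(
        maternal_age_group = c("<=20" = 0.12, "21-35" = 0.80, ">=36" = 0.08),
        income_quartile = c(I = 0.25, II = 0.50, III = 0.25),
        occupation_class = c(I = 0.15, II = 0.25, III = 0.25, IV = 0.25,
                             F = 0.10),
        education_class = c(I = 0.30, II = 0.45, III = 0.25))
}

#' Configuration for a synthetic epiallele cohort
#'
#' Builds the parameter list consumed by \code{\link{simulateCohort}}.  The
#' defaults encode the population structure the analysis targets: a mostly
#' binomial epiallele (hemi-methylated in ~75\% of individuals,
#' non-methylated in ~25\%), a small intermediately methylated group (1-6\%)
#' and rare fully methylated individuals; 14 bimodal CpGs with state medians
#' ~0.10 / ~0.35 / ~0.50 / >0.60; status-dependent RNA fold changes around
#' 1.6-2.1; quadratic age trajectories for metabolic traits with status
#' effects in SD units; and early-life covariate strata tilted towards the
#' non-methylated state.
#'
#' @param n_samples number of individuals.
#' @param n_timepoints number of methylation time points (>= 1).
#' @param status_weights named probabilities over
#'   \code{\link{statusLevels}}; must sum to 1 (tolerance 1e-9).
#' @param bimodal_cpg_count,flanking_cpg_count CpG panel sizes.
#' @param beta_means named mean beta per state.  The intermediate state is
#'   generated as a per-CpG mixture of hemi-like and non-like cell fractions
#'   whose mean equals \code{beta_means["intermediate"]}.
#' @param beta_sd per-CpG measurement noise (truncated to [0, 1] by
#'   clipping), independent across time points.
#' @param sample_level_sd SD of the stable per-individual methylation level
#'   (an offset shared by all bimodal CpGs and all time points).  This is
#'   what makes the per-sample median beta reproducible across decades
#'   within a status group, as longitudinal cohorts show.
#' @param intermediate_profile_sd SD of the per-CpG hemi-like cell fraction
#'   in the intermediate state; this creates the larger between-probe
#'   variance that distinguishes the intermediate group.
#' @param flanking_mean mean beta of the non-bimodal flanking CpGs
#'   (status-independent).
#' @param rna_fold_changes named fold change of the non- vs hemi-methylated
#'   group median per RNA; all > 0.
#' @param rna_cv lognormal coefficient of variation of RNA abundance.
#' @param trait_trajectory_params per-trait list of \code{baseline},
#'   \code{slope}, \code{curvature} (quadratic in age), \code{sd} (residual
#'   SD), \code{status_effect} (SD units, non vs hemi), \code{sex_effect}
#'   (SD units, male vs female), \code{log_transform}.
#' @param measurement_age_offsets years after the baseline examination at
#'   which traits are re-measured (default: a childhood-cohort follow-up
#'   schedule with frequent early examinations).
#' @param covariate_assoc multiplicative tilts of the non-methylated weight
#'   per covariate stratum (see defaults).
#' @param switch_rate probability per later time point that a sample's
#'   status is re-drawn (0 = fully stable epiallele).
#' @param seed default integer seed used by \code{\link{simulateCohort}}.
#' @return A list of class \code{"CohortConfig"}.
#' @export
#' @examples
#' cfg <- cohortConfig(n_samples = 100)
#' cfg$status_weights
cohortConfig <- function(n_samples = 1000L,
                         n_timepoints = 2L,
                         status_weights = c(non = 0.24, intermediate = 0.04,
                                            hemi = 0.715, full = 0.005),
                         bimodal_cpg_count = 14L,
                         flanking_cpg_count = 6L,
                         beta_means = c(non = 0.10, intermediate = 0.35,
                                        hemi = 0.50, full = 0.70),
                         beta_sd = 0.008,
                         sample_level_sd = 0.015,
                         intermediate_profile_sd = 0.08,
                         flanking_mean = 0.80,
                         rna_fold_changes = c("nc886-3p" = 1.62,
                                              "nc886-5p" = 2.03,
                                              "nc886-102nt" = 2.07),
                         rna_cv = 0.5,
                         trait_trajectory_params = .defaultTraitParams(),
                         measurement_age_offsets = c(0, 3, 6, 9, 12, 21,
                                                     27, 31),
                         covariate_assoc = .defaultCovariateAssoc(),
                         switch_rate = 0,
                         seed = 1L) {
    if (n_samples <= 0 || n_timepoints < 1 || bimodal_cpg_count <= 0 ||
        flanking_cpg_count < 0)
        stop("counts must be positive (flanking_cpg_count may be 0)")
    lv <- statusLevels()
    if (!all(names(status_weights) %in% lv))
        stop("status_weights must be named by ", paste(lv, collapse = "/"))
    w <- stats::setNames(numeric(4), lv)
    w[names(status_weights)] <- status_weights
    if (abs(sum(w) - 1) > 1e-9)
        stop("status_weights must sum to 1 (tolerance 1e-9)")
    if (any(w < 0)) stop("status_weights must be non-negative")
    if (!all(lv %in% names(beta_means)))
        stop("beta_means must name all four states")
    if (any(beta_means <= 0 | beta_means >= 1))
        stop("beta means must lie in (0, 1)")
    if (any(rna_fold_changes <= 0)) stop("fold changes must be > 0")
    structure(list(
        n_samples = as.integer(n_samples),
        n_timepoints = as.integer(n_timepoints),
        status_weights = w,
        bimodal_cpg_count = as.integer(bimodal_cpg_count),
        flanking_cpg_count = as.integer(flanking_cpg_count),
        beta_means = beta_means[lv],
        beta_sd = beta_sd,
        sample_level_sd = sample_level_sd,
        intermediate_profile_sd = intermediate_profile_sd,
        flanking_mean = flanking_mean,
        rna_fold_changes = rna_fold_changes,
        rna_cv = rna_cv,
        trait_trajectory_params = trait_trajectory_params,
        measurement_age_offsets = measurement_age_offsets,
        covariate_assoc = covariate_assoc,
        switch_rate = switch_rate,
        seed = as.integer(seed)), class = "CohortConfig")
}

#' Simulate a beta-value matrix for given statuses
#'
#' Draws per-CpG beta values for samples with known epiallele status.
#' Bimodal CpGs are drawn around the state mean (the intermediate state as a
#' per-CpG mixture of hemi-like and non-like cell fractions, giving it
#' larger between-probe spread); flanking CpGs are drawn from a unimodal
#' distribution independent of status.  All values are clipped to [0, 1].
#'
#' @param statuses character or factor of per-sample statuses (values from
#'   \code{\link{statusLevels}}); names (if any) become sample ids.
#' @param panel CpG annotation data.frame with columns \code{cpg},
#'   \code{chromosome}, \code{position}, \code{in_dmr}, \code{bimodal};
#'   defaults to the built-in nc886-like panel.
#' @param params list with \code{beta_means}, \code{beta_sd},
#'   \code{sample_level_sd}, \code{intermediate_profile_sd},
#'   \code{flanking_mean} (defaults from \code{\link{cohortConfig}}).
#' @param seed integer seed.
#' @param sample_offsets optional per-sample stable level offsets added to
#'   the bimodal-CpG means; drawn from
#'   \code{N(0, params$sample_level_sd)} when \code{NULL}.  Pass the same
#'   vector for several time points to make individual levels longitudinally
#'   stable.
#' @param profile_seed seed for the per-sample intermediate-state probe
#'   profiles (the hemi-like cell fraction per CpG).  These mixtures are
#'   established once in early development and are mitotically stable, so
#'   time points of one cohort share this seed.
#' @return A \linkS4class{BetaMatrix}.
#' @export
#' @examples
#' bm <- simulateBetaMatrix(rep(c("non", "hemi"), each = 5), seed = 1)
#' dim(betaValues(bm))
simulateBetaMatrix <- function(statuses, panel = .defaultCpgPanel(),
                               params = cohortConfig(n_samples = 1L),
                               seed = 1L, sample_offsets = NULL,
                               profile_seed = seed) {
    statuses <- as.character(statuses)
    bad <- setdiff(unique(statuses), statusLevels())
    if (length(bad))
        stop("unknown status label(s): ", paste(bad, collapse = ", "))
    n <- length(statuses)
    ids <- names(statuses)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
    mu <- params$beta_means
    sdv <- params$beta_sd
    nb <- sum(panel$bimodal)
    nf <- sum(!panel$bimodal)

    ## stable developmental quantities: the per-CpG hemi-like cell fraction
    ## of every sample (used only where the status is intermediate) is
    ## established once and shared across time points via profile_seed
    set.seed(as.integer(profile_seed))
    f0 <- (mu["intermediate"] - mu["non"]) / (mu["hemi"] - mu["non"])
    fr_all <- matrix(stats::rnorm(nb * n, f0,
                                  params$intermediate_profile_sd),
                     nrow = nb)
    fr_all <- pmin(pmax(fr_all, 0), 1)

    set.seed(as.integer(seed))
    if (is.null(sample_offsets)) {
        lvl_sd <- if (is.null(params$sample_level_sd)) 0
                  else params$sample_level_sd
        sample_offsets <- stats::rnorm(n, 0, lvl_sd)
    }

    ## mean beta per (bimodal CpG, sample)
    m <- matrix(mu[statuses], nrow = nb, ncol = n, byrow = TRUE)
    inter <- statuses == "intermediate"
    if (any(inter)) {
        fr <- fr_all[, inter, drop = FALSE]
        m[, inter] <- fr * mu["hemi"] + (1 - fr) * mu["non"]
    }
    m <- sweep(m, 2L, sample_offsets, "+")
    bimodal_vals <- m + matrix(stats::rnorm(nb * n, 0, sdv), nrow = nb)
    flank_vals <- matrix(stats::rnorm(nf * n, params$flanking_mean, sdv),
                         nrow = nf)
    beta <- rbind(bimodal_vals, flank_vals)[order(c(which(panel$bimodal),
                                                    which(!panel$bimodal))), ,
                                            drop = FALSE]
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(panel$cpg, ids)
    BetaMatrix(beta, panel[, c("chromosome", "position", "in_dmr", "bimodal")])
}

## status-specific multiplier on RNA abundance relative to the
## hemi-methylated reference: the non-methylated state has two active
## alleles (factor = configured fold change), intermediate is geometrically
## halfway, full methylation silences the remaining allele
.rnaStatusMultiplier <- function(fc, statuses) {
    mult <- c(non = fc, intermediate = sqrt(fc), hemi = 1, full = 1 / fc)
    mult[statuses]
}

.simulateExpression <- function(statuses, ids, cfg) {
    rnas <- names(cfg$rna_fold_changes)
    sigma <- sqrt(log(1 + cfg$rna_cv^2))
    vals <- t(vapply(rnas, function(r) {
        base <- .rnaStatusMultiplier(cfg$rna_fold_changes[[r]], statuses)
        base * exp(stats::rnorm(length(statuses), 0, sigma))
    }, numeric(length(statuses))))
    dimnames(vals) <- list(rnas, ids)
    ExpressionTable(vals, value_kind = "abundance")
}

.simulateTraits <- function(statuses, ids, sex, cfg, base_age) {
    n <- length(ids)
    status_mult <- c(non = 1, intermediate = 0.5, hemi = 0, full = 0)[statuses]
    male <- as.numeric(sex == "male")
    rows <- list()
    for (tr in names(cfg$trait_trajectory_params)) {
        p <- cfg$trait_trajectory_params[[tr]]
        for (off in cfg$measurement_age_offsets) {
            age <- base_age + off
            val <- p$baseline + p$slope * age + p$curvature * age^2 +
                (status_mult * p$status_effect + male * p$sex_effect) * p$sd +
                stats::rnorm(n, 0, p$sd)
            rows[[length(rows) + 1L]] <-
                data.frame(sample = ids, trait = tr, age = age, value = val,
                           stringsAsFactors = FALSE)
        }
    }
    rec <- do.call(rbind, rows)
    info <- data.frame(
        trait = names(cfg$trait_trajectory_params),
        units = NA_character_,
        log_transform = vapply(cfg$trait_trajectory_params,
                               function(p) isTRUE(p$log_transform),
                               logical(1)),
        stringsAsFactors = FALSE)
    TraitPanel(rec, info)
}

#' Simulate a complete synthetic cohort
#'
#' Generates a cohort with the full joint structure the downstream analyses
#' assume: per-sample epiallele status drawn from configurable prevalences
#' (tilted by early-life covariate strata), bimodal-CpG beta matrices at one
#' or more time points (statuses constant across time points unless
#' \code{switch_rate > 0}), status-dependent lognormal RNA abundances, and
#' quadratic age-trajectory traits with additive status effects.
#' Deterministic given \code{seed}: all substreams are derived from the one
#' integer seed.
#'
#' @param config a \code{\link{cohortConfig}} list.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return A \linkS4class{SyntheticCohort}.
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 50, seed = 7))
#' table(trueStatus(coh))
simulateCohort <- function(config = cohortConfig(), seed = config$seed) {
    stopifnot(inherits(config, "CohortConfig"))
    cfg <- config
    seed <- as.integer(seed)
    set.seed(seed)
    n <- cfg$n_samples
    ids <- sprintf("S%04d", seq_len(n))

    ## covariates first; status weights are tilted per stratum
    freqs <- .covariateFreqs()
    cov <- data.frame(row.names = ids)
    cov$sex <- sample(c("female", "male"), n, replace = TRUE)
    ## age at the baseline examination (3-18, as in a childhood-recruited
    ## cohort); carried as a numeric covariate because it determines which
    ## age windows a sample's measurements can cover
    cov$baseline_age <- sample(3:18, n, replace = TRUE)
    for (f in names(freqs))
        cov[[f]] <- sample(names(freqs[[f]]), n, replace = TRUE,
                           prob = freqs[[f]])

    w <- matrix(cfg$status_weights, nrow = n, ncol = 4, byrow = TRUE,
                dimnames = list(ids, statusLevels()))
    for (f in names(cfg$covariate_assoc)) {
        tilt <- cfg$covariate_assoc[[f]][cov[[f]]]
        tilt[is.na(tilt)] <- 1
        w[, "non"] <- w[, "non"] * tilt
    }
    w <- w / rowSums(w)
    statuses <- vapply(seq_len(n), function(i)
        sample(statusLevels(), 1L, prob = w[i, ]), character(1))
    names(statuses) <- ids

    ## per-time-point statuses (stable unless switch_rate > 0)
    status_tp <- list(statuses)
    if (cfg$n_timepoints > 1) {
        for (tp in 2:cfg$n_timepoints) {
            st <- status_tp[[tp - 1L]]
            if (cfg$switch_rate > 0) {
                flip <- stats::runif(n) < cfg$switch_rate
                if (any(flip))
                    st[flip] <- vapply(which(flip), function(i)
                        sample(statusLevels(), 1L,
                               prob = cfg$status_weights), character(1))
            }
            status_tp[[tp]] <- st
        }
    }

    panel <- .defaultCpgPanel(cfg$bimodal_cpg_count, cfg$flanking_cpg_count)
    set.seed(seed + 55L)
    offsets <- stats::rnorm(n, 0, cfg$sample_level_sd)
    betas <- lapply(seq_len(cfg$n_timepoints), function(tp)
        simulateBetaMatrix(status_tp[[tp]], panel, cfg,
                           seed = seed + 1000L * tp,
                           sample_offsets = offsets,
                           profile_seed = seed + 31L))
    names(betas) <- sprintf("t%d", seq_len(cfg$n_timepoints))

    set.seed(seed + 77L)
    expr <- lapply(seq_len(cfg$n_timepoints), function(tp)
        .simulateExpression(status_tp[[tp]], ids, cfg))
    names(expr) <- sprintf("blood_t%d", seq_len(cfg$n_timepoints))

    set.seed(seed + 177L)
    traits <- .simulateTraits(statuses, ids, cov$sex, cfg, cov$baseline_age)

    truth <- DataFrame(status = factor(statuses, levels = statusLevels()),
                       row.names = ids)
    new("SyntheticCohort", betaMatrices = betas, expression = expr,
        traits = traits, covariates = as(cov, "DataFrame"), truth = truth,
        config = unclass(cfg))
}
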