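#' @include AllClasses.R
NULL

#' Call epiallele methylation status by hierarchical clustering
#'
#' Classifies samples into epiallele status groups from their beta values
#' over the bimodal CpGs.  Samples whose median beta exceeds
#' \code{full_threshold} are labelled \code{"full"} and never enter the
#' clustering.  The remaining samples are clustered on their bimodal-CpG
#' beta vectors (Euclidean distance, complete linkage, tree cut at
#' \code{k}) and the clusters are labelled \code{non} / \code{intermediate}
#' / \code{hemi} (for \code{k = 3}; \code{non} / \code{hemi} for
#' \code{k = 2}) in ascending order of cluster-median beta.
#'
#' Missing betas are imputed with the per-CpG median when a sample has at
#' most 50\% missing values; samples with more are dropped with a warning.
#'
#' @param beta A \linkS4class{BetaMatrix}.
#' @param bimodal_cpg_ids CpG ids to cluster on (>= 2), e.g. the flagged
#'   rows of \code{\link{detectBimodalCpgs}}.
#' @param full_threshold median beta strictly above which a sample is
#'   called fully methylated.
#' @param k number of clusters (2 or 3).
#' @return A \linkS4class{StatusCalls}.
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 120, seed = 5))
#' bm <- betaMatrices(coh)[[1]]
#' calls <- callStatus(bm, grep("^cgB", rownames(bm), value = TRUE))
#' calls
callStatus <- function(beta, bimodal_cpg_ids, full_threshold = 0.60, k = 3) {
    k <- as.integer(k)
    if (!k %in% c(2L, 3L)) stop("'k' must be 2 or 3")
    b <- betaValues(beta)
    missing_ids <- setdiff(bimodal_cpg_ids, rownames(b))
    if (length(missing_ids))
        stop("CpG id(s) not in matrix: ", paste(missing_ids, collapse = ", "))
    if (length(bimodal_cpg_ids) < 2)
        stop("need >= 2 bimodal CpGs to call status")
    b <- b[bimodal_cpg_ids, , drop = FALSE]

    frac_missing <- colMeans(is.na(b))
    drop <- frac_missing > 0.5
    if (any(drop)) {
        warning(sum(drop), " sample(s) dropped (> 50% missing betas)")
        b <- b[, !drop, drop = FALSE]
    }
    if (anyNA(b)) {
        med <- apply(b, 1L, stats::median, na.rm = TRUE)
        for (i in seq_len(nrow(b)))
            b[i, is.na(b[i, ])] <- med[i]
    }

    med_beta <- apply(b, 2L, stats::median)
    probe_sd <- apply(b, 2L, stats::sd)
    status <- rep(NA_character_, ncol(b))
    names(status) <- colnames(b)
    cluster <- rep(NA_integer_, ncol(b))
    names(cluster) <- colnames(b)

    is_full <- med_beta > full_threshold
    status[is_full] <- "full"
    rest <- colnames(b)[!is_full]
    if (length(rest) < k)
        stop("fewer samples (", length(rest),
             ") than clusters (k = ", k, ") after full-methylation exclusion")

    hc <- stats::hclust(stats::dist(t(b[, rest, drop = FALSE])),
                        method = "complete")
    cl <- stats::cutree(hc, k = k)
    cl_med <- tapply(med_beta[rest], cl, stats::median)
    ord <- order(cl_med)
    labels <- if (k == 3L) c("non", "intermediate", "hemi") else c("non", "hemi")
    relabel <- stats::setNames(labels, names(cl_med)[ord])
    status[rest] <- relabel[as.character(cl)]
    cluster[rest] <- match(as.character(cl), names(cl_med)[ord])

    calls <- DataFrame(
        status = factor(status, levels = statusLevels()),
        median_beta = med_beta, cluster = cluster, probe_sd = probe_sd,
        row.names = colnames(b))
    .StatusCalls(calls, bimodal_cpg_ids, full_threshold, k)
}

#' Assess longitudinal stability of status calls
#'
#' Compares status calls from two time points over their overlapping
#' samples: Spearman correlation of the per-sample median betas, the
#' fraction of samples with an identical status (concordance) and the list
#' of discordant samples (candidates for exclusion from downstream
#' analyses, mirroring the handling of status-switching individuals).
#'
#' @param calls_t1,calls_t2 \linkS4class{StatusCalls} from two time points.
#' @return A \linkS4class{StabilityReport}.
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 120, seed = 5))
#' cpgs <- grep("^cgB", rownames(betaMatrices(coh)[[1]]), value = TRUE)
#' c1 <- callStatus(betaMatrices(coh)[[1]], cpgs)
#' c2 <- callStatus(betaMatrices(coh)[[2]], cpgs)
#' assessStability(c1, c2)
assessStability <- function(calls_t1, calls_t2) {
    stopifnot(is(calls_t1, "StatusCalls"), is(calls_t2, "StatusCalls"))
    ids <- intersect(rownames(statusCalls(calls_t1)),
                     rownames(statusCalls(calls_t2)))
    if (!length(ids))
        stop("no overlapping samples between the two call sets")
    m1 <- medianBeta(calls_t1)[ids]
    m2 <- medianBeta(calls_t2)[ids]
    s1 <- sampleStatus(calls_t1)[ids]
    s2 <- sampleStatus(calls_t2)[ids]
    ct <- suppressWarnings(
        stats::cor.test(m1, m2, method = "spearman", exact = FALSE))
    conc <- mean(s1 == s2)
    disc <- ids[s1 != s2]
    per <- DataFrame(median_beta_t1 = m1, median_beta_t2 = m2,
                     status_t1 = s1, status_t2 = s2,
                     discordant = s1 != s2, row.names = ids)
    new("StabilityReport", nOverlap = length(ids),
        rho = unname(ct$estimate), pValue = ct$p.value,
        concordance = conc, discordant = disc, perSample = per)
}
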