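#' @include dip-test.R
#' @importFrom mclust Mclust mclustBIC
NULL

## two-component Gaussian mixture fit for mode locations; returns
## c(mode1, mode2, separation) or NAs when the fit fails
.mixtureModes <- function(x) {
    x <- x[!is.na(x)]
    fit <- tryCatch(
        suppressWarnings(Mclust(x, G = 2, modelNames = "V", verbose = FALSE)),
        error = function(e) NULL)
    if (is.null(fit))
        fit <- tryCatch(
            suppressWarnings(Mclust(x, G = 2, modelNames = "E",
                                    verbose = FALSE)),
            error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_, NA_real_))
    mu <- unname(sort(fit$parameters$mean))
    c(mu[1], mu[2], mu[2] - mu[1])
}

#' Detect bimodally distributed CpGs in a region
#'
#' Tests every CpG inside a genomic region for bimodality of its beta-value
#' distribution.  A CpG is flagged bimodal when (i) the dip test rejects
#' unimodality at \code{alpha} and (ii) the two modes, estimated from a
#' two-component Gaussian mixture, are separated by at least
#' \code{min_separation} beta units.  The separation guard rejects
#' statistically detectable but biologically trivial bimodality.
#'
#' @param beta A \linkS4class{BetaMatrix}.
#' @param region A \code{GRanges} (1-based, closed intervals) with the
#'   region(s) to scan, e.g. from \code{\link{readRegionBed}}.
#' @param alpha dip-test significance level.
#' @param min_separation minimum mode separation (beta units).
#' @param B Monte-Carlo replicates for the dip null distribution (shared
#'   across CpGs of equal sample size).
#' @return A \code{DataFrame} with one row per tested CpG: \code{cpg},
#'   \code{n}, \code{dip}, \code{dip_p}, \code{mode1}, \code{mode2},
#'   \code{separation}, \code{bimodal}.  Empty (with a warning) when the
#'   region overlaps no CpG; all-missing CpGs are excluded.
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 150, seed = 2))
#' bm <- betaMatrices(coh)[[1]]
#' region <- GenomicRanges::GRanges("chr5",
#'     IRanges::IRanges(135414000, 135417000))
#' rep <- detectBimodalCpgs(bm, region, B = 100)
#' table(rep$bimodal)
detectBimodalCpgs <- function(beta, region, alpha = 0.05,
                              min_separation = 0.2, B = 500) {
    stopifnot(is(region, "GRanges"))
    n_samples <- ncol(beta)
    if (n_samples < 30)
        stop("need >= 30 samples to assess bimodality, got ", n_samples)
    gr <- cpgRanges(beta)
    hits <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr, region)))
    empty <- DataFrame(cpg = character(), n = integer(), dip = numeric(),
                       dip_p = numeric(), mode1 = numeric(),
                       mode2 = numeric(), separation = numeric(),
                       bimodal = logical())
    if (!length(hits)) {
        warning("region overlaps no annotated CpG; returning empty report")
        return(empty)
    }
    b <- betaValues(beta)[hits, , drop = FALSE]
    keep <- rowSums(!is.na(b)) > 0
    b <- b[keep, , drop = FALSE]
    if (!nrow(b)) {
        warning("all CpGs in region are entirely missing")
        return(empty)
    }
    ## share one null distribution per distinct complete-sample count
    ns <- rowSums(!is.na(b))
    nulls <- lapply(unique(ns), dipNullDistribution, B = B)
    names(nulls) <- as.character(unique(ns))
    rows <- lapply(seq_len(nrow(b)), function(i) {
        x <- b[i, ][!is.na(b[i, ])]
        dt <- dipTest(x, null_dips = nulls[[as.character(length(x))]])
        mm <- .mixtureModes(x)
        DataFrame(cpg = rownames(b)[i], n = length(x),
                  dip = dt$statistic, dip_p = dt$p.value,
                  mode1 = mm[1], mode2 = mm[2], separation = mm[3],
                  bimodal = dt$p.value < alpha & !is.na(mm[3]) &
                      mm[3] >= min_separation)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- out$cpg
    out
}
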