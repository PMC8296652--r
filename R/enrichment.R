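#' @include AllClasses.R
NULL

## round half away from zero (publication-style), e.g. 0.0625 -> 0.063
.roundHalfUp <- function(x, digits = 3) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Correlate an ncRNA with its predicted target mRNAs
#'
#' Screens predicted target genes by Spearman correlation of their mRNA
#' levels with the ncRNA level over the shared samples, with
#' Benjamini-Hochberg FDR across the tested targets only.  Flags targets
#' selected at nominal p < 0.05 (the pathway-enrichment input) and at
#' FDR < 0.05 (individually significant correlations).
#'
#' @param ncrna_levels named numeric vector of per-sample ncRNA abundance
#'   (or an \linkS4class{ExpressionTable} plus \code{rna_name}).
#' @param mrna gene x sample expression matrix or
#'   \linkS4class{ExpressionTable}.
#' @param target_ids predicted target gene ids; ids absent from \code{mrna}
#'   are reported as skipped via the \code{"skipped"} attribute.
#' @param rna_name row of \code{ncrna_levels} when it is an
#'   \linkS4class{ExpressionTable}.
#' @param p_select nominal selection threshold (strict inequality).
#' @param fdr_threshold FDR significance threshold.
#' @return A \code{DataFrame} with one row per tested target: \code{gene},
#'   \code{n}, \code{rho}, \code{p}, \code{fdr}, \code{selected_p05},
#'   \code{significant_fdr05}; attribute \code{"skipped"} lists targets not
#'   in the expression matrix.
#' @export
#' @examples
#' set.seed(1)
#' nc <- setNames(rnorm(50), sprintf("s%02d", 1:50))
#' mrna <- matrix(rnorm(250), nrow = 5,
#'                dimnames = list(paste0("G", 1:5), names(nc)))
#' mrna["G1", ] <- -nc + rnorm(50, sd = 0.1)
#' correlateTargets(nc, mrna, paste0("G", 1:5))
correlateTargets <- function(ncrna_levels, mrna, target_ids,
                             rna_name = NULL, p_select = 0.05,
                             fdr_threshold = 0.05) {
    if (is(ncrna_levels, "ExpressionTable")) {
        if (is.null(rna_name))
            stop("'rna_name' required for an ExpressionTable input")
        ncrna_levels <- exprValues(ncrna_levels)[rna_name, ]
    }
    if (is(mrna, "ExpressionTable")) mrna <- exprValues(mrna)
    if (!length(target_ids)) stop("empty target list")
    tested <- intersect(target_ids, rownames(mrna))
    skipped <- setdiff(target_ids, tested)
    if (!length(tested))
        stop("none of the ", length(target_ids),
             " target ids are present in the expression matrix")
    res <- lapply(tested, function(g) {
        y <- mrna[g, ]
        common <- intersect(names(ncrna_levels)[!is.na(ncrna_levels)],
                            names(y)[!is.na(y)])
        if (length(common) < 5)
            return(DataFrame(gene = g, n = length(common),
                             rho = NA_real_, p = NA_real_))
        ct <- suppressWarnings(stats::cor.test(
            ncrna_levels[common], y[common], method = "spearman",
            exact = FALSE))
        DataFrame(gene = g, n = length(common),
                  rho = unname(ct$estimate), p = ct$p.value)
    })
    out <- do.call(rbind, res)
    out$fdr <- stats::p.adjust(out$p, method = "BH")
    out$selected_p05 <- !is.na(out$p) & out$p < p_select
    out$significant_fdr05 <- !is.na(out$fdr) & out$fdr < fdr_threshold
    rownames(out) <- out$gene
    attr(out, "skipped") <- skipped
    out
}

#' Select correlated targets for enrichment
#'
#' Returns the genes correlating with the ncRNA at nominal
#' \code{p < p_threshold} (strict), deduplicated and sorted.  Passing
#' several correlation tables takes the union, i.e. targets correlated with
#' at least one of the ncRNAs.
#'
#' @param ... one or more results of \code{\link{correlateTargets}}.
#' @param p_threshold selection threshold (strict inequality).
#' @return Sorted character vector of selected gene ids (possibly empty).
#' @export
selectCorrelatedTargets <- function(..., p_threshold = 0.05) {
    tabs <- list(...)
    if (!length(tabs)) stop("no correlation tables supplied")
    genes <- unlist(lapply(tabs, function(tb)
        tb$gene[!is.na(tb$p) & tb$p < p_threshold]))
    sort(unique(as.character(genes)))
}

#' Hypergeometric gene-set overlap enrichment
#'
#' Tests each gene set for over-representation of the selected genes by the
#' hypergeometric upper tail: with a universe of N genes of which K are in
#' the set and n are selected, the p-value is P(X >= k) for the observed
#' overlap k.  Benjamini-Hochberg q-values are computed across all sets with
#' K >= 1, and a set is reported when \code{q < fdr} and
#' \code{k >= min_overlap}.  The overlap ratio k/K is reported rounded to 3
#' decimals (half away from zero).
#'
#' @param selected character vector of selected gene ids.
#' @param collection named list of gene sets (see
#'   \code{\link{readGeneSets}}).
#' @param universe gene universe; defaults to all genes appearing in at
#'   least one set of the collection.  Selected genes outside the universe
#'   are dropped with a warning.
#' @param min_overlap minimum overlap for the reported flag.
#' @param fdr q-value threshold for the reported flag.
#' @return A \code{DataFrame} sorted by p with columns \code{set},
#'   \code{K}, \code{k}, \code{k_over_K}, \code{p}, \code{q},
#'   \code{reported}.
#' @export
#' @examples
#' sets <- list(A = paste0("G", 1:20), B = paste0("G", 15:40))
#' enrichGeneSets(paste0("G", 1:10), sets, universe = paste0("G", 1:100))
enrichGeneSets <- function(selected, collection, universe = NULL,
                           min_overlap = 5, fdr = 0.05) {
    if (!length(collection)) stop("empty gene-set collection")
    if (is.null(names(collection)) || anyDuplicated(names(collection)))
        stop("gene sets must have unique names")
    collection <- lapply(collection, function(s) unique(toupper(s)))
    if (is.null(universe))
        universe <- unique(unlist(collection, use.names = FALSE))
    else
        universe <- unique(toupper(universe))
    if (!length(universe)) stop("empty universe")
    selected <- unique(toupper(selected))
    outside <- setdiff(selected, universe)
    if (length(outside)) {
        warning(length(outside),
                " selected gene(s) outside the universe were dropped")
        selected <- intersect(selected, universe)
    }
    N <- length(universe)
    n_sel <- length(selected)
    rows <- lapply(names(collection), function(nm) {
        set_u <- intersect(collection[[nm]], universe)
        K <- length(set_u)
        k <- length(intersect(set_u, selected))
        p <- if (K >= 1)
            stats::phyper(k - 1, K, N - K, n_sel, lower.tail = FALSE)
        else NA_real_
        DataFrame(set = nm, K = K, k = k,
                  k_over_K = if (K >= 1) .roundHalfUp(k / K, 3) else NA_real_,
                  p = p)
    })
    out <- do.call(rbind, rows)
    out$q <- NA_real_
    testable <- out$K >= 1
    out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
    out$reported <- !is.na(out$q) & out$q < fdr & out$k >= min_overlap
    out <- out[order(out$p), ]
    rownames(out) <- out$set
    out
}
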