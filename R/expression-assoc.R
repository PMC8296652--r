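#' @include AllClasses.R
NULL

#' Delta-delta-Cq normalisation of qPCR expression
#'
#' Converts raw Cq cycle values to relative abundances against a reference
#' gene: per sample and RNA, \eqn{\Delta Cq = Cq(RNA) - Cq(ref)} and
#' relative abundance \eqn{2^{-\Delta Cq}}.  Samples missing the reference
#' Cq are dropped with a warning.  Undetected reactions should be encoded
#' as \code{NA} (they are treated as missing, not imputed at the assay
#' ceiling).
#'
#' @param cq An \linkS4class{ExpressionTable} with \code{valueKind == "Cq"}.
#' @param reference_gene reference assay row; defaults to the table's
#'   recorded reference gene.
#' @return An \linkS4class{ExpressionTable} of relative abundances (the
#'   reference gene row is retained with abundance 1).
#' @export
#' @examples
#' cq <- ExpressionTable(matrix(c(24, 25, 25, 25), nrow = 2,
#'         dimnames = list(c("nc886-5p", "B2M"), c("s1", "s2"))),
#'     value_kind = "Cq", reference_gene = "B2M")
#' exprValues(normalizeDdcq(cq))
normalizeDdcq <- function(cq, reference_gene = referenceGene(cq)) {
    stopifnot(is(cq, "ExpressionTable"))
    if (valueKind(cq) != "Cq")
        stop("'cq' must hold Cq values (valueKind == 'Cq')")
    v <- exprValues(cq)
    if (is.na(reference_gene) || !reference_gene %in% rownames(v))
        stop("reference gene '", reference_gene, "' absent from table")
    ref <- v[reference_gene, ]
    keep <- !is.na(ref)
    if (!all(keep))
        warning(sum(!keep), " sample(s) dropped: missing reference Cq")
    v <- v[, keep, drop = FALSE]
    rel <- 2^(-sweep(v, 2L, v[reference_gene, ], "-"))
    ExpressionTable(rel, value_kind = "abundance")
}

## Mann-Whitney p with the tie policy: exact when both groups are small and
## untied, otherwise normal approximation with continuity and tie correction
.mannWhitneyP <- function(x, y) {
    exact <- min(length(x), length(y)) <= 20 &&
        !anyDuplicated(c(x, y))
    suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
}

#' Status-wise fold changes with rank tests
#'
#' For each RNA, computes the fold change of every status group's median
#' relative abundance against the reference group's median (the
#' hemi-methylated group by default, whose own fold change is 1 by
#' construction), a two-sided Mann-Whitney p-value per non-reference group
#' versus the reference, and a Kruskal-Wallis p-value for the trend over
#' all groups when at least three are present.
#'
#' @param expr An \linkS4class{ExpressionTable} of abundances.
#' @param calls A \linkS4class{StatusCalls}.
#' @param reference_status the reference group (default \code{"hemi"}).
#' @param min_group_n groups smaller than this get their fold change
#'   reported but no test p-value.
#' @return A \code{DataFrame} with one row per (RNA, status group):
#'   \code{rna}, \code{status}, \code{n}, \code{fc}, \code{p_mannwhitney},
#'   \code{p_kruskal} (the Kruskal-Wallis p is repeated on each row of an
#'   RNA).
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 200, seed = 11))
#' cpgs <- grep("^cgB", rownames(betaMatrices(coh)[[1]]), value = TRUE)
#' calls <- callStatus(betaMatrices(coh)[[1]], cpgs)
#' foldChangeByStatus(cohortExpression(coh)[[1]], calls)
foldChangeByStatus <- function(expr, calls, reference_status = "hemi",
                               min_group_n = 3) {
    stopifnot(is(expr, "ExpressionTable"), is(calls, "StatusCalls"))
    if (valueKind(expr) != "abundance")
        stop("'expr' must hold abundances; run normalizeDdcq() first")
    st <- sampleStatus(calls)
    v <- exprValues(expr)
    common <- intersect(colnames(v), names(st))
    if (!length(common)) stop("no samples shared between 'expr' and 'calls'")
    v <- v[, common, drop = FALSE]
    st <- droplevels(st[common])
    if (!reference_status %in% levels(st) ||
        sum(st == reference_status, na.rm = TRUE) == 0)
        stop("reference group '", reference_status, "' is empty")

    rows <- list()
    for (r in rownames(v)) {
        x <- v[r, ]
        ok <- !is.na(x)
        groups <- split(x[ok], st[ok], drop = TRUE)
        if (!reference_status %in% names(groups))
            stop("reference group '", reference_status,
                 "' has no expression values for RNA ", r)
        ref <- groups[[reference_status]]
        ref_med <- stats::median(ref)
        if (ref_med == 0) stop("reference group median is 0 for RNA ", r)
        big <- vapply(groups, length, integer(1)) >= min_group_n
        p_kw <- if (sum(big) >= 3)
            stats::kruskal.test(x[ok], droplevels(st[ok]))$p.value
        else NA_real_
        for (g in names(groups)) {
            fc <- stats::median(groups[[g]]) / ref_med
            p_mw <- if (g == reference_status) NA_real_
            else if (length(groups[[g]]) >= min_group_n &&
                     length(ref) >= min_group_n)
                .mannWhitneyP(groups[[g]], ref)
            else NA_real_
            rows[[length(rows) + 1L]] <-
                DataFrame(rna = r, status = g,
                          n = length(groups[[g]]), fc = fc,
                          p_mannwhitney = p_mw, p_kruskal = p_kw)
        }
    }
    out <- do.call(rbind, rows)
    out$status <- factor(out$status, levels = statusLevels())
    out
}

#' Cross-correlate RNA levels across tables
#'
#' Computes Spearman correlations (with p-values and overlap counts) for
#' every pair of (table, RNA) series over their intersecting samples, e.g.
#' the same RNA species measured in different tissues or at different time
#' points.
#'
#' @param tables named list (>= 2) of \linkS4class{ExpressionTable}s.
#' @param min_overlap pairs with fewer shared samples get a missing rho.
#' @return A \code{DataFrame} with columns \code{series_a},
#'   \code{series_b}, \code{n}, \code{rho}, \code{p} for all unordered
#'   pairs (series labelled \code{"<table>:<rna>"}).
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 60, seed = 8))
#' crossCorrelateRnas(cohortExpression(coh))
crossCorrelateRnas <- function(tables, min_overlap = 5) {
    if (length(tables) < 2 || is.null(names(tables)))
        stop("need >= 2 named expression tables")
    series <- list()
    for (lab in names(tables)) {
        v <- exprValues(tables[[lab]])
        for (r in rownames(v))
            series[[paste(lab, r, sep = ":")]] <- v[r, ]
    }
    nm <- names(series)
    rows <- list()
    for (i in seq_along(nm)) for (j in seq_len(i)) {
        a <- series[[nm[i]]]
        b <- series[[nm[j]]]
        common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
        if (length(common) < min_overlap) {
            rows[[length(rows) + 1L]] <-
                DataFrame(series_a = nm[j], series_b = nm[i],
                          n = length(common), rho = NA_real_, p = NA_real_)
        } else {
            ct <- suppressWarnings(stats::cor.test(
                a[common], b[common], method = "spearman", exact = FALSE))
            rows[[length(rows) + 1L]] <-
                DataFrame(series_a = nm[j], series_b = nm[i],
                          n = length(common), rho = unname(ct$estimate),
                          p = ct$p.value)
        }
    }
    do.call(rbind, rows)
}
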