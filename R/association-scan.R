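#' @include AllClasses.R
NULL

#' Per-CpG association scan between methylation and an RNA level
#'
#' For every CpG, fits a linear model of the RNA level on the CpG's beta
#' values plus covariates and reports the effect estimate, standard error
#' and two-sided p-value, flagging CpGs at the genome-wide threshold
#' (p < 5e-8 by default).  This is the screen used to identify
#' expression-associated CpGs in a candidate region.
#'
#' @param beta A \linkS4class{BetaMatrix}.
#' @param rna An \linkS4class{ExpressionTable} (abundance) or a named
#'   numeric vector of per-sample RNA levels.
#' @param covariates optional data.frame of numeric-encoded covariates with
#'   rownames = sample ids; rank-deficient covariate sets are rejected.
#' @param rna_name when \code{rna} is an \linkS4class{ExpressionTable}, the
#'   row to use.
#' @param gw_threshold genome-wide significance threshold for the flag.
#' @return A \code{DataFrame} with one row per CpG: \code{cpg},
#'   \code{estimate}, \code{se}, \code{p}, \code{n}, \code{genome_wide}.
#'   CpGs with constant beta get missing estimates and are excluded from
#'   flagging.
#' @export
#' @examples
#' coh <- simulateCohort(cohortConfig(n_samples = 80, seed = 3))
#' res <- scanCpgAssociations(betaMatrices(coh)[[1]],
#'                            cohortExpression(coh)[[1]],
#'                            rna_name = "nc886-3p")
#' head(res)
scanCpgAssociations <- function(beta, rna, covariates = NULL,
                                rna_name = NULL, gw_threshold = 5e-8) {
    b <- betaValues(beta)
    if (is(rna, "ExpressionTable")) {
        if (is.null(rna_name))
            stop("'rna_name' is required when 'rna' is an ExpressionTable")
        if (!rna_name %in% rownames(rna))
            stop("RNA '", rna_name, "' not found in expression table")
        y <- exprValues(rna)[rna_name, ]
    } else {
        y <- rna
        if (is.null(names(y)))
            stop("'rna' vector must be named by sample id")
    }
    common <- intersect(colnames(b), names(y)[!is.na(y)])
    if (length(common) < 10)
        stop("insufficient observations: need >= 10 complete sample pairs, got ",
             length(common))
    b <- b[, common, drop = FALSE]
    y <- y[common]

    X0 <- matrix(1, nrow = length(common), ncol = 1)
    colnames(X0) <- "(Intercept)"
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        if (!all(common %in% rownames(covariates)))
            stop("covariates missing for some samples")
        cv <- covariates[common, , drop = FALSE]
        if (!all(vapply(cv, is.numeric, logical(1))))
            stop("covariates must be numeric-encoded")
        cvm <- as.matrix(cv)
        if (qr(cbind(X0, cvm))$rank < 1 + ncol(cvm))
            stop("rank-deficient covariates")
        X0 <- cbind(X0, cvm)
    }

    fit1 <- function(xb, yy) {
        ok <- !is.na(xb) & !is.na(yy)
        if (sum(ok) < 10 || stats::var(xb[ok]) == 0)
            return(c(NA_real_, NA_real_, NA_real_, sum(ok)))
        X <- cbind(X0[ok, , drop = FALSE], beta = xb[ok])
        f <- stats::lm.fit(X, yy[ok])
        df <- length(f$residuals) - f$rank
        if (df <= 0 || f$rank < ncol(X))
            return(c(NA_real_, NA_real_, NA_real_, sum(ok)))
        rss <- sum(f$residuals^2)
        XtXinv <- chol2inv(chol(crossprod(X)))
        se <- sqrt(rss / df * XtXinv[ncol(X), ncol(X)])
        est <- f$coefficients[["beta"]]
        tval <- est / se
        p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
        c(est, se, p, sum(ok))
    }
    res <- t(apply(b, 1L, fit1, yy = y))
    out <- DataFrame(cpg = rownames(b),
                     estimate = unname(res[, 1]), se = unname(res[, 2]),
                     p = unname(res[, 3]), n = as.integer(res[, 4]))
    out$genome_wide <- !is.na(out$p) & out$p < gw_threshold
    rownames(out) <- out$cpg
    out
}
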