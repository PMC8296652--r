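## Hartigan's dip statistic, computed from its definition:
## dip(Fn) = min over unimodal cdfs G of sup_x |Fn(x) - G(x)|.
##
## Reduction used here: collapse the sample to distinct values v_1..v_J with
## cumulative counts; at each v_j the ecdf has lower corner hi_j (value
## before the jump) and upper corner lo_j (after the jump).  A unimodal G
## within sup-distance t of Fn exists iff for some mode position m (an atom
## of G at v_m absorbs the jump there) a convex function fits below the
## hi-corners on v_1..v_m while staying within t of the lo-corners at
## v_1..v_{m-1}, and a concave function fits above the lo-corners on
## v_m..v_J within t of the hi-corners at v_{m+1}..v_J.  The best t for a
## side is half the largest gap between the corner ladder and the greatest
## convex minorant (least concave majorant) of the opposite corners, so
##
##   dip = (1/2) * min_m max( A[m], B[m] )
##
## with A[m] the largest lo-vs-minorant gap over the prefix ending at m and
## B[m] the mirrored suffix quantity.  Both gap profiles are computed in a
## single left-to-right (right-to-left) sweep with an incremental convex
## hull; gaps only grow as the minorant is lowered by new points, so each
## sweep tracks a running maximum over the re-spanned hull region.
## Verified against an exhaustive LP formulation of the definition on
## randomized small samples (with and without ties) and against analytic
## point-mass cases.

## prefix convex-side costs.
## v: strictly increasing abscissae; minor: ordinates the convex minorant is
## fitted to (upper ecdf corners); target: ordinates whose gap above the
## minorant is the cost (lower ecdf corners).
## Returns A with A[m] = max_{j < m} (target_j - minorant_{1..m}(v_j)), the
## convex-side cost when the mode sits at v_m.
.dipPrefixCosts <- function(v, minor, target) {
    J <- length(v)
    A <- numeric(J)
    if (J < 2L) return(A)
    gap <- numeric(J)
    stack <- integer(J)
    stack[1L] <- 1L
    top <- 1L
    for (m in 2:J) {
        while (top >= 2L) {
            a <- stack[top - 1L]
            b <- stack[top]
            if ((minor[b] - minor[a]) * (v[m] - v[a]) >=
                (minor[m] - minor[a]) * (v[b] - v[a])) top <- top - 1L
            else break
        }
        astar <- stack[top]
        if (astar < m - 1L) {
            jj <- (astar + 1L):(m - 1L)
            slope <- (minor[m] - minor[astar]) / (v[m] - v[astar])
            gap[jj] <- target[jj] - (minor[astar] + slope * (v[jj] - v[astar]))
            A[m] <- max(A[m - 1L], gap[jj])
        } else {
            gap[m - 1L] <- target[m - 1L] - minor[m - 1L]
            A[m] <- max(A[m - 1L], gap[m - 1L])
        }
        top <- top + 1L
        stack[top] <- m
    }
    A
}

#' Hartigan's dip statistic
#'
#' Computes the dip statistic: the smallest sup-norm distance between the
#' empirical cdf of \code{x} and the class of unimodal distribution
#' functions.  Large values indicate departure from unimodality.  Ties are
#' handled exactly (the empirical cdf steps are collapsed); for a constant
#' sample the dip is 0, and for a sample of n distinct values it is at
#' least \code{1/(2n)}.
#'
#' @param x numeric vector; \code{NA}s are dropped.
#' @return The dip statistic (a number in [0, 0.25]).
#' @seealso \code{\link{dipTest}} for a Monte-Carlo p-value.
#' @export
#' @examples
#' set.seed(1)
#' dipStatistic(rnorm(200))                      # unimodal: small
#' dipStatistic(c(rnorm(100), rnorm(100, 6)))    # bimodal: large
dipStatistic <- function(x) {
    x <- sort(as.numeric(x[!is.na(x)]))
    n <- length(x)
    if (n == 0L) stop("no non-missing values")
    if (n < 2L || x[1L] == x[n]) return(0)
    rl <- rle(x)
    v <- rl$values
    cc <- cumsum(rl$lengths)
    J <- length(v)
    lo <- cc / n                    # ecdf just after each jump
    hi <- c(0, cc[-J]) / n          # ecdf just before each jump
    A <- .dipPrefixCosts(v, hi, lo)
    ## concave suffix side: mirror (negate and reverse) turns the least
    ## concave majorant of lo into a convex minorant problem
    Brev <- .dipPrefixCosts(-rev(v), -rev(lo), -rev(hi))
    B <- rev(Brev)
    min(pmax(A, B)) / 2
}

#' Dip test of unimodality with a Monte-Carlo null
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution by comparing \code{\link{dipStatistic}} against its null
#' distribution under the uniform distribution (the asymptotically least
#' favourable unimodal null), simulated at the observed sample size.
#'
#' @param x numeric vector.
#' @param B number of Monte-Carlo null replicates.
#' @param null_dips optional pre-computed vector of null dip statistics at
#'   the same sample size (see \code{\link{dipNullDistribution}}); when
#'   supplied, \code{B} is ignored.  Useful when testing many variables of
#'   equal length.
#' @return A list with elements \code{statistic}, \code{p.value}, \code{n}
#'   and \code{B}.
#' @export
#' @examples
#' set.seed(1)
#' dipTest(c(rnorm(100, 0, 0.5), rnorm(100, 4, 0.5)), B = 200)$p.value
dipTest <- function(x, B = 500, null_dips = NULL) {
    x <- x[!is.na(x)]
    stat <- dipStatistic(x)
    n <- length(x)
    if (is.null(null_dips))
        null_dips <- dipNullDistribution(n, B)
    B <- length(null_dips)
    p <- (1 + sum(null_dips >= stat)) / (B + 1)
    list(statistic = stat, p.value = p, n = n, B = B)
}

#' Null distribution of the dip statistic
#'
#' Simulates dip statistics of uniform samples of size \code{n}.  The null
#' distribution depends only on \code{n}, so it can be shared across many
#' tests at a common sample size.  Uses a private RNG stream so it neither
#' disturbs nor depends on the caller's RNG state.
#'
#' @param n sample size.
#' @param B number of replicates.
#' @param seed integer seed for the private stream.
#' @return Numeric vector of \code{B} null dip statistics.
#' @export
dipNullDistribution <- function(n, B = 500, seed = 20210722L) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    vapply(seq_len(B), function(i) dipStatistic(stats::runif(n)), numeric(1))
}
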