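## shared fixtures and small independent oracles, built in code

## a BetaMatrix with given values and a minimal nc886-like annotation
makeBetaMatrix <- function(values, bimodal = rep(TRUE, nrow(values))) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("cg%03d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
    ann <- data.frame(
        chromosome = "chr5",
        position = 135415000L + 100L * seq_len(nrow(values)),
        in_dmr = bimodal, bimodal = bimodal)
    BetaMatrix(values, ann)
}

## StatusCalls built directly from a status vector (for tests that need
## calls without running the clusterer)
makeCalls <- function(statuses, median_beta = NULL) {
    ids <- names(statuses)
    if (is.null(ids)) ids <- sprintf("s%03d", seq_along(statuses))
    if (is.null(median_beta))
        median_beta <- c(non = 0.10, intermediate = 0.35,
                         hemi = 0.50, full = 0.70)[as.character(statuses)]
    calls <- S4Vectors::DataFrame(
        status = factor(as.character(statuses), levels = statusLevels()),
        median_beta = unname(median_beta),
        cluster = NA_integer_, probe_sd = NA_real_, row.names = ids)
    epistatus:::.StatusCalls(calls, character(), 0.60, 3L)
}

## exhaustive minimum-diameter k-partition of a distance matrix (oracle for
## the hierarchical clustering on well-separated data, n <= 8)
minDiameterPartition <- function(d, k = 3) {
    d <- as.matrix(d)
    n <- nrow(d)
    best <- NULL
    best_diam <- Inf
    assignments <- expand.grid(rep(list(seq_len(k)), n))
    for (i in seq_len(nrow(assignments))) {
        a <- as.integer(assignments[i, ])
        if (length(unique(a)) != k) next
        diam <- max(vapply(seq_len(k), function(g) {
            idx <- which(a == g)
            if (length(idx) < 2) 0 else max(d[idx, idx])
        }, numeric(1)))
        if (diam < best_diam - 1e-12) {
            best_diam <- diam
            best <- a
        }
    }
    list(assignment = best, diameter = best_diam)
}

## hypergeometric upper-tail by exhaustive enumeration over all draws
## (oracle for small universes)
hyperTailEnum <- function(N, K, n, k) {
    if (n == 0) return(as.numeric(k <= 0))
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)   # items 1..K are the "successes"
    mean(hits >= k)
}
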