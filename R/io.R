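#' @include AllClasses.R
NULL

#' Read a genomic region from a BED file
#'
#' BED intervals are 0-based half-open on disk; the returned \code{GRanges}
#' uses the package's 1-based closed convention (the conversion is handled
#' by the importer).
#'
#' @param path BED file path.
#' @return A \code{GRanges}.
#' @export
readRegionBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
    fgsea::gmtPathways(path)
}

#' Read a beta matrix with CpG annotation
#'
#' @param beta_tsv TSV with CpG ids in the first column, samples in the
#'   remaining columns (as written by \code{\link{writeCohort}}).
#' @param annotation_csv CSV with columns \code{cpg}, \code{chromosome},
#'   \code{position}, \code{in_dmr} (and optionally \code{bimodal}).
#' @return A \linkS4class{BetaMatrix}.
#' @export
readBetaMatrix <- function(beta_tsv, annotation_csv) {
    tab <- utils::read.delim(beta_tsv, row.names = 1, check.names = FALSE)
    ann <- utils::read.csv(annotation_csv, stringsAsFactors = FALSE)
    rownames(ann) <- ann$cpg
    ann <- ann[rownames(tab), setdiff(colnames(ann), "cpg"), drop = FALSE]
    BetaMatrix(as.matrix(tab), ann)
}

#' Read/write status calls
#'
#' @param calls A \linkS4class{StatusCalls}.
#' @param path CSV path.
#' @return \code{writeStatusCalls}: the path, invisibly;
#'   \code{readStatusCalls}: a \linkS4class{StatusCalls}.
#' @name statuscalls-io
NULL

#' @rdname statuscalls-io
#' @export
writeStatusCalls <- function(calls, path) {
    df <- as.data.frame(statusCalls(calls))
    df <- cbind(sample = rownames(df), df)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname statuscalls-io
#' @export
readStatusCalls <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    calls <- DataFrame(
        status = factor(df$status, levels = statusLevels()),
        median_beta = df$median_beta,
        cluster = as.integer(df$cluster),
        probe_sd = df$probe_sd,
        row.names = df$sample)
    .StatusCalls(calls, character(), 0.60, 3L)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes, into \code{dir}: one beta TSV per time point (rows = CpG ids,
#' columns = sample ids), a CpG annotation CSV, a sample sheet CSV with
#' covariates, one expression TSV per table, a long-format trait CSV and a
#' truth-label CSV.
#'
#' @param cohort A \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "SyntheticCohort"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    bms <- betaMatrices(cohort)
    for (nm in names(bms)) {
        b <- betaValues(bms[[nm]])
        utils::write.table(
            cbind(cpg = rownames(b), as.data.frame(b)),
            file.path(dir, paste0("beta_", nm, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ann <- as.data.frame(cpgAnnotation(bms[[1]]))
    utils::write.csv(cbind(cpg = rownames(ann), ann),
                     file.path(dir, "cpg_annotation.csv"), row.names = FALSE)
    cov <- as.data.frame(cohortCovariates(cohort))
    utils::write.csv(cbind(sample = rownames(cov), cov),
                     file.path(dir, "samples.csv"), row.names = FALSE)
    for (nm in names(cohortExpression(cohort))) {
        v <- exprValues(cohortExpression(cohort)[[nm]])
        utils::write.table(
            cbind(rna = rownames(v), as.data.frame(v)),
            file.path(dir, paste0("expression_", nm, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.csv(as.data.frame(traitRecords(cohortTraits(cohort))),
                     file.path(dir, "traits.csv"), row.names = FALSE)
    truth <- as.data.frame(cohort@truth)
    utils::write.csv(cbind(sample = rownames(truth), truth),
                     file.path(dir, "truth.csv"), row.names = FALSE)
    invisible(dir)
}

#' Read a cohort configuration from YAML
#'
#' Reads a key-value (nested sections allowed) YAML file whose fields
#' mirror the arguments of \code{\link{cohortConfig}}; unknown fields are
#' rejected.
#'
#' @param path YAML file path.
#' @return A \code{"CohortConfig"} list.
#' @export
readCohortConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(cohortConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    for (f in c("status_weights", "beta_means", "rna_fold_changes",
                "covariate_assoc"))
        if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
    if (!is.null(vals$covariate_assoc)) {
        ## re-nest "group.level" names produced by unlist
        ca <- vals$covariate_assoc
        parts <- strsplit(names(ca), ".", fixed = TRUE)
        groups <- vapply(parts, `[`, character(1), 1)
        lvls <- vapply(parts, function(p) paste(p[-1], collapse = "."),
                       character(1))
        vals$covariate_assoc <- lapply(split(seq_along(ca), groups),
                                       function(ii)
                                           stats::setNames(ca[ii], lvls[ii]))
    }
    do.call(cohortConfig, vals)
}
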