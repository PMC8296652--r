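#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Epiallele methylation status levels
#'
#' Ordered labels for the four epiallele states: \code{non} (neither allele
#' methylated, beta ~ 0.10), \code{intermediate} (mixed cell populations,
#' beta ~ 0.35), \code{hemi} (one allele methylated, beta ~ 0.50) and
#' \code{full} (both alleles methylated in at least part of the cells,
#' median beta > 0.60).
#'
#' @return Character vector of the four status labels in ascending
#'   methylation order.
#' @export
#' @examples
#' statusLevels()
statusLevels <- function() c("non", "intermediate", "hemi", "full")

## ---------------------------------------------------------------------------
## BetaMatrix
## ---------------------------------------------------------------------------

#' BetaMatrix: CpG x sample methylation beta values
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"beta"} assay
#' (rows = CpGs, columns = samples, values in [0, 1], \code{NA} allowed) with
#' per-CpG annotation columns \code{chromosome}, \code{position} (1-based)
#' and \code{in_dmr}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases BetaMatrix-class
#' @exportClass BetaMatrix
setClass("BetaMatrix", contains = "SummarizedExperiment")

.validBetaMatrix <- function(object) {
    msg <- NULL
    if (!("beta" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (!is.numeric(b))
            msg <- c(msg, "'beta' assay must be numeric")
        else if (any(b < 0 | b > 1, na.rm = TRUE))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "CpG ids (rownames) must be present and unique")
    needed <- c("chromosome", "position", "in_dmr")
    missing <- setdiff(needed, colnames(rowData(object)))
    if (length(missing))
        msg <- c(msg, paste0("missing CpG annotation column(s): ",
                             paste(missing, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
}
setValidity("BetaMatrix", .validBetaMatrix)

#' Construct a BetaMatrix
#'
#' @param beta numeric matrix of beta values, rows = CpGs, columns = samples.
#'   Row and column names are required.
#' @param annotation \code{data.frame} or \code{DataFrame} with one row per
#'   CpG (matched to \code{rownames(beta)}) and columns \code{chromosome},
#'   \code{position} (1-based) and \code{in_dmr} (logical).
#' @return A \linkS4class{BetaMatrix}.
#' @export
#' @examples
#' b <- matrix(c(0.1, 0.5, 0.12, 0.48), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' ann <- data.frame(chromosome = "chr5", position = c(101, 201),
#'                   in_dmr = TRUE)
#' BetaMatrix(b, ann)
BetaMatrix <- function(beta, annotation) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)))
        stop("'beta' must have CpG ids as rownames")
    if (is.null(colnames(beta)))
        stop("'beta' must have sample ids as colnames")
    annotation <- as(annotation, "DataFrame")
    if (!is.null(rownames(annotation)) &&
        !identical(rownames(annotation), as.character(seq_len(nrow(annotation)))))
        annotation <- annotation[rownames(beta), , drop = FALSE]
    if (nrow(annotation) != nrow(beta))
        stop("'annotation' must have one row per CpG")
    rownames(annotation) <- rownames(beta)
    new("BetaMatrix",
        SummarizedExperiment(assays = list(beta = beta), rowData = annotation))
}

## ---------------------------------------------------------------------------
## ExpressionTable
## ---------------------------------------------------------------------------

#' ExpressionTable: RNA x sample expression values
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"value"} assay
#' (rows = RNA species or genes, columns = samples).  The measurement kind is
#' recorded in \code{metadata(x)$value_kind}: \code{"Cq"} for raw qPCR cycle
#' values (positive) or \code{"abundance"} for (relative) abundances.  For Cq
#' tables, \code{metadata(x)$reference_gene} names the reference assay used
#' by \code{\link{normalizeDdcq}}.
#'
#' @aliases ExpressionTable-class
#' @exportClass ExpressionTable
setClass("ExpressionTable", contains = "SummarizedExperiment")

.validExpressionTable <- function(object) {
    msg <- NULL
    if (!("value" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'value' is required")
    kind <- metadata(object)$value_kind
    if (is.null(kind) || !kind %in% c("Cq", "abundance"))
        msg <- c(msg, "metadata 'value_kind' must be 'Cq' or 'abundance'")
    else if (kind == "Cq") {
        v <- assay(object, "value")
        if (any(v <= 0, na.rm = TRUE))
            msg <- c(msg, "Cq values must be positive")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "RNA ids (rownames) must be present and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionTable", .validExpressionTable)

#' Construct an ExpressionTable
#'
#' @param values numeric matrix, rows = RNA ids, columns = sample ids.
#' @param value_kind \code{"Cq"} or \code{"abundance"}.
#' @param reference_gene for Cq tables, the row name of the reference gene
#'   (e.g. \code{"B2M"}); ignored for abundance tables.
#' @return An \linkS4class{ExpressionTable}.
#' @export
#' @examples
#' cq <- matrix(c(25, 24, 25, 25), nrow = 2,
#'              dimnames = list(c("nc886-3p", "B2M"), c("s1", "s2")))
#' ExpressionTable(cq, value_kind = "Cq", reference_gene = "B2M")
ExpressionTable <- function(values, value_kind = c("abundance", "Cq"),
                            reference_gene = NA_character_) {
    value_kind <- match.arg(value_kind)
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have RNA ids as rownames and sample ids as colnames")
    se <- SummarizedExperiment(assays = list(value = values))
    metadata(se)$value_kind <- value_kind
    metadata(se)$reference_gene <- reference_gene
    new("ExpressionTable", se)
}

## ---------------------------------------------------------------------------
## StatusCalls
## ---------------------------------------------------------------------------

#' StatusCalls: per-sample epiallele status assignments
#'
#' Holds one status call per sample, together with the median beta over the
#' bimodal CpGs used for calling, the hierarchical-clustering cluster id
#' (\code{NA} for samples assigned \code{"full"} by threshold, which never
#' enter the clustering) and the per-sample between-probe SD.
#'
#' @slot calls \code{DataFrame} with rownames = sample ids and columns
#'   \code{status} (factor over \code{\link{statusLevels}}),
#'   \code{median_beta}, \code{cluster}, \code{probe_sd}.
#' @slot cpgIds CpG ids the calls are based on.
#' @slot fullThreshold median-beta threshold above which samples are labelled
#'   \code{"full"}.
#' @slot k number of clusters the tree was cut at.
#' @aliases StatusCalls-class
#' @exportClass StatusCalls
setClass("StatusCalls",
         representation(calls = "DataFrame", cpgIds = "character",
                        fullThreshold = "numeric", k = "integer"))

.validStatusCalls <- function(object) {
    msg <- NULL
    needed <- c("status", "median_beta", "cluster", "probe_sd")
    if (!all(needed %in% colnames(object@calls)))
        msg <- c(msg, paste0("'calls' must have columns ",
                             paste(needed, collapse = ", ")))
    else {
        st <- object@calls$status
        if (!is.factor(st) || !all(levels(st) == statusLevels()))
            msg <- c(msg, "'status' must be a factor over statusLevels()")
        if (anyNA(st))
            msg <- c(msg, "every sample must be assigned exactly one status")
    }
    if (is.null(rownames(object@calls)) || anyDuplicated(rownames(object@calls)))
        msg <- c(msg, "sample ids (rownames of calls) must be unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("StatusCalls", .validStatusCalls)

## internal constructor
.StatusCalls <- function(calls, cpgIds, fullThreshold, k) {
    new("StatusCalls", calls = calls, cpgIds = as.character(cpgIds),
        fullThreshold = fullThreshold, k = as.integer(k))
}

## ---------------------------------------------------------------------------
## TraitPanel
## ---------------------------------------------------------------------------

#' TraitPanel: repeated trait measurements with ages
#'
#' Long-format records of repeated measurements: one row per
#' (sample, trait, age) with the measured value.  Per-trait metadata flags
#' traits whose skewed values are log-transformed before area-under-curve
#' integration.
#'
#' @slot records \code{DataFrame} with columns \code{sample}, \code{trait},
#'   \code{age} (years, positive) and \code{value}.
#' @slot traitInfo \code{DataFrame} with columns \code{trait}, \code{units},
#'   \code{log_transform}.
#' @aliases TraitPanel-class
#' @exportClass TraitPanel
setClass("TraitPanel",
         representation(records = "DataFrame", traitInfo = "DataFrame"))

.validTraitPanel <- function(object) {
    msg <- NULL
    needed <- c("sample", "trait", "age", "value")
    if (!all(needed %in% colnames(object@records)))
        msg <- c(msg, paste0("'records' must have columns ",
                             paste(needed, collapse = ", ")))
    else {
        age <- object@records$age
        if (any(!is.finite(age)) || any(age <= 0))
            msg <- c(msg, "ages must be positive and finite")
    }
    if (!all(c("trait", "log_transform") %in% colnames(object@traitInfo)))
        msg <- c(msg, "'traitInfo' must have columns trait, log_transform")
    if (is.null(msg)) TRUE else msg
}
setValidity("TraitPanel", .validTraitPanel)

#' Construct a TraitPanel
#'
#' @param records data.frame with columns \code{sample}, \code{trait},
#'   \code{age}, \code{value}.
#' @param traitInfo optional data.frame with columns \code{trait},
#'   \code{units}, \code{log_transform}; defaults to no transformation.
#' @return A \linkS4class{TraitPanel}.
#' @export
#' @examples
#' rec <- data.frame(sample = "s1", trait = "glucose",
#'                   age = c(6, 12, 18), value = c(4.8, 5.0, 5.1))
#' TraitPanel(rec)
TraitPanel <- function(records, traitInfo = NULL) {
    records <- as(as.data.frame(records), "DataFrame")
    if (is.null(traitInfo)) {
        traitInfo <- DataFrame(trait = unique(as.character(records$trait)),
                               units = NA_character_, log_transform = FALSE)
    } else {
        traitInfo <- as(as.data.frame(traitInfo), "DataFrame")
        if (!("units" %in% colnames(traitInfo)))
            traitInfo$units <- NA_character_
    }
    new("TraitPanel", records = records, traitInfo = traitInfo)
}

## ---------------------------------------------------------------------------
## StabilityReport
## ---------------------------------------------------------------------------

#' StabilityReport: longitudinal stability of status calls
#'
#' @slot nOverlap number of samples present at both time points.
#' @slot rho Spearman correlation of median betas across time points.
#' @slot pValue p-value of the correlation test.
#' @slot concordance fraction of overlapping samples with identical status.
#' @slot discordant ids of samples whose status differs between time points.
#' @slot perSample \code{DataFrame} with per-sample medians and statuses at
#'   both time points.
#' @aliases StabilityReport-class
#' @exportClass StabilityReport
setClass("StabilityReport",
         representation(nOverlap = "integer", rho = "numeric",
                        pValue = "numeric", concordance = "numeric",
                        discordant = "character", perSample = "DataFrame"))

.validStabilityReport <- function(object) {
    msg <- NULL
    if (length(object@rho) == 1 && !is.na(object@rho) &&
        (object@rho < -1 || object@rho > 1))
        msg <- c(msg, "rho must lie in [-1, 1]")
    if (object@concordance < 0 || object@concordance > 1)
        msg <- c(msg, "concordance must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
}
setValidity("StabilityReport", .validStabilityReport)

## ---------------------------------------------------------------------------
## SyntheticCohort
## ---------------------------------------------------------------------------

#' SyntheticCohort: a simulated multi-omic cohort
#'
#' Container for everything \code{\link{simulateCohort}} generates: one
#' \linkS4class{BetaMatrix} per time point, expression tables, a trait panel,
#' covariates and the true per-sample status labels.
#'
#' @slot betaMatrices list of \linkS4class{BetaMatrix}, one per time point.
#' @slot expression list of \linkS4class{ExpressionTable}.
#' @slot traits \linkS4class{TraitPanel}.
#' @slot covariates \code{DataFrame} of per-sample covariates (sex, maternal
#'   age group, income quartile, occupation class).
#' @slot truth \code{DataFrame} with the true status per sample.
#' @slot config the \code{\link{cohortConfig}} list used.
#' @aliases SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
         representation(betaMatrices = "list", expression = "list",
                        traits = "TraitPanel", covariates = "DataFrame",
                        truth = "DataFrame", config = "list"))

.validSyntheticCohort <- function(object) {
    msg <- NULL
    ids <- rownames(object@truth)
    for (bm in object@betaMatrices)
        if (!identical(colnames(bm), ids))
            msg <- c(msg, "sample ids must be identical across beta matrices")
    for (et in object@expression)
        if (!identical(colnames(et), ids))
            msg <- c(msg, "sample ids must be identical across expression tables")
    if (!identical(rownames(object@covariates), ids))
        msg <- c(msg, "covariate sample ids must match truth labels")
    if (is.null(msg)) TRUE else msg
}
setValidity("SyntheticCohort", .validSyntheticCohort)
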