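#' @include AllGenerics.R
NULL

#' Accessors for BetaMatrix
#'
#' \code{betaValues} returns the beta matrix (rows = CpGs, columns =
#' samples); \code{cpgAnnotation} the per-CpG annotation;
#' \code{cpgRanges} the CpG positions as a width-1 \code{GRanges}.
#'
#' @param x A \linkS4class{BetaMatrix}.
#' @param ... ignored.
#' @return See description.
#' @name BetaMatrix-accessors
#' @aliases betaValues cpgAnnotation cpgRanges
NULL

#' @rdname BetaMatrix-accessors
#' @export
setMethod("betaValues", "BetaMatrix", function(x, ...) assay(x, "beta"))

#' @rdname BetaMatrix-accessors
#' @export
setMethod("cpgAnnotation", "BetaMatrix", function(x, ...) rowData(x))

#' @rdname BetaMatrix-accessors
#' @export
setMethod("cpgRanges", "BetaMatrix", function(x, ...) {
    ann <- rowData(x)
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(ann$chromosome),
        ranges = IRanges::IRanges(start = ann$position, width = 1L))
    names(gr) <- rownames(x)
    S4Vectors::mcols(gr)$in_dmr <- ann$in_dmr
    gr
})

#' Accessors for ExpressionTable
#'
#' @param x An \linkS4class{ExpressionTable}.
#' @param ... ignored.
#' @return \code{exprValues}: the value matrix; \code{valueKind}: "Cq" or
#'   "abundance"; \code{referenceGene}: the reference-gene id (or NA).
#' @name ExpressionTable-accessors
#' @aliases exprValues valueKind referenceGene
NULL

#' @rdname ExpressionTable-accessors
#' @export
setMethod("exprValues", "ExpressionTable", function(x, ...) assay(x, "value"))

#' @rdname ExpressionTable-accessors
#' @export
setMethod("valueKind", "ExpressionTable", function(x, ...) metadata(x)$value_kind)

#' @rdname ExpressionTable-accessors
#' @export
setMethod("referenceGene", "ExpressionTable",
          function(x, ...) metadata(x)$reference_gene)

#' Accessors for StatusCalls
#'
#' @param x A \linkS4class{StatusCalls}.
#' @param ... ignored.
#' @return \code{statusCalls}: the full per-sample \code{DataFrame};
#'   \code{sampleStatus}: named factor of statuses; \code{medianBeta}: named
#'   numeric of per-sample median betas.
#' @name StatusCalls-accessors
#' @aliases statusCalls sampleStatus medianBeta
NULL

#' @rdname StatusCalls-accessors
#' @export
setMethod("statusCalls", "StatusCalls", function(x, ...) x@calls)

#' @rdname StatusCalls-accessors
#' @export
setMethod("sampleStatus", "StatusCalls", function(x, ...) {
    out <- x@calls$status
    names(out) <- rownames(x@calls)
    out
})

#' @rdname StatusCalls-accessors
#' @export
setMethod("medianBeta", "StatusCalls", function(x, ...) {
    out <- x@calls$median_beta
    names(out) <- rownames(x@calls)
    out
})

#' Accessors for TraitPanel
#'
#' @param x A \linkS4class{TraitPanel}.
#' @param ... ignored.
#' @return \code{traitRecords}: long-format measurement records;
#'   \code{traitInfo}: per-trait metadata.
#' @name TraitPanel-accessors
#' @aliases traitRecords traitInfo
NULL

#' @rdname TraitPanel-accessors
#' @export
setMethod("traitRecords", "TraitPanel", function(x, ...) x@records)

#' @rdname TraitPanel-accessors
#' @export
setMethod("traitInfo", "TraitPanel", function(x, ...) x@traitInfo)

#' Accessors for SyntheticCohort
#'
#' @param x A \linkS4class{SyntheticCohort}.
#' @param ... ignored.
#' @return The corresponding component (see
#'   \linkS4class{SyntheticCohort}).
#' @name SyntheticCohort-accessors
#' @aliases betaMatrices cohortExpression cohortTraits cohortCovariates
#'   trueStatus
NULL

#' @rdname SyntheticCohort-accessors
#' @export
setMethod("betaMatrices", "SyntheticCohort", function(x, ...) x@betaMatrices)

#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortExpression", "SyntheticCohort", function(x, ...) x@expression)

#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortTraits", "SyntheticCohort", function(x, ...) x@traits)

#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortCovariates", "SyntheticCohort", function(x, ...) x@covariates)

#' @rdname SyntheticCohort-accessors
#' @export
setMethod("trueStatus", "SyntheticCohort", function(x, ...) {
    out <- x@truth$status
    names(out) <- rownames(x@truth)
    out
})

#' Accessors for StabilityReport
#'
#' @param x A \linkS4class{StabilityReport}.
#' @param ... ignored.
#' @return \code{concordance}: fraction of overlapping samples with an
#'   identical status at both time points; \code{discordantSamples}: ids of
#'   the samples whose status switched.
#' @name StabilityReport-accessors
#' @aliases concordance discordantSamples
NULL

#' @rdname StabilityReport-accessors
#' @export
setMethod("concordance", "StabilityReport", function(x, ...) x@concordance)

#' @rdname StabilityReport-accessors
#' @export
setMethod("discordantSamples", "StabilityReport", function(x, ...) x@discordant)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "StatusCalls", function(object) {
    tab <- table(object@calls$status)
    cat("StatusCalls with", nrow(object@calls), "samples over",
        length(object@cpgIds), "CpGs\n")
    cat("  status counts:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  full-methylation threshold: median beta >",
        object@fullThreshold, "; k =", object@k, "\n")
})

setMethod("show", "StabilityReport", function(object) {
    cat("StabilityReport over", object@nOverlap, "overlapping samples\n")
    cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n",
                object@rho, object@pValue))
    cat(sprintf("  status concordance = %.3f (%d discordant)\n",
                object@concordance, length(object@discordant)))
    if (length(object@discordant))
        cat("  discordant:", paste(utils::head(object@discordant, 10),
                                   collapse = ", "),
            if (length(object@discordant) > 10) "..." else "", "\n")
})

setMethod("show", "TraitPanel", function(object) {
    cat("TraitPanel:", nrow(object@records), "records,",
        length(unique(object@records$sample)), "samples,",
        nrow(object@traitInfo), "traits\n")
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort with", nrow(object@truth), "samples,",
        length(object@betaMatrices), "time point(s)\n")
    tab <- table(object@truth$status)
    cat("  true status counts:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  expression tables:", length(object@expression),
        "| trait records:", nrow(object@traits@records), "\n")
})
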