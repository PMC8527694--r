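#' @include AllClasses.R
NULL

#' Accessors
#'
#' Accessor generics for the package's classes.  \code{membership} returns
#' the sparse binary matrix of a [VariantMatrix-class] or
#' [BiomarkerMatrix-class]; \code{asvIds}/\code{sampleIds} the row/column
#' identities; \code{biomarkerOrder} the per-biomarker locus count;
#' \code{resultTable}/\code{fdrCurve} the per-group table and FDR curve of
#' a [DiffAbundanceResult-class]; \code{aucValues}, \code{medianAuc} and
#' \code{sdAuc} the per-repeat and summary AUCs of a
#' [PredictionEvaluation-class].
#'
#' @param x an object of the documented classes
#' @return the extracted component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("asvIds", function(x) standardGeneric("asvIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname accessors
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))
#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setGeneric("designMode", function(x) standardGeneric("designMode"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("biomarkerOrder", function(x) standardGeneric("biomarkerOrder"))
#' @rdname accessors
#' @export
setGeneric("biomarkerLabels", function(x) standardGeneric("biomarkerLabels"))
#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
#' @rdname accessors
#' @export
setGeneric("fdrCurve", function(x) standardGeneric("fdrCurve"))
#' @rdname accessors
#' @export
setGeneric("aucValues", function(x) standardGeneric("aucValues"))
#' @rdname accessors
#' @export
setGeneric("medianAuc", function(x) standardGeneric("medianAuc"))
#' @rdname accessors
#' @export
setGeneric("sdAuc", function(x) standardGeneric("sdAuc"))

#' @rdname accessors
#' @export
setMethod("asvIds", "AlignedSeqSet", function(x) names(x))
#' @rdname accessors
#' @export
setMethod("asvIds", "CountTable", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("asvIds", "RelAbundanceTable", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("asvIds", "VariantMatrix", function(x) rownames(x@membership))
#' @rdname accessors
#' @export
setMethod("asvIds", "BiomarkerMatrix", function(x) rownames(x@membership))
#' @rdname accessors
#' @export
setMethod("sampleIds", "CountTable", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "RelAbundanceTable", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "GroupAbundanceTable", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "StudyDesign", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("phenotype", "StudyDesign", function(x) {
    structure(x@phenotype, names = x@sampleIds)
})
#' @rdname accessors
#' @export
setMethod("pairId", "StudyDesign", function(x) {
    structure(x@pairId, names = x@sampleIds)
})
#' @rdname accessors
#' @export
setMethod("familyId", "StudyDesign", function(x) {
    structure(x@familyId, names = x@sampleIds)
})
#' @rdname accessors
#' @export
setMethod("designMode", "StudyDesign", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("membership", "VariantMatrix", function(x) x@membership)
#' @rdname accessors
#' @export
setMethod("membership", "BiomarkerMatrix", function(x) x@membership)
#' @rdname accessors
#' @export
setMethod("biomarkerOrder", "BiomarkerMatrix", function(x) {
    structure(x@order, names = colnames(x@membership))
})
#' @rdname accessors
#' @export
setMethod("biomarkerLabels", "BiomarkerMatrix", function(x) colnames(x@membership))
#' @rdname accessors
#' @export
setMethod("resultTable", "DiffAbundanceResult", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("fdrCurve", "DiffAbundanceResult", function(x) x@curve)
#' @rdname accessors
#' @export
setMethod("aucValues", "PredictionEvaluation", function(x) x@auc)
#' @rdname accessors
#' @export
setMethod("medianAuc", "PredictionEvaluation", function(x) stats::median(x@auc))
#' @rdname accessors
#' @export
setMethod("sdAuc", "PredictionEvaluation", function(x) stats::sd(x@auc))

setMethod("show", "StudyDesign", function(object) {
    cat(sprintf("StudyDesign: %d samples (%d case / %d control), mode=%s\n",
                length(object@sampleIds),
                sum(object@phenotype == "case"),
                sum(object@phenotype == "control"),
                object@mode))
    if (object@mode == "paired")
        cat(sprintf("  %d case-control pairs\n",
                    length(unique(object@pairId))))
    if (!all(is.na(object@familyId)))
        cat(sprintf("  %d families\n",
                    length(unique(object@familyId[!is.na(object@familyId)]))))
})

setMethod("show", "VariantMatrix", function(object) {
    cat(sprintf("VariantMatrix: %d ASVs x %d variants (density %.3f)\n",
                nrow(object@membership), ncol(object@membership),
                length(object@membership@i) /
                    max(1, prod(dim(object@membership)))))
})

setMethod("show", "BiomarkerMatrix", function(object) {
    tab <- table(object@order)
    cat(sprintf("BiomarkerMatrix: %d ASVs x %d biomarkers (%s)\n",
                nrow(object@membership), ncol(object@membership),
                paste(sprintf("order %s: %d", names(tab), tab),
                      collapse = ", ")))
})

setMethod("show", "NullDistribution", function(object) {
    cat(sprintf(
        "NullDistribution: %s, %s iterations over %d groups%s\n",
        object@mode, format(object@nIterations, big.mark = ","),
        length(object@groupIds),
        if (object@exhaustive) " (exhaustive sign-flip enumeration)" else ""))
})

setMethod("show", "DiffAbundanceResult", function(object) {
    cat(sprintf("DiffAbundanceResult: %d groups, %s mode, %s permutations\n",
                nrow(object@table), object@mode,
                format(object@nIterations, big.mark = ",")))
    for (q in c(0.05, 0.1, 0.25))
        cat(sprintf("  FDR < %.2f: %d groups (%.2f%%)\n", q,
                    sum(object@table$fdr < q),
                    100 * mean(object@table$fdr < q)))
})

setMethod("show", "PredictionEvaluation", function(object) {
    cat(sprintf(
        "PredictionEvaluation: median AUC %.3f (+/- 1 SD: %.3f), %d repeats of %d%%/%d%% splits\n",
        medianAuc(object), sdAuc(object), object@nRepeats,
        round(100 * (1 - object@testFraction)),
        round(100 * object@testFraction)))
})

setMethod("show", "SBBSimSpec", function(object) {
    cat(sprintf("SBBSimSpec: %d ASVs x %d columns, clade of %d, effect %.1f, %s\n",
                object@nAsvs, object@alignmentWidth, object@cladeSize,
                object@effectSize,
                if (object@mode == "paired")
                    sprintf("%d pairs", object@nPairs)
                else sprintf("%d case / %d control", object@nCase,
                             object@nControl)))
    cat(sprintf("  diagnostic loci: %s; depth %d; sparsity target %.2f; seed %d\n",
                paste(object@diagnosticLoci, collapse = ","),
                object@countDepth, object@sparsityTarget, object@seed))
})
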