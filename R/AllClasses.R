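#' @import methods
#' @importClassesFrom Matrix ngCMatrix
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Matrix colSums rowSums t fac2sparse sparseMatrix
#' @importFrom SummarizedExperiment assay assays assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.ALIGN_ALPHABET <- c("A", "C", "G", "T", "-")
.BASES <- c("A", "C", "G", "T")

#' Aligned ASV sequence set
#'
#' Holds the output of a multiple sequence alignment of ASV (amplicon
#' sequence variant) 16S sequences: equal-width gapped sequences over the
#' alphabet \code{A,C,G,T,-}, keyed by unique ASV identifiers.  Extends
#' \linkS4class{DNAStringSet}, so all \pkg{Biostrings} accessors
#' (\code{width}, \code{names}, subsetting) apply.
#'
#' Ambiguity codes (N, R, Y, ...) assert no single base and are mapped to
#' the gap state on construction; they never generate sequence variants.
#' U is mapped to T so RNA-alphabet inputs are tolerated.
#'
#' @seealso [readAlignedFasta()], [oneHotEncode()]
#' @export
setClass("AlignedSeqSet", contains = "DNAStringSet")

setValidity("AlignedSeqSet", function(object) {
    if (length(object) == 0L)
        return("alignment must contain at least one sequence")
    w <- Biostrings::width(object)
    if (length(unique(w)) != 1L)
        return(sprintf("ragged alignment: widths range %d-%d (first offending record: '%s')",
                       min(w), max(w),
                       names(object)[which(w != w[1L])[1L]]))
    if (w[1L] < 1L)
        return("alignment width must be >= 1")
    ids <- names(object)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        return("every sequence needs a non-empty ASV id")
    if (anyDuplicated(ids))
        return(sprintf("duplicate ASV id: '%s'", ids[duplicated(ids)][1L]))
    af <- Biostrings::alphabetFrequency(object)
    extra <- setdiff(colnames(af)[colSums(af) > 0], .ALIGN_ALPHABET)
    if (length(extra))
        return(sprintf("characters outside {A,C,G,T,-} present after normalization: %s",
                       paste(extra, collapse = ",")))
    TRUE
})

#' Construct an AlignedSeqSet
#'
#' @param x named character vector of aligned sequences, or an
#'   XStringSet with names.  Lowercase input is uppercased, U mapped to T,
#'   and ambiguity characters (anything outside \code{A,C,G,T,-}, including
#'   \code{.}) mapped to the gap state.
#' @return an [AlignedSeqSet-class] object
#' @examples
#' AlignedSeqSet(c(a1 = "ACG", a2 = "A-G"))
#' @export
AlignedSeqSet <- function(x) {
    if (is(x, "XStringSet")) {
        ids <- names(x)
        x <- as.character(x)
        names(x) <- ids
    }
    ids <- names(x)
    x <- toupper(x)
    x <- chartr("U", "T", x)
    x <- gsub("[^ACGT-]", "-", x)
    out <- new("AlignedSeqSet", Biostrings::DNAStringSet(x))
    names(out) <- ids
    validObject(out)
    out
}

#' ASV read-count table
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{counts} assay of
#' non-negative integers, rows = ASVs, columns = samples.  Samples with zero
#' total count are rejected at construction: relative-abundance
#' normalization is undefined for them.
#'
#' @seealso [readCountTable()], [relAbundance()]
#' @export
setClass("CountTable", contains = "SummarizedExperiment")

setValidity("CountTable", function(object) {
    if (!"counts" %in% assayNames(object))
        return("CountTable needs a 'counts' assay")
    m <- assay(object, "counts")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("counts need ASV row names and sample column names")
    if (anyDuplicated(rownames(m))) return("duplicate ASV ids")
    if (anyDuplicated(colnames(m))) return("duplicate sample ids")
    bad <- which(!is.finite(m) | m < 0 | m != round(m))
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(m))
        return(sprintf("count at (%s, %s) is not a non-negative integer: %s",
                       rownames(m)[rc[1L]], colnames(m)[rc[2L]], m[bad[1L]]))
    }
    tot <- colSums(m)
    if (any(tot == 0))
        return(sprintf("sample '%s' has zero total count",
                       colnames(m)[which(tot == 0)[1L]]))
    TRUE
})

#' @rdname CountTable-class
#' @param counts integer matrix, ASVs x samples, with dimnames
#' @export
CountTable <- function(counts) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    out <- new("CountTable", SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts)))
    validObject(out)
    out
}

#' Relative-abundance table
#'
#' ASV x sample proportions: each sample column sums to one.  Produced by
#' [relAbundance()].
#'
#' @export
setClass("RelAbundanceTable", contains = "SummarizedExperiment")

setValidity("RelAbundanceTable", function(object) {
    if (!"relabund" %in% assayNames(object))
        return("RelAbundanceTable needs a 'relabund' assay")
    m <- assay(object, "relabund")
    if (any(m < 0)) return("negative relative abundance")
    if (any(abs(colSums(m) - 1) > 1e-9))
        return("sample columns must sum to 1 (tolerance 1e-9)")
    TRUE
})

#' Group (biomarker) abundance table
#'
#' Groups x samples aggregate relative abundances.  Groups may overlap
#' (sequence-based biomarkers are not a partition of the ASVs), so columns
#' need not sum to one across groups, but every single entry lies in [0, 1].
#'
#' @export
setClass("GroupAbundanceTable", contains = "SummarizedExperiment")

setValidity("GroupAbundanceTable", function(object) {
    if (!"groupabund" %in% assayNames(object))
        return("GroupAbundanceTable needs a 'groupabund' assay")
    m <- assay(object, "groupabund")
    if (any(m < -1e-12)) return("negative group abundance")
    if (any(m > 1 + 1e-9)) return("group abundance above 1")
    TRUE
})

#' Case-control study design
#'
#' Sample-to-phenotype assignment with optional pair structure (each case
#' matched to one control, e.g. discordant sibling pairs) or family
#' structure (e.g. concordant twins).  \code{mode} selects the downstream
#' test: \code{"paired"} uses the Wilcoxon signed-rank statistic on
#' within-pair differences, \code{"unpaired"} the Mann-Whitney U statistic.
#'
#' @slot sampleIds character, unique sample identifiers
#' @slot phenotype character, one of \code{"case"}/\code{"control"} per sample
#' @slot pairId character, pair identifier per sample (NA when absent)
#' @slot familyId character, family identifier per sample (NA when absent)
#' @slot mode \code{"paired"} or \code{"unpaired"}
#' @seealso [readMetadata()], [permuteDesign()]
#' @export
setClass("StudyDesign", representation(
    sampleIds = "character",
    phenotype = "character",
    pairId = "character",
    familyId = "character",
    mode = "character"))

setValidity("StudyDesign", function(object) {
    n <- length(object@sampleIds)
    if (n < 2L) return("need at least two samples")
    if (anyDuplicated(object@sampleIds)) return("duplicate sample ids")
    if (length(object@phenotype) != n || length(object@pairId) != n ||
        length(object@familyId) != n)
        return("per-sample slots must all have one entry per sample")
    if (!all(object@phenotype %in% c("case", "control")))
        return(sprintf("unknown phenotype label: '%s'",
                       setdiff(object@phenotype, c("case", "control"))[1L]))
    if (!identical(object@mode, "paired") && !identical(object@mode, "unpaired"))
        return("mode must be 'paired' or 'unpaired'")
    if (object@mode == "paired") {
        if (anyNA(object@pairId))
            return("paired mode requires a pair id for every sample")
        tab <- split(object@phenotype, object@pairId)
        bad <- names(tab)[!vapply(tab, function(ph)
            length(ph) == 2L && setequal(ph, c("case", "control")), logical(1))]
        if (length(bad))
            return(sprintf("pair '%s' is not one case plus one control", bad[1L]))
    } else {
        if (!all(is.na(object@pairId)))
            return("unpaired mode must not carry pair ids")
    }
    TRUE
})

#' @rdname StudyDesign-class
#' @param sampleIds,phenotype,pairId,familyId per-sample vectors
#' @param mode \code{"paired"}, \code{"unpaired"}, or NULL to infer
#'   (paired iff \code{pairId} is fully populated)
#' @export
StudyDesign <- function(sampleIds, phenotype, pairId = NULL, familyId = NULL,
                        mode = NULL) {
    n <- length(sampleIds)
    if (is.null(pairId)) pairId <- rep(NA_character_, n)
    if (is.null(familyId)) familyId <- rep(NA_character_, n)
    if (is.null(mode)) mode <- if (!anyNA(pairId)) "paired" else "unpaired"
    new("StudyDesign", sampleIds = as.character(sampleIds),
        phenotype = as.character(phenotype),
        pairId = as.character(pairId), familyId = as.character(familyId),
        mode = mode)
}

#' One-hot variant encoding of an alignment
#'
#' Binary ASV x variant membership, where a variant is the presence of a
#' base (A, C, G or T) at a post-alignment column.  Gap and ambiguity
#' states generate no variant, so an ASV has at most one variant per
#' position.  Columns are ordered by position, then base A<C<G<T.
#'
#' @slot membership ngCMatrix, ASVs x variants
#' @slot position integer, 1-based alignment column per variant
#' @slot base character, one of A/C/G/T per variant
#' @seealso [oneHotEncode()]
#' @export
setClass("VariantMatrix", representation(
    membership = "ngCMatrix",
    position = "integer",
    base = "character"))

setValidity("VariantMatrix", function(object) {
    nv <- ncol(object@membership)
    if (length(object@position) != nv || length(object@base) != nv)
        return("one position and base per variant column")
    if (nv > 0) {
        if (any(object@position < 1L)) return("positions are 1-based")
        if (!all(object@base %in% .BASES)) return("variant bases must be A/C/G/T")
        if (any(colSums(object@membership) == 0))
            return("every stored variant must be observed in >= 1 ASV")
        perPos <- object@membership %*% t(fac2sparse(factor(object@position)))
        if (max(perPos) > 1)
            return("an ASV carries two bases at one position")
    }
    TRUE
})

#' Sparse biomarker membership matrix
#'
#' Binary ASV x biomarker membership for order-N sequence-based biomarkers
#' (N-locus combinations of variants at distinct positions).  An entry is
#' set iff the ASV carries every variant of the biomarker.  Only biomarkers
#' realized in at least one ASV are stored; the universe is data-derived,
#' never the full combinatorial space.  Column names are canonical labels
#' of the form \code{"12A/40C"} (positions ascending).
#'
#' @slot membership ngCMatrix, ASVs x biomarkers
#' @slot order integer per biomarker (1, 2 or 3; mixed after LD pruning)
#' @seealso [enumerateBiomarkers()], [ldPrune()]
#' @export
setClass("BiomarkerMatrix", representation(
    membership = "ngCMatrix",
    order = "integer"))

setValidity("BiomarkerMatrix", function(object) {
    m <- object@membership
    if (length(object@order) != ncol(m))
        return("one order per biomarker column")
    if (ncol(m) > 0) {
        if (!all(object@order %in% 1:3)) return("biomarker order must be 1, 2 or 3")
        if (is.null(colnames(m))) return("biomarker columns must be labelled")
        if (anyDuplicated(colnames(m))) return("duplicate biomarker labels")
        if (any(colSums(m) == 0))
            return("every stored biomarker must be carried by >= 1 ASV")
    }
    if (is.null(rownames(m))) return("rows must be named by ASV id")
    TRUE
})

#' Permutation null distribution
#'
#' Summary of the design-preserving permutation null of the per-group test
#' statistics.  Because signed-rank and centered Mann-Whitney statistics
#' live on an exact lattice (multiples of 1/4), the null is stored as
#' pooled exceedance counts over that lattice: \code{exceedance[i]} is the
#' total number of (group, iteration) null statistics with absolute value
#' \code{>= grid[i]}.  Memory is independent of the iteration count.
#'
#' @slot nIterations number of permutations summarized
#' @slot seed integer seed used (NA for exhaustive enumeration)
#' @slot mode "paired" or "unpaired"
#' @slot exhaustive TRUE when all 2^k sign patterns were enumerated
#' @slot grid ascending lattice of candidate |statistic| thresholds
#' @slot exceedance pooled null exceedance count per grid point
#' @slot groupIds groups the null was built on
#' @export
setClass("NullDistribution", representation(
    nIterations = "numeric",
    seed = "numeric",
    mode = "character",
    exhaustive = "logical",
    grid = "numeric",
    exceedance = "numeric",
    groupIds = "character"))

setValidity("NullDistribution", function(object) {
    if (length(object@grid) != length(object@exceedance))
        return("grid and exceedance must align")
    if (is.unsorted(object@grid)) return("grid must ascend")
    if (any(diff(object@exceedance) > 1e-9))
        return("exceedance counts must be non-increasing in the threshold")
    if (object@nIterations < 1) return("need >= 1 iteration")
    TRUE
})

#' Differential-abundance result
#'
#' Per-group observed statistic, direction (+1 case-enriched, -1
#' case-depleted) and permutation FDR estimate, plus the
#' fraction-significant-versus-FDR-cutoff curve.
#'
#' @slot table data.frame: group_id, order, statistic, direction, fdr
#' @slot curve data.frame: fdr_cutoff, fraction_significant
#' @slot nIterations,mode,seed provenance of the null
#' @seealso [sbbDiffAbundance()], [estimateFdr()]
#' @export
setClass("DiffAbundanceResult", representation(
    table = "data.frame",
    curve = "data.frame",
    nIterations = "numeric",
    mode = "character",
    seed = "numeric"))

#' Hierarchical clustering of significant biomarkers vs ASVs
#'
#' Agglomerative clustering (Hamming-fraction distance) of the binary
#' significant-biomarker x ASV matrix, on both axes.
#'
#' @slot biomarkerTree,asvTree \code{hclust} objects
#' @slot biomarkerClusters,asvClusters integer cluster labels (may be empty
#'   when no cut was requested)
#' @slot linkage linkage criterion used
#' @export
setClass("ClusterAssignment", representation(
    biomarkerTree = "ANY",
    asvTree = "ANY",
    biomarkerClusters = "integer",
    asvClusters = "integer",
    linkage = "character"))

#' Repeated-split phenotype-prediction evaluation
#'
#' Per-repeat ROC-AUC values of a random-forest classifier under repeated
#' stratified train/test splits, with a pointwise-median ROC band.
#'
#' @slot auc AUC per repeat
#' @slot roc data.frame: fpr, tpr_median, tpr_lo, tpr_hi (lo/hi = median -/+ 1 SD)
#' @slot nRepeats,testFraction,seed protocol parameters
#' @seealso [evaluatePrediction()]
#' @export
setClass("PredictionEvaluation", representation(
    auc = "numeric",
    roc = "data.frame",
    nRepeats = "integer",
    testFraction = "numeric",
    seed = "numeric"))

setValidity("PredictionEvaluation", function(object) {
    if (length(object@auc) != object@nRepeats)
        return("exactly one AUC per repeat")
    if (any(object@auc < 0 | object@auc > 1)) return("AUC must lie in [0,1]")
    TRUE
})

#' Synthetic-dataset specification
#'
#' Parameters of the clade-structured generator: sequences evolve from a
#' random root down a balanced binary tree; a planted clade shares a
#' diagnostic multi-locus biomarker found in no other ASV; case samples
#' have the clade's abundance multiplied by \code{effectSize}
#' (\code{effectSize = 1} is the null).  Defaults reflect the paired
#' discordant-pair study conditions used throughout the package's
#' validation: 60 pairs, effect size 4, 10,000 reads per sample.
#'
#' @seealso [sbbSimSpec()], [simulateAlignment()], [simulateCounts()]
#' @export
setClass("SBBSimSpec", representation(
    nAsvs = "integer",
    alignmentWidth = "integer",
    cladeSize = "integer",
    substitutionProb = "numeric",
    indelProb = "numeric",
    diagnosticLoci = "integer",
    mode = "character",
    nPairs = "integer",
    nCase = "integer",
    nControl = "integer",
    familySize = "integer",
    effectSize = "numeric",
    countDepth = "integer",
    sparsityTarget = "numeric",
    cladeBaseline = "numeric",
    theta = "numeric",
    seed = "integer"))

setValidity("SBBSimSpec", function(object) {
    if (object@nAsvs < 2L) return("need >= 2 ASVs")
    if (object@cladeSize < 1L || object@cladeSize > object@nAsvs %/% 2L)
        return("planted clade must have 1..nAsvs/2 members")
    if (length(object@diagnosticLoci) < 1L)
        return("need >= 1 diagnostic locus")
    if (max(object@diagnosticLoci) > object@alignmentWidth)
        return("alignment width too small to host the diagnostic loci")
    if (anyDuplicated(object@diagnosticLoci))
        return("diagnostic loci must be distinct positions")
    if (object@effectSize <= 0) return("effectSize must be > 0")
    if (object@sparsityTarget < 0 || object@sparsityTarget >= 1)
        return("sparsityTarget must lie in [0, 1)")
    if (object@cladeBaseline <= 0 || object@cladeBaseline >= 1)
        return("cladeBaseline must lie in (0, 1)")
    if (object@theta <= 0) return("theta must be > 0")
    if (object@mode == "paired" && object@nPairs < 2L)
        return("need >= 2 pairs")
    if (object@mode == "unpaired" &&
        (object@nCase < 2L || object@nControl < 2L))
        return("need >= 2 case and >= 2 control samples")
    TRUE
})
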