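#' @include AllClasses.R
NULL

#' Binary matrix of significant biomarkers versus their carrier ASVs
#'
#' Restricts a biomarker membership matrix to the biomarkers whose
#' permutation FDR falls below \code{fdrCutoff}, and to the ASVs carrying
#' at least one retained biomarker.  Rows are biomarkers, columns ASVs --
#' the object that is hierarchically clustered to reveal conserved groups
#' of bacteria sharing many significant biomarkers.
#'
#' @param result a [DiffAbundanceResult-class]
#' @param bm the [BiomarkerMatrix-class] the groups came from
#' @param fdrCutoff retain biomarkers with FDR strictly below this value
#' @return binary base matrix (0/1), significant biomarkers x carrier ASVs;
#'   zero rows (with a warning) when nothing passes
#' @export
significantBiomarkers <- function(result, bm, fdrCutoff = 0.1) {
    stopifnot(is(result, "DiffAbundanceResult"), is(bm, "BiomarkerMatrix"))
    tab <- result@table
    keep <- tab$group_id[tab$fdr < fdrCutoff]
    keep <- intersect(colnames(bm@membership), keep)
    if (length(keep) == 0L) {
        warning("no biomarker passes FDR < ", fdrCutoff)
        return(matrix(0, 0L, 0L))
    }
    sub <- bm@membership[, keep, drop = FALSE]
    carriers <- rowSums(sub) > 0
    sm <- t(as.matrix(sub[carriers, , drop = FALSE])) * 1
    sm
}

# fraction of mismatching entries between binary rows
.hammingFraction <- function(x) {
    stats::dist(x, method = "manhattan") / ncol(x)
}

#' Hierarchically cluster significant biomarkers and their ASVs
#'
#' Agglomerative clustering of the binary biomarker x ASV matrix using the
#' Hamming distance expressed as the fraction of mismatching entries, on
#' both axes.  \code{stats::hclust} merges are deterministic given the
#' input (ties broken by lowest pairwise index).  Cluster labels are
#' assigned when a cut (\code{k} clusters or height \code{h}) is
#' requested; the cut is deliberately user-supplied, since the number of
#' conserved groups is a judgement call.
#'
#' @param sm binary matrix from [significantBiomarkers()] (>= 1 row)
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"single"}
#' @param k,h optional cut: number of clusters, or merge height
#' @return a [ClusterAssignment-class]
#' @export
clusterBiomarkers <- function(sm, linkage = c("average", "complete", "single"),
                              k = NULL, h = NULL) {
    linkage <- match.arg(linkage)
    if (!is.matrix(sm) || nrow(sm) == 0L)
        stop("need a non-empty biomarker x ASV matrix")
    cutLabels <- function(tree, n, nms) {
        if (is.null(tree))
            return(structure(rep(1L, n), names = nms))
        if (!is.null(k)) return(stats::cutree(tree, k = min(k, n)))
        if (!is.null(h)) return(stats::cutree(tree, h = h))
        structure(integer(0), names = character(0))
    }
    bioTree <- if (nrow(sm) >= 2L)
        stats::hclust(.hammingFraction(sm), method = linkage) else NULL
    asvTree <- if (ncol(sm) >= 2L)
        stats::hclust(.hammingFraction(t(sm)), method = linkage) else NULL
    new("ClusterAssignment",
        biomarkerTree = bioTree, asvTree = asvTree,
        biomarkerClusters = cutLabels(bioTree, nrow(sm), rownames(sm)),
        asvClusters = cutLabels(asvTree, ncol(sm), colnames(sm)),
        linkage = linkage)
}

setMethod("show", "ClusterAssignment", function(object) {
    nb <- if (is.null(object@biomarkerTree)) 1L
          else length(object@biomarkerTree$order)
    na <- if (is.null(object@asvTree)) 1L else length(object@asvTree$order)
    cat(sprintf("ClusterAssignment: %d biomarkers x %d ASVs, %s linkage, Hamming-fraction distance\n",
                nb, na, object@linkage))
    if (length(object@biomarkerClusters))
        cat(sprintf("  biomarker clusters: %d\n",
                    length(unique(object@biomarkerClusters))))
})

#' Per-phenotype abundance summary for one group
#'
#' Medians and quartiles of a group's abundance in cases and controls,
#' plus per-pair (case minus control) differences for paired designs --
#' the numbers behind a per-biomarker enrichment boxplot.
#'
#' @param ga a [GroupAbundanceTable-class]
#' @param design a [StudyDesign-class]
#' @param groupId one group (biomarker label) present in \code{ga}
#' @return list with \code{summary} (data.frame: phenotype, n, q1, median,
#'   q3) and, for paired designs, \code{pairDifferences} (named by pair id)
#' @export
summarizeGroup <- function(ga, design, groupId) {
    stopifnot(is(ga, "GroupAbundanceTable"), is(design, "StudyDesign"))
    M <- assay(ga, "groupabund")
    if (!groupId %in% rownames(M)) stop("unknown group: ", groupId)
    v <- M[groupId, ]
    smry <- do.call(rbind, lapply(c("case", "control"), function(ph) {
        x <- v[design@sampleIds[design@phenotype == ph]]
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(phenotype = ph, n = length(x), q1 = q[1L],
                   median = q[2L], q3 = q[3L], stringsAsFactors = FALSE)
    }))
    out <- list(summary = smry)
    if (design@mode == "paired") {
        pp <- .pairIndices(design, colnames(M))
        d <- v[pp$case] - v[pp$control]
        names(d) <- unique(design@pairId)
        out$pairDifferences <- d
    }
    out
}
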