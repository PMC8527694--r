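#' @include AllClasses.R
NULL

#' Normalize read counts to relative abundance
#'
#' Divides each ASV's count by its sample's total, so each sample column
#' sums to one.  Relative abundance is the only normalization used:
#' downstream inference is nonparametric and permutation-based, so
#' compositional artefacts are absorbed by the permuted null rather than
#' modelled.
#'
#' @param counts a [CountTable-class] (zero-total samples are rejected at
#'   construction, so the division is always defined)
#' @return a [RelAbundanceTable-class]
#' @examples
#' ct <- CountTable(matrix(c(2, 3, 5, 0, 1, 9), 3,
#'                  dimnames = list(paste0("a", 1:3), c("s1", "s2"))))
#' assay(relAbundance(ct))
#' @export
relAbundance <- function(counts) {
    stopifnot(is(counts, "CountTable"))
    m <- assay(counts, "counts")
    r <- sweep(m, 2L, colSums(m), "/")
    out <- new("RelAbundanceTable", SummarizedExperiment::SummarizedExperiment(
        assays = list(relabund = r)))
    validObject(out)
    out
}

#' Aggregate relative abundance over ASV groups
#'
#' Computes each group's abundance in each sample as the sum of the
#' relative abundances of its member ASVs, i.e. the matrix product of the
#' transposed binary membership with the relative-abundance matrix.
#' Groups may overlap (sequence-based biomarkers are not a partition), so
#' no renormalization across groups is performed.
#'
#' ASVs present in \code{rel} but absent from the membership contribute to
#' no group; a membership row naming an ASV unknown to \code{rel} is an
#' error.
#'
#' @param rel a [RelAbundanceTable-class]
#' @param groups a [BiomarkerMatrix-class], or any binary matrix
#'   (base or \pkg{Matrix}) with ASV row names and group column names
#' @return a [GroupAbundanceTable-class]; when \code{groups} is a
#'   [BiomarkerMatrix-class] the biomarker order is carried in
#'   \code{rowData}
#' @export
aggregateByGroup <- function(rel, groups) {
    stopifnot(is(rel, "RelAbundanceTable"))
    ord <- NULL
    if (is(groups, "BiomarkerMatrix")) {
        ord <- groups@order
        groups <- groups@membership
    }
    if (is.null(rownames(groups)) || is.null(colnames(groups)))
        stop("group membership needs ASV row names and group column names")
    unknown <- setdiff(rownames(groups), asvIds(rel))
    if (length(unknown))
        stop("membership references ASV(s) absent from the abundance table: ",
             paste(utils::head(unknown, 5L), collapse = ", "))
    B <- as(as(Matrix::Matrix(groups, sparse = TRUE), "dMatrix"),
            "CsparseMatrix")
    R <- assay(rel, "relabund")[rownames(groups), , drop = FALSE]
    vals <- as.matrix(Matrix::crossprod(B, R))
    dimnames(vals) <- list(colnames(groups), colnames(R))
    rd <- if (!is.null(ord)) S4Vectors::DataFrame(order = ord) else NULL
    out <- new("GroupAbundanceTable",
               SummarizedExperiment::SummarizedExperiment(
                   assays = list(groupabund = vals),
                   rowData = rd))
    validObject(out)
    out
}
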