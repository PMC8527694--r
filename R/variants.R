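#' @include AllClasses.R
NULL

#' One-hot encode an aligned sequence set
#'
#' Converts the alignment into a sparse binary ASV x variant matrix, where
#' a variant is the presence of one base (A, C, G or T) at one
#' post-alignment column.  Only variants observed in at least one ASV get
#' a column.  Gaps (and the ambiguity characters mapped to gaps on read)
#' generate no variant, so each ASV carries at most one variant per
#' position -- exactly one where its character is a base.
#'
#' Columns are ordered deterministically by position, then base A<C<G<T,
#' and labelled \code{"<position><base>"} (1-based positions), e.g.
#' \code{"12A"}.
#'
#' @param seqs an [AlignedSeqSet-class]
#' @return a [VariantMatrix-class]
#' @examples
#' vm <- oneHotEncode(AlignedSeqSet(c(a1 = "ACG", a2 = "A-G")))
#' membership(vm)
#' @export
oneHotEncode <- function(seqs) {
    if (!is(seqs, "AlignedSeqSet")) seqs <- AlignedSeqSet(seqs)
    if (length(seqs) == 0L) stop("empty sequence set")
    L <- as.matrix(seqs)                       # ASVs x columns, characters
    nA <- nrow(L)
    triplets <- lapply(seq_along(.BASES), function(b) {
        w <- which(L == .BASES[b], arr.ind = TRUE, useNames = FALSE)
        cbind(w[, 1L], (w[, 2L] - 1L) * 4L + b) # (asv, variant code)
    })
    tri <- do.call(rbind, triplets)
    if (nrow(tri) == 0L) {                     # all-gap alignment
        m <- sparseMatrix(i = integer(0), j = integer(0),
                          dims = c(nA, 0L),
                          dimnames = list(names(seqs), character(0)))
        return(new("VariantMatrix", membership = as(m, "ngCMatrix"),
                   position = integer(0), base = character(0)))
    }
    codes <- sort(unique(tri[, 2L]))           # position-major, base-minor
    pos <- (codes - 1L) %/% 4L + 1L
    base <- .BASES[(codes - 1L) %% 4L + 1L]
    m <- sparseMatrix(i = tri[, 1L], j = findInterval(tri[, 2L], codes),
                      dims = c(nA, length(codes)),
                      dimnames = list(names(seqs), paste0(pos, base)))
    new("VariantMatrix", membership = as(m, "ngCMatrix"),
        position = as.integer(pos), base = base)
}
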