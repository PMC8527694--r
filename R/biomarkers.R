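#' @include AllClasses.R variants.R
NULL

.bmLabel <- function(vm, vIdx) {
    # vIdx: matrix order x n of variant column indices (positions ascending)
    apply(vIdx, 2L, function(v)
        paste0(vm@position[v], vm@base[v], collapse = "/"))
}

.newBiomarkerMatrix <- function(m, order, labels = NULL) {
    if (!is.null(labels)) colnames(m) <- labels
    new("BiomarkerMatrix", membership = as(m, "ngCMatrix"),
        order = as.integer(order))
}

.subsetBiomarkers <- function(bm, j) {
    new("BiomarkerMatrix", membership = bm@membership[, j, drop = FALSE],
        order = bm@order[j])
}

#' Enumerate order-N sequence-based biomarkers
#'
#' For each ASV, emits every combination of \code{order} of its variants
#' (necessarily at distinct positions, since an ASV carries at most one
#' base per position).  The biomarker universe is the union of realized
#' combinations over all ASVs -- never the full combinatorial space -- and
#' the membership bit for (ASV, biomarker) is set iff the ASV carries every
#' variant of the biomarker.  This is the per-row outer-product ("square
#' product" / "cube") construction on the one-hot matrix, carried out
#' sparsely.
#'
#' Biomarker columns are ordered deterministically by their variant index
#' tuples (position-major), and labelled canonically with positions
#' ascending, e.g. \code{"1A/2C/3G"}.
#'
#' @param vm a [VariantMatrix-class] from [oneHotEncode()]
#' @param order number of loci per biomarker: 1, 2 or 3
#' @return a [BiomarkerMatrix-class]
#' @examples
#' vm <- oneHotEncode(AlignedSeqSet(c(a1 = "ACG")))
#' biomarkerLabels(enumerateBiomarkers(vm, 2))  # "1A/2C" "1A/3G" "2C/3G"
#' @export
enumerateBiomarkers <- function(vm, order) {
    stopifnot(is(vm, "VariantMatrix"))
    if (length(order) != 1L || is.na(order) || !(order %in% 1:3))
        stop("order must be 1, 2 or 3")
    order <- as.integer(order)
    m <- vm@membership
    nA <- nrow(m)
    if (order == 1L)
        return(.newBiomarkerMatrix(m, rep(1L, ncol(m))))

    tm <- as(t(m), "CsparseMatrix")     # variants x ASVs; @i sorted per column
    p <- tm@p
    vi <- tm@i + 1L                     # 1-based variant indices
    M0 <- as.double(ncol(m) + 1L)       # radix for exact double keys

    keyList <- vector("list", nA)
    for (a in seq_len(nA)) {
        v <- vi[seq.int(p[a] + 1L, length.out = p[a + 1L] - p[a])]
        if (length(v) < order) next
        cmb <- utils::combn(as.double(v), order)
        keyList[[a]] <- if (order == 2L) cmb[1L, ] * M0 + cmb[2L, ]
                        else (cmb[1L, ] * M0 + cmb[2L, ]) * M0 + cmb[3L, ]
    }
    lens <- lengths(keyList)
    if (sum(lens) == 0) {
        empty <- sparseMatrix(i = integer(0), j = integer(0),
                              dims = c(nA, 0L),
                              dimnames = list(rownames(m), character(0)))
        return(.newBiomarkerMatrix(empty, integer(0)))
    }
    allKeys <- unlist(keyList, use.names = FALSE)
    ukeys <- sort(unique(allKeys))
    res <- sparseMatrix(i = rep.int(seq_len(nA), lens),
                        j = findInterval(allKeys, ukeys),
                        dims = c(nA, length(ukeys)),
                        dimnames = list(rownames(m), NULL))
    if (order == 2L) {
        v2 <- ukeys %% M0
        v1 <- (ukeys - v2) / M0
        vIdx <- rbind(v1, v2)
    } else {
        v3 <- ukeys %% M0
        r <- (ukeys - v3) / M0
        v2 <- r %% M0
        v1 <- (r - v2) / M0
        vIdx <- rbind(v1, v2, v3)
    }
    .newBiomarkerMatrix(res, rep(order, length(ukeys)), .bmLabel(vm, vIdx))
}

#' Drop uninformative (universal) biomarkers
#'
#' Removes biomarkers carried by every ASV in the dataset: their aggregate
#' relative abundance is identically 1 in every sample, so no differential
#' test on them is meaningful.  Biomarkers carried by zero ASVs cannot
#' exist by construction.  Low-prevalence biomarkers are deliberately
#' retained -- rare but highly abundant ASVs are informative, and no
#' prevalence filter is applied.
#'
#' @param bm a [BiomarkerMatrix-class]
#' @return the filtered [BiomarkerMatrix-class]
#' @export
filterUninformative <- function(bm) {
    stopifnot(is(bm, "BiomarkerMatrix"))
    universal <- colSums(bm@membership) == nrow(bm@membership)
    if (all(universal) && ncol(bm@membership) > 0L)
        warning("every biomarker is carried by all ASVs; empty result")
    .subsetBiomarkers(bm, !universal)
}

#' Prune biomarkers in complete linkage disequilibrium
#'
#' Two biomarkers are in complete LD when exactly the same set of ASVs
#' carries both, i.e. their membership columns are bitwise identical; they
#' then aggregate to identical group abundances and are redundant.  This
#' collapses each equivalence class of identical columns to one
#' representative: the member of lowest order, breaking ties by the
#' lexicographically smallest canonical label.
#'
#' When several matrices (e.g. orders 1 and 2) are supplied, pruning is by
#' default performed jointly across orders; set \code{acrossOrders = FALSE}
#' to prune each order's matrix separately (duplicates may then persist
#' between orders).  Both scopes are exposed because either is defensible;
#' the joint default removes all redundancy.
#'
#' @param bms a [BiomarkerMatrix-class] or a list of them sharing one ASV axis
#' @param acrossOrders collapse classes across input matrices (default) or
#'   within each matrix only
#' @return a list with elements \code{pruned} (a [BiomarkerMatrix-class] of
#'   the representatives, in the combined input column order) and
#'   \code{classes} (data.frame with columns \code{representative},
#'   \code{member}, \code{order}; every biomarker appears exactly once as a
#'   member, representatives included)
#' @examples
#' vm <- oneHotEncode(AlignedSeqSet(c(a1 = "ACG", a2 = "ATG")))
#' pr <- ldPrune(enumerateBiomarkers(vm, 1))
#' pr$classes
#' @export
ldPrune <- function(bms, acrossOrders = TRUE) {
    if (is(bms, "BiomarkerMatrix")) bms <- list(bms)
    stopifnot(length(bms) >= 1L,
              all(vapply(bms, is, logical(1), "BiomarkerMatrix")))
    ids <- rownames(bms[[1L]]@membership)
    for (b in bms[-1L])
        if (!identical(rownames(b@membership), ids))
            stop("biomarker matrices do not share the same ASV axis")

    if (!acrossOrders && length(bms) > 1L) {
        parts <- lapply(bms, ldPrune, acrossOrders = TRUE)
        pruned <- .combineBiomarkers(lapply(parts, `[[`, "pruned"))
        classes <- do.call(rbind, lapply(parts, `[[`, "classes"))
        rownames(classes) <- NULL
        return(list(pruned = pruned, classes = classes))
    }

    full <- .combineBiomarkers(bms)
    m <- full@membership
    nb <- ncol(m)
    if (nb == 0L)
        return(list(pruned = full,
                    classes = data.frame(representative = character(0),
                                         member = character(0),
                                         order = integer(0))))
    colFac <- factor(rep.int(seq_len(nb), diff(m@p)), levels = seq_len(nb))
    sigs <- vapply(split(m@i, colFac), paste, character(1), collapse = ",")
    classes <- split(seq_len(nb), sigs)
    labels <- colnames(m)
    repIdx <- vapply(classes, function(memb) {
        memb[order(full@order[memb], labels[memb])[1L]]
    }, integer(1))
    keep <- sort(unname(repIdx))
    classDf <- do.call(rbind, lapply(seq_along(classes), function(k) {
        memb <- classes[[k]]
        memb <- memb[order(full@order[memb], labels[memb])]
        data.frame(representative = labels[repIdx[k]],
                   member = labels[memb], order = full@order[memb],
                   stringsAsFactors = FALSE)
    }))
    classDf <- classDf[order(match(classDf$representative, labels)), ]
    rownames(classDf) <- NULL
    list(pruned = .subsetBiomarkers(full, keep), classes = classDf)
}

# column-bind biomarker matrices sharing an ASV axis; duplicate labels
# (same biomarker fed twice) are collapsed to their first occurrence
.combineBiomarkers <- function(bms) {
    if (length(bms) == 1L) return(bms[[1L]])
    ids <- rownames(bms[[1L]]@membership)
    for (b in bms[-1L])
        if (!identical(rownames(b@membership), ids))
            stop("biomarker matrices do not share the same ASV axis")
    m <- do.call(cbind, lapply(bms, slot, "membership"))
    ord <- unlist(lapply(bms, slot, "order"), use.names = FALSE)
    dup <- duplicated(colnames(m))
    new("BiomarkerMatrix", membership = as(m[, !dup, drop = FALSE],
                                           "ngCMatrix"),
        order = as.integer(ord[!dup]))
}

#' Extract biomarkers of several orders from an alignment
#'
#' Convenience wrapper: one-hot encodes the alignment, enumerates
#' biomarkers at each requested order, drops universal biomarkers, and
#' (optionally) LD-prunes the combined set.
#'
#' @param seqs an [AlignedSeqSet-class]
#' @param orders subset of \code{1:3}
#' @param prune perform LD pruning (default TRUE)
#' @param acrossOrders see [ldPrune()]
#' @param keepUniversal keep biomarkers carried by all ASVs (default FALSE)
#' @return a list: \code{biomarkers} (a [BiomarkerMatrix-class]),
#'   \code{classes} (LD class data.frame, NULL when \code{prune = FALSE}),
#'   \code{variants} (the [VariantMatrix-class])
#' @export
extractBiomarkers <- function(seqs, orders = c(1L, 2L), prune = TRUE,
                              acrossOrders = TRUE, keepUniversal = FALSE) {
    orders <- sort(unique(as.integer(orders)))
    if (length(orders) == 0L || !all(orders %in% 1:3))
        stop("orders must be a non-empty subset of {1, 2, 3}")
    vm <- oneHotEncode(seqs)
    bms <- lapply(orders, function(N) {
        b <- enumerateBiomarkers(vm, N)
        if (!keepUniversal) b <- filterUninformative(b)
        b
    })
    if (prune) {
        pr <- ldPrune(bms, acrossOrders = acrossOrders)
        list(biomarkers = pr$pruned, classes = pr$classes, variants = vm)
    } else {
        list(biomarkers = .combineBiomarkers(bms), classes = NULL,
             variants = vm)
    }
}
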