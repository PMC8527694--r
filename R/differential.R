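#' @include AllClasses.R
NULL

# case/control column indices per pair, in order of first appearance
.pairIndices <- function(design, sampleOrder) {
    loc <- match(design@sampleIds, sampleOrder)
    if (anyNA(loc)) stop("design samples missing from the abundance table")
    pid <- factor(design@pairId, levels = unique(design@pairId))
    sp <- split(seq_along(design@sampleIds), pid)
    caseIdx <- vapply(sp, function(ii)
        loc[ii[design@phenotype[ii] == "case"]], integer(1))
    ctrlIdx <- vapply(sp, function(ii)
        loc[ii[design@phenotype[ii] == "control"]], integer(1))
    list(case = caseIdx, control = ctrlIdx)
}

# per-row signed midranks of within-pair differences; zeros dropped (rank 0)
.signedRanks <- function(D) {
    out <- apply(D, 1L, function(d) {
        r <- numeric(length(d))
        nz <- d != 0
        if (any(nz)) r[nz] <- sign(d[nz]) * rank(abs(d[nz]))
        r
    })
    # apply transposes; restore groups x pairs
    if (is.null(dim(out))) out <- matrix(out, ncol = 1L)
    t(out)
}

# per-row midranks across all samples
.rowRanks <- function(M) {
    out <- apply(M, 1L, rank)
    if (is.null(dim(out))) out <- matrix(out, ncol = 1L)
    t(out)
}

.checkDesignSize <- function(design) {
    nCase <- sum(design@phenotype == "case")
    nCtrl <- sum(design@phenotype == "control")
    if (nCase < 2L || nCtrl < 2L)
        stop("insufficient data: need >= 2 samples per phenotype")
}

#' Per-group nonparametric test statistics
#'
#' Computes one centered test statistic per group, oriented so that larger
#' magnitude means stronger differential signal and positive sign means
#' case-enriched.  Paired designs use the Wilcoxon signed-rank statistic on
#' within-pair (case minus control) differences, centered at its null mean
#' (zero differences dropped, midranks for ties); unpaired designs use the
#' Mann-Whitney U statistic for the case group, centered at
#' \eqn{n_1 n_2 / 2}.  Groups with identical abundance in every sample
#' (e.g. all zero) receive the null-center statistic 0.
#'
#' Computation is independent across groups (embarrassingly parallel); the
#' implementation vectorizes it as rank-matrix algebra, so results are
#' invariant to any chunking or evaluation order.
#'
#' @param ga a [GroupAbundanceTable-class]
#' @param design a [StudyDesign-class] on the same samples
#' @return data.frame with columns \code{group_id}, \code{statistic},
#'   \code{direction} (sign of the statistic)
#' @export
computeGroupStatistics <- function(ga, design) {
    stopifnot(is(ga, "GroupAbundanceTable"), is(design, "StudyDesign"))
    .checkDesignSize(design)
    M <- assay(ga, "groupabund")
    if (design@mode == "paired") {
        pp <- .pairIndices(design, colnames(M))
        D <- M[, pp$case, drop = FALSE] - M[, pp$control, drop = FALSE]
        stat <- rowSums(.signedRanks(D)) / 2
    } else {
        loc <- match(design@sampleIds, colnames(M))
        if (anyNA(loc)) stop("design samples missing from the abundance table")
        Rk <- .rowRanks(M[, loc, drop = FALSE])
        isCase <- design@phenotype == "case"
        n1 <- sum(isCase)
        n <- length(isCase)
        stat <- rowSums(Rk[, isCase, drop = FALSE]) - n1 * (n + 1) / 2
    }
    data.frame(group_id = rownames(M), statistic = unname(stat),
               direction = sign(unname(stat)), stringsAsFactors = FALSE)
}

#' Permute phenotype labels, preserving the study structure
#'
#' Draws one structure-preserving relabelling using the current RNG state.
#' Paired mode: each pair independently keeps or swaps both of its labels
#' with probability 1/2.  Unpaired mode: per-family phenotype label
#' vectors are permuted among families of equal size (samples without a
#' family id are singleton families), which preserves both within-family
#' concordance patterns and the exact overall case/control counts.
#'
#' @param design a [StudyDesign-class]
#' @return a relabelled [StudyDesign-class]
#' @export
permuteDesign <- function(design) {
    stopifnot(is(design, "StudyDesign"))
    ph <- design@phenotype
    if (design@mode == "paired") {
        pid <- factor(design@pairId, levels = unique(design@pairId))
        swap <- stats::runif(nlevels(pid)) < 0.5
        flip <- swap[as.integer(pid)]
        ph[flip] <- ifelse(ph[flip] == "case", "control", "case")
    } else {
        fid <- design@familyId
        nas <- which(is.na(fid))
        fid[nas] <- paste0(".singleton.", seq_along(nas))
        fams <- split(seq_along(fid), factor(fid, levels = unique(fid)))
        sizes <- lengths(fams)
        for (s in unique(sizes)) {
            grp <- which(sizes == s)
            src <- grp[sample.int(length(grp))]
            for (j in seq_along(grp))
                ph[fams[[grp[j]]]] <- design@phenotype[fams[[src[j]]]]
        }
    }
    new("StudyDesign", sampleIds = design@sampleIds, phenotype = ph,
        pairId = design@pairId, familyId = design@familyId,
        mode = design@mode)
}

.chunkSizes <- function(total, chunkSize) {
    n <- ceiling(total / chunkSize)
    sizes <- rep(chunkSize, n)
    sizes[n] <- total - chunkSize * (n - 1)
    as.integer(sizes)
}

# draw chunk matrices sequentially (RNG order fixed), tabulate bin indices
# of the permuted statistics; only the RNG-free tabulation is parallelized
.chunkedTabulate <- function(sizes, gen, binFun, gridN, threads) {
    if (threads > 1L && .Platform$OS.type == "unix") {
        mats <- lapply(sizes, gen)
        as.numeric(Reduce(`+`, parallel::mclapply(mats, function(S)
            tabulate(binFun(S), nbins = gridN), mc.cores = threads)))
    } else {
        counts <- numeric(gridN)
        for (c0 in sizes)
            counts <- counts + tabulate(binFun(gen(c0)), nbins = gridN)
        counts
    }
}

# all 2^k sign patterns for pattern indices lo..hi (0-based), as k x n matrix
.signPatterns <- function(k, lo, hi) {
    idx <- lo:hi
    S <- matrix(0, nrow = k, ncol = length(idx))
    for (b in seq_len(k))
        S[b, ] <- ifelse(bitwAnd(idx, bitwShiftL(1L, b - 1L)) > 0, 1, -1)
    S
}

#' Build the permutation null distribution
#'
#' Recomputes the per-group statistics of [computeGroupStatistics()] under
#' structure-preserving label permutations and accumulates a pooled
#' exceedance summary.  Ranks are invariant under relabelling, so the
#' permuted statistics reduce to products of a fixed (signed-)rank matrix
#' with per-iteration sign or indicator vectors; iterations are processed
#' in chunks and memory never scales with \code{nGroups * nIterations}.
#'
#' For paired designs with at most 20 pairs and \code{2^k <= nIterations},
#' all \code{2^k} sign patterns are enumerated instead of sampled
#' (\code{exhaustive = "auto"}), giving the exact permutation distribution.
#'
#' @param ga a [GroupAbundanceTable-class]
#' @param design a [StudyDesign-class]
#' @param nIterations number of permutations (default 100,000)
#' @param seed integer seed; NULL uses the current RNG state
#' @param exhaustive \code{"auto"}, \code{"never"} or \code{"always"}
#' @param chunkSize iterations per chunk
#' @param threads worker processes for the chunked statistic computation
#'   (the permutation matrices are always drawn sequentially from the seeded
#'   RNG, so results are identical for any thread count)
#' @param identityPermutation diagnostic: force every iteration to the
#'   identity relabelling
#' @return a [NullDistribution-class]
#' @export
buildNullDistribution <- function(ga, design, nIterations = 1e5,
                                  seed = NULL,
                                  exhaustive = c("auto", "never", "always"),
                                  chunkSize = 512L, threads = 1L,
                                  identityPermutation = FALSE) {
    stopifnot(is(ga, "GroupAbundanceTable"), is(design, "StudyDesign"))
    exhaustive <- match.arg(exhaustive)
    if (nIterations < 1) stop("need >= 1 iteration")
    .checkDesignSize(design)
    if (!is.null(seed)) set.seed(seed)
    M <- assay(ga, "groupabund")

    if (design@mode == "paired") {
        pp <- .pairIndices(design, colnames(M))
        k <- length(pp$case)
        SR <- .signedRanks(M[, pp$case, drop = FALSE] -
                           M[, pp$control, drop = FALSE])
        doExhaustive <- !identityPermutation && switch(exhaustive,
            auto = k <= 20L && 2^k <= nIterations,
            always = TRUE, never = FALSE)
        if (doExhaustive && k > 25L)
            stop("exhaustive enumeration limited to <= 25 pairs")
        maxStat <- k * (k + 1) / 4
        grid <- seq(0, maxStat, by = 0.25)
        counts <- numeric(length(grid))
        if (doExhaustive) {
            total <- 2^k
            starts <- seq(0, total - 1, by = chunkSize)
            for (lo in starts) {
                hi <- min(lo + chunkSize - 1, total - 1)
                st <- abs(SR %*% .signPatterns(k, lo, hi)) / 2
                counts <- counts + tabulate(round(st * 4) + 1L,
                                            nbins = length(grid))
            }
            nIterations <- total
        } else {
            gen <- function(c0) {
                if (identityPermutation) matrix(1, k, c0)
                else matrix(sample(c(-1, 1), k * c0, replace = TRUE), k, c0)
            }
            binFun <- function(S) round(abs(SR %*% S) * 2) + 1L
            counts <- .chunkedTabulate(.chunkSizes(nIterations, chunkSize),
                                       gen, binFun, length(grid), threads)
        }
        return(new("NullDistribution", nIterations = nIterations,
                   seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
                   mode = "paired",
                   exhaustive = isTRUE(doExhaustive),
                   grid = grid, exceedance = rev(cumsum(rev(counts))),
                   groupIds = rownames(M)))
    }

    # unpaired: centered Mann-Whitney via rank sums over permuted labels
    loc <- match(design@sampleIds, colnames(M))
    if (anyNA(loc)) stop("design samples missing from the abundance table")
    Rk <- .rowRanks(M[, loc, drop = FALSE])
    n <- length(design@sampleIds)
    n1 <- sum(design@phenotype == "case")
    n2 <- n - n1
    center <- n1 * (n + 1) / 2
    maxStat <- n1 * n2 / 2
    grid <- seq(0, maxStat, by = 0.25)
    gen <- function(c0) {
        Z <- matrix(0, n, c0)
        for (j in seq_len(c0)) {
            d <- if (identityPermutation) design else permuteDesign(design)
            Z[d@phenotype == "case", j] <- 1
        }
        Z
    }
    binFun <- function(Z) round(abs(Rk %*% Z - center) * 4) + 1L
    counts <- .chunkedTabulate(.chunkSizes(nIterations, chunkSize),
                               gen, binFun, length(grid), threads)
    new("NullDistribution", nIterations = nIterations,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
        mode = "unpaired", exhaustive = FALSE,
        grid = grid, exceedance = rev(cumsum(rev(counts))),
        groupIds = rownames(M))
}

#' Estimate permutation FDR per group
#'
#' Plug-in estimator: for each group \eqn{g} with threshold
#' \eqn{t = |statistic_g|},
#' \deqn{FDR(g) = \min(1, E_{perm}[\#\{null\ |stat| \ge t\}] /
#'   \#\{observed\ |stat| \ge t\}),}
#' followed by step-up monotonization so estimates are non-increasing in
#' \eqn{|statistic|}.  A group whose statistic exceeds every null statistic
#' gets estimate 0; the resolution of the estimator is 1/\code{nIterations}
#' per group.  Also computes the fraction-significant-versus-cutoff curve.
#'
#' @param obs data.frame from [computeGroupStatistics()] (optionally with an
#'   \code{order} column, carried through)
#' @param null a [NullDistribution-class] built on the same groups
#' @param curveGrid FDR cutoffs at which to evaluate the curve
#' @return a [DiffAbundanceResult-class]
#' @export
estimateFdr <- function(obs, null, curveGrid = seq(0, 1, by = 0.005)) {
    stopifnot(is.data.frame(obs), is(null, "NullDistribution"))
    if (nrow(obs) == 0L) stop("empty observed statistic set")
    if (!setequal(obs$group_id, null@groupIds) ||
        nrow(obs) != length(null@groupIds))
        stop("null distribution was built on different groups")
    t <- abs(obs$statistic)
    step <- 0.25
    idx <- pmin(as.integer(round(t / step)) + 1L, length(null@grid))
    eNull <- null@exceedance[idx] / null@nIterations
    nObs <- length(t) - (rank(t, ties.method = "min") - 1L)
    raw <- pmin(1, eNull / nObs)
    o <- order(-t)
    fdr <- numeric(length(raw))
    fdr[o] <- rev(cummin(rev(raw[o])))
    tab <- data.frame(group_id = obs$group_id, stringsAsFactors = FALSE)
    if (!is.null(obs$order)) tab$order <- obs$order
    tab$statistic <- obs$statistic
    tab$direction <- obs$direction
    tab$fdr <- fdr
    curve <- data.frame(
        fdr_cutoff = curveGrid,
        fraction_significant = vapply(curveGrid, function(q) mean(fdr < q),
                                      numeric(1)))
    new("DiffAbundanceResult", table = tab, curve = curve,
        nIterations = null@nIterations, mode = null@mode, seed = null@seed)
}

#' Differential abundance by permutation FDR
#'
#' End-to-end per-group testing: observed statistics
#' ([computeGroupStatistics()]), structure-preserving permutation null
#' ([buildNullDistribution()]) and plug-in FDR estimates ([estimateFdr()]).
#'
#' @inheritParams buildNullDistribution
#' @param ... passed to [buildNullDistribution()]
#' @return a [DiffAbundanceResult-class]
#' @export
sbbDiffAbundance <- function(ga, design, nIterations = 1e5, seed = NULL,
                             ...) {
    obs <- computeGroupStatistics(ga, design)
    rd <- SummarizedExperiment::rowData(ga)
    if ("order" %in% colnames(rd)) obs$order <- rd$order
    null <- buildNullDistribution(ga, design, nIterations = nIterations,
                                  seed = seed, ...)
    estimateFdr(obs, null)
}
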