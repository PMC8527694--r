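#' @include AllClasses.R
NULL

#' Build a synthetic-dataset specification
#'
#' Defines a clade-structured simulation: ASV sequences evolve from a
#' random root down a balanced binary tree with i.i.d. per-position
#' substitutions (and optional inherited deletions); a planted clade is
#' given private bases at the diagnostic loci, so it is exactly the set of
#' carriers of one diagnostic multi-locus biomarker; case samples have the
#' clade's relative abundance multiplied by \code{effectSize}.
#'
#' Counts follow a Dirichlet-multinomial model: a baseline composition
#' gives each background ASV a log-normal mean proportion (the log-scale
#' spread is calibrated so the expected fraction of zero count cells
#' matches \code{sparsityTarget}) while the planted clade splits a fixed
#' \code{cladeBaseline} share; per-sample proportions are Dirichlet draws
#' around that baseline with concentration \code{theta}, and counts are
#' multinomial at fixed \code{countDepth} (relative-abundance
#' normalization removes depth anyway).
#'
#' @param nAsvs number of ASVs (leaves)
#' @param alignmentWidth alignment columns
#' @param cladeSize ASVs in the planted clade (at most \code{nAsvs/2})
#' @param substitutionProb per-position, per-branch substitution probability
#' @param indelProb per-position, per-branch deletion probability (gaps
#'   propagate to descendants)
#' @param diagnosticLoci positions of the planted biomarker's loci; default
#'   two loci at one third and two thirds of the width
#' @param mode \code{"paired"} (case-control pairs) or \code{"unpaired"}
#'   (concordant families)
#' @param nPairs pairs in paired mode
#' @param nCase,nControl samples per phenotype in unpaired mode
#' @param familySize samples per (concordant) family in unpaired mode
#' @param effectSize multiplicative abundance shift of the clade in cases;
#'   1 = null data
#' @param countDepth reads per sample
#' @param sparsityTarget expected fraction of zero cells in the count table
#' @param cladeBaseline mean total relative abundance of the planted clade
#'   in controls (a moderately abundant family-level group by default)
#' @param theta Dirichlet concentration around the baseline composition;
#'   smaller values mean more sample-to-sample overdispersion
#' @param seed master seed for both generators
#' @return an [SBBSimSpec-class]
#' @examples
#' sbbSimSpec(nAsvs = 16, nPairs = 10, seed = 7)
#' @export
sbbSimSpec <- function(nAsvs = 32L, alignmentWidth = 64L, cladeSize = 4L,
                       substitutionProb = 0.05, indelProb = 0.01,
                       diagnosticLoci = NULL,
                       mode = c("paired", "unpaired"),
                       nPairs = 60L, nCase = 30L, nControl = 30L,
                       familySize = 2L, effectSize = 4,
                       countDepth = 10000L, sparsityTarget = 0.5,
                       cladeBaseline = 0.05, theta = 50,
                       seed = 1L) {
    mode <- match.arg(mode)
    if (is.null(diagnosticLoci))
        diagnosticLoci <- unique(pmax(1L, round(alignmentWidth * c(1, 2) / 3)))
    new("SBBSimSpec", nAsvs = as.integer(nAsvs),
        alignmentWidth = as.integer(alignmentWidth),
        cladeSize = as.integer(cladeSize),
        substitutionProb = substitutionProb, indelProb = indelProb,
        diagnosticLoci = as.integer(diagnosticLoci), mode = mode,
        nPairs = as.integer(nPairs), nCase = as.integer(nCase),
        nControl = as.integer(nControl), familySize = as.integer(familySize),
        effectSize = effectSize, countDepth = as.integer(countDepth),
        sparsityTarget = sparsityTarget, cladeBaseline = cladeBaseline,
        theta = theta, seed = as.integer(seed))
}

# mutate one sequence (character vector) along one branch
.mutateBranch <- function(s, pSub, pIndel, mask) {
    isBase <- s %in% .BASES & !mask
    mut <- isBase & stats::runif(length(s)) < pSub
    if (any(mut))
        s[mut] <- vapply(s[mut], function(b)
            sample(setdiff(.BASES, b), 1L), character(1))
    del <- isBase & stats::runif(length(s)) < pIndel
    s[del] <- "-"
    s
}

# balanced recursive bifurcation down to n leaves
.evolve <- function(s, n, pSub, pIndel, mask) {
    if (n == 1L) return(list(s))
    nl <- ceiling(n / 2)
    c(.evolve(.mutateBranch(s, pSub, pIndel, mask), nl, pSub, pIndel, mask),
      .evolve(.mutateBranch(s, pSub, pIndel, mask), n - nl, pSub, pIndel,
              mask))
}

#' Simulate a clade-structured aligned sequence set
#'
#' Generates \code{nAsvs} aligned sequences by mutating a random root down
#' a balanced binary tree.  The diagnostic loci are masked from mutation;
#' after the tree walk, the planted clade (the subtree of the first
#' \code{cladeSize} leaves) receives a private base at each diagnostic
#' locus, so the clade is exactly the carrier set of the diagnostic
#' biomarker and no other ASV carries any of its variants.
#'
#' The clade ASV ids and the diagnostic biomarker's canonical label are
#' stored in \code{metadata()} of the returned object.
#'
#' @param spec an [SBBSimSpec-class]
#' @return an [AlignedSeqSet-class] with metadata fields \code{cladeAsvs}
#'   and \code{diagnosticBiomarker}
#' @export
simulateAlignment <- function(spec) {
    stopifnot(is(spec, "SBBSimSpec"))
    set.seed(spec@seed)
    W <- spec@alignmentWidth
    mask <- rep(FALSE, W)
    mask[spec@diagnosticLoci] <- TRUE
    root <- sample(.BASES, W, replace = TRUE)
    leaves <- .evolve(root, spec@nAsvs, spec@substitutionProb,
                      spec@indelProb, mask)
    ids <- sprintf("asv%04d", seq_len(spec@nAsvs))
    clade <- seq_len(spec@cladeSize)
    # private clade bases: cycle each root base forward in A<C<G<T
    loci <- sort(spec@diagnosticLoci)
    cladeBase <- .BASES[match(root[loci], .BASES) %% 4L + 1L]
    for (a in seq_len(spec@nAsvs)) {
        leaves[[a]][loci] <- if (a %in% clade) cladeBase else root[loci]
    }
    seqs <- AlignedSeqSet(structure(
        vapply(leaves, paste, character(1), collapse = ""), names = ids))
    S4Vectors::metadata(seqs) <- list(
        cladeAsvs = ids[clade],
        diagnosticBiomarker = paste0(loci, cladeBase, collapse = "/"))
    seqs
}

# Dirichlet-multinomial zero probability per cell, alpha_k = theta * m_k
.dmZeroFraction <- function(m, theta, depth) {
    a <- theta * m
    mean(exp(lgamma(theta - a + depth) + lgamma(theta) -
             lgamma(theta + depth) - lgamma(theta - a)))
}

# baseline composition: planted clade splits cladeBaseline equally;
# background ASVs get log-normal means whose spread is calibrated so the
# expected zero fraction of the count table matches the sparsity target
.baselineComposition <- function(spec, clade) {
    K <- spec@nAsvs
    z <- stats::rnorm(K - length(clade))
    mFor <- function(sigma) {
        m <- numeric(K)
        m[clade] <- spec@cladeBaseline / length(clade)
        bg <- exp(sigma * z)
        m[-clade] <- (1 - spec@cladeBaseline) * bg / sum(bg)
        m
    }
    f <- function(sigma)
        .dmZeroFraction(mFor(sigma), spec@theta, spec@countDepth) -
            spec@sparsityTarget
    sigma <- if (f(0) >= 0) 0
             else if (f(30) <= 0) 30
             else stats::uniroot(f, c(0, 30), tol = 1e-6)$root
    mFor(sigma)
}

#' Simulate a count table and study design with planted effect
#'
#' Per-sample proportions are Dirichlet draws (concentration \code{theta})
#' around a baseline composition in which the planted clade holds a
#' \code{cladeBaseline} share and background ASVs have log-normal means
#' calibrated to the sparsity target; in case samples the planted clade's
#' proportions are multiplied by \code{effectSize} and renormalized;
#' counts are drawn multinomially at \code{countDepth} reads per sample.
#' With
#' \code{effectSize = 1} cases and controls are exchangeable (null data).
#' A realized zero fraction more than 5 percentage points from the target
#' triggers a warning reporting the realized value.
#'
#' @param spec an [SBBSimSpec-class]
#' @param seqs the matching alignment from [simulateAlignment()]
#' @return list with \code{counts} (a [CountTable-class]) and \code{design}
#'   (a [StudyDesign-class])
#' @export
simulateCounts <- function(spec, seqs) {
    stopifnot(is(spec, "SBBSimSpec"), is(seqs, "AlignedSeqSet"))
    if (length(seqs) != spec@nAsvs)
        stop("alignment does not match the spec")
    set.seed(spec@seed %% 2147483000L + 1L)
    ids <- names(seqs)
    clade <- match(S4Vectors::metadata(seqs)$cladeAsvs, ids)
    if (anyNA(clade)) stop("alignment lacks planted-clade metadata")

    if (spec@mode == "paired") {
        pid <- rep(sprintf("p%04d", seq_len(spec@nPairs)), each = 2L)
        ph <- rep(c("case", "control"), spec@nPairs)
        sam <- paste0(pid, "_", ifelse(ph == "case", "case", "ctrl"))
        design <- StudyDesign(sam, ph, pairId = pid, mode = "paired")
    } else {
        nFam <- ceiling(spec@nCase / spec@familySize) +
                ceiling(spec@nControl / spec@familySize)
        ph <- c(rep("case", spec@nCase), rep("control", spec@nControl))
        fidCase <- rep(seq_len(ceiling(spec@nCase / spec@familySize)),
                       each = spec@familySize)[seq_len(spec@nCase)]
        fidCtrl <- rep(seq_len(ceiling(spec@nControl / spec@familySize)),
                       each = spec@familySize)[seq_len(spec@nControl)] +
                   max(fidCase)
        fid <- sprintf("f%03d", c(fidCase, fidCtrl))
        sam <- sprintf("s%04d", seq_along(ph))
        design <- StudyDesign(sam, ph, familyId = fid, mode = "unpaired")
    }

    K <- spec@nAsvs
    alpha <- spec@theta * .baselineComposition(spec, clade)
    counts <- matrix(0, K, length(sam), dimnames = list(ids, sam))
    for (j in seq_along(sam)) {
        g <- stats::rgamma(K, shape = alpha)
        if (all(g == 0)) g[sample.int(K, 1L)] <- 1   # degenerate underflow
        p <- g / sum(g)
        if (design@phenotype[j] == "case" && spec@effectSize != 1) {
            p[clade] <- p[clade] * spec@effectSize
            p <- p / sum(p)
        }
        counts[, j] <- stats::rmultinom(1L, spec@countDepth, p)
    }
    realized <- mean(counts == 0)
    if (abs(realized - spec@sparsityTarget) > 0.05)
        warning(sprintf(
            "realized zero fraction %.3f misses the sparsity target %.2f",
            realized, spec@sparsityTarget))
    list(counts = CountTable(counts), design = design)
}

#' Simulate a complete dataset
#'
#' Runs [simulateAlignment()] and [simulateCounts()] and returns all the
#' pieces a pipeline run needs.
#'
#' @param spec an [SBBSimSpec-class]
#' @return list: \code{seqs}, \code{counts}, \code{design},
#'   \code{cladeAsvs}, \code{diagnosticBiomarker}
#' @examples
#' sim <- simulateDataset(sbbSimSpec(nAsvs = 8, nPairs = 4, seed = 1))
#' sim$diagnosticBiomarker
#' @export
simulateDataset <- function(spec) {
    seqs <- simulateAlignment(spec)
    cd <- simulateCounts(spec, seqs)
    list(seqs = seqs, counts = cd$counts, design = cd$design,
         cladeAsvs = S4Vectors::metadata(seqs)$cladeAsvs,
         diagnosticBiomarker = S4Vectors::metadata(seqs)$diagnosticBiomarker)
}

#' Write a simulated dataset to disk
#'
#' Writes the aligned FASTA, count TSV and metadata TSV that the readers
#' of this package consume, making simulated fixtures round-trippable
#' through the full pipeline.
#'
#' @param spec an [SBBSimSpec-class]
#' @param dir output directory (created if needed)
#' @return named character vector of the three paths, invisibly
#' @export
writeSimulatedDataset <- function(spec, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateDataset(spec)
    paths <- c(alignment = file.path(dir, "alignment.fasta"),
               counts = file.path(dir, "counts.tsv"),
               metadata = file.path(dir, "metadata.tsv"))
    writeAlignedFasta(sim$seqs, paths[["alignment"]])
    writeCountTable(sim$counts, paths[["counts"]])
    writeMetadata(sim$design, paths[["metadata"]])
    invisible(paths)
}
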