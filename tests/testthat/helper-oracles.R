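# Shared fixtures and independent oracle implementations.  Oracles work
# directly on character matrices / dense matrices / explicit loops, never
# through the package's sparse-key machinery.

suppressPackageStartupMessages({
    library(Matrix)
    library(SummarizedExperiment)
})

# random gapped alignment as a named character vector
randomAlignment <- function(nAsvs, width, gapProb = 0.15) {
    chars <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(nAsvs), function(i) {
        s <- sample(chars, width, replace = TRUE)
        s[runif(width) < gapProb] <- "-"
        paste(s, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("asv%02d", seq_len(nAsvs))
    seqs
}

alignmentChars <- function(seqs) {
    do.call(rbind, strsplit(unname(seqs), ""))
}

# Exhaustive oracle: enumerate every combination of `order` distinct
# positions and every base tuple observed at those positions, checking
# membership by direct character comparison; keeps combos carried by >= 1
# sequence.  Returns membership columns keyed by canonical label.
oracleBiomarkers <- function(seqs, order) {
    chars <- alignmentChars(seqs)
    W <- ncol(chars)
    bases <- c("A", "C", "G", "T")
    out <- new.env(parent = emptyenv())
    if (W < order) return(list())
    posCombs <- utils::combn(W, order)
    recurse <- function(ps, t, memb, label) {
        if (t > length(ps)) {
            assign(paste(label, collapse = "/"), memb, envir = out)
            return(invisible())
        }
        p <- ps[t]
        for (b in intersect(bases, unique(chars[, p]))) {
            m2 <- memb & (chars[, p] == b)
            if (any(m2))
                recurse(ps, t + 1L, m2, c(label, paste0(p, b)))
        }
    }
    for (ci in seq_len(ncol(posCombs)))
        recurse(posCombs[, ci, drop = TRUE], 1L, rep(TRUE, nrow(chars)),
                character(0))
    labs <- ls(out)
    setNames(lapply(labs, get, envir = out), labs)
}

# dense comparison helper: BiomarkerMatrix -> named list of logical columns
bmAsColumns <- function(bm) {
    m <- as.matrix(membership(bm))
    setNames(lapply(seq_len(ncol(m)), function(j) unname(m[, j] > 0)),
             colnames(m))
}

# per-group loop-summation oracle for Eq.-(2)-style aggregation
oracleAggregate <- function(relMat, membMat) {
    out <- matrix(0, ncol(membMat), ncol(relMat),
                  dimnames = list(colnames(membMat), colnames(relMat)))
    for (g in seq_len(ncol(membMat)))
        for (p in seq_len(ncol(relMat))) {
            s <- 0
            for (a in seq_len(nrow(membMat)))
                if (membMat[a, g] > 0)
                    s <- s + relMat[rownames(membMat)[a], p]
            out[g, p] <- s
        }
    out
}

# textbook Wilcoxon signed-rank: sum of positive-difference ranks, centered
# at m(m+1)/4 over the m nonzero differences (midranks for ties)
oracleSignedRank <- function(d) {
    d <- d[d != 0]
    if (length(d) == 0) return(0)
    r <- rank(abs(d))
    sum(r[d > 0]) - length(d) * (length(d) + 1) / 4
}

# textbook Mann-Whitney U for the case sample, centered at n1*n2/2
oracleMannWhitney <- function(case, control) {
    u <- 0
    for (x in case)
        for (y in control)
            u <- u + (x > y) + 0.5 * (x == y)
    u - length(case) * length(control) / 2
}

# small paired GroupAbundanceTable + design with given group x pair
# case/control values
makePairedGa <- function(caseMat, ctrlMat, groupIds = NULL) {
    k <- ncol(caseMat)
    if (is.null(groupIds)) groupIds <- sprintf("g%03d", seq_len(nrow(caseMat)))
    sam <- c(rbind(sprintf("p%02d_case", seq_len(k)),
                   sprintf("p%02d_ctrl", seq_len(k))))
    vals <- matrix(0, nrow(caseMat), 2 * k,
                   dimnames = list(groupIds, sam))
    vals[, seq(1, 2 * k, by = 2)] <- caseMat
    vals[, seq(2, 2 * k, by = 2)] <- ctrlMat
    design <- StudyDesign(sam,
                          rep(c("case", "control"), k),
                          pairId = rep(sprintf("p%02d", seq_len(k)), each = 2),
                          mode = "paired")
    ga <- new("GroupAbundanceTable",
              SummarizedExperiment::SummarizedExperiment(
                  assays = list(groupabund = vals)))
    validObject(ga)
    list(ga = ga, design = design)
}

# unpaired analogue; optional familyId
makeUnpairedGa <- function(vals, phenotype, familyId = NULL) {
    sam <- colnames(vals)
    design <- StudyDesign(sam, phenotype, familyId = familyId,
                          mode = "unpaired")
    ga <- new("GroupAbundanceTable",
              SummarizedExperiment::SummarizedExperiment(
                  assays = list(groupabund = vals)))
    validObject(ga)
    list(ga = ga, design = design)
}

# best label agreement between two flat clusterings over all relabellings
# of the (small) reference label set
clusterAgreement <- function(found, truth) {
    ids <- sort(unique(truth))
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
        out
    }
    best <- 0
    for (pm in perms(ids)) {
        mapped <- pm[match(truth, ids)]
        best <- max(best, mean(mapped == found))
    }
    best
}
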