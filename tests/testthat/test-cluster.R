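makeToyResult <- function(labels, fdr) {
    new("DiffAbundanceResult",
        table = data.frame(group_id = labels,
                           statistic = seq_along(labels),
                           direction = 1, fdr = fdr,
                           stringsAsFactors = FALSE),
        curve = data.frame(fdr_cutoff = 0.1,
                           fraction_significant = mean(fdr < 0.1)),
        nIterations = 100, mode = "paired", seed = 1)
}

test_that("significant-biomarker matrix applies the cutoff and trims carriers", {
    seqs <- AlignedSeqSet(c(a1 = "AAC", a2 = "ATC", a3 = "TTG"))
    bm <- enumerateBiomarkers(oneHotEncode(seqs), 1)
    labs <- biomarkerLabels(bm)
    fdr <- rep(1, length(labs))
    fdr[match(c("1A", "2T"), labs)] <- c(0.05, 0.09)
    fdr[match("3G", labs)] <- 0.2
    res <- makeToyResult(labs, fdr)
    sm <- significantBiomarkers(res, bm, 0.1)
    expect_setequal(rownames(sm), c("1A", "2T"))
    # retained ASVs = union of the retained biomarkers' carriers
    expect_setequal(colnames(sm), c("a1", "a2", "a3"))
    expect_identical(sm["1A", ], c(a1 = 1, a2 = 1, a3 = 0))

    smAll <- significantBiomarkers(makeToyResult(labs, rep(0.5, length(labs))),
                                   bm, 1.0)
    expect_setequal(rownames(smAll), labs)
    expect_warning(empty <- significantBiomarkers(res, bm, 0.01),
                   "no biomarker")
    expect_identical(nrow(empty), 0L)
})

test_that("hamming-fraction distance and merges behave on hand-built rows", {
    sm <- rbind(b1 = c(0, 1, 0, 1), b2 = c(0, 1, 0, 1), b3 = c(0, 1, 1, 0))
    colnames(sm) <- paste0("a", 1:4)
    ca <- clusterBiomarkers(sm, k = 2)
    d <- as.matrix(SBBtools:::.hammingFraction(sm))
    expect_identical(unname(d["b1", "b2"]), 0)          # identical rows
    expect_identical(unname(d["b2", "b3"]), 0.5)        # 0101 vs 0110
    expect_true(all(diag(d) == 0))
    expect_identical(d, t(d))
    expect_identical(min(ca@biomarkerTree$height), 0)   # merged at height 0
    expect_identical(unname(ca@biomarkerClusters["b1"]),
                     unname(ca@biomarkerClusters["b2"]))
    expect_false(ca@biomarkerClusters["b1"] == ca@biomarkerClusters["b3"])
})

test_that("clustering is invariant to row order up to relabelling", {
    set.seed(55)
    sm <- matrix(rbinom(12 * 8, 1, 0.4), 12, 8,
                 dimnames = list(sprintf("b%02d", 1:12), sprintf("a%d", 1:8)))
    ca <- clusterBiomarkers(sm, k = 3)
    perm <- sample(12)
    ca2 <- clusterBiomarkers(sm[perm, ], k = 3)
    g1 <- ca@biomarkerClusters
    g2 <- ca2@biomarkerClusters[names(g1)]
    # same partition: co-membership matrices agree
    co <- function(g) outer(g, g, "==")
    expect_identical(unname(co(g1)), unname(co(g2)))
})

test_that("single-row input yields a singleton assignment", {
    sm <- matrix(c(1, 0, 1), 1, dimnames = list("b1", paste0("a", 1:3)))
    ca <- clusterBiomarkers(sm, k = 2)
    expect_null(ca@biomarkerTree)
    expect_identical(ca@biomarkerClusters, c(b1 = 1L))
})

test_that("planted blocks are recovered from a noisy membership matrix", {
    set.seed(71)
    truth <- rep(1:4, each = 10)
    sm <- matrix(0, 40, 32)
    for (b in 1:4)
        sm[truth == b, ((b - 1) * 8 + 1):(b * 8)] <- 1
    flip <- matrix(runif(length(sm)) < 0.05, nrow(sm))
    sm[flip] <- 1 - sm[flip]
    dimnames(sm) <- list(sprintf("b%02d", 1:40), sprintf("a%02d", 1:32))
    ca <- clusterBiomarkers(sm, k = 4)
    expect_gte(clusterAgreement(unname(ca@biomarkerClusters), truth), 0.95)
})

test_that("group summaries match direct order statistics", {
    set.seed(83)
    fx <- makePairedGa(matrix(runif(3 * 6), 3), matrix(runif(3 * 6), 3),
                       groupIds = c("gA", "gB", "gC"))
    sm <- summarizeGroup(fx$ga, fx$design, "gB")
    M <- assay(fx$ga, "groupabund")
    for (ph in c("case", "control")) {
        x <- M["gB", fx$design@sampleIds[fx$design@phenotype == ph]]
        row <- sm$summary[sm$summary$phenotype == ph, ]
        expect_equal(row$median, sort(x)[3:4] |> mean())
        expect_equal(row$n, 6)
        expect_equal(row$q1, unname(quantile(x, 0.25)))
    }
    expect_length(sm$pairDifferences, 6)
    expect_equal(unname(sm$pairDifferences),
                 unname(M["gB", seq(1, 12, 2)] - M["gB", seq(2, 12, 2)]))
    expect_error(summarizeGroup(fx$ga, fx$design, "nope"), "unknown group")

    # identical values across phenotypes: zero median difference
    flat <- makePairedGa(matrix(0.3, 1, 4), matrix(0.3, 1, 4),
                         groupIds = "g0")
    s0 <- summarizeGroup(flat$ga, flat$design, "g0")
    expect_equal(diff(s0$summary$median), 0)
})
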