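test_that("paired statistics match the textbook signed-rank computation", {
    # 6 hand-rankable pairs plus degenerate and tie cases
    # dyadic values so within-pair differences and ties are float-exact
    cases <- list(
        c(0.3125, 0.125, 0.25, -0.0625, 0.1875, -0.21875),
        c(0, 0, 0, 0, 0, 0),                         # all-zero differences
        c(0.125, -0.125, 0.25, -0.25, 0.375, 0.0625),  # tied magnitudes
        c(0.5, 0.375, 0.3125, 0.25, 0.125, 0.0625))    # complete positivity
    ctrl <- matrix(0.25, length(cases), 6)
    caseM <- ctrl + do.call(rbind, cases)
    fx <- makePairedGa(caseM, ctrl)
    got <- computeGroupStatistics(fx$ga, fx$design)
    for (i in seq_along(cases))
        expect_equal(got$statistic[i], oracleSignedRank(cases[[i]]),
                     info = paste("case", i))
    expect_identical(got$direction, sign(got$statistic))
    # all-zero group sits at the null center
    expect_identical(got$statistic[2], 0)
})

test_that("unpaired statistics match the rank-pair counting oracle", {
    vals <- rbind(g1 = c(3, 4, 5, 0, 1, 2),
                  g2 = c(1, 3, 2, 4, 0, 5),
                  g3 = c(2, 2, 2, 2, 2, 2)) / 10
    colnames(vals) <- paste0("s", 1:6)
    fx <- makeUnpairedGa(vals, rep(c("case", "control"), each = 3))
    got <- computeGroupStatistics(fx$ga, fx$design)
    for (i in 1:3)
        expect_equal(got$statistic[i],
                     oracleMannWhitney(vals[i, 1:3], vals[i, 4:6]))
    # complete separation attains the extreme centered value, i.e. U = 9
    expect_equal(got$statistic[1], 4.5)
    expect_equal(got$statistic[1] + 3 * 3 / 2, 9)
    expect_identical(got$statistic[3], 0)
})

test_that("statistics are invariant to group and sample order", {
    set.seed(61)
    k <- 8
    fx <- makePairedGa(matrix(runif(5 * k), 5), matrix(runif(5 * k), 5))
    base <- computeGroupStatistics(fx$ga, fx$design)
    gperm <- sample(nrow(fx$ga))
    sperm <- sample(ncol(fx$ga))
    shuffled <- computeGroupStatistics(fx$ga[gperm, sperm], fx$design)
    expect_equal(shuffled$statistic[match(base$group_id, shuffled$group_id)],
                 base$statistic)
})

test_that("designs with fewer than two samples per phenotype are rejected", {
    vals <- matrix(runif(6), 2, 3,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
    fx <- makeUnpairedGa(vals, c("case", "control", "control"))
    expect_error(computeGroupStatistics(fx$ga, fx$design),
                 "insufficient")
})

test_that("paired permutation swaps each pair about half the time, reproducibly", {
    fx <- makePairedGa(matrix(runif(8), 2, 4), matrix(runif(8), 2, 4))
    set.seed(77)
    a <- permuteDesign(fx$design)
    set.seed(77)
    b <- permuteDesign(fx$design)
    expect_identical(phenotype(a), phenotype(b))
    # per-pair swap frequency over 10,000 draws
    set.seed(78)
    k <- 4
    swaps <- matrix(0, 10000, k)
    caseIdx <- which(fx$design@phenotype == "case")
    for (it in 1:10000) {
        d <- permuteDesign(fx$design)
        swaps[it, ] <- d@phenotype[caseIdx] != "case"
    }
    freq <- colMeans(swaps)
    expect_true(all(freq > 0.485 & freq < 0.515))
    # every permuted design stays a valid pairing
    expect_no_error(validObject(d))
})

test_that("unpaired permutation preserves family concordance and label counts", {
    vals <- matrix(runif(3 * 8), 3, 8,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
    # three twin families (2 case-families, 1 control-family) + 2 singletons
    ph <- c("case", "case", "case", "case", "control", "control",
            "control", "case")
    fid <- c("f1", "f1", "f2", "f2", "f3", "f3", NA, NA)
    fx <- makeUnpairedGa(vals, ph, familyId = fid)
    set.seed(5)
    for (i in 1:50) {
        d <- permuteDesign(fx$design)
        expect_identical(sum(d@phenotype == "case"), 5L)
        for (f in c("f1", "f2", "f3"))
            expect_length(unique(d@phenotype[which(fid == f)]), 1L)
    }
})

test_that("identity permutation reproduces the observed statistics", {
    set.seed(9)
    fx <- makePairedGa(matrix(runif(12), 3, 4), matrix(runif(12), 3, 4))
    obs <- computeGroupStatistics(fx$ga, fx$design)
    null <- buildNullDistribution(fx$ga, fx$design, nIterations = 1,
                                  identityPermutation = TRUE)
    # the null's pooled exceedance at each observed threshold counts the
    # observed statistics themselves
    for (t in abs(obs$statistic)) {
        i <- round(t / 0.25) + 1
        expect_equal(null@exceedance[i], sum(abs(obs$statistic) >= t))
    }
})

test_that("null building is deterministic given a seed and invariant to chunking/threads", {
    set.seed(13)
    fx <- makePairedGa(matrix(runif(40), 4, 10), matrix(runif(40), 4, 10))
    n1 <- buildNullDistribution(fx$ga, fx$design, nIterations = 400,
                                seed = 3, exhaustive = "never",
                                chunkSize = 64L)
    n2 <- buildNullDistribution(fx$ga, fx$design, nIterations = 400,
                                seed = 3, exhaustive = "never",
                                chunkSize = 64L)
    expect_identical(n1@exceedance, n2@exceedance)
    n3 <- buildNullDistribution(fx$ga, fx$design, nIterations = 400,
                                seed = 3, exhaustive = "never",
                                chunkSize = 64L, threads = 2L)
    expect_identical(n1@exceedance, n3@exceedance)
})

test_that("exhaustive mode equals direct sign-pattern enumeration (4 pairs)", {
    set.seed(21)
    k <- 4
    fx <- makePairedGa(matrix(runif(3 * k), 3), matrix(runif(3 * k), 3))
    null <- buildNullDistribution(fx$ga, fx$design, nIterations = 16,
                                  exhaustive = "auto")
    expect_true(null@exhaustive)
    expect_identical(null@nIterations, 16)
    # direct enumeration of all 16 patterns through the textbook oracle
    M <- assay(fx$ga, "groupabund")
    D <- M[, seq(1, 8, 2)] - M[, seq(2, 8, 2)]
    allStats <- c()
    for (bits in 0:15) {
        s <- ifelse(bitwAnd(bits, 2^(0:3)) > 0, 1, -1)
        allStats <- c(allStats, apply(sweep(D, 2, s, "*"), 1,
                                      oracleSignedRank))
    }
    for (i in seq_along(null@grid))
        expect_equal(null@exceedance[i],
                     sum(abs(allStats) >= null@grid[i] - 1e-12))
})

test_that("FDR estimates: separation gives 0, duplicates agree, curve monotone", {
    set.seed(33)
    k <- 10
    ctrl <- matrix(runif(20 * k, 0, 0.02), 20)
    caseM <- ctrl
    caseM[1, ] <- ctrl[1, ] + 0.5          # maximal separation for group 1
    caseM[2, ] <- caseM[1, ]; ctrl[2, ] <- ctrl[1, ]   # duplicate of group 1
    fx <- makePairedGa(caseM, ctrl)
    res <- sbbDiffAbundance(fx$ga, fx$design, nIterations = 500, seed = 4)
    tab <- resultTable(res)
    expect_equal(tab$fdr[1], 0)
    expect_identical(tab$fdr[1], tab$fdr[2])
    expect_identical(tab$direction[1], 1)
    # monotone: fdr non-increasing in |statistic|
    o <- order(-abs(tab$statistic))
    expect_true(all(diff(tab$fdr[o]) >= -1e-12))
    crv <- fdrCurve(res)
    expect_true(all(diff(crv$fraction_significant) >= 0))
})

test_that("estimateFdr refuses a null built on different groups", {
    set.seed(44)
    fx <- makePairedGa(matrix(runif(8), 2, 4), matrix(runif(8), 2, 4))
    null <- buildNullDistribution(fx$ga, fx$design, nIterations = 50,
                                  seed = 1, exhaustive = "never")
    obs <- computeGroupStatistics(fx$ga, fx$design)
    expect_error(estimateFdr(obs[0, ], null), "empty")
    obs$group_id <- c("other1", "other2")
    expect_error(estimateFdr(obs, null), "different groups")
})
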