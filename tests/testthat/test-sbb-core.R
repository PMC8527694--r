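test_that("one-hot encoding matches a direct character scan", {
    seqs <- AlignedSeqSet(c(a1 = "ACG"))
    vm <- oneHotEncode(seqs)
    expect_identical(colnames(membership(vm)), c("1A", "2C", "3G"))
    expect_true(all(as.matrix(membership(vm))))

    allGap <- AlignedSeqSet(c(a1 = "---"))
    expect_identical(ncol(membership(oneHotEncode(allGap))), 0L)

    set.seed(41)
    for (i in 1:5) {
        seqs <- AlignedSeqSet(randomAlignment(5, 8))
        vm <- oneHotEncode(seqs)
        chars <- alignmentChars(as.character(seqs))
        expect_equal(unname(rowSums(membership(vm))),
                     unname(rowSums(chars != "-")))
        # each set bit states base presence at that position
        m <- as.matrix(membership(vm))
        for (j in seq_len(ncol(m)))
            expect_identical(unname(m[, j]),
                             chars[, vm@position[j]] == vm@base[j])
    }
})

test_that("variant columns are ordered by position then base, A<C<G<T", {
    vm <- oneHotEncode(AlignedSeqSet(c(a1 = "TG", a2 = "AG", a3 = "AC")))
    expect_identical(colnames(membership(vm)), c("1A", "1T", "2C", "2G"))
})

test_that("the three-base worked example enumerates exactly as expected", {
    vm <- oneHotEncode(AlignedSeqSet(c(a1 = "ACG")))
    expect_identical(biomarkerLabels(enumerateBiomarkers(vm, 1)),
                     c("1A", "2C", "3G"))
    lab2 <- biomarkerLabels(enumerateBiomarkers(vm, 2))
    expect_identical(lab2, c("1A/2C", "1A/3G", "2C/3G"))
    expect_length(lab2, choose(3, 2))
    expect_identical(biomarkerLabels(enumerateBiomarkers(vm, 3)),
                     "1A/2C/3G")
})

test_that("order-2 enumeration equals the full position-pair/base-pair double loop", {
    set.seed(7)
    seqs <- randomAlignment(10, 6, gapProb = 0.2)
    bm <- enumerateBiomarkers(oneHotEncode(AlignedSeqSet(seqs)), 2)
    got <- bmAsColumns(bm)
    # full-space double loop: every position pair, every base pair
    chars <- alignmentChars(seqs)
    bases <- c("A", "C", "G", "T")
    want <- list()
    for (p1 in 1:5) for (p2 in (p1 + 1):6)
        for (b1 in bases) for (b2 in bases) {
            memb <- chars[, p1] == b1 & chars[, p2] == b2
            if (any(memb))
                want[[paste0(p1, b1, "/", p2, b2)]] <- memb
        }
    expect_setequal(names(got), names(want))
    for (lab in names(want))
        expect_identical(got[[lab]], unname(want[[lab]]), label = lab)
})

test_that("enumeration rejects bad orders and handles too-narrow alignments", {
    vm <- oneHotEncode(AlignedSeqSet(c(a1 = "A", a2 = "C")))
    expect_error(enumerateBiomarkers(vm, 4), "order")
    expect_error(enumerateBiomarkers(vm, 0), "order")
    expect_identical(ncol(membership(enumerateBiomarkers(vm, 2))), 0L)
})

test_that("gap-free count law and cross-order nesting hold", {
    set.seed(11)
    seqs <- AlignedSeqSet(randomAlignment(6, 7, gapProb = 0))
    vm <- oneHotEncode(seqs)
    for (N in 1:3) {
        bm <- enumerateBiomarkers(vm, N)
        expect_equal(unname(rowSums(membership(bm))),
                     rep(choose(7, N), 6))
    }
    # nesting: an ASV carrying an order-2 biomarker carries both loci
    gappy <- AlignedSeqSet(randomAlignment(8, 6, gapProb = 0.25))
    vm <- oneHotEncode(gappy)
    b1 <- bmAsColumns(enumerateBiomarkers(vm, 1))
    b2 <- enumerateBiomarkers(vm, 2)
    labs2 <- biomarkerLabels(b2)
    cols2 <- bmAsColumns(b2)
    for (lab in labs2) {
        parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
        for (part in parts)
            expect_true(all(cols2[[lab]] <= b1[[part]]), label = lab)
    }
})

test_that("enumeration is deterministic", {
    set.seed(5)
    seqs <- AlignedSeqSet(randomAlignment(12, 10))
    vm <- oneHotEncode(seqs)
    a <- enumerateBiomarkers(vm, 2)
    b <- enumerateBiomarkers(vm, 2)
    expect_identical(biomarkerLabels(a), biomarkerLabels(b))
    expect_identical(as.matrix(membership(a)), as.matrix(membership(b)))
})

test_that("universal biomarkers are dropped, rare ones kept", {
    seqs <- AlignedSeqSet(c(a1 = "AAG", a2 = "ACG", a3 = "ATG"))
    bm <- enumerateBiomarkers(oneHotEncode(seqs), 1)
    kept <- filterUninformative(bm)
    expect_false(any(c("1A", "3G") %in% biomarkerLabels(kept)))
    expect_true(all(c("2A", "2C", "2T") %in% biomarkerLabels(kept)))
    # carried by 1 of 3 ASVs: retained
    expect_true(all(colSums(membership(kept)) == 1))

    allSame <- AlignedSeqSet(c(a1 = "AC", a2 = "AC"))
    bmAll <- enumerateBiomarkers(oneHotEncode(allSame), 1)
    expect_warning(res <- filterUninformative(bmAll), "every biomarker")
    expect_identical(ncol(membership(res)), 0L)
})

test_that("LD pruning collapses exactly the identical membership columns", {
    # two loci always co-varying across ASVs -> complete LD
    seqs <- AlignedSeqSet(c(a1 = "CAAC", a2 = "CAAC", a3 = "GTAC"))
    bm2 <- enumerateBiomarkers(oneHotEncode(seqs), 2)
    pr <- ldPrune(bm2)
    cls <- pr$classes
    # 1C/2A and its co-varying partners collapse into one class
    grp <- cls$representative[cls$member == "1C/2A"]
    expect_gt(sum(cls$representative == grp), 1)
    # all-distinct columns stay untouched
    distinct <- AlignedSeqSet(c(a1 = "AC", a2 = "AG", a3 = "TG"))
    bm1 <- enumerateBiomarkers(oneHotEncode(distinct), 1)
    pr1 <- ldPrune(bm1)
    expect_identical(biomarkerLabels(pr1$pruned), biomarkerLabels(bm1))
    expect_true(all(table(pr1$classes$representative) == 1))
})

test_that("LD class count equals distinct-column count on random matrices", {
    set.seed(23)
    for (i in 1:3) {
        ii <- sample(20, 600, replace = TRUE)
        jj <- sample(200, 600, replace = TRUE)
        empty <- setdiff(seq_len(200), jj)
        ii <- c(ii, sample(20, length(empty), replace = TRUE))
        jj <- c(jj, empty)
        m <- Matrix::sparseMatrix(
            i = ii, j = jj, dims = c(20, 200),
            dimnames = list(sprintf("a%02d", 1:20),
                            sprintf("%dA", seq_len(200))))  # synthetic labels
        bm <- new("BiomarkerMatrix", membership = as(m, "ngCMatrix"),
                  order = rep(1L, 200))
        pr <- ldPrune(bm)
        nDistinct <- nrow(unique(as.data.frame(t(as.matrix(m)))))
        expect_identical(ncol(membership(pr$pruned)), nDistinct)
        # classes partition the universe
        expect_setequal(pr$classes$member, colnames(m))
        expect_identical(anyDuplicated(pr$classes$member), 0L)
    }
})

test_that("cross-order pruning prefers the lowest order, and both scopes work", {
    # column 2 of the alignment perfectly tracks column 1
    seqs <- AlignedSeqSet(c(a1 = "ACT", a2 = "ACT", a3 = "TGT"))
    vm <- oneHotEncode(seqs)
    b1 <- enumerateBiomarkers(vm, 1)
    b2 <- enumerateBiomarkers(vm, 2)
    joint <- ldPrune(list(b1, b2), acrossOrders = TRUE)
    # 1A, 2C and 1A/2C share a membership column; representative is order 1
    cl <- joint$classes
    expect_identical(cl$representative[cl$member == "1A/2C"], "1A")
    expect_identical(cl$representative[cl$member == "2C"], "1A")
    sep <- ldPrune(list(b1, b2), acrossOrders = FALSE)
    # within-order pruning keeps one column per order for the duplicate pair
    expect_true(all(c("1A", "1A/2C") %in%
                    biomarkerLabels(sep$pruned)))
})

test_that("pruning refuses mismatched ASV axes", {
    b1 <- enumerateBiomarkers(oneHotEncode(
        AlignedSeqSet(c(a1 = "AC", a2 = "AG"))), 1)
    b2 <- enumerateBiomarkers(oneHotEncode(
        AlignedSeqSet(c(x1 = "AC", x2 = "AG"))), 1)
    expect_error(ldPrune(list(b1, b2)), "ASV axis")
})

test_that("sparse construction equals the exhaustive oracle on random alignments", {
    set.seed(97)
    for (i in 1:4) {
        seqs <- randomAlignment(sample(5:12, 1), sample(6:12, 1))
        vm <- oneHotEncode(AlignedSeqSet(seqs))
        for (N in 1:3) {
            got <- bmAsColumns(enumerateBiomarkers(vm, N))
            want <- oracleBiomarkers(seqs, N)
            expect_setequal(names(got), names(want))
            for (lab in names(want))
                expect_identical(got[[lab]], unname(want[[lab]]))
        }
    }
})
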