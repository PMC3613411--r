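test_that("unique substitutions are counted with outgroup polarization", {
    aln <- Biostrings::AAStringSet(c(a = "MKVMS", b = "MKVMS",
                                     o = "MKVMS"))
    cu <- countUniqueSubstitutions(aln, "a", "b", "o")
    expect_equal(c(cu$nA, cu$nB), c(0L, 0L))

    aln2 <- Biostrings::AAStringSet(c(a = "MKV", b = "MKA", o = "MKA"))
    cu2 <- countUniqueSubstitutions(aln2, "a", "b", "o")
    expect_equal(c(cu2$nA, cu2$nB), c(1L, 0L))

    # gap/X columns are excluded; all-different columns count for neither
    aln3 <- Biostrings::AAStringSet(c(a = "MK-AW", b = "MKVCW",
                                      o = "MKVDX"))
    cu3 <- countUniqueSubstitutions(aln3, "a", "b", "o")
    expect_equal(cu3$nCompared, 3L)
    expect_equal(cu3$nUninformative, 1L)

    expect_error(countUniqueSubstitutions(aln3, "a", "b", "zz"),
                 "unknown")
})

test_that("counts match a position-by-position hand tally", {
    case <- makeRelativeRateCase(0.10, 0.05, 500, seed = 9)
    m <- do.call(rbind, strsplit(as.character(case$alignment), ""))
    handA <- sum(m["A", ] != m["B", ] & m["B", ] == m["O", ])
    handB <- sum(m["B", ] != m["A", ] & m["A", ] == m["O", ])
    cu <- countUniqueSubstitutions(case$alignment, "A", "B", "O")
    expect_equal(cu$nA, handA)
    expect_equal(cu$nB, handB)
})

test_that("the chi-square statistic is symmetric and handles zeros", {
    x <- tajimaChi2(22, 15)
    y <- tajimaChi2(15, 22)
    expect_equal(x$chi_square, y$chi_square)
    expect_equal(x$p_value, y$p_value)
    expect_equal(x$df, 1L)

    z <- tajimaChi2(0, 0)
    expect_equal(z$chi_square, 0)
    expect_equal(z$p_value, 1)

    expect_error(tajimaChi2(-1, 5), "non-negative")

    # chi-square is zero exactly when the counts are equal
    expect_equal(tajimaChi2(7, 7)$chi_square, 0)
    expect_gt(tajimaChi2(7, 8)$chi_square, 0)
})

test_that("protein distances behave like p and its Poisson correction", {
    aln <- Biostrings::AAStringSet(c(x = strrep("A", 100),
                                     y = strrep("A", 100)))
    expect_equal(pDistance(aln, "x", "y"), 0)
    expect_equal(poissonDistance(aln, "x", "y"), 0)

    y2 <- paste0(strrep("A", 99), "W")
    aln2 <- Biostrings::AAStringSet(c(x = strrep("A", 100), y = y2))
    expect_equal(pDistance(aln2, "x", "y"), 0.01)

    set.seed(51)
    for (r in 1:10) {
        a <- paste(sample(c("A", "W", "K"), 50, TRUE), collapse = "")
        b <- paste(sample(c("A", "W", "K"), 50, TRUE), collapse = "")
        aln3 <- Biostrings::AAStringSet(c(a = a, b = b))
        p <- pDistance(aln3, "a", "b")
        if (p > 0 && p < 1)
            expect_gt(poissonDistance(aln3, "a", "b"), p)
    }

    alnSat <- Biostrings::AAStringSet(c(x = "AAAA", y = "WWWW"))
    expect_error(poissonDistance(alnSat, "x", "y"), "saturated")
    alnGap <- Biostrings::AAStringSet(c(x = "--", y = "AA"))
    expect_error(pDistance(alnGap, "x", "y"), "pairwise-complete")
})

test_that("neighbor joining recovers additive trees exactly", {
    gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
    dm <- additive_matrix(gen)
    tr <- njTree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
    # branch lengths recovered: tip pendant edges match
    pend <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
    names(pend) <- tr$tip.label
    expect_equal(pend[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 1))

    # permuting the label order leaves the topology unchanged
    perm <- sample(rownames(dm))
    tr2 <- njTree(dm[perm, perm])
    expect_equal(as.numeric(ape::dist.topo(tr, tr2)), 0)

    expect_error(njTree(dm[1:2, 1:2]), "3 taxa")
    bad <- dm; bad[1, 2] <- bad[1, 2] + 1
    expect_error(njTree(bad), "symmetric")
})

test_that("NJ recovers the generating topology from random additive matrices", {
    set.seed(52)
    for (r in 1:15) {
        gen <- ape::rtree(sample(4:8, 1))
        gen$edge.length <- gen$edge.length + 0.1  # keep away from zero
        tr <- njTree(additive_matrix(gen))
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0,
                     info = paste("replicate", r))
    }
})

test_that("outgroup rooting is idempotent and places the outgroup first", {
    gen <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:2):1);")
    tr <- njTree(additive_matrix(gen))
    r1 <- rootAtOutgroup(tr, "D")
    expect_true(ape::is.rooted(r1))
    # D attaches directly at the root
    rootKids <- r1$edge[r1$edge[, 1] == length(r1$tip.label) + 1L, 2]
    expect_true(match("D", r1$tip.label) %in% rootKids)
    r2 <- rootAtOutgroup(r1, "D")
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(r1), ape::unroot(r2))), 0)
    expect_error(rootAtOutgroup(tr, "ZZ"), "unknown")
})

test_that("bootstrap supports are reproducible and resolve clear clusters", {
    # two well-separated 3-taxon clusters
    set.seed(53)
    base1 <- paste(sample(AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          120, TRUE), collapse = "")
    base2 <- paste(sample(AA, 120, TRUE), collapse = "")
    jitter <- function(s, k) {
        x <- strsplit(s, "")[[1]]
        i <- sample(length(x), k)
        x[i] <- vapply(x[i], function(r) sample(setdiff(AA, r), 1), "")
        paste(x, collapse = "")
    }
    aln <- Biostrings::AAStringSet(c(
        a1 = jitter(base1, 2), a2 = jitter(base1, 2), a3 = jitter(base1, 2),
        b1 = jitter(base2, 2), b2 = jitter(base2, 2), b3 = jitter(base2, 2)))
    bs <- suppressWarnings(bootstrapSupport(aln, nReplicates = 200, seed = 99))
    expect_false(bs$degenerate)
    expect_gte(max(bs$support), 95)

    bs2 <- suppressWarnings(bootstrapSupport(aln, nReplicates = 200, seed = 99))
    expect_identical(bs$support, bs2$support)

    # row order does not change the supports of the same clades
    perm <- sample(names(aln))
    bs3 <- suppressWarnings(bootstrapSupport(aln[perm], nReplicates = 50, seed = 7))
    bs4 <- suppressWarnings(bootstrapSupport(aln[perm], nReplicates = 50, seed = 7))
    expect_identical(bs3$support, bs4$support)

    alnId <- Biostrings::AAStringSet(c(x = "AAA", y = "AAA", z = "AAA"))
    expect_true(bootstrapSupport(alnId, nReplicates = 5,
                                 seed = 1)$degenerate)
})
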