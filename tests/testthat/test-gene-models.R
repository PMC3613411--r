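test_that("FASTA reading enforces the record contract", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(">x\nACGT", f)
    x <- readDnaFasta(f)
    expect_equal(names(x), "x")
    expect_equal(unname(Biostrings::width(x)), 4L)

    writeLines(">x\nACGT\n>x\nGGGG", f)
    expect_error(readDnaFasta(f), "duplicate")

    writeLines(">x\nACGU", f)
    expect_error(readDnaFasta(f), "illegal")

    # CRLF endings and lowercase tolerated
    writeBin(charToRaw(">y\r\nacgtn\r\n"), f)
    y <- readDnaFasta(f)
    expect_equal(as.character(y[[1]]), "ACGTN")

    writeLines(character(0), f)
    expect_error(readDnaFasta(f), "empty")
})

test_that("simulated gene FASTA round-trips through write and read", {
    tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
    sim <- simulateGeneFamily(tr, simulationConfig(), seed = 7)
    f <- withr::local_tempfile(fileext = ".fa")
    writeFasta(sim$sequences, f)
    back <- readDnaFasta(f)
    expect_identical(as.character(back), as.character(sim$sequences))
    expect_identical(names(back), names(sim$sequences))
})

test_that("gene models order exons by transcription direction", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "s1\t.\tgene\t10\t100\t.\t+\t.\tID=g1",
                 "s1\t.\tCDS\t60\t80\t.\t+\t.\tParent=g1",
                 "s1\t.\tCDS\t10\t30\t.\t+\t.\tParent=g1",
                 "s1\t.\tCDS\t90\t100\t.\t+\t.\tParent=g1"), gff)
    gm <- readGeneModel(gff)
    tab <- exonTable(gm)
    expect_equal(tab$index, 1:3)
    expect_equal(tab$start, c(10L, 60L, 90L))
    expect_equal(tab$phase, c(0L, (21L) %% 3L, (21L + 21L) %% 3L))

    writeLines(c("##gff-version 3",
                 "s1\t.\tgene\t10\t100\t.\t-\t.\tID=g1",
                 "s1\t.\tCDS\t60\t80\t.\t-\t.\tParent=g1",
                 "s1\t.\tCDS\t10\t30\t.\t-\t.\tParent=g1",
                 "s1\t.\tCDS\t90\t100\t.\t-\t.\tParent=g1"), gff)
    gmm <- readGeneModel(gff)
    expect_equal(exonTable(gmm)$start[1], 90L)  # exon 1 has largest start

    writeLines(c("##gff-version 3",
                 "s1\t.\tCDS\t10\t30\t.\t+\t.\tParent=g1",
                 "s1\t.\tCDS\t25\t40\t.\t+\t.\tParent=g1"), gff)
    expect_error(readGeneModel(gff), "overlapping")

    writeLines(c("##gff-version 3",
                 "s1\t.\tCDS\t10\t30\t.\t+\t.\tParent=g1",
                 "s1\t.\tCDS\t40\t50\t.\t-\t.\tParent=g1"), gff)
    expect_error(readGeneModel(gff), "strand")
})

test_that("a synthetic 19-exon model survives the GFF3 round trip", {
    tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
    sim <- simulateGeneFamily(tr, simulationConfig(), seed = 11)
    expect_equal(nExons(sim$refModel), 19L)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeGeneModel(sim$refModel, gff)
    back <- readGeneModel(gff, reference = TRUE)
    expect_equal(exonTable(back)[, c("start", "end", "phase")],
                 exonTable(sim$refModel)[, c("start", "end", "phase")])
})

test_that("CDS extraction respects strand and bounds", {
    g <- Biostrings::DNAString("ATGAAACCCGGG")
    gm <- GeneModel("g", "sp", "s", "+", start = 1, end = 6)
    expect_equal(as.character(extractCds(g, gm)), "ATGAAA")
    gmm <- GeneModel("g", "sp", "s", "-", start = 1, end = 6)
    expect_equal(as.character(extractCds(g, gmm)), "TTTCAT")
    gbad <- GeneModel("g", "sp", "s", "+", start = 10, end = 20)
    expect_error(extractCds(g, gbad), "outside")
})

test_that("every simulated functional gene yields one terminal stop", {
    tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
    cfg <- simulationConfig(lossBranches = "A")
    for (seed in 1:5) {
        sim <- simulateGeneFamily(tr, cfg, seed = seed)
        for (sp in c("B", "C")) {
            aa <- as.character(translateCds(
                extractCds(sim$sequences[[sp]], sim$models[[sp]])))
            expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
            expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
        }
    }
})

test_that("translation follows the standard code with N handling", {
    expect_equal(as.character(translateCds("ATGTAA")), "M*")
    expect_equal(as.character(translateCds("ATGNNNTGA")), "MX*")
    expect_error(translateCds(""), "empty")
    expect_warning(out <- translateCds("ATGTAAC"), "trailing")
    expect_equal(as.character(out), "M*")

    set.seed(5)
    for (r in 1:10) {
        cds <- random_dna(300 * 3)
        expect_equal(as.character(translateCds(cds)),
                     oracle_translate(cds))
    }
})

test_that("locus span arithmetic is exact and additive", {
    expect_equal(locusSpan(1, 1), 1L)
    expect_equal(locusSpan(27719709, 27746554), 26846L)
    expect_error(locusSpan(10, 5), "before")
    # additivity over abutting sub-intervals
    expect_equal(locusSpan(100, 149) + locusSpan(150, 220),
                 locusSpan(100, 220))
})

test_that("Newick trees round trip with labels and branch lengths", {
    f <- withr::local_tempfile(fileext = ".nwk")
    writeLines("((A:1.5,B:2.25):0.5,C:3);", f)
    tr <- readSpeciesTree(f)
    expect_equal(sort(tr$tip.label), c("A", "B", "C"))
    expect_equal(sum(tr$edge[, 1] == length(tr$tip.label) + 1L), 2L)
    txt <- writeSpeciesTree(tr)
    tr2 <- ape::read.tree(text = txt)
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    expect_equal(sort(tr2$edge.length), sort(tr$edge.length))

    writeLines("((A,B,C;", f)
    expect_error(readSpeciesTree(f))

    # packaged phylogeny round trips with an identical tip set
    vt <- vertebratePhylogeny()
    vt2 <- ape::read.tree(text = writeSpeciesTree(vt))
    expect_setequal(vt2$tip.label, vt$tip.label)
})
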