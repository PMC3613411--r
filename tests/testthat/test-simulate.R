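tr6 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1,F:1);")
tr6 <- ape::root(ape::unroot(tr6), outgroup = "F", resolve.root = TRUE)

test_that("zero rates propagate the root unchanged", {
    cfg <- simulationConfig(substitutionRate = 0, indelRate = 0,
                            lossBranches = "A")
    sim <- simulateGeneFamily(tr6, cfg, seed = 1)
    expect_equal(nrow(sim$truth), 0L)
    ref <- as.character(sim$refSequence)
    for (sp in tr6$tip.label)
        expect_identical(as.character(sim$sequences[[sp]]), ref)
})

test_that("disruptions are confined to the loss subtree", {
    cfg <- simulationConfig(lossBranches = list(c("A", "B")))
    for (seed in 1:5) {
        sim <- simulateGeneFamily(tr6, cfg, seed = seed)
        expect_setequal(sim$lossTips, c("A", "B"))
        expect_true(all(sim$truth$species %in% c("A", "B")))
        expect_gt(nrow(sim$truth), 0)
    }
})

test_that("functional constraints hold across seeds", {
    cfg <- simulationConfig(lossBranches = "D")
    for (seed in 1:25) {
        sim <- simulateGeneFamily(tr6, cfg, seed = seed)
        for (sp in setdiff(tr6$tip.label, "D")) {
            model <- sim$models[[sp]]
            seq <- sim$sequences[[sp]]
            aa <- as.character(translateCds(extractCds(seq, model)))
            expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
            expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
            # GT-AG introns
            tab <- exonTable(model)
            s <- as.character(seq)
            for (i in seq_len(nrow(tab) - 1L)) {
                expect_equal(substr(s, tab$end[i] + 1, tab$end[i] + 2),
                             "GT")
                expect_equal(substr(s, tab$start[i + 1] - 2,
                                    tab$start[i + 1] - 1), "AG")
            }
        }
    }
})

test_that("simulation is bit-reproducible under a fixed seed", {
    cfg <- simulationConfig(lossBranches = "A")
    s1 <- simulateGeneFamily(tr6, cfg, seed = 77)
    s2 <- simulateGeneFamily(tr6, cfg, seed = 77)
    expect_identical(as.character(s1$sequences), as.character(s2$sequences))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateGeneFamily(tr6, cfg, seed = 78)
    expect_false(identical(as.character(s1$sequences),
                           as.character(s3$sequences)))
})

test_that("the relative-rate generator matches its own truth", {
    z <- makeRelativeRateCase(0, 0, 100, seed = 1)
    expect_equal(z$truth$nA, 0L)
    expect_equal(z$truth$nB, 0L)
    cu <- countUniqueSubstitutions(z$alignment, "A", "B", "O")
    expect_equal(tajimaChi2(cu$nA, cu$nB)$chi_square, 0)

    r1 <- makeRelativeRateCase(0.1, 0.05, 500, seed = 4)
    r2 <- makeRelativeRateCase(0.1, 0.05, 500, seed = 4)
    expect_identical(as.character(r1$alignment),
                     as.character(r2$alignment))

    expect_error(makeRelativeRateCase(1, 0.5, 10), "rates")
})

test_that("loss branches may be named by tip, node label, or MRCA set", {
    tr <- ape::read.tree(text = "((A:1,B:1)ab:1,C:1);")
    cfg1 <- simulationConfig(lossBranches = "ab")
    sim1 <- simulateGeneFamily(tr, cfg1, seed = 2)
    expect_setequal(sim1$lossTips, c("A", "B"))
    cfg2 <- simulationConfig(lossBranches = list(c("A", "B")))
    sim2 <- simulateGeneFamily(tr, cfg2, seed = 2)
    expect_setequal(sim2$lossTips, c("A", "B"))
    expect_error(simulateGeneFamily(
        tr, simulationConfig(lossBranches = "nope"), seed = 1), "not in tree")
})

test_that("flat key-value config files round trip", {
    f <- withr::local_tempfile(fileext = ".cfg")
    writeLines(c("# comment", "nExons = 12", "substitutionRate 0.01",
                 "exonLengthRange = 50,90",
                 "lossBranches = A+B,D"), f)
    cfg <- readSimulationConfig(f)
    expect_equal(cfg$nExons, 12L)
    expect_equal(cfg$substitutionRate, 0.01)
    expect_equal(cfg$exonLengthRange, c(50L, 90L))
    expect_equal(cfg$lossBranches, list(c("A", "B"), "D"))
    writeLines("whatKey = 1", f)
    expect_error(readSimulationConfig(f), "unknown config key")
})
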