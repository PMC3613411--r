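test_that("splice events follow the GT-AG consensus with exon attribution", {
    donors <- stats::setNames(rep("GT", 18), 1:18)
    acceptors <- stats::setNames(rep("AG", 18), 2:19)
    expect_equal(nrow(detectSpliceMutations(donors, acceptors)), 0)

    donors[["2"]] <- "AT"
    ev <- detectSpliceMutations(donors, acceptors, species = "sp")
    expect_equal(nrow(ev), 1)
    expect_equal(ev$exon, 2L)
    expect_equal(ev$category, "SPLICE_DONOR")

    # ferret-like: acceptor mutations before exons 9, 10 and 12
    donors[["2"]] <- "GT"
    acceptors[c("9", "10", "12")] <- "AA"
    ev <- detectSpliceMutations(donors, acceptors, species = "ferretlike")
    expect_equal(nrow(ev), 3)
    expect_true(all(ev$category == "SPLICE_ACCEPTOR"))
    expect_equal(ev$exon, c(9L, 10L, 12L))

    # GC donors are flagged, not silently accepted
    acceptors[c("9", "10", "12")] <- "AG"
    donors[["5"]] <- "GC"
    ev <- detectSpliceMutations(donors, acceptors)
    expect_match(ev$detail, "noncanonical")

    # missing boundaries are skipped
    donors[["5"]] <- NA_character_
    expect_equal(nrow(detectSpliceMutations(donors, acceptors)), 0)
})

test_that("premature stops are found exactly where the scan oracle finds them", {
    set.seed(21)
    cds <- random_orf(200)
    exonLens <- c(rep(60L, 9), 3L * 200L - 540L)
    expect_equal(nrow(detectPrematureStops(cds, exonLens)), 0)

    # one engineered TGA mid exon 7 (exon 7 covers bases 361..420)
    mut <- cds
    substr(mut, 379, 381) <- "TGA"
    ev <- detectPrematureStops(mut, exonLens, species = "sp")
    expect_equal(nrow(ev), 1)
    expect_equal(ev$exon, 7L)
    expect_equal(ev$category, "PREMATURE_STOP")

    # 100 random single-base substitutions vs the brute-force oracle
    for (r in 1:100) {
        m <- cds
        pos <- sample(nchar(cds) - 3L, 1)  # keep the terminal stop
        substr(m, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
        got <- detectPrematureStops(m, exonLens)
        want <- oracle_stop_codons(m)
        expect_equal(nrow(got), length(want))
        if (length(want)) {
            wantExon <- findInterval((want - 1L) * 3L,
                                     c(0L, cumsum(exonLens)))
            expect_equal(got$exon, wantExon)
        }
    }
})

test_that("status classification implements the pseudogene rules", {
    # cow-like: 8 frameshift exons + 6 splice exons
    fsx <- c(2, 5, 7, 8, 15, 17, 18, 19)
    spx <- c(2, 9, 10, 12, 15, 18)
    ev <- rbind(
        do.call(rbind, lapply(fsx, function(e)
            data.frame(species = "Cow", exon = e, category = "FRAMESHIFT",
                       detail = ""))),
        do.call(rbind, lapply(spx, function(e)
            data.frame(species = "Cow", exon = e, category = "SPLICE_DONOR",
                       detail = ""))))
    expect_equal(statusOf(classifyStatus(ev, 19, 19, species = "Cow")),
                 "INACTIVATED")

    # squirrel-like: a single frameshift in exon 8
    ev1 <- data.frame(species = "Squirrel", exon = 8,
                      category = "FRAMESHIFT", detail = "")
    expect_equal(statusOf(classifyStatus(ev1, 19, 19)),
                 "POTENTIALLY_INTACT")

    expect_equal(statusOf(classifyStatus(NULL, 19, 19)), "INTACT")
    expect_equal(statusOf(classifyStatus(NULL, 17, 19)),
                 "POTENTIALLY_INTACT")
    expect_equal(statusOf(classifyStatus(NULL, 0, 19,
                                         sequenceFound = FALSE,
                                         absence = "DELETED")), "DELETED")
    expect_equal(statusOf(classifyStatus(NULL, 0, 19,
                                         sequenceFound = FALSE)),
                 "UNRESOLVED")
    expect_error(classifyStatus(NULL, 20, 19), "exceeds")
})

test_that("adding events never moves a report toward INTACT", {
    rank <- c(INTACT = 1, POTENTIALLY_INTACT = 2, INACTIVATED = 3)
    set.seed(22)
    for (r in 1:20) {
        n1 <- sample(0:3, 1)
        n2 <- n1 + sample(1:3, 1)
        mk <- function(n) if (n == 0) NULL else
            data.frame(species = "s", exon = sample(19, n, replace = TRUE),
                       category = "FRAMESHIFT", detail = "")
        s1 <- statusOf(classifyStatus(mk(n1), 19, 19))
        s2 <- statusOf(classifyStatus(mk(n2), 19, 19))
        expect_gte(rank[[s2]], rank[[s1]])
    }
})

test_that("tabulation counts distinct mutated exons per species", {
    ev <- censusEvents()
    rep <- runStatusReplay(ev, exonsTotal = 19L)
    tab <- rep$bySpecies
    expect_equal(tab$n_mutated_exons[tab$species == "Cow"], 11L)
    expect_equal(sum(tab$status == "INACTIVATED"), 14L)
    expect_setequal(tab$species[tab$status == "POTENTIALLY_INTACT"],
                    c("Squirrel", "Tree_shrew", "Opossum"))
    expect_true(all(tab$n_mutated_exons <= 19L))

    # union count is invariant to event ordering
    shuf <- ev[sample(nrow(ev)), ]
    tab2 <- runStatusReplay(shuf, exonsTotal = 19L,
                            species = tab$species)$bySpecies
    expect_equal(tab2$n_mutated_exons, tab$n_mutated_exons)

    # zero events yield zero counts
    r0 <- classifyStatus(NULL, 19, 19, species = "none")
    t0 <- tabulateDisruptions(list(r0))
    expect_equal(t0$bySpecies$n_events, 0L)
    expect_equal(t0$bySpecies$n_mutated_exons, 0L)
})

test_that("scanGene recovers injected truth on simulated loss clades", {
    tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
    cfg <- simulationConfig(lossBranches = list(c("A", "B")))
    exact <- 0L
    nrep <- 10L
    for (s in seq_len(nrep)) {
        sim <- simulateGeneFamily(tr, cfg, seed = 100 + s)
        det <- do.call(rbind, lapply(c("A", "B"), function(sp)
            events(scanGene(sim$refSequence, sim$refModel,
                            sim$sequences[[sp]], sp))))
        tk <- sort(unique(with(sim$truth, paste(species, exon, category))))
        dk <- sort(unique(with(det, paste(species, exon, category))))
        if (identical(tk, dk)) exact <- exact + 1L
        # functional tips must scan clean
        for (sp in c("C", "D")) {
            r <- scanGene(sim$refSequence, sim$refModel,
                          sim$sequences[[sp]], sp)
            expect_equal(statusOf(r), "INTACT")
        }
    }
    expect_gte(exact, nrep - 1L)
})

test_that("a missing target sequence routes through absence calling", {
    tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
    sim <- simulateGeneFamily(tr, simulationConfig(), seed = 3)
    r <- scanGene(sim$refSequence, sim$refModel, NA, "ghost",
                  absence = "DELETED")
    expect_equal(statusOf(r), "DELETED")
    r2 <- scanGene(sim$refSequence, sim$refModel, NA, "ghost")
    expect_equal(statusOf(r2), "UNRESOLVED")
})
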