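#' Scan a set of candidate loci against a reference gene model
#'
#' Runs [scanGene()] for every species in `targets`; species listed with
#' an `NA`/missing sequence are routed through synteny-based absence
#' calling ([callAbsence()]) when fragment maps are supplied.  Results
#' are tabulated with [tabulateDisruptions()].
#'
#' @param refGenome reference locus (`DNAString`/`DNAStringSet`).
#' @param refModel reference [GeneModel].
#' @param targets named list (or `DNAStringSet`) of candidate loci; an
#'   `NA` element marks a species with no recovered sequence.
#' @param maps optional fragment maps ([readFragmentMap()] layout)
#'   covering the sequence-less species.
#' @param target gene symbol used for absence calling.
#' @param flank5,flank3 flanking anchors for absence calling (required
#'   when `maps` is given).
#' @param flank intronic flank length for exon alignment (bases).
#' @return a `RunReport` list: `reports` (named list of
#'   [GeneStatusReport]), `disruptionTable`, `statusCounts`,
#'   `absenceCalls`, and a `provenance` block (package version and the
#'   run configuration digest).
#' @export
runScan <- function(refGenome, refModel, targets, maps = NULL,
                    target = "GENE", flank5 = NA_character_,
                    flank3 = NA_character_, flank = 20L) {
    species <- names(targets)
    if (is.null(species) || any(!nzchar(species)))
        stop("targets must be named by species")
    reports <- vector("list", length(targets))
    absCalls <- list()
    for (i in seq_along(targets)) {
        tgt <- targets[[i]]
        if (is(tgt, "DNAString")) tgt <- as.character(tgt)
        absence <- NULL
        if ((is.null(tgt) || (length(tgt) == 1L && is.na(tgt))) &&
            !is.null(maps)) {
            sm <- maps[maps$species == species[i], , drop = FALSE]
            if (nrow(sm)) {
                call <- callAbsence(sm, target, flank5, flank3)
                absCalls[[length(absCalls) + 1L]] <- call
                absence <- call$status
            }
        }
        reports[[i]] <- scanGene(refGenome, refModel, tgt, species[i],
                                 flank = flank, absence = absence)
    }
    names(reports) <- species
    tab <- tabulateDisruptions(reports)
    absenceCalls <- if (length(absCalls)) do.call(rbind, absCalls)
        else data.frame(species = character(0), target = character(0),
                        status = character(0), evidence = character(0),
                        stringsAsFactors = FALSE)
    cfg <- list(target = target, flank5 = flank5, flank3 = flank3,
                flank = as.integer(flank), species = species)
    list(reports = reports, disruptionTable = tab$bySpecies,
         statusCounts = tab$statusCounts, absenceCalls = absenceCalls,
         provenance = .provenance(cfg))
}

#' Replay tabulated disruption records through the classifier
#'
#' Classifies species from an event table alone (e.g. the bundled
#' census), without sequence-level scanning: every species gets
#' [classifyStatus()] applied to its events, assuming full exon
#' recovery.
#'
#' @param events event `data.frame` (columns `species`, `exon`,
#'   `category`, `detail`).
#' @param exonsTotal number of reference exons.
#' @param species optional character vector fixing the species set and
#'   order (defaults to those present in `events`).
#' @return list of [GeneStatusReport] plus the tabulation, as in
#'   [tabulateDisruptions()].
#' @export
runStatusReplay <- function(events, exonsTotal = 19L, species = NULL) {
    if (is.null(species)) species <- unique(events$species)
    reports <- lapply(species, function(s) {
        ev <- events[events$species == s, , drop = FALSE]
        classifyStatus(ev, exonsTotal, exonsTotal, species = s)
    })
    names(reports) <- species
    tab <- tabulateDisruptions(reports)
    c(list(reports = reports), tab)
}

#' Map loss events and run relative-rate tests
#'
#' `runParsimony()` wraps [dolloMinEvents()] with report formatting;
#' `runRateTests()` applies [tajimaChi2()] / [relativeRateTest()] to a
#' table of lineage triples, optionally adding a Bonferroni column
#' (off by default; the raw per-test p-values are the primary output).
#'
#' @param tree rooted `phylo`.
#' @param states named tip-state vector (see [dolloMinEvents()]).
#' @return `runParsimony()`: list with `placement` ([LossPlacement]),
#'   `nEvents`, `fitchScore`, and `annotatedNewick`.
#' @export
runParsimony <- function(tree, states) {
    missing <- setdiff(tree$tip.label, names(states))
    if (length(missing))
        stop("no state for tip(s): ", paste(missing, collapse = ", "))
    pl <- dolloMinEvents(tree, states)
    list(placement = pl, nEvents = nEvents(pl),
         fitchScore = fitchScore(tree, states),
         annotatedNewick = annotateLossTree(pl))
}

#' @rdname runParsimony
#' @param triples `data.frame` with columns `lineage_a`, `lineage_b`,
#'   `outgroup` and either counts (`n_a`, `n_b`) or nothing (counts are
#'   then taken from `aln`).
#' @param aln aligned [Biostrings::AAStringSet] (needed when `triples`
#'   carries no counts).
#' @param bonferroni add a Bonferroni-adjusted p-value column.
#' @return `runRateTests()`: `data.frame` of test rows.
#' @export
runRateTests <- function(triples, aln = NULL, bonferroni = FALSE) {
    haveCounts <- all(c("n_a", "n_b") %in% names(triples))
    rows <- lapply(seq_len(nrow(triples)), function(i) {
        if (haveCounts)
            tajimaChi2(triples$n_a[i], triples$n_b[i],
                       lineageA = triples$lineage_a[i],
                       lineageB = triples$lineage_b[i],
                       outgroup = triples$outgroup[i])
        else {
            if (is.null(aln))
                stop("need an alignment when triples carry no counts")
            relativeRateTest(aln, triples$lineage_a[i],
                             triples$lineage_b[i], triples$outgroup[i])
        }
    })
    out <- do.call(rbind, rows)
    if (bonferroni)
        out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
    rownames(out) <- NULL
    out
}

.provenance <- function(cfg) {
    txt <- paste(deparse(cfg, control = "all"), collapse = "")
    tf <- tempfile()
    writeLines(txt, tf)
    h <- unname(tools::md5sum(tf))
    unlink(tf)
    list(package = "GeneLossKit",
         version = as.character(utils::packageVersion("GeneLossKit")),
         configHash = h)
}

#' Write a run report to disk
#'
#' Emits fixed-column-order TSVs (`disruptions.tsv`, `status.tsv`,
#' `absence.tsv`) plus a versioned JSON with the full report; re-running
#' on identical inputs reproduces byte-identical files (the provenance
#' block contains no timestamps).
#'
#' @param report a `RunReport` from [runScan()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
writeReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    w <- function(df, file) {
        p <- file.path(dir, file)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        p
    }
    ev <- do.call(rbind, c(list(.emptyEvents()),
                           lapply(report$reports, events)))
    rownames(ev) <- NULL
    paths <- c(paths, w(ev, "disruptions.tsv"))
    status <- data.frame(
        species = vapply(report$reports, geneSpecies, ""),
        status = vapply(report$reports, statusOf, ""),
        n_disruptions = vapply(report$reports, nDisruptions, 0L),
        stringsAsFactors = FALSE)
    rownames(status) <- NULL
    paths <- c(paths, w(status, "status.tsv"))
    paths <- c(paths, w(report$absenceCalls, "absence.tsv"))
    json <- list(schema = "GeneLossKit-report-v1",
                 provenance = report$provenance,
                 statusCounts = as.list(report$statusCounts),
                 status = status, disruptions = ev,
                 absenceCalls = report$absenceCalls)
    jp <- file.path(dir, "report.json")
    jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, jp)
    invisible(paths)
}
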