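STOP_CODONS <- c("TAA", "TAG", "TGA")

# one canonical event row; keeps column order stable everywhere
.eventRow <- function(species, exon, category, detail) {
    data.frame(species = species, exon = as.integer(exon),
               category = category, detail = detail,
               stringsAsFactors = FALSE)
}

.emptyEvents <- function() {
    data.frame(species = character(0), exon = integer(0),
               category = character(0), detail = character(0),
               stringsAsFactors = FALSE)
}

#' Detect a frameshift in one aligned exon
#'
#' A frameshift is called when the net insertion/deletion length within
#' the exon-proper columns is not a multiple of three.  Two compensating
#' indels inside one exon cancel; the damage they leave behind is caught
#' downstream by the premature-stop scan on the frame-restored sequence.
#'
#' @param ea an [ExonAlignment] with `found = TRUE`.
#' @param species species label for the event record.
#' @return a 0- or 1-row event `data.frame` (columns `species`, `exon`,
#'   `category`, `detail`).
#' @export
detectFrameshift <- function(ea, species = NA_character_) {
    stopifnot(is(ea, "ExonAlignment"))
    if (!ea@found) stop("frameshift detection needs a found exon")
    if (ea@netIndel %% 3L == 0L) return(.emptyEvents())
    .eventRow(species, ea@exonIndex, "FRAMESHIFT",
              sprintf("net indel %+d", ea@netIndel))
}

#' Detect splice-dinucleotide disruptions
#'
#' Checks the canonical GT-AG consensus at every intron boundary.  A
#' donor that is not `GT` yields a `SPLICE_DONOR` event on the preceding
#' exon; an acceptor that is not `AG` yields a `SPLICE_ACCEPTOR` event on
#' the following exon.  `GC` donors are still splice-competent in a
#' minority of real introns, so they are reported with a
#' `noncanonical (GC)` detail flag rather than silently passed.  Missing
#' boundaries (`NA`, e.g. from an unfound exon) are skipped.
#'
#' @param donors named character vector of donor dinucleotides, names =
#'   index of the exon the intron follows (exons `1..n-1`).
#' @param acceptors named character vector of acceptor dinucleotides,
#'   names = index of the exon the intron precedes (exons `2..n`).
#' @param species species label for the event records.
#' @return event `data.frame`, ordered by exon index.
#' @export
detectSpliceMutations <- function(donors, acceptors,
                                  species = NA_character_) {
    out <- list()
    for (i in seq_along(donors)) {
        d <- donors[[i]]
        if (is.na(d)) next
        if (!identical(d, "GT")) {
            detail <- if (identical(d, "GC"))
                "noncanonical (GC) donor" else paste("donor", d)
            out[[length(out) + 1L]] <-
                .eventRow(species, as.integer(names(donors)[i]),
                          "SPLICE_DONOR", detail)
        }
    }
    for (i in seq_along(acceptors)) {
        a <- acceptors[[i]]
        if (is.na(a)) next
        if (!identical(a, "AG"))
            out[[length(out) + 1L]] <-
                .eventRow(species, as.integer(names(acceptors)[i]),
                          "SPLICE_ACCEPTOR", paste("acceptor", a))
    }
    if (!length(out)) return(.emptyEvents())
    ev <- do.call(rbind, out)
    ev[order(ev$exon, ev$category), , drop = FALSE]
}

#' Detect premature stop codons in a frame-restored coding sequence
#'
#' Scans the repaired coding sequence (target bases projected onto
#' reference coordinates, so the reference reading frame applies) for
#' in-frame stop codons strictly upstream of the reference terminal
#' stop.  Codons containing `N` never count.  Each stop is attributed to
#' the exon containing the codon's first base.
#'
#' @param repairedCds character or `DNAString`, length equal to the
#'   reference coding length.
#' @param exonLengths integer vector of reference exon lengths in
#'   transcription order (defines the codon-to-exon attribution).
#' @param species species label for the event records.
#' @return event `data.frame`.
#' @export
detectPrematureStops <- function(repairedCds, exonLengths,
                                 species = NA_character_) {
    cds <- toupper(as.character(repairedCds))
    L <- nchar(cds)
    if (L < 3L) stop("coding sequence shorter than one codon")
    nCodons <- L %/% 3L
    if (nCodons < 2L) return(.emptyEvents())
    starts <- seq(1L, by = 3L, length.out = nCodons - 1L) # exclude terminal
    codons <- substring(cds, starts, starts + 2L)
    hit <- which(codons %in% STOP_CODONS)
    if (!length(hit)) return(.emptyEvents())
    bounds <- cumsum(exonLengths)
    exonOf <- findInterval(starts[hit] - 1L, c(0L, bounds),
                           left.open = FALSE)
    do.call(rbind, lapply(seq_along(hit), function(k)
        .eventRow(species, exonOf[k], "PREMATURE_STOP",
                  sprintf("%s at codon %d", codons[hit[k]], hit[k]))))
}

# Premature-stop scan over per-exon target sequences, reading each exon
# in the frame the reference carries into it (phase = coding bases
# carried over).  Frame is restored at every exon boundary, so a
# frameshifting indel scrambles reading only within its own exon; the
# codons scanned depend just on the base string assigned to the exon,
# never on where the aligner placed a gap.  Codons spanning exon
# junctions are not scanned; the final complete codon of the last exon
# (the terminal stop position) is excluded.  `exonStrings` may contain
# NA for exons that were not recovered.
.exonStopEvents <- function(exonStrings, phases, species = NA_character_) {
    n <- length(exonStrings)
    out <- list()
    for (i in seq_len(n)) {
        s <- exonStrings[[i]]
        if (is.null(s) || is.na(s) || !nzchar(s)) next
        off <- (3L - phases[i]) %% 3L
        len <- nchar(s)
        if (len - off < 3L) next
        starts <- seq(off + 1L, len - 2L, by = 3L)
        if (i == n && length(starts))
            starts <- starts[-length(starts)]  # reference terminal stop
        if (!length(starts)) next
        codons <- substring(s, starts, starts + 2L)
        hit <- which(codons %in% STOP_CODONS & !grepl("N", codons))
        for (k in hit)
            out[[length(out) + 1L]] <-
                .eventRow(species, i, "PREMATURE_STOP",
                          sprintf("%s at exon offset %d", codons[k],
                                  starts[k]))
    }
    if (!length(out)) return(.emptyEvents())
    do.call(rbind, out)
}

#' Classify the functional status of one species' gene
#'
#' Applies the pseudogene rules: a gene with two or more disrupting
#' events is `INACTIVATED`; exactly one event leaves it
#' `POTENTIALLY_INTACT` (a single change may be a sequencing error or a
#' rare allele); zero events with full exon recovery is `INTACT`, while
#' zero events with missing exons stays `POTENTIALLY_INTACT` (missing
#' exons are not counted as disruptions).  When no sequence was found at
#' all, a synteny-based absence call decides between `DELETED` and
#' `UNRESOLVED`.
#'
#' @param events event `data.frame` (see [detectFrameshift()]).
#' @param exonsFound,exonsTotal exon recovery counts.
#' @param species species label.
#' @param sequenceFound `FALSE` when no part of the gene was found.
#' @param absence optional absence verdict (`"PRESENT"`, `"DELETED"`,
#'   `"UNRESOLVED"`) from [callAbsence()], consulted only when
#'   `sequenceFound = FALSE`.
#' @param alignments optional list of [ExonAlignment] objects to carry in
#'   the report.
#' @return a [GeneStatusReport].
#' @export
classifyStatus <- function(events, exonsFound, exonsTotal,
                           species = NA_character_, sequenceFound = TRUE,
                           absence = NULL, alignments = list()) {
    exonsFound <- as.integer(exonsFound)
    exonsTotal <- as.integer(exonsTotal)
    if (exonsFound > exonsTotal)
        stop("exonsFound exceeds exonsTotal")
    if (is.null(events) || !nrow(events)) events <- .emptyEvents()
    n <- nrow(events)
    status <- if (!sequenceFound) {
        if (!is.null(absence) && identical(absence, "DELETED"))
            "DELETED" else "UNRESOLVED"
    } else if (n >= 2L) "INACTIVATED"
    else if (n == 1L) "POTENTIALLY_INTACT"
    else if (exonsFound == exonsTotal) "INTACT"
    else "POTENTIALLY_INTACT"
    new("GeneStatusReport", species = as.character(species),
        status = status, nDisruptions = n, exonsFound = exonsFound,
        exonsTotal = exonsTotal, events = events,
        alignments = alignments)
}

#' Tabulate disruptions across species
#'
#' Builds the two-column disruption table used for reporting: per
#' species, the sorted distinct exon lists in a "frame shift" column
#' (frameshifts and premature stops folded together) and a "splice
#' junction" column (donor and acceptor events), the number of distinct
#' mutated exons, and the total event count, plus a summary of species
#' counts per status.
#'
#' @param reports list of [GeneStatusReport] objects.
#' @return a list with elements `bySpecies` (`data.frame` with columns
#'   `species`, `status`, `frameshift_exons`, `splice_exons`,
#'   `n_mutated_exons`, `n_events`) and `statusCounts` (named integer
#'   vector over all status levels).
#' @export
tabulateDisruptions <- function(reports) {
    if (!length(reports)) stop("need at least one report")
    rows <- lapply(reports, function(r) {
        ev <- events(r)
        fs <- sort(unique(ev$exon[ev$category %in%
                                  c("FRAMESHIFT", "PREMATURE_STOP")]))
        sp <- sort(unique(ev$exon[ev$category %in%
                                  c("SPLICE_DONOR", "SPLICE_ACCEPTOR")]))
        data.frame(species = geneSpecies(r), status = statusOf(r),
                   frameshift_exons = paste(fs, collapse = ","),
                   splice_exons = paste(sp, collapse = ","),
                   n_mutated_exons = length(unique(ev$exon)),
                   n_events = nrow(ev), stringsAsFactors = FALSE)
    })
    bySpecies <- do.call(rbind, rows)
    counts <- table(factor(bySpecies$status, levels = VALID_STATUS))
    list(bySpecies = bySpecies,
         statusCounts = stats::setNames(as.integer(counts), names(counts)))
}

#' Scan a candidate locus for coding disruptions
#'
#' End-to-end disruption detection for one species: each reference exon,
#' carried with intronic flanks, is fit-aligned into the target locus;
#' frameshifts, splice-dinucleotide changes, and premature stops (on the
#' frame-restored projection) are collected and the gene status is
#' classified.  The target window must be supplied in the transcription
#' orientation of the gene; minus-strand reference models are handled by
#' flipping the reference internally.
#'
#' @param refGenome `DNAString`/`DNAStringSet` holding the reference
#'   locus.
#' @param refModel the reference [GeneModel].
#' @param target character or `DNAString`: candidate locus of the query
#'   species, or `NULL`/`NA` when no sequence was found.
#' @param species query species label.
#' @param flank intronic flank length carried with each exon (bases).
#' @param absence optional absence verdict for missing sequences, see
#'   [classifyStatus()].
#' @return a [GeneStatusReport] with per-exon alignments attached.
#' @export
scanGene <- function(refGenome, refModel, target, species,
                     flank = 20L, absence = NULL) {
    if (is(refGenome, "DNAStringSet")) {
        stopifnot(length(refGenome) == 1L)
        refGenome <- refGenome[[1]]
    }
    tab <- exonTable(refModel)
    n <- nrow(tab)
    if (is.null(target) || (length(target) == 1L && is.na(target)) ||
        (is.character(target) && !nzchar(target)))
        return(classifyStatus(.emptyEvents(), 0L, n, species = species,
                              sequenceFound = FALSE, absence = absence))
    refSeq <- toupper(as.character(refGenome))
    if (identical(modelStrand(refModel), "-")) {
        refSeq <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(refSeq)))
        L <- nchar(refSeq)
        newStart <- L - tab$end + 1L
        newEnd <- L - tab$start + 1L
        tab$start <- newStart
        tab$end <- newEnd
    }
    tgt <- toupper(as.character(target))

    aligns <- vector("list", n)
    donors <- stats::setNames(rep(NA_character_, max(n - 1L, 0L)),
                              seq_len(max(n - 1L, 0L)))
    acceptors <- stats::setNames(rep(NA_character_, max(n - 1L, 0L)),
                                 if (n > 1L) 2:n else integer(0))
    exonLens <- tab$end - tab$start + 1L
    exonStrings <- as.list(rep(NA_character_, n))
    fsEvents <- list()
    cursor <- 0L  # last target base claimed by an upstream exon
    prevRefEnd <- 0L
    slack <- 250L
    for (i in seq_len(n)) {
        ws <- max(1L, tab$start[i] - flank)
        we <- min(nchar(refSeq), tab$end[i] + flank)
        refPiece <- substr(refSeq, ws, we)
        es <- tab$start[i] - ws + 1L
        ee <- tab$end[i] - ws + 1L
        # exons are collinear: search downstream of the previous exon,
        # within a window sized by the reference gap plus slack, falling
        # back to the whole locus if the window misses
        from <- cursor + 1L
        to <- min(nchar(tgt),
                  cursor + (tab$end[i] - prevRefEnd) + flank + slack)
        ea <- NULL
        if (from <= 1L || to - from >= 3L * (ee - es + 1L)) {
            ea <- alignExon(substr(tgt, from, to), refSeq = refPiece,
                            exonStart = es, exonEnd = ee, exonIndex = i,
                            isFirst = i == 1L, isLast = i == n,
                            mode = "fit")
            if (ea@found && !is.na(ea@tgtStart)) {
                ea@tgtStart <- ea@tgtStart + from - 1L
                ea@tgtEnd <- ea@tgtEnd + from - 1L
                if (i < n && !is.na(ea@tgtEnd) &&
                    ea@tgtEnd + 2L <= nchar(tgt))
                    ea@donor <- substr(tgt, ea@tgtEnd + 1L, ea@tgtEnd + 2L)
                if (i > 1L && !is.na(ea@tgtStart) && ea@tgtStart > 2L)
                    ea@acceptor <- substr(tgt, ea@tgtStart - 2L,
                                          ea@tgtStart - 1L)
            } else ea <- NULL
        }
        if (is.null(ea))
            ea <- alignExon(refPiece, tgt, exonStart = es, exonEnd = ee,
                            exonIndex = i, isFirst = i == 1L,
                            isLast = i == n, mode = "fit")
        aligns[[i]] <- ea
        if (ea@found && !is.na(ea@tgtEnd)) {
            cursor <- ea@tgtEnd
            prevRefEnd <- tab$end[i]
        }
        if (ea@found) {
            if (i < n) donors[[as.character(i)]] <- ea@donor
            if (i > 1L) acceptors[[as.character(i)]] <- ea@acceptor
            fsEvents[[length(fsEvents) + 1L]] <-
                detectFrameshift(ea, species = species)
            if (!is.na(ea@tgtStart))
                exonStrings[[i]] <- substr(tgt, ea@tgtStart, ea@tgtEnd)
        }
    }
    found <- vapply(aligns, function(a) a@found, logical(1))
    if (!any(found))
        return(classifyStatus(.emptyEvents(), 0L, n, species = species,
                              sequenceFound = FALSE, absence = absence))
    ev <- rbind(do.call(rbind, c(list(.emptyEvents()), fsEvents)),
                detectSpliceMutations(donors, acceptors,
                                      species = species),
                .exonStopEvents(exonStrings, tab$phase,
                                species = species))
    ev <- ev[order(ev$exon, ev$category), , drop = FALSE]
    rownames(ev) <- NULL
    classifyStatus(ev, sum(found), n, species = species,
                   sequenceFound = TRUE, alignments = aligns)
}
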