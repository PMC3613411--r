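#' Read an ordered gene-neighborhood map
#'
#' A fragment map lists, for every assembly fragment of a species, the
#' genes detected on it with orientation and start coordinate.  The TSV
#' has columns `species`, `fragment`, `symbol`, `strand`, `start`
#' (comment lines starting with `#` are skipped).  Symbols are
#' uppercased and hits are sorted by start within fragments.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with the five columns above.
#' @export
readFragmentMap <- function(path) {
    m <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    need <- c("species", "fragment", "symbol", "strand", "start")
    if (!all(need %in% names(m)))
        stop("fragment map needs columns: ", paste(need, collapse = ", "))
    m$symbol <- toupper(m$symbol)
    m[order(m$species, m$fragment, m$start), need]
}

# neighbors of the target, split by side relative to the target's
# transcription direction; each side ordered nearest-first.  A target
# split over several fragments (partial assemblies) contributes the
# neighbors from every fragment it sits on.
.sidedNeighbors <- function(map, target) {
    hits <- map[map$symbol == target, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    five <- three <- map[0L, , drop = FALSE]
    for (h in seq_len(nrow(hits))) {
        hit <- hits[h, ]
        frag <- map[map$fragment == hit$fragment & map$symbol != target, ,
                    drop = FALSE]
        before <- frag[frag$start < hit$start, , drop = FALSE]
        after <- frag[frag$start > hit$start, , drop = FALSE]
        before <- before[order(-before$start), , drop = FALSE] # nearest 1st
        after <- after[order(after$start), , drop = FALSE]
        if (identical(hit$strand, "-")) {
            tmp <- before; before <- after; after <- tmp
        }
        five <- rbind(five, before)
        three <- rbind(three, after)
    }
    five <- five[!duplicated(five$symbol), , drop = FALSE]
    three <- three[!duplicated(three$symbol), , drop = FALSE]
    list(five = five, three = three, targetStrand = hits$strand[1L])
}

#' Find flanking genes conserved across reference species
#'
#' Identifies the nearest gene symbols 5' and 3' of the target that are
#' shared -- on the same side, with the same orientation relative to the
#' target -- by every reference species map.  These anchors let a
#' missing gene be searched for by synteny.
#'
#' @param maps `data.frame` in [readFragmentMap()] layout covering two or
#'   more reference species that carry the target.
#' @param target gene symbol of interest (uppercased).
#' @return list with elements `flank5` and `flank3` (either may be `NA`
#'   if no shared anchor exists on that side; both missing is an error).
#' @export
findConservedFlanks <- function(maps, target) {
    target <- toupper(target)
    sp <- unique(maps$species)
    sided <- lapply(sp, function(s)
        .sidedNeighbors(maps[maps$species == s, , drop = FALSE], target))
    names(sided) <- sp
    sided <- Filter(Negate(is.null), sided)
    if (length(sided) < 2L)
        stop("target must be present in at least two reference maps")

    pickShared <- function(side) {
        first <- sided[[1L]][[side]]
        for (k in seq_len(nrow(first))) {
            sym <- first$symbol[k]
            relOri <- first$strand[k] == sided[[1L]]$targetStrand
            ok <- vapply(sided[-1L], function(sd) {
                i <- match(sym, sd[[side]]$symbol)
                !is.na(i) &&
                    (sd[[side]]$strand[i] == sd$targetStrand) == relOri
            }, logical(1))
            if (all(ok)) return(sym)
        }
        NA_character_
    }
    flank5 <- pickShared("five")
    flank3 <- pickShared("three")
    if (is.na(flank5) && is.na(flank3))
        stop("no shared flanking gene found for ", target)
    list(flank5 = flank5, flank3 = flank3)
}

#' Call presence, deletion, or unresolved absence of a gene
#'
#' Applies conserved-flank logic to one species' fragment map:
#' `PRESENT` if the target is hit anywhere in the map; `DELETED` if both
#' flanking anchors sit on one fragment, in the expected relative
#' orientation to each other, with no target hit between them (an intact
#' neighborhood with the gene gone); `UNRESOLVED` otherwise, e.g. flanks
#' on different short fragments, where an assembly gap cannot be ruled
#' out.  Intervening unrelated genes between the flanks do not block a
#' `DELETED` call (gene neighborhoods tolerate insertions), but the
#' target must be absent from the whole map.
#'
#' @param speciesMap fragment map (one species) in [readFragmentMap()]
#'   layout.
#' @param target gene symbol of interest.
#' @param flank5,flank3 anchor symbols from [findConservedFlanks()].
#' @param sameOrientation expected relative orientation of the two
#'   flanks to each other (`TRUE` = same strand, as in the reference
#'   neighborhoods).
#' @return a one-row `data.frame` with columns `species`, `target`,
#'   `status`, `evidence`.
#' @export
callAbsence <- function(speciesMap, target, flank5, flank3,
                        sameOrientation = TRUE) {
    if (!nrow(speciesMap)) stop("empty fragment map")
    target <- toupper(target)
    species <- speciesMap$species[1L]
    mk <- function(status, evidence)
        data.frame(species = species, target = target, status = status,
                   evidence = evidence, stringsAsFactors = FALSE)

    tgtHits <- speciesMap[speciesMap$symbol == target, , drop = FALSE]
    if (nrow(tgtHits))
        return(mk("PRESENT",
                  paste("target on fragment",
                        paste(unique(tgtHits$fragment), collapse = ","))))
    if (is.na(flank5) || is.na(flank3))
        return(mk("UNRESOLVED", "missing flank anchor"))
    frags <- unique(speciesMap$fragment)
    for (f in frags) {
        sub <- speciesMap[speciesMap$fragment == f, , drop = FALSE]
        i5 <- match(flank5, sub$symbol)
        i3 <- match(flank3, sub$symbol)
        if (is.na(i5) || is.na(i3)) next
        if ((sub$strand[i5] == sub$strand[i3]) != sameOrientation) next
        lo <- min(sub$start[i5], sub$start[i3])
        hi <- max(sub$start[i5], sub$start[i3])
        between <- sub$symbol[sub$start > lo & sub$start < hi]
        if (target %in% between) next  # unreachable given PRESENT check
        return(mk("DELETED",
                  sprintf("flanks %s and %s linked on fragment %s, no %s between",
                          flank5, flank3, f, target)))
    }
    mk("UNRESOLVED",
       "flanking anchors not linked on a single fragment")
}
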