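.extdata <- function(file) {
    p <- system.file("extdata", file, package = "GeneLossKit",
                     mustWork = TRUE)
    p
}

#' Bundled vertebrate GCKR census fixtures
#'
#' Machine-readable transcriptions of a published census of glucokinase
#' regulatory protein (GCKR) gene structures across vertebrate genomes:
#' genomic locus records, per-species lists of exons bearing inactivating
#' mutations, functional status categories, relative-rate substitution
#' counts, schematic gene neighborhoods around the locus, and the
#' consensus vertebrate species tree used for loss mapping.
#'
#' @return `locusCensus()`, `disruptionCensus()`, `statusCensus()`,
#'   `rateCountCensus()` and `neighborhoodMaps()` return `data.frame`s;
#'   `vertebratePhylogeny()` returns a rooted `phylo`.
#' @name census
#' @examples
#' head(locusCensus())
#' sum(!locusCensus()$found)  # species with no GCKR-like sequence
NULL

#' @rdname census
#' @export
locusCensus <- function() {
    x <- utils::read.delim(.extdata("locus_census.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
    x$found <- as.logical(x$found)
    x
}

#' @rdname census
#' @export
disruptionCensus <- function() {
    utils::read.delim(.extdata("disruption_census.tsv"),
                      comment.char = "#", stringsAsFactors = FALSE,
                      na.strings = NULL)
}

#' @rdname census
#' @export
statusCensus <- function() {
    utils::read.delim(.extdata("status_census.tsv"),
                      comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname census
#' @export
rateCountCensus <- function() {
    utils::read.delim(.extdata("rate_counts.tsv"),
                      comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname census
#' @export
neighborhoodMaps <- function() {
    readFragmentMap(.extdata("neighborhoods.tsv"))
}

#' @rdname census
#' @export
vertebratePhylogeny <- function() {
    readSpeciesTree(.extdata("vertebrate_tree.nwk"))
}

# split a comma-separated exon list into integers
.exonList <- function(x) {
    if (is.na(x) || !nzchar(x)) return(integer(0))
    as.integer(strsplit(x, ",")[[1]])
}

#' Replay the disruption census as event records
#'
#' Converts the per-species exon lists of [disruptionCensus()] into the
#' package's event `data.frame` layout (one `FRAMESHIFT` event per
#' frameshift-column exon, one `SPLICE_DONOR` event per splice-column
#' exon), suitable for [classifyStatus()] and [tabulateDisruptions()].
#'
#' @return event `data.frame` with columns `species`, `exon`,
#'   `category`, `detail`.
#' @export
censusEvents <- function() {
    dc <- disruptionCensus()
    rows <- lapply(seq_len(nrow(dc)), function(i) {
        fs <- .exonList(dc$frameshift_exons[i])
        sp <- .exonList(dc$splice_exons[i])
        rbind(if (length(fs)) .eventRow(dc$species[i], fs, "FRAMESHIFT",
                                        "census frameshift column"),
              if (length(sp)) .eventRow(dc$species[i], sp, "SPLICE_DONOR",
                                        "census splice column"))
    })
    ev <- do.call(rbind, c(list(.emptyEvents()), rows))
    rownames(ev) <- NULL
    ev
}

#' Tip states for loss mapping derived from the census
#'
#' Builds the per-species character used by [dolloMinEvents()] on the
#' bundled phylogeny.  With `mode = "dual-mutation"` (the conservative
#' default), only species whose gene carries both a frameshift and a
#' splice-junction mutation are scored `NONFUNCTIONAL`; intact and
#' potentially intact genes are `FUNCTIONAL`; everything else --
#' species with no sequence (possibly an assembly gap) and
#' single-class mutants -- is `MISSING`, constraining nothing.  With
#' `mode = "census"`, all `INACTIVATED` species are `NONFUNCTIONAL`.
#'
#' @param mode `"dual-mutation"` or `"census"`.
#' @return named character vector over the census species.
#' @export
censusTipStates <- function(mode = c("dual-mutation", "census")) {
    mode <- match.arg(mode)
    st <- statusCensus()
    out <- stats::setNames(rep("MISSING", nrow(st)), st$species)
    out[st$status %in% c("INTACT", "POTENTIALLY_INTACT")] <- "FUNCTIONAL"
    if (mode == "census") {
        out[st$status == "INACTIVATED"] <- "NONFUNCTIONAL"
    } else {
        dc <- disruptionCensus()
        dual <- dc$species[nzchar(dc$frameshift_exons) &
                           nzchar(dc$splice_exons)]
        out[names(out) %in% dual] <- "NONFUNCTIONAL"
    }
    out
}
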