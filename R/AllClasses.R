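#' @import methods
#' @importFrom S4Vectors metadata
#' @useDynLib GeneLossKit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

VALID_STATUS <- c("INTACT", "POTENTIALLY_INTACT", "INACTIVATED",
                  "DELETED", "UNRESOLVED")
VALID_CATEGORY <- c("FRAMESHIFT", "PREMATURE_STOP", "SPLICE_DONOR",
                    "SPLICE_ACCEPTOR")
VALID_ABSENCE <- c("PRESENT", "DELETED", "UNRESOLVED")

#' Multi-exon gene model
#'
#' Ordered coding exons of a gene on a genomic sequence.  Coordinates are
#' 1-based inclusive, stored on the plus strand; for minus-strand genes
#' exon indices still count in transcription order (exon 1 has the
#' largest start coordinate) and sequence extraction reverse-complements.
#' The `phase` of an exon is the number of coding bases carried over from
#' the previous exons (cumulative exon length so far, modulo 3).
#'
#' @slot geneId gene identifier.
#' @slot species species label.
#' @slot seqId identifier of the genomic sequence the model lives on.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon coordinates in transcription
#'   order, with a `phase` metadata column.
#' @slot reference logical; reference models additionally assert a coding
#'   length divisible by three ending in a stop codon (checked at
#'   extraction time, when the sequence is available).
#' @exportClass GeneModel
setClass("GeneModel",
    representation(geneId = "character", species = "character",
                   seqId = "character", strand = "character",
                   exons = "IRanges", reference = "logical"))

setValidity("GeneModel", function(object) {
    msg <- character(0)
    if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) == 0L)
        msg <- c(msg, "a gene model needs at least one exon")
    if (length(ex) > 1L) {
        st <- IRanges::start(ex)
        ordered <- if (identical(object@strand, "-")) all(diff(st) < 0)
                   else all(diff(st) > 0)
        if (!ordered)
            msg <- c(msg, "exons must be in transcription order")
        ov <- IRanges::findOverlaps(ex, ex)
        if (length(ov) > length(ex))
            msg <- c(msg, "exons of one gene must not overlap")
    }
    ph <- S4Vectors::mcols(ex)$phase
    if (is.null(ph) || any(is.na(ph)) || !all(ph %in% 0:2))
        msg <- c(msg, "every exon needs a phase in {0,1,2}")
    if (length(msg)) msg else TRUE
})

#' Per-species gene status report
#'
#' The aggregated functional verdict for one species' copy of the gene:
#' the detected coding-disrupting events, how many reference exons were
#' recovered, and the resulting status category.  Two or more disrupting
#' events mark a gene `INACTIVATED`; exactly one leaves it
#' `POTENTIALLY_INTACT` (a single change could be a sequencing error or a
#' rare allele); a gene whose sequence is absent is `DELETED` when
#' synteny supports deletion and `UNRESOLVED` otherwise.
#'
#' @slot species species label.
#' @slot status one of `INTACT`, `POTENTIALLY_INTACT`, `INACTIVATED`,
#'   `DELETED`, `UNRESOLVED`.
#' @slot nDisruptions number of disrupting events.
#' @slot exonsFound,exonsTotal exon recovery counts.
#' @slot events `data.frame` with columns `species`, `exon`, `category`,
#'   `detail` (one row per event).
#' @slot alignments list of per-exon [ExonAlignment] objects (may be
#'   empty for reports built from tabulated data).
#' @exportClass GeneStatusReport
setClass("GeneStatusReport",
    representation(species = "character", status = "character",
                   nDisruptions = "integer", exonsFound = "integer",
                   exonsTotal = "integer", events = "data.frame",
                   alignments = "list"))

setValidity("GeneStatusReport", function(object) {
    msg <- character(0)
    if (!object@status %in% VALID_STATUS)
        msg <- c(msg, "unknown status")
    if (object@exonsFound > object@exonsTotal)
        msg <- c(msg, "exonsFound may not exceed exonsTotal")
    if (object@nDisruptions != nrow(object@events))
        msg <- c(msg, "nDisruptions must equal the number of event rows")
    if (object@status == "INACTIVATED" && object@nDisruptions < 2L)
        msg <- c(msg, "INACTIVATED requires at least two disruptions")
    if (object@status == "INTACT" &&
        (object@nDisruptions != 0L ||
         object@exonsFound != object@exonsTotal))
        msg <- c(msg, "INTACT requires zero disruptions and full exon recovery")
    if (nrow(object@events) &&
        !all(object@events$category %in% VALID_CATEGORY))
        msg <- c(msg, "unknown event category")
    if (length(msg)) msg else TRUE
})

#' One exon aligned against a candidate locus
#'
#' Result of the affine-gap alignment of a flanked reference exon against
#' a target genomic window: the gapped strings, identity and coverage
#' over the exon-proper columns, the net insertion/deletion length inside
#' the exon, and the splice dinucleotides read off the target next to the
#' aligned exon boundaries.
#'
#' @slot exonIndex ordinal of the exon in the reference model.
#' @slot refAligned,tgtAligned gapped alignment strings (equal length).
#' @slot identity fraction of aligned exon columns that match (columns
#'   with `N` in either row are excluded).
#' @slot coverage fraction of the exon length recovered as aligned
#'   (base-to-base) columns.
#' @slot found `TRUE` when identity >= 0.5 over >= 50 percent of the
#'   exon length.
#' @slot donor,acceptor the intron-terminal dinucleotides adjacent to the
#'   exon in the target (`NA` where not applicable or not recoverable).
#' @slot netIndel signed base count (target minus reference) over the
#'   exon-proper columns.
#' @slot score alignment score.
#' @slot tgtStart,tgtEnd 1-based positions of the exon-proper region in
#'   the target window.
#' @exportClass ExonAlignment
setClass("ExonAlignment",
    representation(exonIndex = "integer", refAligned = "character",
                   tgtAligned = "character", identity = "numeric",
                   coverage = "numeric", found = "logical",
                   donor = "character", acceptor = "character",
                   netIndel = "integer", score = "numeric",
                   tgtStart = "integer", tgtEnd = "integer"))

setValidity("ExonAlignment", function(object) {
    msg <- character(0)
    if (nchar(object@refAligned) != nchar(object@tgtAligned))
        msg <- c(msg, "aligned strings must have equal length")
    if (!is.na(object@identity) &&
        (object@identity < 0 || object@identity > 1))
        msg <- c(msg, "identity must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Placement of irreversible loss events on a species tree
#'
#' A minimum-cardinality set of branches such that every nonfunctional
#' tip descends from exactly one loss branch and no functional tip
#' descends from any (Dollo parsimony).  Branches are edge indices into
#' `tree$edge`; a loss on the root itself (all tips coverable) is
#' recorded with `rootEvent = TRUE`.
#'
#' @slot tree the rooted `phylo` tree the placement refers to.
#' @slot edges integer indices of loss edges in `tree$edge`.
#' @slot rootEvent logical; `TRUE` when the single event sits at the root.
#' @slot nEvents number of events.
#' @exportClass LossPlacement
setClass("LossPlacement",
    representation(tree = "ANY", edges = "integer", rootEvent = "logical",
                   nEvents = "integer"))

setValidity("LossPlacement", function(object) {
    msg <- character(0)
    if (object@nEvents != length(object@edges) + as.integer(object@rootEvent))
        msg <- c(msg, "nEvents must equal the number of loss edges")
    if (object@rootEvent && length(object@edges))
        msg <- c(msg, "a root event excludes any other loss edge")
    if (length(msg)) msg else TRUE
})
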