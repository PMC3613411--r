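#' Align a flanked reference exon against a target window
#'
#' Global (or fit) affine-gap alignment of a reference exon, carried with
#' short intronic flanks for splice-site inspection, against a candidate
#' genomic window.  Scoring is match +1, mismatch -1, gap open -4, gap
#' extend -1 per base; the traceback is deterministic (match/mismatch
#' preferred over a gap in the target over a gap in the reference at
#' equal score).  An exon is `found` when identity >= 0.5 over at least
#' 50 percent of the exon length.  `netIndel` is the signed base count
#' (target minus reference) over the exon-proper columns.  The splice
#' dinucleotides are read from the target immediately outside the aligned
#' exon boundaries: the donor follows the exon (absent for the last
#' exon), the acceptor precedes it (absent for the first).
#'
#' @param refSeq character or `DNAString`: the reference exon plus
#'   flanks.
#' @param targetSeq character or `DNAString`: the target window.
#' @param exonStart,exonEnd 1-based range of the exon proper within
#'   `refSeq` (defaults to the whole of `refSeq`, i.e. no flanks).
#' @param exonIndex ordinal of the exon in its model.
#' @param isFirst,isLast flags controlling which splice dinucleotides
#'   are reported.
#' @param mode `"global"` aligns end to end; `"fit"` leaves leading and
#'   trailing target bases unaligned, for placing an exon inside a
#'   larger locus.
#' @return an [ExonAlignment].
#' @export
#' @examples
#' ea <- alignExon("AAATGCATGCA", "AAATGCATGCA")
#' ea@identity
alignExon <- function(refSeq, targetSeq, exonStart = 1L,
                      exonEnd = nchar(as.character(refSeq)),
                      exonIndex = 1L, isFirst = TRUE, isLast = TRUE,
                      mode = c("global", "fit")) {
    mode <- match.arg(mode)
    ref <- toupper(as.character(refSeq))
    tgt <- toupper(as.character(targetSeq))
    if (!nzchar(ref) || !nzchar(tgt))
        stop("empty input sequence")
    stopifnot(exonStart >= 1L, exonEnd <= nchar(ref), exonStart <= exonEnd)
    res <- .gotoh_align(ref, tgt, if (mode == "fit") 1L else 0L)

    ra <- strsplit(res$ref_aln, "")[[1]]
    ta <- strsplit(res$tgt_aln, "")[[1]]
    refPos <- cumsum(ra != "-")          # 0 before first ref base
    tgtPos <- cumsum(ta != "-") + res$tgt_start - 1L

    # exon-proper columns: those holding a reference base of the exon,
    # plus insertion columns strictly inside the exon
    inExon <- refPos >= exonStart & refPos <= exonEnd &
        !(ra == "-" & refPos == exonEnd)
    # insertion columns before the exon's first base belong to the flank
    inExon[ra == "-" & refPos == (exonStart - 1L)] <- FALSE

    exCols <- which(inExon)
    alnCols <- exCols[ra[exCols] != "-" & ta[exCols] != "-"]
    idCols <- alnCols[ra[alnCols] != "N" & ta[alnCols] != "N"]
    exonLen <- exonEnd - exonStart + 1L
    identity <- if (length(idCols))
        mean(ra[idCols] == ta[idCols]) else 0
    coverage <- length(alnCols) / exonLen
    found <- identity >= 0.5 && coverage >= 0.5
    netIndel <- as.integer(sum(ta[exCols] != "-") - sum(ra[exCols] != "-"))

    # target coordinates of the exon-proper region
    exTgt <- exCols[ta[exCols] != "-"]
    tStart <- if (length(exTgt)) as.integer(min(tgtPos[exTgt])) else NA_integer_
    tEnd <- if (length(exTgt)) as.integer(max(tgtPos[exTgt])) else NA_integer_

    donor <- acceptor <- NA_character_
    if (!isLast && !is.na(tEnd) && tEnd + 2L <= nchar(tgt))
        donor <- substr(tgt, tEnd + 1L, tEnd + 2L)
    if (!isFirst && !is.na(tStart) && tStart - 2L >= 1L)
        acceptor <- substr(tgt, tStart - 2L, tStart - 1L)

    new("ExonAlignment", exonIndex = as.integer(exonIndex),
        refAligned = res$ref_aln, tgtAligned = res$tgt_aln,
        identity = identity, coverage = coverage, found = found,
        donor = donor, acceptor = acceptor, netIndel = netIndel,
        score = res$score, tgtStart = tStart, tgtEnd = tEnd)
}

# Project the aligned target bases of one exon onto reference exon
# coordinates: deleted reference positions become "N", inserted target
# bases are dropped.  Restores the reference reading frame for the
# premature-stop scan.  Returns a character vector of length exonLen.
.projectExon <- function(ea, exonStart, exonEnd) {
    out <- rep("N", exonEnd - exonStart + 1L)
    ra <- strsplit(ea@refAligned, "")[[1]]
    ta <- strsplit(ea@tgtAligned, "")[[1]]
    refPos <- cumsum(ra != "-")
    keep <- which(ra != "-" & ta != "-" &
                  refPos >= exonStart & refPos <= exonEnd)
    out[refPos[keep] - exonStart + 1L] <- ta[keep]
    out
}
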