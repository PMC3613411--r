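#' Construct a gene model
#'
#' Builds a [GeneModel] from plus-strand exon coordinates.  Exons are
#' sorted into transcription order (ascending start on `+`, descending on
#' `-`) and phases are computed as the cumulative coding length carried
#' over from the previous exons, modulo 3.
#'
#' @param geneId,species,seqId,strand model identity fields.
#' @param start,end integer vectors of 1-based inclusive exon
#'   coordinates on the plus strand.
#' @param reference logical flag marking a trusted reference model.
#' @return a [GeneModel].
#' @export
#' @examples
#' GeneModel("GCKR", "Human", "chr2", "+",
#'           start = c(1, 101, 201), end = c(60, 160, 260))
GeneModel <- function(geneId, species, seqId, strand = "+",
                      start, end, reference = FALSE) {
    stopifnot(length(start) == length(end), length(start) >= 1L)
    if (any(end < start))
        stop("exon end before start")
    o <- order(start, decreasing = identical(strand, "-"))
    start <- as.integer(start[o]); end <- as.integer(end[o])
    widths <- end - start + 1L
    phase <- as.integer(c(0L, cumsum(widths)[-length(widths)] %% 3L))
    ex <- IRanges::IRanges(start = start, end = end)
    S4Vectors::mcols(ex)$phase <- phase
    new("GeneModel", geneId = as.character(geneId),
        species = as.character(species), seqId = as.character(seqId),
        strand = strand, exons = ex, reference = isTRUE(reference))
}

.firstToken <- function(x) sub("\\s.*$", "", x)

#' Read and write FASTA sequences
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and friends that
#' enforce the package's contracts: record ids are the first whitespace
#' token of the header, residues are uppercased, duplicate ids and
#' residues outside the allowed alphabet (`A`,`C`,`G`,`T`,`N` for DNA;
#' the 20 amino acids plus `*`, `X`, `-` for protein) are errors, and an
#' empty file is an error.  `writeFasta()` wraps at 60 columns.
#'
#' @param path path to a FASTA file (CRLF line endings tolerated).
#' @param x an `XStringSet` to write.
#' @return `readDnaFasta()` a [Biostrings::DNAStringSet];
#'   `readProteinFasta()` a [Biostrings::AAStringSet]; `writeFasta()` the
#'   path, invisibly.
#' @export
readDnaFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0L) stop("empty FASTA file: ", path)
    # read without alphabet coercion first, so illegal residues are
    # caught instead of silently dropped
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop("no records in FASTA file: ", path)
    names(x) <- .firstToken(names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate record ids in ", path, ": ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    chars <- toupper(as.character(x))
    bad <- grepl("[^ACGTN]", chars)
    if (any(bad))
        stop("illegal DNA characters in record(s): ",
             paste(names(x)[bad], collapse = ", "))
    Biostrings::DNAStringSet(stats::setNames(chars, names(x)))
}

#' @rdname readDnaFasta
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0L) stop("empty FASTA file: ", path)
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop("no records in FASTA file: ", path)
    names(x) <- .firstToken(names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate record ids in ", path)
    chars <- toupper(as.character(x))
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY*X-]", chars)
    if (any(bad))
        stop("illegal protein characters in record(s): ",
             paste(names(x)[bad], collapse = ", "))
    if (any(!nzchar(chars))) stop("empty protein record")
    Biostrings::AAStringSet(stats::setNames(chars, names(x)))
}

#' @rdname readDnaFasta
#' @export
writeFasta <- function(x, path) {
    Biostrings::writeXStringSet(x, filepath = path, width = 60L)
    invisible(path)
}

#' Read a gene model from a GFF3-subset file
#'
#' Expects `gene` and `CDS` features with `ID`/`Parent` attributes and
#' 1-based inclusive coordinates.  CDS lines are grouped by parent gene,
#' sorted into transcription order, and phases are (re)computed from the
#' cumulative coding length; mixed strands or overlapping CDS within one
#' gene are errors.
#'
#' @param path path to the GFF3 file.
#' @param geneId optional gene to extract when the file holds several.
#' @param species,reference passed through to the model.
#' @return a [GeneModel].
#' @export
readGeneModel <- function(path, geneId = NULL, species = NA_character_,
                          reference = FALSE) {
    gr <- rtracklayer::import(path, format = "gff3")
    cds <- gr[tolower(as.character(gr$type)) == "cds"]
    if (length(cds) == 0L) stop("no CDS features in ", path)
    parent <- vapply(as.list(cds$Parent), function(p)
        if (length(p)) p[[1]] else NA_character_, character(1))
    if (anyNA(parent)) {
        if (!is.null(cds$ID)) parent[is.na(parent)] <- cds$ID[is.na(parent)]
        if (anyNA(parent)) stop("CDS feature without Parent/ID in ", path)
    }
    if (is.null(geneId)) {
        geneId <- unique(parent)
        if (length(geneId) > 1L)
            stop("several genes in ", path,
                 "; pick one with the geneId argument")
    }
    sel <- parent == geneId
    if (!any(sel)) stop("gene ", geneId, " not found in ", path)
    cds <- cds[sel]
    strands <- unique(as.character(GenomicRanges::strand(cds)))
    if (length(strands) != 1L || !strands %in% c("+", "-"))
        stop("mixed or missing strands within gene ", geneId)
    if (!GenomicRanges::isDisjoint(cds))
        stop("overlapping CDS within gene ", geneId)
    GeneModel(geneId = geneId, species = species,
              seqId = as.character(GenomicRanges::seqnames(cds))[1],
              strand = strands,
              start = GenomicRanges::start(cds),
              end = GenomicRanges::end(cds),
              reference = reference)
}

#' Write a gene model as GFF3
#'
#' Emits one `gene` line spanning the model plus one `CDS` line per exon,
#' with `ID`/`Parent` attributes, via [rtracklayer::export()].
#'
#' @param model a [GeneModel].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneModel <- function(model, path) {
    tab <- exonTable(model)
    gr <- GenomicRanges::GRanges(
        seqnames = model@seqId,
        ranges = IRanges::IRanges(
            start = c(min(tab$start), sort(tab$start)),
            end = c(max(tab$end), sort(tab$end))),
        strand = model@strand)
    gr$type <- c("gene", rep("CDS", nrow(tab)))
    gr$ID <- c(geneId(model), paste0(geneId(model), ".cds",
                                     seq_len(nrow(tab))))
    gr$Parent <- c(NA_character_, rep(geneId(model), nrow(tab)))
    suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
    invisible(path)
}

#' Extract and translate a coding sequence
#'
#' `extractCds()` concatenates the exon substrings of a genomic sequence
#' in transcription order, reverse-complementing minus-strand models.
#' `translateCds()` translates with the standard genetic code; stop
#' codons become `*`, any codon containing `N` becomes `X`, and 1-2
#' trailing bases are dropped with a warning.
#'
#' @param genome a [Biostrings::DNAString] (or single-sequence set).
#' @param model a [GeneModel] whose coordinates lie within `genome`.
#' @param cds a DNA string (character or `DNAString`) of length >= 3.
#' @return `extractCds()` a [Biostrings::DNAString]; `translateCds()` a
#'   [Biostrings::AAString].
#' @export
#' @examples
#' gm <- GeneModel("g", "sp", "s", "+", start = 1, end = 6)
#' extractCds(Biostrings::DNAString("ATGAAA"), gm)
extractCds <- function(genome, model) {
    if (is(genome, "DNAStringSet")) {
        stopifnot(length(genome) == 1L)
        genome <- genome[[1]]
    }
    tab <- exonTable(model)
    if (any(tab$start < 1L) || any(tab$end > length(genome)))
        stop("exon coordinates outside the genomic sequence")
    pieces <- lapply(seq_len(nrow(tab)), function(i)
        Biostrings::subseq(genome, tab$start[i], tab$end[i]))
    cds <- do.call(Biostrings::xscat, pieces)
    if (identical(model@strand, "-"))
        cds <- Biostrings::reverseComplement(cds)
    if (isTRUE(model@reference)) {
        if (length(cds) %% 3L != 0L)
            stop("reference model coding length not divisible by 3")
        last <- as.character(Biostrings::subseq(cds, length(cds) - 2L))
        if (!last %in% c("TAA", "TAG", "TGA"))
            stop("reference model does not end in a stop codon")
    }
    cds
}

#' @rdname extractCds
#' @export
translateCds <- function(cds) {
    if (is.character(cds)) cds <- Biostrings::DNAString(cds)
    if (length(cds) == 0L) stop("empty coding sequence")
    if (length(cds) < 3L) stop("coding sequence shorter than one codon")
    extra <- length(cds) %% 3L
    if (extra > 0L) {
        warning(extra, " trailing base(s) ignored in translation")
        cds <- Biostrings::subseq(cds, 1L, length(cds) - extra)
    }
    suppressWarnings(
        Biostrings::translate(cds, if.fuzzy.codon = "X",
                              no.init.codon = TRUE))
}

#' Span of a genomic locus
#'
#' Length in bases of a 1-based inclusive interval, `end - start + 1`.
#'
#' @param start,end integer coordinate vectors (recycled).
#' @return integer vector of spans.
#' @export
#' @examples
#' locusSpan(27719709, 27746554)  # the human GCKR locus, 26846 bp
locusSpan <- function(start, end) {
    if (any(end < start)) stop("end before start")
    as.integer(end - start + 1L)
}

#' Read and write Newick trees
#'
#' Wrappers around [ape::read.tree()] / [ape::write.tree()] that preserve
#' labels, branch lengths, and polytomies on round trip.
#'
#' @param path Newick file to read, or output path for writing (`NULL`
#'   returns the Newick text).
#' @param tree a `phylo` object.
#' @return `readSpeciesTree()` a `phylo`; `writeSpeciesTree()` the Newick
#'   string, invisibly when written to file.
#' @export
readSpeciesTree <- function(path) {
    tr <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ",
                                            path, ": ", conditionMessage(e)))
    if (is.null(tr)) stop("Newick parse error in ", path)
    tr
}

#' @rdname readSpeciesTree
#' @export
writeSpeciesTree <- function(tree, path = NULL) {
    txt <- ape::write.tree(tree)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}
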