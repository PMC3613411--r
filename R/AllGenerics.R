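#' Accessors for GeneLossKit classes
#'
#' Small accessor generics: `geneId()`, `geneSpecies()`, `exonTable()`,
#' `nExons()`, `modelStrand()` for [GeneModel]; `statusOf()`, `events()`,
#' `nDisruptions()` for [GeneStatusReport]; `lossEdges()`, `nEvents()`
#' for [LossPlacement].
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value; `exonTable()` returns a
#'   `data.frame` with columns `index`, `start`, `end`, `phase` in
#'   transcription order.
#' @name accessors
#' @examples
#' gm <- GeneModel("g", "sp", "chr", "+", start = c(1, 11), end = c(6, 16))
#' nExons(gm)
#' exonTable(gm)
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("geneSpecies", function(x) standardGeneric("geneSpecies"))
#' @rdname accessors
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))
#' @rdname accessors
#' @export
setGeneric("nExons", function(x) standardGeneric("nExons"))
#' @rdname accessors
#' @export
setGeneric("modelStrand", function(x) standardGeneric("modelStrand"))
#' @rdname accessors
#' @export
setGeneric("statusOf", function(x) standardGeneric("statusOf"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("nDisruptions", function(x) standardGeneric("nDisruptions"))
#' @rdname accessors
#' @export
setGeneric("lossEdges", function(x) standardGeneric("lossEdges"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)
#' @rdname accessors
setMethod("geneSpecies", "GeneModel", function(x) x@species)
#' @rdname accessors
setMethod("geneSpecies", "GeneStatusReport", function(x) x@species)
#' @rdname accessors
setMethod("exonTable", "GeneModel", function(x) {
    data.frame(index = seq_along(x@exons),
               start = IRanges::start(x@exons),
               end = IRanges::end(x@exons),
               phase = S4Vectors::mcols(x@exons)$phase)
})
#' @rdname accessors
setMethod("nExons", "GeneModel", function(x) length(x@exons))
#' @rdname accessors
setMethod("modelStrand", "GeneModel", function(x) x@strand)
#' @rdname accessors
setMethod("statusOf", "GeneStatusReport", function(x) x@status)
#' @rdname accessors
setMethod("events", "GeneStatusReport", function(x) x@events)
#' @rdname accessors
setMethod("nDisruptions", "GeneStatusReport", function(x) x@nDisruptions)
#' @rdname accessors
setMethod("lossEdges", "LossPlacement", function(x) x@edges)
#' @rdname accessors
setMethod("nEvents", "LossPlacement", function(x) x@nEvents)

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel", object@geneId, "(", object@species, ")\n")
    cat("  ", length(object@exons), "exons on", object@seqId,
        "strand", object@strand, "\n")
    cat("  coding span:", min(IRanges::start(object@exons)), "-",
        max(IRanges::end(object@exons)), "\n")
    invisible(NULL)
})

setMethod("show", "GeneStatusReport", function(object) {
    cat("GeneStatusReport for", object@species, "\n")
    cat("  status:", object@status, "|", object@nDisruptions,
        "disruption(s) |", object@exonsFound, "/", object@exonsTotal,
        "exons found\n")
    if (nrow(object@events)) {
        tab <- table(object@events$category)
        cat("  events:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    invisible(NULL)
})

setMethod("show", "ExonAlignment", function(object) {
    cat(sprintf(
        "ExonAlignment exon %d: identity %.3f, coverage %.3f, net indel %+d%s\n",
        object@exonIndex, object@identity, object@coverage,
        object@netIndel, if (object@found) "" else " (not found)"))
    invisible(NULL)
})

setMethod("show", "LossPlacement", function(object) {
    cat("LossPlacement:", object@nEvents, "loss event(s)\n")
    if (object@rootEvent) cat("  single event at the root\n")
    invisible(NULL)
})
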