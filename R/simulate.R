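BASES <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
SENSE_CODONS <- {
    all3 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
    setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Simulation settings for a multi-exon gene family
#'
#' Defaults emulate a 19-exon liver-expressed regulatory gene evolving
#' along a species tree: functional branches conserve the open reading
#' frame and the GT-AG splice dinucleotides, while designated loss
#' branches (and everything below them) evolve free of those constraints
#' at an elevated rate, accumulating frameshifting indels, premature
#' stops, and splice-site mutations.
#'
#' @param nExons number of coding exons (>= 2).
#' @param exonLengthRange,intronLengthRange integer length ranges
#'   (bases) sampled uniformly.
#' @param flankLength untranscribed flanking sequence added on each side
#'   of the gene (bases).
#' @param substitutionRate expected substitutions per site per unit
#'   branch length.
#' @param indelRate expected indel events per site per unit branch
#'   length.
#' @param indelGeomProb geometric length parameter for indels; lengths
#'   are `3 * (rgeom + 1)` inside exons on functional branches (frame
#'   preserved) and `rgeom + 1` otherwise, capped at half the segment.
#' @param lossBranches where function is lost: a character vector of tip
#'   or node labels, or a list of tip-label vectors, each naming the
#'   branch above the most recent common ancestor of those tips.
#' @param postLossRateMultiplier rate multiplier (>= 1) on and below
#'   loss branches.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(nExons = 19L,
                             exonLengthRange = c(48L, 120L),
                             intronLengthRange = c(60L, 160L),
                             flankLength = 120L,
                             substitutionRate = 0.02,
                             indelRate = 0.0015,
                             indelGeomProb = 0.5,
                             lossBranches = list(),
                             postLossRateMultiplier = 2) {
    stopifnot(nExons >= 2L, length(exonLengthRange) == 2L,
              length(intronLengthRange) == 2L,
              exonLengthRange[1] >= 9L, intronLengthRange[1] >= 10L,
              substitutionRate >= 0, indelRate >= 0,
              indelGeomProb > 0, indelGeomProb < 1,
              postLossRateMultiplier >= 1)
    if (is.character(lossBranches)) lossBranches <- as.list(lossBranches)
    structure(list(nExons = as.integer(nExons),
                   exonLengthRange = as.integer(exonLengthRange),
                   intronLengthRange = as.integer(intronLengthRange),
                   flankLength = as.integer(flankLength),
                   substitutionRate = substitutionRate,
                   indelRate = indelRate,
                   indelGeomProb = indelGeomProb,
                   lossBranches = lossBranches,
                   postLossRateMultiplier = postLossRateMultiplier),
              class = "SimulationConfig")
}

#' Read a simulation config from a flat key-value file
#'
#' Lines of the form `key = value` (or `key value`); list-valued keys
#' use comma separation, `lossBranches` entries use `+` to join tip
#' labels into an MRCA branch spec.  Unknown keys are errors.
#'
#' @param path path to the config file.
#' @return a `SimulationConfig`.
#' @export
readSimulationConfig <- function(path) {
    ln <- trimws(readLines(path))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    kv <- strsplit(sub("\\s*=\\s*", " ", ln), "\\s+")
    keys <- vapply(kv, `[[`, "", 1L)
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = " "), "")
    args <- list()
    for (i in seq_along(keys)) {
        k <- keys[i]; v <- vals[i]
        args[[k]] <- switch(k,
            nExons = , flankLength = as.integer(v),
            exonLengthRange = , intronLengthRange =
                as.integer(strsplit(v, ",")[[1]]),
            substitutionRate = , indelRate = , indelGeomProb = ,
            postLossRateMultiplier = as.numeric(v),
            lossBranches = lapply(strsplit(v, ",")[[1]], function(b)
                strsplit(b, "\\+")[[1]]),
            stop("unknown config key: ", k))
    }
    do.call(simulationConfig, args)
}

# resolve loss branch specs to the set of nodes at or below them
.lossNodeSet <- function(tree, lossBranches) {
    if (!length(lossBranches)) return(integer(0))
    nt <- length(tree$tip.label)
    desc <- .descendantTips(tree)
    heads <- vapply(lossBranches, function(spec) {
        if (length(spec) == 1L) {
            i <- match(spec, tree$tip.label)
            if (!is.na(i)) return(i)
            j <- match(spec, tree$node.label)
            if (!is.na(j)) return(nt + j)
            stop("loss branch label not in tree: ", spec)
        }
        idx <- match(spec, tree$tip.label)
        if (anyNA(idx)) stop("loss branch tips not in tree: ",
                             paste(spec[is.na(idx)], collapse = ", "))
        ape::getMRCA(tree, spec)
    }, integer(1))
    below <- unlist(lapply(heads, function(h) {
        if (h <= nt) return(h)
        nodes <- h
        repeat {
            ch <- tree$edge[tree$edge[, 1L] %in% nodes, 2L]
            new <- setdiff(ch, nodes)
            if (!length(new)) break
            nodes <- c(nodes, new)
        }
        nodes
    }))
    unique(below)
}

# ---- internal piece machinery ------------------------------------------
# A gene is an ordered list of pieces (flank5, exon1, intron1, ...,
# exonN, flank3).  Each piece carries its bases and, per base, the
# column of the corresponding ROOT piece (0 for inserted bases), which
# makes frame-true projection onto the ancestor exact.

.rootGene <- function(cfg) {
    n <- cfg$nExons
    exLens <- sample(seq(cfg$exonLengthRange[1], cfg$exonLengthRange[2]),
                     n, replace = TRUE)
    pad <- (3L - sum(exLens) %% 3L) %% 3L
    exLens[n] <- exLens[n] + pad
    nCodons <- sum(exLens) %/% 3L
    cds <- c("ATG",
             sample(SENSE_CODONS, nCodons - 2L, replace = TRUE),
             sample(c("TAA", "TAG", "TGA"), 1L))
    cds <- strsplit(paste(cds, collapse = ""), "")[[1]]
    stopifnot(length(cds) == sum(exLens))
    ends <- cumsum(exLens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    piece <- function(b, type) list(type = type, bases = b,
                                    col = seq_along(b))
    pieces <- list(piece(sample(BASES, cfg$flankLength, TRUE), "flank"))
    for (i in seq_len(n)) {
        pieces <- c(pieces, list(piece(cds[starts[i]:ends[i]], "exon")))
        if (i < n) {
            il <- sample(seq(cfg$intronLengthRange[1],
                             cfg$intronLengthRange[2]), 1L)
            ib <- c("G", "T", sample(BASES, il - 4L, TRUE), "A", "G")
            pieces <- c(pieces, list(piece(ib, "intron")))
        }
    }
    pieces <- c(pieces, list(piece(sample(BASES, cfg$flankLength, TRUE),
                                   "flank")))
    pieces
}

.cdsOf <- function(gene) {
    unlist(lapply(gene, function(p) if (p$type == "exon") p$bases),
           use.names = FALSE)
}

.hasInternalStop <- function(cdsChars) {
    n <- length(cdsChars) %/% 3L
    if (n < 2L) return(FALSE)
    s <- paste(cdsChars, collapse = "")
    starts <- seq(1L, by = 3L, length.out = n - 1L)
    any(substring(s, starts, starts + 2L) %in% c("TAA", "TAG", "TGA"))
}

.evolveGene <- function(gene, t, isLoss, cfg) {
    mult <- if (isLoss) cfg$postLossRateMultiplier else 1
    pSub <- min(1, cfg$substitutionRate * t * mult)
    pInd <- min(1, cfg$indelRate * t * mult)
    exonIdx <- which(vapply(gene, function(p) p$type == "exon", logical(1)))
    exLens <- function() vapply(gene[exonIdx], function(p)
        length(p$bases), integer(1))

    # substitutions
    for (pi in seq_along(gene)) {
        p <- gene[[pi]]
        len <- length(p$bases)
        nMut <- stats::rbinom(1L, len, pSub)
        if (!nMut) next
        sites <- sample.int(len, nMut)
        for (s in sites) {
            cur <- p$bases[s]
            alts <- sample(setdiff(BASES, cur))
            if (isLoss || p$type == "flank") {
                p$bases[s] <- alts[1L]
                next
            }
            if (p$type == "intron") {
                if (s <= 2L || s > len - 2L) next  # splice dinucleotide
                p$bases[s] <- alts[1L]
                next
            }
            # functional exon: no premature stop, keep start + terminal stop
            off <- sum(exLens()[seq_len(match(pi, exonIdx) - 1L)])
            gp <- off + s
            tot <- sum(exLens())
            if (gp <= 3L || gp > tot - 3L) next
            codonIdx <- (gp - 1L) %/% 3L
            gene[[pi]] <- p  # keep the working copy current
            cds <- .cdsOf(gene)
            cstart <- codonIdx * 3L + 1L
            for (alt in alts) {
                cds[gp] <- alt
                codon <- paste(cds[cstart:(cstart + 2L)], collapse = "")
                if (!codon %in% c("TAA", "TAG", "TGA")) {
                    p$bases[s] <- alt
                    break
                }
            }
        }
        gene[[pi]] <- p
    }

    # indels
    for (pi in seq_along(gene)) {
        p <- gene[[pi]]
        len <- length(p$bases)
        nInd <- stats::rbinom(1L, len, pInd)
        if (!nInd) next
        for (dummy in seq_len(nInd)) {
            len <- length(p$bases)
            k <- stats::rgeom(1L, cfg$indelGeomProb) + 1L
            if (p$type == "exon" && !isLoss) k <- 3L * k
            k <- min(k, max(1L, len %/% 2L))
            if (p$type == "exon" && !isLoss && k %% 3L != 0L) next
            del <- stats::runif(1) < 0.5
            # indels stay clear of feature boundaries (8 bp margin) so
            # every injected event has an unambiguous exon/intron
            # attribution; splice disruption enters through
            # substitutions at the dinucleotides instead
            margin <- if (p$type == "flank") 0L else 8L
            lo <- margin + 1L
            hi <- (if (del) len - k + 1L else len) - margin
            if (hi < lo) next
            pos <- sample(seq(lo, hi), 1L)
            old <- p
            if (del) {
                drop <- pos:(pos + k - 1L)
                p$bases <- p$bases[-drop]
                p$col <- p$col[-drop]
            } else {
                ins <- sample(BASES, k, TRUE)
                p$bases <- append(p$bases, ins, after = pos)
                p$col <- append(p$col, rep(0L, k), after = pos)
            }
            if (p$type == "exon" && !isLoss) {
                gene[[pi]] <- p
                if (.hasInternalStop(.cdsOf(gene))) {
                    p <- old
                    gene[[pi]] <- old
                }
            }
        }
        gene[[pi]] <- p
    }
    gene
}

# ground-truth disruption events of a tip gene relative to the root
.truthEvents <- function(gene, rootGene, species) {
    exonIdx <- which(vapply(gene, function(p) p$type == "exon", logical(1)))
    intronIdx <- which(vapply(gene, function(p) p$type == "intron",
                              logical(1)))
    rootLens <- vapply(rootGene[exonIdx], function(p) length(p$bases),
                       integer(1))
    ev <- list()
    for (i in seq_along(exonIdx)) {
        net <- length(gene[[exonIdx[i]]]$bases) - rootLens[i]
        if (net %% 3L != 0L)
            ev[[length(ev) + 1L]] <-
                .eventRow(species, i, "FRAMESHIFT",
                          sprintf("net indel %+d", net))
    }
    for (j in seq_along(intronIdx)) {
        b <- gene[[intronIdx[j]]]$bases
        if (!identical(paste(b[1:2], collapse = ""), "GT"))
            ev[[length(ev) + 1L]] <-
                .eventRow(species, j, "SPLICE_DONOR",
                          paste("donor", paste(b[1:2], collapse = "")))
        la <- paste(b[c(length(b) - 1L, length(b))], collapse = "")
        if (!identical(la, "AG"))
            ev[[length(ev) + 1L]] <-
                .eventRow(species, j + 1L, "SPLICE_ACCEPTOR",
                          paste("acceptor", la))
    }
    phases <- as.integer(c(0L, cumsum(rootLens)[-length(rootLens)] %% 3L))
    exonStrings <- lapply(gene[exonIdx], function(p)
        paste(p$bases, collapse = ""))
    stops <- .exonStopEvents(exonStrings, phases, species = species)
    ev <- rbind(do.call(rbind, c(list(.emptyEvents()), ev)), stops)
    ev <- ev[order(ev$exon, ev$category), , drop = FALSE]
    rownames(ev) <- NULL
    ev
}

.geneToSeqModel <- function(gene, species, geneIdLabel) {
    lens <- vapply(gene, function(p) length(p$bases), integer(1))
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    exonIdx <- which(vapply(gene, function(p) p$type == "exon", logical(1)))
    seq <- paste(unlist(lapply(gene, `[[`, "bases"), use.names = FALSE),
                 collapse = "")
    model <- GeneModel(geneIdLabel, species, species, "+",
                       start = starts[exonIdx], end = ends[exonIdx])
    list(sequence = seq, model = model)
}

#' Simulate a multi-exon gene family along a species tree
#'
#' Starting from a random root gene with an intact open reading frame and
#' GT-AG introns, sequences evolve down the tree under the constraints
#' described in [simulationConfig()].  The result bundles per-tip genomic
#' sequences and gene models, the root reference, and a truth table of
#' every disruption (category and exon) present in each tip relative to
#' the root -- computed from the simulator's exact base-to-root-column
#' bookkeeping, not from the mutation history, so compensating or
#' overwritten mutations are already resolved.
#'
#' @param tree rooted `phylo`; missing edge lengths default to 1.
#' @param config a [simulationConfig()].
#' @param seed integer seed; the output is bit-reproducible given
#'   (tree, config, seed).
#' @return list with elements `sequences` (named [Biostrings::DNAStringSet]),
#'   `models` (named list of [GeneModel]), `refSequence`, `refModel`
#'   (the root gene), `truth` (event `data.frame`), and `lossTips`
#'   (character).
#' @export
simulateGeneFamily <- function(tree, config = simulationConfig(),
                               seed = 1L) {
    stopifnot(inherits(tree, "phylo"))
    set.seed(seed)
    nt <- length(tree$tip.label)
    lossNodes <- .lossNodeSet(tree, config$lossBranches)
    el <- tree$edge.length
    if (is.null(el)) el <- rep(1, nrow(tree$edge))
    genes <- vector("list", nt + tree$Nnode)
    root <- nt + 1L
    genes[[root]] <- .rootGene(config)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
        par <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
        t <- el[which(tree$edge[, 1L] == par & tree$edge[, 2L] == ch)]
        genes[[ch]] <- .evolveGene(genes[[par]], t,
                                   isLoss = ch %in% lossNodes, config)
    }
    ref <- .geneToSeqModel(genes[[root]], "root", "simgene")
    ref$model@reference <- TRUE
    seqs <- character(nt)
    models <- vector("list", nt)
    truth <- list()
    for (i in seq_len(nt)) {
        sm <- .geneToSeqModel(genes[[i]], tree$tip.label[i], "simgene")
        seqs[i] <- sm$sequence
        models[[i]] <- sm$model
        truth[[i]] <- .truthEvents(genes[[i]], genes[[root]],
                                   tree$tip.label[i])
    }
    names(models) <- tree$tip.label
    truth <- do.call(rbind, c(list(.emptyEvents()), truth))
    rownames(truth) <- NULL
    list(sequences = stats::setNames(
             Biostrings::DNAStringSet(seqs), tree$tip.label),
         models = models,
         refSequence = Biostrings::DNAString(ref$sequence),
         refModel = ref$model,
         truth = truth,
         lossTips = tree$tip.label[intersect(seq_len(nt), lossNodes)])
}

#' Simulate a three-taxon alignment with unequal lineage rates
#'
#' Draws an outgroup protein of `nSites` residues uniformly over the 20
#' amino acids; lineages `A` and `B` each mutate every site independently
#' with their own probability (to a uniformly chosen different residue).
#' The expected unique-substitution ratio approximates `rateA / rateB`.
#'
#' @param rateA,rateB per-site substitution probabilities in `[0, 1)`.
#' @param nSites alignment length (>= 1).
#' @param seed integer seed.
#' @return list with `alignment` (an [Biostrings::AAStringSet] with rows
#'   `A`, `B`, `O`) and `truth` (`nA`, `nB`: counts of sites mutated on
#'   exactly one lineage).
#' @export
makeRelativeRateCase <- function(rateA, rateB, nSites, seed = 1L) {
    if (rateA < 0 || rateA >= 1 || rateB < 0 || rateB >= 1)
        stop("rates must lie in [0, 1)")
    stopifnot(nSites >= 1L)
    set.seed(seed)
    o <- sample(AA20, nSites, replace = TRUE)
    mutate <- function(x, hit) {
        x[hit] <- vapply(x[hit], function(r)
            sample(setdiff(AA20, r), 1L), character(1))
        x
    }
    hitA <- stats::runif(nSites) < rateA
    hitB <- stats::runif(nSites) < rateB
    a <- mutate(o, hitA)
    b <- mutate(o, hitB)
    aln <- Biostrings::AAStringSet(c(
        A = paste(a, collapse = ""),
        B = paste(b, collapse = ""),
        O = paste(o, collapse = "")))
    list(alignment = aln,
         truth = list(nA = sum(hitA & !hitB), nB = sum(hitB & !hitA)))
}
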