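TIP_STATES <- c("FUNCTIONAL", "NONFUNCTIONAL", "MISSING")

# per-node indicators over a rooted phylo: does the subtree contain a
# FUNCTIONAL / NONFUNCTIONAL tip?  Returned as a list of two logical
# vectors indexed by node number (tips 1..n, internals n+1..).
.subtreeStates <- function(tree, states) {
    nt <- length(tree$tip.label)
    nn <- nt + tree$Nnode
    if (!all(tree$tip.label %in% names(states)))
        stop("every tip needs a state; missing: ",
             paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
    st <- states[tree$tip.label]
    if (!all(st %in% TIP_STATES))
        stop("tip states must be FUNCTIONAL, NONFUNCTIONAL or MISSING")
    hasF <- hasN <- logical(nn)
    hasF[seq_len(nt)] <- st == "FUNCTIONAL"
    hasN[seq_len(nt)] <- st == "NONFUNCTIONAL"
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in seq_len(nrow(po))) {
        p <- po[k, 1L]; ch <- po[k, 2L]
        hasF[p] <- hasF[p] || hasF[ch]
        hasN[p] <- hasN[p] || hasN[ch]
    }
    list(hasF = hasF, hasN = hasN)
}

#' Minimum irreversible loss events on a rooted tree (Dollo parsimony)
#'
#' The root is fixed functional and inactivation is irreversible, so the
#' optimal placement puts one event on the stem of every maximal clade
#' that contains at least one nonfunctional tip and no functional tip
#' (tips with `MISSING` state constrain nothing).  Computed by a
#' post-order sweep.
#'
#' @param tree rooted `phylo` (polytomies allowed; unique tip labels).
#' @param states named character vector mapping every tip label to
#'   `"FUNCTIONAL"`, `"NONFUNCTIONAL"` or `"MISSING"`.
#' @return a [LossPlacement].
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' st <- c(A = "NONFUNCTIONAL", B = "NONFUNCTIONAL", C = "FUNCTIONAL")
#' nEvents(dolloMinEvents(tr, st))  # one event on the (A,B) stem
dolloMinEvents <- function(tree, states) {
    if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
    if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
    ss <- .subtreeStates(tree, states)
    nt <- length(tree$tip.label)
    root <- nt + 1L
    coverable <- !ss$hasF
    if (coverable[root]) {
        n <- as.integer(ss$hasN[root])
        return(new("LossPlacement", tree = tree, edges = integer(0),
                   rootEvent = n == 1L, nEvents = n))
    }
    # child node is a loss node iff coverable & hasN & parent not coverable
    lossEdges <- which(coverable[tree$edge[, 2L]] &
                       ss$hasN[tree$edge[, 2L]] &
                       !coverable[tree$edge[, 1L]])
    new("LossPlacement", tree = tree, edges = as.integer(lossEdges),
        rootEvent = FALSE, nEvents = length(lossEdges))
}

#' Exhaustive-search oracle for the minimum loss count
#'
#' Independent check of [dolloMinEvents()]: enumerates subsets of
#' candidate edges (those whose subtree holds no functional tip and at
#' least one nonfunctional tip) in increasing cardinality until a subset
#' is found under which every nonfunctional tip descends from exactly
#' one chosen edge.  Intended for small trees; the enumeration is capped.
#'
#' @param tree rooted `phylo`.
#' @param states named tip-state vector, see [dolloMinEvents()].
#' @param maxSubsets cap on the number of subsets inspected per
#'   cardinality before giving up with a size error.
#' @return a [LossPlacement].
#' @export
bruteForceMinEvents <- function(tree, states, maxSubsets = 2e6) {
    ss <- .subtreeStates(tree, states)
    nt <- length(tree$tip.label)
    root <- nt + 1L
    st <- states[tree$tip.label]
    nfTips <- which(st == "NONFUNCTIONAL")
    if (!length(nfTips))
        return(new("LossPlacement", tree = tree, edges = integer(0),
                   rootEvent = FALSE, nEvents = 0L))
    if (!ss$hasF[root]) {
        # whole tree coverable: one event at the root
        return(new("LossPlacement", tree = tree, edges = integer(0),
                   rootEvent = TRUE, nEvents = 1L))
    }
    if (length(nfTips) > 30L)
        stop("tree too large for exhaustive search")
    cand <- which(!ss$hasF[tree$edge[, 2L]] & ss$hasN[tree$edge[, 2L]])
    if (!length(cand)) stop("no feasible placement exists")
    # bitmask of covered nonfunctional tips per candidate edge; a subset
    # is feasible iff the masks are disjoint and their union is complete
    # (sum == bitwise-or == full mask)
    desc <- .descendantTips(tree)
    masks <- vapply(cand, function(e)
        sum(2^(match(intersect(desc[[tree$edge[e, 2L]]], nfTips),
                     nfTips) - 1L)), numeric(1))
    full <- 2^length(nfTips) - 1
    for (k in seq_len(length(cand))) {
        if (choose(length(cand), k) > maxSubsets)
            stop("tree too large for exhaustive search")
        sets <- utils::combn(length(cand), k)
        sums <- colSums(matrix(masks[sets], nrow = k))
        for (j in which(sums == full)) {
            m <- masks[sets[, j]]
            if (Reduce(bitwOr, as.integer(m)) == full)
                return(new("LossPlacement", tree = tree,
                           edges = as.integer(cand[sets[, j]]),
                           rootEvent = FALSE, nEvents = k))
        }
    }
    stop("no feasible placement exists")
}

# list of descendant tip numbers per node
.descendantTips <- function(tree) {
    nt <- length(tree$tip.label)
    nn <- nt + tree$Nnode
    out <- vector("list", nn)
    for (i in seq_len(nt)) out[[i]] <- i
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in seq_len(nrow(po)))
        out[[po[k, 1L]]] <- c(out[[po[k, 1L]]], out[[po[k, 2L]]])
    out
}

#' Annotate loss branches on the Newick output
#'
#' Marks the child node of every loss branch with a `_PSI` label suffix
#' (the pseudogenization symbol), so the number of marks in the emitted
#' Newick equals the event count and survives a read/write round trip.
#'
#' @param placement a [LossPlacement].
#' @return Newick text of the decorated tree.
#' @export
annotateLossTree <- function(placement) {
    stopifnot(is(placement, "LossPlacement"))
    tree <- placement@tree
    nt <- length(tree$tip.label)
    if (is.null(tree$node.label))
        tree$node.label <- rep("", tree$Nnode)
    if (placement@rootEvent) {
        tree$node.label[1L] <- paste0(tree$node.label[1L], "_PSI")
    } else {
        for (e in placement@edges) {
            ch <- tree$edge[e, 2L]
            if (ch <= nt)
                tree$tip.label[ch] <- paste0(tree$tip.label[ch], "_PSI")
            else
                tree$node.label[ch - nt] <-
                    paste0(tree$node.label[ch - nt], "_PSI")
        }
    }
    ape::write.tree(tree)
}

#' Reversible-parsimony diagnostic score
#'
#' Fitch parsimony count for the same binary character, allowing
#' regain; reported as a diagnostic next to the Dollo count (the Dollo
#' count is never below it).  `MISSING` tips are treated as ambiguous.
#'
#' @inheritParams dolloMinEvents
#' @return integer parsimony score.
#' @export
fitchScore <- function(tree, states) {
    st <- states[tree$tip.label]
    chr <- ifelse(st == "FUNCTIONAL", "f",
                  ifelse(st == "NONFUNCTIONAL", "n", "?"))
    dat <- phangorn::phyDat(matrix(chr, ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = c("f", "n"))
    as.integer(phangorn::parsimony(tree, dat, method = "fitch"))
}
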