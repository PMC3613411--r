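.alnMatrix <- function(aln) {
    if (is(aln, "AAStringSet")) {
        w <- Biostrings::width(aln)
        if (length(unique(w)) != 1L)
            stop("alignment rows must have equal length")
        m <- do.call(rbind, strsplit(as.character(aln), ""))
        rownames(m) <- names(aln)
        return(m)
    }
    if (is.matrix(aln)) return(aln)
    stop("alignment must be an AAStringSet or a character matrix")
}

#' Count lineage-unique substitutions against an outgroup
#'
#' For two lineages `a`, `b` and an outgroup, counts alignment columns
#' where one lineage carries a residue different from the other two
#' (which agree): substitutions unique to that lineage under parsimony
#' polarization.  Columns containing a gap, `X`, or `*` in any of the
#' three rows are excluded; columns where all three residues differ are
#' informative for neither lineage and are reported separately.
#'
#' @param aln an aligned [Biostrings::AAStringSet] (or character matrix).
#' @param a,b,outgroup row ids.
#' @return list with `nA`, `nB`, `nUninformative` (all-different
#'   columns), and `nCompared` (columns surviving complete-case
#'   filtering).
#' @export
countUniqueSubstitutions <- function(aln, a, b, outgroup) {
    m <- .alnMatrix(aln)
    ids <- c(a, b, outgroup)
    if (!all(ids %in% rownames(m)))
        stop("unknown sequence id: ",
             paste(setdiff(ids, rownames(m)), collapse = ", "))
    ra <- m[a, ]; rb <- m[b, ]; ro <- m[outgroup, ]
    bad <- c("-", "X", "*")
    keep <- !(ra %in% bad | rb %in% bad | ro %in% bad)
    ra <- ra[keep]; rb <- rb[keep]; ro <- ro[keep]
    list(nA = sum(ra != rb & rb == ro),
         nB = sum(rb != ra & ra == ro),
         nUninformative = sum(ra != rb & rb != ro & ra != ro),
         nCompared = sum(keep))
}

#' Tajima relative-rate chi-square test
#'
#' Tests whether two lineages accumulated equal numbers of unique
#' substitutions: `chi^2 = (nA - nB)^2 / (nA + nB)` on one degree of
#' freedom, no continuity correction.  With both counts zero the
#' statistic is 0 and the p-value 1.
#'
#' @param nA,nB non-negative unique-substitution counts.
#' @param lineageA,lineageB,outgroup optional labels carried into the
#'   result.
#' @return one-row `data.frame` with columns `lineage_a`, `lineage_b`,
#'   `outgroup`, `n_a`, `n_b`, `chi_square`, `df`, `p_value`.
#' @export
#' @examples
#' tajimaChi2(22, 15)  # chi-square 1.32
tajimaChi2 <- function(nA, nB, lineageA = "A", lineageB = "B",
                       outgroup = "outgroup") {
    if (nA < 0 || nB < 0) stop("substitution counts must be non-negative")
    tot <- nA + nB
    chi <- if (tot == 0) 0 else (nA - nB)^2 / tot
    p <- if (chi == 0) 1 else stats::pchisq(chi, df = 1, lower.tail = FALSE)
    data.frame(lineage_a = lineageA, lineage_b = lineageB,
               outgroup = outgroup, n_a = as.integer(nA),
               n_b = as.integer(nB), chi_square = chi, df = 1L,
               p_value = p, stringsAsFactors = FALSE)
}

#' @rdname tajimaChi2
#' @param aln,a,b aligned sequences and row ids; the counts are taken
#'   from [countUniqueSubstitutions()].
#' @export
relativeRateTest <- function(aln, a, b, outgroup) {
    cu <- countUniqueSubstitutions(aln, a, b, outgroup)
    out <- tajimaChi2(cu$nA, cu$nB, lineageA = a, lineageB = b,
                      outgroup = outgroup)
    out$n_uninformative <- cu$nUninformative
    out$n_compared <- cu$nCompared
    out
}

#' Protein p-distance and Poisson-corrected distance
#'
#' `pDistance()` is the fraction of mismatching residues over pairwise
#' complete columns (no gap, `X`, or `*` in either row);
#' `poissonDistance()` is the multiple-hit correction `-ln(1 - p)`.
#'
#' @param aln aligned [Biostrings::AAStringSet] or character matrix.
#' @param i,j row ids or indices.
#' @return a numeric distance.
#' @export
pDistance <- function(aln, i, j) {
    m <- .alnMatrix(aln)
    ri <- m[i, ]; rj <- m[j, ]
    bad <- c("-", "X", "*")
    keep <- !(ri %in% bad | rj %in% bad)
    if (!sum(keep)) stop("no pairwise-complete columns between ", i,
                         " and ", j)
    mean(ri[keep] != rj[keep])
}

#' @rdname pDistance
#' @export
poissonDistance <- function(aln, i, j) {
    p <- pDistance(aln, i, j)
    if (p >= 1) stop("saturated pair (p = 1): Poisson distance infinite")
    -log(1 - p)
}

#' Pairwise protein distance matrix
#'
#' @param aln aligned [Biostrings::AAStringSet] or character matrix.
#' @param method `"poisson"` (default) or `"p"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
proteinDistanceMatrix <- function(aln, method = c("poisson", "p")) {
    method <- match.arg(method)
    m <- .alnMatrix(aln)
    ids <- rownames(m)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    fn <- if (method == "poisson") poissonDistance else pDistance
    for (i in seq_len(n - 1L))
        for (j in seq(i + 1L, n))
            d[i, j] <- d[j, i] <- fn(m, ids[i], ids[j])
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]; negative branch lengths are
#' clamped to zero with a warning (a reporting convention that does not
#' change the topology).
#'
#' @param dm symmetric distance matrix with labels.
#' @return an unrooted `phylo`.
#' @export
njTree <- function(dm) {
    dm <- as.matrix(dm)
    if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
    if (!isSymmetric(unname(dm), tol = 1e-8))
        stop("distance matrix must be symmetric")
    tr <- ape::nj(dm)
    if (any(tr$edge.length < 0)) {
        warning("negative branch length(s) clamped to zero")
        tr$edge.length[tr$edge.length < 0] <- 0
    }
    tr
}

#' Root a tree on an outgroup's pendant edge
#'
#' Places the root at the midpoint of the outgroup's pendant edge, so
#' the outgroup attaches directly at the root.  Re-rooting with the same
#' outgroup is idempotent.
#'
#' @param tree a `phylo`.
#' @param outgroup tip label to root on.
#' @return a rooted `phylo`.
#' @export
rootAtOutgroup <- function(tree, outgroup) {
    i <- match(outgroup, tree$tip.label)
    if (is.na(i)) stop("unknown tip: ", outgroup)
    if (is.null(tree$edge.length))
        return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
    pend <- which(tree$edge[, 2L] == i)
    phytools::reroot(tree, i, position = tree$edge.length[pend] / 2)
}

#' Bootstrap support for neighbor-joining clades
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree on
#' each replicate, and reports for every internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#' All column indices are drawn up front from a single seeded generator,
#' so supports are exactly reproducible.
#'
#' @param aln aligned [Biostrings::AAStringSet] or character matrix.
#' @param method distance used, see [proteinDistanceMatrix()].
#' @param nReplicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return list with `tree` (NJ tree on the full alignment, `node.label`
#'   holding supports), `support` (numeric vector over internal nodes),
#'   `degenerate` (`TRUE` when all pairwise distances are zero and the
#'   topology is a tie-break artifact).
#' @export
bootstrapSupport <- function(aln, method = c("poisson", "p"),
                             nReplicates = 100L, seed = 1L) {
    method <- match.arg(method)
    m <- .alnMatrix(aln)
    if (ncol(m) < 2L) stop("alignment needs at least 2 columns")
    if (nReplicates < 1L) stop("need at least one replicate")
    set.seed(seed)
    idx <- matrix(sample.int(ncol(m), ncol(m) * nReplicates,
                             replace = TRUE), ncol = nReplicates)
    full <- proteinDistanceMatrix(m, method = method)
    refTree <- njTree(full)
    degenerate <- all(full == 0)
    boots <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
        mb <- m[, idx[, r], drop = FALSE]
        boots[[r]] <- suppressWarnings(
            njTree(proteinDistanceMatrix(mb, method = method)))
    }
    class(boots) <- "multiPhylo"
    counts <- ape::prop.clades(refTree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- 100 * counts / nReplicates
    refTree$node.label <- as.character(round(support, 1))
    list(tree = refTree, support = support, degenerate = degenerate)
}
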