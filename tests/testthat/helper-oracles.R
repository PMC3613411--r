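# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths (and Biostrings) so they can stand as
# second opinions.

# hand-written standard genetic code, indexed by codon
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n)
  codons <- substring(cds, starts, starts + 2L)
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  paste(aa, collapse = "")
}

# plain-R affine-gap global alignment score (Gotoh), match +1,
# mismatch -1, gap of length L costs open + L * extend
oracle_align_score <- function(a, b, open = 4, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(n)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- if (a[i] == b[j] && a[i] != "N") 1 else -1
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# brute-force scan for new in-frame stops in a mutated CDS (excludes the
# terminal codon), returning the codon indices that hold stops
oracle_stop_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n - 1L)
  codons <- substring(cds, starts, starts + 2L)
  which(codons %in% c("TAA", "TAG", "TGA") & !grepl("N", codons))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# random coding sequence free of internal stops, with terminal stop
random_orf <- function(nCodons) {
  sense <- setdiff(names(CODON_TABLE), c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, nCodons - 2L, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

# random rooted tree with random tip states
random_state_case <- function(nTips) {
  tr <- ape::rtree(nTips)
  states <- sample(c("FUNCTIONAL", "NONFUNCTIONAL", "MISSING"),
                   nTips, replace = TRUE)
  names(states) <- tr$tip.label
  list(tree = tr, states = states)
}

# additive distance matrix from a tree with branch lengths
additive_matrix <- function(tree) ape::cophenetic.phylo(tree)
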