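---
title: "Tracing gene loss across vertebrate genomes with GeneLossKit"
author: "GeneLossKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing gene loss across vertebrate genomes with GeneLossKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneLossKit)
```

## The problem

Several vertebrate lineages — ruminants, cats, bats, hedgehogs, birds —
have little or no glucokinase (GCK) activity in the liver despite
carrying apparently functional *GCK* genes. Because glucokinase
regulatory protein (GCKR) stabilises hepatic GCK, loss of the *GCKR*
gene is a sufficient explanation: a species without GCKR degrades its
liver GCK regardless of the *GCK* locus. Testing that hypothesis is a
comparative-genomics exercise with four parts, and GeneLossKit
implements each as a reusable, tested component:

1. **Pseudogene detection** — find coding-sequence-disrupting mutations
   (frameshifting indels, premature stop codons, splice-dinucleotide
   changes) in a candidate locus relative to a reference gene model, and
   classify the per-species gene status.
2. **Synteny-based absence calling** — for species where no gene-like
   sequence exists at all, decide from conserved flanking genes whether
   the gene was deleted or may hide in an assembly gap.
3. **Dollo parsimony loss mapping** — count and place the minimum number
   of irreversible inactivation events on the species phylogeny.
4. **Relative-rate tests and distance trees** — check that lineages with
   intact open reading frames are *not* cryptic pseudogenes, which would
   show accelerated protein evolution.

A fifth component, the **simulator**, generates multi-exon gene families
evolving along a tree with a known truth table, so the detector can be
validated end to end without any external data. Bundled fixtures
transcribe a published census of GCKR gene structures (locus records,
per-exon disruption lists, status categories, substitution counts,
schematic gene neighborhoods, and the consensus vertebrate phylogeny),
so the package reproduces that study's headline numbers from its own
data directory.

## Disruption detection

### Exon alignment

Candidate loci are scanned exon by exon. Each reference exon is carried
with 20 bp of intronic flank (so the splice dinucleotides are visible)
and aligned into the target with an affine-gap Gotoh aligner: match +1,
mismatch −1, gap open −4, gap extend −1 per base, implemented in C++
with a fully deterministic traceback (diagonal preferred over
gap-in-target over gap-in-reference at equal score). In `"fit"` mode the
reference is aligned globally while leading and trailing target bases
are free, which places an exon inside a multi-kilobase locus. Scanning
exploits collinearity: each exon is searched downstream of the previous
one within a window sized by the reference gap plus 250 bp of slack,
falling back to the whole locus if the window misses.

An exon is **found** when identity ≥ 0.5 over at least 50% of its
length, where identity is the fraction of aligned (non-gap, non-`N`)
exon columns that match. This rule has a known edge: because gapped
columns are excluded from the denominator, a global alignment of two
*unrelated* sequences can occasionally reach identity ≈ 0.5 by gapping
out mismatches (about a third of reversed random 60-mers do). Such
alignments always carry strongly negative scores, and in fit-mode
scanning the threshold behaves well; the tests therefore assert
rejection of reversed sequences as a majority property together with
exact score agreement against an independent dynamic-programming
oracle.

### The three disruption classes

* **Frameshift** — called per exon from the *net* indel length over the
  exon-proper alignment columns, modulo 3. Two compensating indels in
  one exon cancel; the damage they leave behind is still caught by the
  stop-codon scan. Reported tables fold premature stops into the
  frameshift column (mirroring the two-column census layout) while the
  internal records keep all four categories.
* **Splice disruption** — the donor must be `GT` and the acceptor `AG`.
  The donor dinucleotide is attributed to the exon it follows, the
  acceptor to the exon it precedes. `GC` donors, splice-competent in a
  minority of real introns, are reported as events with a
  `noncanonical (GC)` detail flag rather than silently accepted.
* **Premature stop** — each found exon's target bases are read in the
  reading frame the reference carries into that exon (its *phase*), so
  the frame is restored at every exon boundary and a frameshifting
  indel scrambles translation only within its own exon. Any in-frame
  `TAA`/`TAG`/`TGA` strictly upstream of the reference terminal stop is
  an event on the exon containing it. Codons containing `N` never
  count; codons spanning exon junctions are not scanned (at most
  `n_exons − 1` of roughly 500 codons).

The frame-local reading deserves a note. An alternative is to project
target bases onto reference columns via the alignment and scan that
projection; but near an indel, equally scoring alignments place the gap
at different columns, so the projected sequence — and hence the stop
calls — would depend on an arbitrary traceback choice. The frame-local
scan depends only on *which bases* the alignment assigns to the exon,
not on where gaps sit inside it, which makes detection reproducible and
lets the simulator compute the identical quantity exactly. The
projection-style scan remains available as `detectPrematureStops()` for
analyses that start from a pre-repaired coding sequence.

### Status classification

Statuses follow the rule that pseudogenization must be demonstrated
twice over: **INACTIVATED** requires two or more disrupting events; a
single event leaves a gene **POTENTIALLY_INTACT**, since one apparent
mutation can be a sequencing error or a rare allele; zero events with
all exons recovered is **INTACT**, and zero events with missing exons
stays POTENTIALLY_INTACT (a missing exon is evidence of nothing — the
census keeps such genes potentially intact). Species with no sequence
at all become **DELETED** only when synteny supports deletion, else
**UNRESOLVED**.

## Synteny-based absence calls

A gene can be absent from an assembly because it was deleted or because
it sits in a gap. The discriminating observation is the gene
neighborhood: if the two conserved flanking genes (`FNDC4` 5′ and
`ZNF512` 3′ for the GCKR locus in tetrapods) are linked on a *single*
fragment in the expected relative orientation with no target between
them, the neighborhood is intact and the gene is gone — `DELETED`. If
the flanks sit on separate short fragments the call is `UNRESOLVED`.
Intervening unrelated genes do not block a deletion call (fish
neighborhoods show such insertions), but a target hit anywhere in the
species map forces `PRESENT`. Orientation is checked between the two
flanks rather than against absolute strand, so calls are invariant to
fragment polarity — a property the tests verify by mirror-flipping
fixtures.

## Dollo parsimony

Gene inactivation is irreversible, so the loss character is modelled as
Dollo: the root is functional, and transitions go one way. Under that
model the minimum event placement is exact and closed-form: one event on
the stem of every *maximal* clade containing at least one nonfunctional
tip and no functional tip. Tips scored `MISSING` (no sequence — possibly
an assembly gap — or absent from the census) constrain nothing: they may
sit below a loss event or not. The implementation is a post-order sweep;
an independent exhaustive oracle (`bruteForceMinEvents()`) enumerates
candidate-edge subsets by increasing cardinality, bitmask-vectorised so
it handles the full 65-tip census tree in well under a second, and the
two agree on 200 random trees per test run.

On the bundled phylogeny with the 13 dual-mutation species (both a
frameshift and a splice mutation) scored nonfunctional, strict Dollo
needs **nine** events: tarsier; the cow–sheep–dolphin clade; alpaca;
cat; the bats; the hedgehog stem (its sister, shrew, is MISSING); hyrax;
tenrec; and xenarthrans. The published reconstruction quotes "at least
six" — a lower bound, which the package treats as such: the published
count merged hyrax, tenrec and the xenarthrans into one ancestral
Afrotheria+Xenarthra event, which strict Dollo forbids because the
elephant (intact) nests inside that clade. A reversible Fitch score is
reported alongside as a diagnostic (seven for the census data), never as
the headline count.

## Relative-rate tests and trees

If the intact-ORF genes of dog, panda, horse and pig were pseudogenes of
long standing, they would accumulate substitutions faster than genes
under selection. The Tajima relative-rate test needs no rate model:
with an outgroup O, a column where lineage A differs while B and O
agree is a substitution unique to A. Counting `nA` and `nB` over
complete columns (no gap, `X`, or `*` in any of the three rows — stops
and ambiguity codes are treated as missing data) gives

$$\chi^2 = \frac{(n_A - n_B)^2}{n_A + n_B}, \quad df = 1,$$

with no continuity correction — `(22 − 15)²/37 = 1.32` reproduces the
published statistic exactly, which a Yates-corrected form would not.
Columns where all three residues differ polarise neither lineage; they
are excluded from both counts and reported as `n_uninformative`.

Distance trees use the observed proportion of differing residues
(*p*-distance) and its Poisson multiple-hit correction `−ln(1 − p)`;
neighbor joining is delegated to `ape::nj()`, with negative branch
lengths clamped to zero as a reporting convention. The maximum
likelihood JTT/Dayhoff distances used for the original figures are not
reimplemented: their exact numeric procedure is not recoverable, so
tree correctness is established by property (NJ recovers the generating
topology from any additive matrix) rather than by matching published
figures. Bootstrap supports resample alignment columns with all indices
drawn up front from one seeded generator, making supports
bit-reproducible; trees are rooted by splitting the outgroup's pendant
edge at its midpoint.

## The simulator and what passing tests mean

`simulateGeneFamily()` evolves a random multi-exon gene (defaults: 19
exons of 48–120 bp, introns of 60–160 bp, ATG…stop ORF, GT–AG introns)
down a tree. On functional branches, substitutions that would create an
in-frame stop or touch a splice dinucleotide are rejected, and exonic
indels come in multiples of three; on designated loss branches and
below, those constraints lift and rates multiply (default ×2 over a
substitution rate of 0.02 and an indel rate of 0.0015 per site per unit
branch length — values in the range of fast-evolving mammalian loci,
chosen once as the test conditions). DNA substitutions are uniform
across the three alternative bases (Jukes–Cantor-like) and indel
lengths are geometric (p = 0.5, capped at half the segment): the tests
need event counts, not mutational realism.

Two bookkeeping choices matter:

* **Truth from final state.** The truth table is computed from the
  simulator's exact base-to-root-column mapping at the tips, not from
  the mutation log, so overwritten or compensating mutations are
  already resolved and truth-versus-detector comparison is exact
  equality of (category, exon) sets.
* **Indels avoid feature boundaries.** Injected indels keep an 8 bp
  margin from exon/intron boundaries. An indel *at* a junction is
  intrinsically ambiguous — an equally scoring alignment can push it
  across the boundary, turning a frameshift into an apparent splice
  change — so boundary-adjacent indels would make the truth table
  ill-defined rather than the detector wrong. Splice disruption is
  injected through substitutions at the dinucleotides themselves.

Under these conditions the detector recovers the injected (category,
exon) set exactly in ≥ 99% of 500 simulated loss-clade genes (currently
500/500), and every functional tip scans INTACT. What this does *not*
establish: performance on diverged real genomes (the simulator has no
rate heterogeneity, repeats, or GC structure), paralog disambiguation,
or splice-site recognition beyond the terminal dinucleotides. Assembly
gaps are emulated only as wholly withheld sequences.

Problem sizes used by the test suite and acceptance checks — 500
simulated gene families on a 4-tip tree, 200 random ≤ 12-tip trees for
the parsimony oracle, 100 seeds × 2000 sites for the rate-ratio
recovery, 200 bootstrap replicates — were chosen so the whole suite
runs in a few minutes on one CPU while keeping sampling error far from
every asserted bound.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout; minus-strand models
  store plus-strand coordinates and reverse-complement at extraction.
* Phase is defined as coding bases carried over from previous exons
  (cumulative length mod 3); phases in input GFF3 are recomputed rather
  than trusted.
* `N` in DNA translates to `X`; `X`, `*` and gaps are excluded from all
  rate and distance computations; a saturated pair (p = 1) is an error
  rather than an infinite distance.
* `(0, 0)` substitution counts give χ² = 0 and p = 1.
* A tree whose tips are all nonfunctional/missing takes a single loss
  event at the root.
* All generators and the bootstrap are bit-reproducible given a seed;
  pipeline reports contain no timestamps, so identical inputs produce
  byte-identical output files.

## Reproducing the census numbers

```{r census}
# Table of relative-rate tests from the packaged substitution counts
runRateTests(rateCountCensus())[, c("lineage_a", "lineage_b",
                                    "chi_square", "p_value")]

# Disruption census: 14 inactivated species, cow with 11 mutated exons
rep <- runStatusReplay(censusEvents(), exonsTotal = 19)
rep$statusCounts
subset(rep$bySpecies, species == "Cow")

# Nine species lack the gene entirely; birds are true deletions
sum(!locusCensus()$found[!duplicated(locusCensus()$species)])
maps <- neighborhoodMaps()
callAbsence(maps[maps$species == "Chicken", ], "GCKR",
            "FNDC4", "ZNF512")$status

# Dollo loss mapping on the bundled phylogeny
runParsimony(vertebratePhylogeny(), censusTipStates())$nEvents
```

## Known limitations

* Exon presence thresholds (identity ≥ 0.5 over ≥ 50% of length) and
  the GT–AG-only splice consensus are conventions; the census source
  did not state its criteria, so borderline exons could be judged
  differently.
* The fit-mode scan assumes exon collinearity; inverted or transposed
  exons would be reported as missing.
* Ortholog identification is out of scope: fragment maps and candidate
  loci must already be orthologous (the marmoset multi-copy case is
  deliberately not handled).
* The "at least six" loss events of the source reconstruction is
  reproduced as a bound; the exact placement the original authors
  intended cannot be recovered under strict Dollo (see above).
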