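---
title: "Methods: tracing intron gain after endosymbiotic gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing intron gain after endosymbiotic gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introntrace)
```

## The model

Mitochondria descend from an alpha-proteobacterial endosymbiont, and over
evolutionary time much of the organelle genome was relocated to the host
nucleus. An organellar gene carries no spliceosomal introns, so a
nuclear-encoded gene of proto-mitochondrial origin started its nuclear life
intron-less: every intron it carries today was gained after the transfer.
`introntrace` treats this as a three-layer inference problem:

1. **Observation layer** — where are the introns? A protein is aligned to
   its genomic locus; the unaligned genomic gaps are putative introns,
   filtered by length, canonical `GT..AG` splice sites, and a translated
   junction check.
2. **History layer** — when did the gene become nuclear? Presence in the
   mitochondrial genome (`M`), nuclear encoding (`N`) or missing data (`U`)
   per species, combined with a rooted species tree under Dollo parsimony
   (a transfer happens at most once per lineage and is never reversed),
   yields the minimal set of transfer branches and their relative ages.
3. **Comparison layer** — are introns at the same position in different
   lineages? Positions are (protein-alignment column, phase) pairs; a shared
   position between independently transferred lineages cannot be inherited
   and must be a parallel gain, whereas within a singly transferred clade it
   is expected to reflect descent.

## Spliced alignment and the acceptance filters

The aligner seeds exact amino-acid k-mers (default `seed_k = 5`) against the
three forward-frame translations of the locus, merges them into maximal
exact matches, and chains blocks by dynamic programming that maximises the
number of protein residues covered, with genomic gaps (introns) costing
nothing. Two numerical choices matter:

* **Small overlaps are trimmed, not forbidden.** A maximal match can
  overshoot a phase-1/2 split codon when the codon straddling the true
  junction happens to translate to the right residue (~1/20 chance per
  junction side). The chain DP therefore tolerates up to 3 residues of
  protein overlap between consecutive blocks and trims the downstream block
  at reconstruction. Without this, an entire short exon can drop out of the
  chain and its two flanking introns are lost.
* **Boundary rescue within ±12 nt.** The candidate intron placement implied
  by block ends is slid up to 12 nt left or right; a placement is considered
  only if the spliced translation around the junction still matches the
  query, and placements whose gap starts `GT` and ends `AG` are preferred
  (ties: smallest shift, then leftmost). The inferred coding offset
  `3 * p_end + (start - g_end)` is invariant under these shifts, so rescue
  never moves an intron to a wrong coding position.

Accepted introns must be **longer than 20 nt** (strict: 21 nt passes, 20
does not), start `GT` and end `AG`, and pass the junction check: the 9
exonic nucleotides before the donor and the 9 after the acceptor are
spliced, the complete codons inside that 18-nt window are translated in the
coding frame, and the translation must equal the corresponding query
residues. For phase-1/2 introns the window is not codon-aligned, so the
comparison covers the complete codons it contains — the reassembled split
codon always is one of them. When a flanking exon is shorter than 9 nt the
window is truncated symmetrically. Rejected candidates are logged with the
first failing filter (`LENGTH`, `SITE`, `JUNCTION`), in that order.

The interpretation of "18 nucleotides surrounding the splicing site" as
9 + 9 around a single junction was an open choice; 18 nt divide into 6
codons only after splicing, which is what motivated this reading.

## Gene-structure statistics

Intron density is `1000 * n_introns / cds_len`, with the stop codon excluded
from `cds_len` (the effect of that convention is below 0.5% and applied
consistently to simulator and analysis). Phases are counted over all
introns; exon symmetry classifies each internal exon by its flanking phases
(terminal exons have only one flank and are excluded — the 3x3 class scheme
requires two). Per-species panels are the same computations grouped by a
`by` vector, not separate code; both the pooled and the per-species grouping
are exposed because figure-level conventions differ on this.

## Transfer timing by Dollo parsimony

The root state is mitochondrial; a transfer on a branch makes every leaf
below it nuclear; no reversal exists. The minimal scenario is found in
closed form: a node is *legal* if no `M` leaf lies below it and at least one
`N` leaf does; events sit on the maximal legal nodes. Equally parsimonious
deeper placements exist exactly when a maximal legal node is not the most
recent common ancestor of its `N` leaves (unknown-state leaves and
multifurcations create such slack); the scenario is then flagged unresolved
and all alternatives are enumerated rather than guessed. Unknown (`U`)
covers both genuine absence and missing mitochondrial-genome data, which the
source framework does not separate.

One design decision deviates from a literal branch-above-a-node reading: a
**virtual root-stem branch** is a legal transfer location, so a gene nuclear
in every sampled species is a single ancestral transfer rather than one
event per root child. This matches how an all-nuclear gene is convention-
ally described as transferred "at the root".

A claimed invariant had to be weakened after analysis: flipping one leaf
from `U` to `N` changes the event count by 0 or +1, and no flip ever
decreases it, but a `U`→`M` flip *can* add more than one event (it can break
one ancestral event into per-subtree events at a multifurcation). The
property tests assert the corrected statements.

Relative timing is the partial order of event branches by ancestry: nested
events are ordered (rootward = more ancient), sibling events are
incomparable, and per focal species the events on its root path are binned
into age classes by branch depth.

## Shared intron positions

A position is an (alignment column, phase) pair — "same amino acid" alone
would conflate phase-1 and phase-2 introns of one codon, while phase
equality makes positions nucleotide-exact. A distinct position is shared
between two groups iff at least one sequence of each carries it, and
group-specific iff all carriers are in one group; percentages are relative
to the total number of distinct positions across all groups in the family
set. The source tables imply inconsistent denominators between their two
panels, so this single auditable definition is fixed and used everywhere,
including the independent-versus-single transfer comparison (per class:
`100 * shared positions between the focal groups / total distinct positions
in the class's families`).

Conserved blocks emulate a block-finding web service with a windowed
heuristic: a column passes when its gap fraction is at most 0.1 and the mean
pairwise residue identity, averaged over a 10-column sliding window, is at
least 0.5; runs of at least 8 passing columns become blocks. All four
parameters are configurable; the defaults make unrelated random alignments
(20 x 200, uniform residues) blockless in ≥ 99% of seeds while identical
sequences form one full-width block. Restriction to blocks is cell-wise
non-increasing by construction.

## Proto-splice sites and codon usage

The proto-splice test is the classical 4-nt consensus: `(C|A)AG` ending the
exonic sequence before the insertion point and `(A|G)` starting it after,
evaluated on the *spliced* coding sequence (never on intron interiors).
Exactly 4 of the 256 possible (trinucleotide, nucleotide) contexts qualify;
the tests enumerate all of them against a regex oracle instead of
hard-coding the count. Whether flanking positions beyond these 4 nt matter
is left out deliberately — the consensus cited by the source is 4 nt.

Codon usage is computed per amino acid from in-frame coding sequence;
the genetic-code table is configurable (standard by default, vertebrate
mitochondrial available) but affects only the codon-to-amino-acid grouping,
not position/phase logic. The glutamine CAA/CAG contrast between
mitochondrial and nuclear compartments is the motivating use.

## What the simulator emulates — and what it does not

`sim_config()` encodes the stated world: a 12-leaf, four-group species tree
with a trifurcating root (so multifurcation handling is always exercised),
unit branch lengths, 20 genes of 200–400 residues, 1–3 minimal transfer
events per gene (weights 0.5/0.3/0.2), gain rate λ = 2 gains per kb coding
sequence per unit branch length, loss rate μ = 0.1, phase weights 5:3:2,
intron lengths uniform on 60–500 nt, amino-acid substitution probability
0.02 per site per unit branch length, and compartment codon usage that is
uniform within synonymous families except glutamine (nuclear 90% CAG,
mitochondrial 90% CAA). On the transfer branch the gene's synonymous codons
are resampled from nuclear usage — the codon-adaptation step that creates
proto-splice sites in nuclear copies.

Choices a user should know about:

* **Minimum intron spacing 30 nt** (also from the cds ends). The round-trip
  guarantee requires every exon to contain at least one full seed k-mer;
  without a spacing floor, uniform gains routinely create internal exons
  shorter than any seed, which no seed-and-chain aligner can recover. Real
  internal exons under ~30 nt are also rare. This is a generator default of
  the stated world, set before any acceptance measurement.
* **Intron interiors are boundary-hygienic**: the donor `GT` is the only
  `GT` in the first 15 nt and the acceptor `AG` the only `AG` in the last
  15 nt, so the ±12 nt boundary rescue has a unique canonical solution.
  Substitutions never touch boundary dinucleotides — sequence divergence
  models alignment realism, not structure change.
* **Indel-free by default**, so the true alignment is positional and
  shared-position truth is unambiguous. A `simple` indel mode (codon-level
  insertions/deletions with a tracked homology-column registry) exists to
  stress alignment-column mapping; it does not guarantee aligner round-trips
  because deletions can shrink exons below the spacing floor.
* Ground truth records every gain event; a shared (column, phase) position
  is labelled `descent` when all carriers trace to one event and `parallel`
  otherwise, which is what calibrates the shared-fraction comparison.

A green test on synthetic data establishes that the implementation is
faithful to this model; it does *not* establish that real genomes meet the
model's assumptions (no pseudogenes or sequencing errors, forward-strand
coding orientation, canonical splice sites only, exact protein/genome
correspondence). Reverse strands and non-canonical `GC-AG`/`AT-AC` introns
are explicit non-goals.

## Numerical and testing notes

* Coordinates are 0-based half-open internally; only `anchor_residue` and
  human-facing reports are 1-based.
* All randomness flows through a mandatory seed; pipeline reruns under the
  same config are byte-identical (checked file-by-file with md5).
* The parsimony oracle in the tests enumerates branch subsets exhaustively.
  Full enumeration of *all* rooted multifurcating topologies up to 6 leaves
  crossed with all 3^n state assignments does not fit a CI budget, so the
  exhaustive cross runs on a fixed panel of 2–4-leaf topologies plus seeded
  random 5–6-leaf trees, with 200 random assignments on 7–10-leaf trees;
  the oracle itself is unscaled.
* Statistical acceptance checks (phase weights, glutamine usage, the
  parallel-gain expectation Σ p₁p₂) use 3σ binomial/CLT bounds. For codon
  usage the unit of independence is one representative cds per gene per
  compartment — pooling all leaves of a family would understate the variance
  because they share ancestral codons.
* Configs are JSON (no YAML parser is assumed in the target environment).

## Known limitations

* The spliced aligner assumes exact protein/locus correspondence (true for
  the simulator; real data with annotation errors would need the coverage
  threshold and junction filter relaxed and would lose the exactness
  guarantees).
* `compare_transfer_classes` reports `NA` for empty classes rather than 0,
  and its denominators follow the fixed definition above; reproducing other
  published percentages that used undocumented denominators is out of scope.
* Absolute dating, probabilistic transfer reconstruction, and species-tree
  inference are out of scope; the tree is an input.
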