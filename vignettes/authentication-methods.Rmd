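---
title: "Chloroplast barcode markers and monophyly-based authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chloroplast barcode markers and monophyly-based authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagmark)
```

## The problem

Closely related medicinal plants — the package's motivating system is the
*Patrinia* species sold as the herb Baijiangcao — often cannot be separated
by the universal plant barcodes (ITS2, *rbcL*, *psbA-trnH*). When complete
chloroplast genomes are available for a handful of reference accessions, a
different strategy works: scan the plastome alignment for localized
divergence hotspots, sequence those loci across many accessions, and
authenticate specimens by two complementary signals computed from the
per-locus alignments:

1. **diagnostic markers** — alignment columns (or gap runs) where one taxon
   carries a state found in no other taxon; and
2. **tree-based discrimination** — whether each taxon's accessions form a
   monophyletic clade in a distance tree rooted on an external outgroup.

`diagmark` implements both, together with the scan that locates candidate
loci, a seeded simulator that generates data with known truth, and a
pipeline that evaluates every loci combination.

## Nucleotide diversity scan

Nucleotide diversity π is the mean proportion of pairwise differences per
site. For a window of columns, every column containing any gap or ambiguity
code in any sequence is excluded entirely (column-wise exclusion); over the
remaining columns the per-column mean pairwise mismatch fraction is
averaged. Windows are placed on alignment coordinates — gap columns count
toward a window's span — so that reported hotspot positions refer to the
alignment the user supplied. Defaults follow common plastome practice:
window 600 bp, step 200 bp, and a hotspot threshold of π > 0.05 (strict
inequality). Trailing partial windows are dropped rather than padded so that
all π values average the same number of potential sites; windows with no
usable column have undefined π and are excluded from hotspot calling with a
warning.

Above-threshold windows that overlap or are book-ended are merged into one
hotspot region. Note one subtlety we chose not to paper over: for *merged
regions*, raising the threshold is not monotone in general (a region held
together by a mid-π window can split into two). It is monotone when
divergence blocks are well separated relative to the window span, which is
the regime in which hotspot scans are interpreted; the tests assert
monotonicity only there.

## Diagnostic sites and InDel events

All site-level computations exclude the outgroup: it serves only to root
trees. Gaps (`-`) and ambiguity codes are treated as missing, never as
states; `.` is rejected at parse time.

- A column is **variable** if ≥ 2 distinct bases occur among defined ingroup
  bases, and **parsimony-informative** if ≥ 2 distinct bases are each
  carried by ≥ 2 accessions. "Informative variable nucleotide" counts in the
  pipeline report use the parsimony-informative definition, a deliberate
  choice where the field sometimes leaves the term loose.
- A **species-specific SNP** for taxon T at a column requires: every T
  accession fixed for one base X; X absent from all other ingroup
  accessions; and every non-T ingroup accession *defined* (A/C/G/T) there.
  The last clause matters: a candidate state opposite accessions with gaps
  (e.g. near amplicon ends) is not evidence of specificity, and such columns
  are disqualified outright. Under a clean two-state partition between two
  internally fixed taxa, both taxa are reported.
- An **InDel event** is a maximal run of contiguous columns sharing an
  identical per-accession presence/absence pattern with at least one gap.
  An event belongs to taxon T when the accessions bearing sequence (or,
  symmetrically, the gap) are exactly T's accessions; polarity is
  `insertion` when one taxon bears sequence, `deletion` when one taxon bears
  the gap (bearing-sequence is checked first, which matters only in
  two-taxon alignments where the two readings coincide), otherwise
  `unpolarized`. Events touching the alignment ends are kept but flagged
  `edge = TRUE`, since terminal gaps usually reflect amplicon length.

## Distance models

From each sequence pair, compared under pairwise deletion (both characters
in {A,C,G,T}), we take the transition proportion *P* (A↔G, C↔T), the
transversion proportion *Q*, and the pooled GC fraction θ of both sequences
over compared sites. With *p* = *P* + *Q*:

- p-distance: *d* = *p*
- JC69: *d* = −(3/4) ln(1 − 4*p*/3)
- K2P: *d* = −(1/2) ln(1 − 2*P* − *Q*) − (1/4) ln(1 − 2*Q*)
- T3P: *d* = −*h* ln(1 − *P*/*h* − *Q*) − (1/2)(1 − *h*) ln(1 − 2*Q*),
  with *h* = 2θ(1 − θ); at θ = 0.5 this reduces exactly to K2P.

A gamma shape *a* replaces each −ln(*w*) by *a*(*w*^(−1/*a*) − 1); the
default shape when a "+Gamma" model is requested without one is 1.0, since
shape estimates are rarely reported alongside model labels. "+Invariable"
corrections are not implemented — the distance form is under-determined
without the invariant-site fraction — and requests fall back to the base
model. Pairwise deletion (rather than complete deletion) preserves
information when amplicon sets have unequal coverage. A pair whose log
argument is non-positive is *saturated*: `seq_distance()` returns `NA`, and
`distance_matrix()` substitutes twice the largest finite distance while
flagging the pair, keeping tree building runnable without hiding the
problem. θ = 0 or 1 makes the T3P map degenerate (h = 0); such pairs fall
back to JC69.

## Trees, rooting, and the discrimination rate

NJ uses the Saitou–Nei agglomeration (via `ape::nj`); any negative branch
length is clamped to zero with the deficit moved to a sibling branch so path
sums are preserved. Tie situations resolve deterministically (same input,
same tree). UPGMA uses average-linkage clustering with node heights at half
the merge distance, so its output is ultrametric by construction.

Rooting places the root on the edge separating the outgroup from the
ingroup, splitting that edge's length equally; a non-separable outgroup is
an error, not a silent midpoint root. Monophyly is defined on rooted trees
only (MRCA's leaf set equals the queried set; singletons are trivially
monophyletic), and requesting it on an unrooted tree errors. The
**discrimination success rate** of a rooted tree is
100 × (number of monophyletic ingroup taxa) / (number of ingroup taxa).
In the pipeline, NJ trees are rooted on the outgroup before evaluation while
UPGMA trees carry their own root.

Bootstrap support resamples alignment columns with replacement, rebuilds the
tree per replicate, and scores each internal edge of the point tree by the
percentage of replicates containing the same unrooted bipartition
(`ape::prop.clades`); replicates in which some pair loses all comparable
sites are skipped, warned about, and removed from the denominator. The seed
is a required argument.

## The simulator and what it does (not) emulate

`simulate_dataset()` emulates the structure of a multi-accession barcoding
study: several ingroup taxa with low intra-taxon diversity, fixed
inter-taxon diagnostic substitutions, contiguous gap-block InDels (including
taxon-private insertions), and one diverged outgroup, over loci of typical
amplicon length (roughly 300–1100 bp). Per locus, a uniform-random ancestor
is copied to every accession; planted SNPs fix the target taxon's state;
insertions occupy pre-allocated gap blocks (only the target taxon bears
sequence; the outgroup is gapped there), so planted coordinates are final
alignment coordinates and never shift; background substitutions hit each
ingroup accession i.i.d. (uniform among the three alternative bases),
avoiding planted columns so the truth table stays exact; the outgroup
derives from the ancestor, not from any taxon. Identical config + seed gives
byte-identical output.

Defaults reflect the emulated study: 6 taxa, 5 accessions per taxon,
background rate 0.002 substitutions/site (amplicons within a species are
nearly identical), outgroup divergence 0.05 (a confamilial outgroup).
What the simulator does **not** model: phylogenetic structure among taxa
(each taxon differs from the ancestor independently), rate heterogeneity,
recombination, sequencing error, or alignment error. Passing tests on
simulated data therefore validate the *computations* — recovery of planted
truth, correctness of formulas, monophyly logic — not the field performance
of any particular marker set.

`table2_fixture()` is the deterministic counterpart: a synthetic worked
example whose planted markers reproduce, at the exact printed positions, a
published diagnostic-marker table for six *Patrinia* taxa (including the
24-bp insertion at psaI-ycf4 columns 185–208 and the disqualified
"substitution-like" column near the petA start). Its backbone is a fixed
repeating base pattern, not random draws, so it is fully reproducible and
invariant elsewhere.

## Pipeline choices

- Combination counts (informative and species-specific nucleotides) are
  computed per constituent locus and summed, not recomputed on the
  concatenation, so reported positions stay locus-local; for disjoint loci
  the two views agree.
- One global distance model (default T3P) is used for all combinations;
  per-dataset model selection (e.g. by BIC) is out of scope and consumed as
  configuration.
- Concatenation defaults to the intersection of accession sets with a
  warning listing dropped accessions; `strict` mode requires identical sets.
- A failing combination (saturation-free matrix impossible, too few taxa,
  no shared accessions) is logged and skipped; the rest proceed.
- Discrimination for each combination is evaluated over the taxa that have
  accessions in that combination's alignment.

## Problem sizes used in validation

The test-suite and acceptance computations run at deliberately modest,
field-realistic sizes chosen once: 200 random alignments (≤ 8 sequences ×
≤ 50 columns) against a brute-force π oracle; a (P, Q, θ) grid for the
closed-form distances; 100 random additive trees on 4–6 leaves against
exhaustive least-squares topology enumeration; a 30 kb, 8-sequence synthetic
plastome with three planted divergence blocks for the hotspot scan; and 20
seeded replicates of the full six-taxon authentication (700-bp locus, 3
private SNPs per taxon, background 0.002, outgroup divergence 0.05, K2P +
NJ + outgroup rooting), which recover a 100% discrimination rate.

## Known limitations

- Distances assume pairwise deletion; columns missing in many accessions
  can leave pairs with few compared sites and noisy distances.
- Saturated pairs are patched (twice the largest finite distance) to keep
  agglomeration running; trees containing flagged pairs deserve scrutiny.
- The parsimony-informative definition of "informative" sites is one of
  several in use; counts from other tools may differ.
- Sequence alignment itself is upstream of this package: all coordinates
  are alignment coordinates, and alignment choices change them.
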