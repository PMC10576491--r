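---
title: "Characterizing rearranged avian mitogenomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing rearranged avian mitogenomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

`mitochar` implements the descriptive analyses applied to annotated avian
mitochondrial genomes, with particular support for the duplicated
control-region (CR) gene order found in leaf warblers and other
passerines. This vignette explains the models and procedures behind each
stage, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic-data tests do and do
not demonstrate about real data.

## The data model

A `MitoRecord` is a circular DNA sequence plus a feature table over a
controlled vocabulary: 13 protein-coding genes (PCGs), 22 tRNAs (with the
duplicated Leu/Ser isoacceptors distinguished by anticodon class), two
rRNAs, and the control regions `CR1`/`CR2`. Coordinates are 1-based
inclusive (the GenBank convention) everywhere; conversion happens only at
parse/write boundaries. Strands are labelled J (majority) and N
(minority), the labels used in the mitogenomics literature, and are
mapped to GenBank `+`/`complement()` on write. A feature may wrap the
origin only on a circular record. GenBank qualifier spellings (`ND2`,
`COI`, `tRNA-Phe`, `D-loop`, ...) are resolved through a user-extensible
YAML synonym table; unresolvable features are retained as warnings rather
than dropped, because silently losing annotation is the worst failure
mode for a characterization tool.

## Composition and skew

Strand asymmetry is summarized by AT-skew = (A − T)/(A + T) and GC-skew =
(G − C)/(G + C); both are undefined (reported `NA`) when the denominator
is zero. Percentages are computed over unambiguous bases only — IUPAC
ambiguity codes including N are tallied separately and excluded from both
the percentage denominator and the skew formulas. Published composition
tables rarely state this choice; here it is explicit and ours. Values are
kept at full precision internally and rounded only in reports (2 decimals
for percentages, 4 for skews, 1 for repeat copy numbers).

Codon-position composition works on the concatenated coding-sense CDS
set with each gene's terminal (stop) codon removed, since terminators are
not subject to the same selective constraints. N-strand genes are
reverse-complemented before concatenation because position statistics are
meaningless off the reading strand.

## Codon usage

CDS assembly honors strand and `codon_start`, verifies the absence of
in-frame internal stops, and completes 1–2 nt incomplete terminators (T
or TA) to TAA, modelling post-transcriptional polyadenylation; the
pre-padding terminator is reported verbatim in inventories. The genetic
code is vertebrate mitochondrial (table 2), in which AGA/AGG are
terminators, ATA codes Met and TGA codes Trp — hence Met and Trp are
two-codon families and no single-codon family exists. Relative synonymous
codon usage is

RSCU(c) = X_c · n / Σ_{c' in family} X_{c'}

with the family defined by the amino acid (Leu and Ser are six-codon
families). The L1/L2 and S1/S2 labels carried in output tables are
display sub-families — L1 = UUR-Leu, L2 = CUN-Leu, S1 = AGY-Ser,
S2 = UCN-Ser, the orientation conventional in the avian mitogenomics
literature (sources using these labels rarely define them; the assignment
here is stated rather than inferred). RSCU is computed over the
concatenated 13 PCGs of a record by default; per-gene tables are a matter
of calling `rscu()` on a single CDS. Within any used family the values
sum to the family size, a property the test suite checks against an
independent naive codon-counting oracle.

## Gene order and the TDRL search

Arrangements are circular and compared up to rotation (rotation is pure
relabeling); the canonical anchor is trnF, which is adjacent to rrnS in
both the ancestral avian order and the rearranged one, giving stable
report ordering. Breakpoints are directed adjacencies in J-strand reading
order present in one arrangement and absent in the other, with CR1/CR2
normalized to a single CR identity so orders differing in control-region
multiplicity remain comparable.

The tandem duplication–random loss (TDRL) search enumerates every
contiguous block up to `max_block` genes (default 8, keeping the survivor
enumeration exhaustive in well under a minute) and every survivor
pattern; genes named in `retain_both` may keep both copies, which is how
an ancestral single CR explains an observed CR1 + remnant CR2 pair.
Two modelling decisions: TDRL preserves orientation (inversions are a
different mechanism and out of scope), and survivor patterns of the form
first^j second^(k−j) are excluded as no-ops since deleting a clean prefix
of one copy and suffix of the other reproduces the input — without this
rule every identical pair of orders would be "explained" by arbitrarily
many vacuous events. Candidate pruning is exact, not heuristic: the set
of genes that must retain both copies is forced by per-gene count
differences, and strand multisets must agree; anything else cannot be a
single TDRL. Every returned solution is replayable mechanically with
`apply_tdrl()`, and the tests replay all of them.

The search models presence/absence only; whether a remnant CR retains
sequence homology with its progenitor is not represented.

## Control region annotation

`CR1` is partitioned into ETAS domain I, central conserved domain II and
CSB domain III from explicit boundary specifications. The shipped default
corresponds to the *P. fuscatus*-style 1104-nt CR1 (1–424 / 425–859 /
860–1104); boundaries for other species must be supplied by the user —
proportional rescaling is deliberately not done, because domain
boundaries are defined by sequence elements, not length fractions.

Conserved boxes are matched by Hamming distance over fixed-length windows
(no indels): the boxes are short, conservation claims in the literature
are similarity-based, and indel handling would add alignment machinery
without improving the call. Each motif reports its minimum-distance
window within the mismatch budget (default 3), leftmost on ties; motifs
with no window within budget are absent from the result, which is how
elements like CSB2/CSB3/OH/LSP/HSP — included in the library as
approximate consensus patterns precisely so their absence is reportable —
show up as "not identified". C-strings (poly-C runs with up to a set
number of single-base interruptions, each flanked by C) are found by
run-length analysis, reporting maximal non-overlapping windows.

### The tandem repeat detector

The detector is a deliberate simplification of wraparound-dynamic-
programming repeat finders: substitutions only, no indels within units.
Candidate periods come from recurrence distances of exact 8-mers. For a
candidate period p, the match diagonal (`seq[i]` vs `seq[i + p]`) is
extended from the seed under a +1 match / −5 mismatch score, each
direction stopping 12 below its running maximum and trimming back to the
maximum; boundaries are then refined by searching up to 12 bases of trim
at each end and keeping the region with the best signed consensus score.
The consensus is the columnwise majority over stacked units with ties
resolved to the first unit's base; copy number is region length divided
by period (stored unrounded, reported to 1 decimal); percent identity is
the fraction of region positions matching the consensus. Overlapping
detections are resolved best-score-first. The mismatch penalty trades
tolerance for boundary stability: repeats need roughly ≥ 85% local
identity to extend through degraded stretches, and in exchange the
reported extent does not wander into flanking sequence. A flanking base
that genuinely continues the periodicity is still absorbed — on a 46-bp
unit that perturbs the copy number by ~0.02, invisible at the reported
precision.

## tRNA stems

Cloverleaf structures are inputs (YAML specifications of arm intervals),
not predictions — structure prediction belongs to dedicated folding
tools. Stem pairs are classified purely by the unordered base pair:
{A,T} and {G,C} Watson–Crick, {G,T} wobble (G–U in the RNA), anything
else a mismatch; sequences are handled as DNA throughout. Cross-species
stem conservation is the percentage of stem columns identical across all
species — the strict criterion, chosen because majority-based relaxations
have no agreed definition; arms absent from a spec (the DHU arm of
trnS(AGY)) are reported `NA`, never fabricated.

## Distances and neighbor joining

p-distance is the proportion of differing sites among comparable sites.
Gaps, N and ambiguity codes are treated as missing, never partially
matched. Complete deletion (drop a column for everyone if anyone is
missing) is the default, matching the default of the widely used
distance software; pairwise deletion is available by flag. The triangle
inequality is not asserted anywhere — p-distance can violate it.

Neighbor joining follows the standard Q-criterion agglomeration with two
determinism rules: Q-ties are broken by the lexicographically smallest
pair of subtree labels, and a negative branch estimate is clamped to zero
with the deficit moved to its sister edge so the pair's summed length is
preserved. Unrooted trees are written with a trifurcating root and branch
lengths to 6 decimals. On additive matrices NJ provably recovers the
generating topology; the tests verify this on random 5–8 taxon trees and
cross-check topology against an independent NJ implementation.

## The synthetic-data generator

`generate_mitogenome()` lays out genes in template order with realistic
lengths (PCG lengths typical of passerines, tRNAs 66–75 bp, rRNAs ~974–988
and ~1598–1602 bp, a 1104-nt CR1, a ~220-nt remnant CR2), in-frame CDSs
with ATG starts, configured terminators including the incomplete TA/T
stops, conserved boxes and a C-string planted at recorded CR1 positions
(optionally with edits), a tandem repeat planted in CR2, and an
intergenic spacer absorbing residual length before the origin. Every
planted quantity is returned in a truth record, and generation is fully
deterministic given the configuration.

Defaults are the study conditions the package targets: the rearranged
duplicated-CR gene order, a 16,950-bp genome, base frequencies
A 0.30 / C 0.32 / G 0.15 / T 0.23 (the published six-genome averages,
rounded), and the 46-bp two-copy repeat unit. Two non-obvious choices:

- PCG codons are sampled from per-base weights rebalanced by iterative
  proportional fitting after removing the (A-rich) stop codons, and
  N-strand genes are sampled in complement space, so whole-genome
  composition tracks the target frequencies; the residual distortion from
  fixed starts/stops and planted motifs keeps recovered percentages
  within about one percentage point, which is what the plant/recover
  suite asserts (a ±0.8 binomial check applies to the raw random-sequence
  generator at n = 17,000).
- The bases flanking the planted repeat are guarded against accidentally
  continuing its periodicity, so the planted copy number is the true
  maximal periodic extent and recovery can be asserted exactly.

What the generator does not emulate — and therefore what passing tests do
not show about real data: gene overlaps (common in real mitogenomes,
e.g. atp8/atp6), rate heterogeneity and indels in the alignment
simulator, sequence decay of the remnant CR, tRNA sequences that actually
fold into their specs, and base-composition heterogeneity along the
genome. The alignment simulator applies a per-branch per-site
substitution probability q (to one of the three other bases uniformly);
the expected p-distance across k branches is (3/4)(1 − (1 − 4q/3)^k),
which the tests check against simulation.

## Problem sizes and numerical conventions

The test suite runs at desk scale by design: the TDRL enumeration is
exhaustive at block length ≤ 8; repeat recovery is checked for periods
10–46 and copy numbers 2.0–3.0 across 20 seeds; the NJ-on-simulated-data
study uses 40 replicates of 2,000 sites on a 6-taxon balanced tree at
q = 0.05 and the additive-recovery property uses 50 random 5–8 taxon
trees; the full plant/recover suite generates 20 complete synthetic
mitogenomes. Degenerate inputs error early with specific messages (empty
sequences, frame violations naming the gene, coordinate errors, missing
gene complements listing the absences, undefined distances naming the
pair). All randomness flows through explicit seeds; identical
configurations produce byte-identical GenBank output and reports.

## Known limitations

GenBank parsing targets the feature subset relevant to mitogenomes (CDS,
tRNA, rRNA, D-loop/misc_feature; simple, `complement()` and origin-
wrapping `join()` locations), not the full flat-file grammar. Domain
boundaries and cloverleaf specs for species other than the shipped
examples must be supplied by the user. The repeat detector's scoring is
not that of the classical wraparound tool (match/mismatch only, no
indels), so degraded repeats below ~85% identity may be truncated or
missed. Multi-event rearrangement scenarios, inversion mechanisms, and
model-corrected distances are out of scope.
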