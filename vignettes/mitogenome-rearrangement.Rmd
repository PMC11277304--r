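---
title: "Characterizing mitogenome rearrangements: composition, tandem repeats, remnants, TDRL and character mapping"
author: "mitorearr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing mitogenome rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

## The scientific problem

Insect mitochondrial genomes are circular molecules of roughly 16 kb
carrying a nearly frozen inventory: 13 protein-coding genes (PCGs), 22
tRNAs, 2 rRNAs and one A+T-rich control region, distributed over a
majority (J) and a minority (N) coding strand. Because the ancestral
gene arrangement is shared across most insects, a deviation from it is
a rare, near-irreversible event that can serve as a phylogenetic
character. A classic deviation is a *transposition* of neighboring
tRNAs — in some fireflies, the exchange of *trnW* and *trnC* next to
ND2 — which is most economically explained by **tandem
duplication–random loss (TDRL)**: a contiguous block is duplicated in
tandem one or more times, and one copy of each redundant gene is
subsequently silenced and lost. The molecular fingerprint of such an
event is an intergenic spacer at the rearranged junction containing
**tandem repeat units (TRUs)**, each composed of a degenerate fragment
of the displaced gene (a pseudogene *remnant*) plus a linker.

`mitorearr` implements the full chain of analyses used to characterize
such a genome: base composition and strand skews, nonsynonymous
divergence (Ka), circular gene-order comparison, tandem-repeat
decomposition of spacers, remnant detection by local alignment,
exhaustive TDRL scenario reconstruction ranked by remnant evidence,
and Fitch parsimony mapping of the rearrangement on a phylogeny. A
synthetic-genome generator with a complete truth log makes every stage
testable without any external data.

## Composition and strand skews

Strand asymmetry is summarized by

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

computed over unambiguous bases only (`base_composition()`). A zero
denominator is reported as skew 0 with an `undefined_skew` flag.
Frequencies are fractions of A/C/G/T; IUPAC ambiguity codes are counted
separately and treated as mismatches in all downstream alignments.
Reports round skews to two decimals, the conventional presentation.

## Nonsynonymous divergence (NG86)

`ng86_ka()` implements Nei–Gojobori (1986) counting under the
invertebrate mitochondrial code (translation table 5), the default
behavior of the standard desktop tools, with the Jukes–Cantor
correction $K_a = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_N)$. Choices
that the method leaves open were fixed as follows:

* **Site fractions.** At each codon position the fraction of
  synonymous changes is computed among the changes that do not create
  a stop codon; each position contributes one site, so synonymous +
  nonsynonymous sites always sum to 3 per codon. A position whose
  every change creates a stop counts as nonsynonymous.
* **Pathways.** Codons differing at 2–3 positions average their
  difference counts over all orderings of the changes, excluding
  pathways that pass through a stop codon; if no pathway is valid the
  codon pair is skipped and counted.
* **Skipping.** Codons containing gaps or ambiguity codes, and stop
  codons, are skipped.
* **Saturation.** $p_N \ge 3/4$ has no finite correction and is
  reported as a saturation flag with `Ka = NA`.

`ka_against_reference()` extracts the 13 PCGs from two annotated
records, strips terminal stop codons, aligns each gene as codons by a
global alignment of the translations (match +1, mismatch −1, gap −2,
back-threaded to nucleotides), and reports per-gene and concatenated
estimates. Site counts are averaged between the two sequences, which
makes the statistic symmetric in its arguments.

## Gene orders and rearrangement classification

A `gene_order` is a circular list of (gene, strand) tokens; equality
is rotation-invariant. `ancestral_insect_order()` hard-codes the
plesiomorphic 37-gene + control-region arrangement (ND2 neighborhood:
ND2, trnW, trnC(−), trnY(−)). `compare_orders()` counts circular
breakpoints and searches all single-event explanations — adjacent
swap, block transposition, block inversion — by exhaustive
application to the reference; anything else is `complex`. Strands are
carried per gene but not permuted: the trnW/trnC transposition leaves
each gene on its own strand, so it classifies as an unsigned adjacent
swap, which is the convention used here for "same-strand
transposition". The leucine and serine tRNA paralogs are
distinguished by anticodon family (trnL1 = CUN, trnL2 = UUR,
trnS1 = AGN, trnS2 = UCN).

## Tandem-repeat decomposition

`decompose_tandem()` is a self-contained tandem-repeat search in the
spirit of Tandem Repeats Finder, restricted to gapless copies (the
TRUs of interest are length-identical). For each candidate period
$p$ the lag profile $s_i = [x_i = x_{i+p}]$ is scored (+1 match, −3
mismatch) and its maximal-scoring interval found (Kadane). An interval
of length $\ell$ supports a repeat region of $\ell + p$ bp. Because a
single point mutation breaks the lag profile *twice* and an edge
mutation can therefore clip a whole copy, the candidate is refined
against the majority-rule consensus, which a mutation breaks only
once: the copy grid is re-anchored leftward over edge mutations (up to
6 bp), clipped full copies of ≥ 80% consensus identity are re-admitted
at both ends, and the trailing partial unit is the best
mismatch-tolerant consensus prefix. Defaults: periods 10–300 bp, at
least 2 copies, interval score ≥ 10, interval identity ≥ 0.8.
Overlapping candidates are deduplicated best-score-first; ties break
to the smaller period, then the leftmost start — so a 2-copy
decomposition at period $2p$ never shadows the $p$-periodic truth.
Exact reproduction of Tandem Repeats Finder scores is a non-goal.

The trailing partial unit is reported after the full copies; whether a
partial unit precedes or follows the full units is not observable from
a decomposition alone, and the leading convention was not adopted.

## Remnant detection

`scan_remnants()` aligns every library gene (typically the record's
own intact tRNAs) and its reverse complement against a spacer with
Smith–Waterman (Gotoh affine gaps: match +1, mismatch −1, gap open −2
plus −2 per base — the EMBOSS/Biostrings convention), implemented in
C++. Two practical points matter on ~85% AT sequence:

* **Linear gaps fail.** With a flat −2 per gap base, isolated
  single-base gaps are so cheap that the maximal alignment routinely
  drifts off the true remnant diagonal chasing chance matches in the
  linker; affine costs suppress exactly this.
* **End trimming.** Even gapless maximal alignments absorb chance
  extensions on low-complexity sequence. Each maximal alignment is
  therefore trimmed to its maximal-scoring core under a conservative
  rescoring (mismatch −3, gap −4) before thresholds are applied. The
  trim keeps a full-length remnant with one interior mismatch intact.

After each accepted hit the raw alignment span is masked and the scan
repeated, so all tandem remnant copies are found; overlaps across
library genes resolve greedily by score. Defaults: hit length ≥ 15 bp,
identity ≥ 0.8, score ≥ 15 — comfortably below a 29 bp remnant at
97–100% identity, and strict enough that random 300 bp spacers yield
no hits in ≥ 99% of seeds. The hit strand records which orientation
of the source gene matched, evidence for the copy direction of the
duplication.

`annotate_trus()` joins the two analyses: each hit is assigned to the
repeat copy containing it (boundary-spanning hits are flagged), each
copy is partitioned into remnant and linker segments, and pairwise
linker identity across copies is reported.

## TDRL scenario reconstruction

A TDRL scenario is (block, copy count $k$, loss pattern): the block is
expanded into $k$ tandem copies and every gene is retained in exactly
one copy. `enumerate_scenarios()` exhausts all blocks, copy counts
and loss patterns over a small window and keeps the scenarios whose
surviving order equals the derived window. Cost model: one duplication
event regardless of copy count (a multi-copy expansion is a single
event), losses are free, and `copy_count` is the secondary parsimony
criterion. The windows passed in contain only the rearranged span —
flanking genes are fixed and cannot be part of the duplicated block;
allowing them would admit less parsimonious multi-gene blocks whose
extra remnants (e.g. of a 1 kb PCG) are never observed.

Predicted remnants are the lost gene copies lying strictly between
the first and last retained copy in the expanded array.
`rank_by_remnants()` puts scenarios whose predicted remnants match the
observed ones (same genes, counts and order, ignoring genes never
observed as remnants — lost copies of the other gene are expected to
degrade into the linker) first, then sorts by copy count. Reproducing
$n$ observed remnants of the downstream gene therefore forces
$k \ge n + 2$: six trnW remnants select the 8-copy expansion, whose
loss pattern (lose the upstream trnW, both genes of the six middle
copies, and the downstream trnC) reproduces the derived trnC–trnW
order with six trnW remnants in between. A fragment found inside the
trailing partial unit restates the partial repeat and is not counted
as an extra lost copy. Strand is carried through unchanged; TDRL
cannot invert, so inversion evidence rejects the model upstream.

## Character mapping

`fitch_map()` runs the two-pass Fitch algorithm on a rooted
bifurcating tree with leaf states 0/1/`?` (`?` = full state set;
taxa without mitogenomes stay unscored). Ambiguities resolve to state
0 at the root and children inherit the parental state whenever
optimal, which delays gains. The character is a synapomorphy of a
clade when the score is 1, the single change is a gain, and the gain
edge subtends exactly the state-1 leaves (unscored `?` leaves may fall
inside — the claim is then "at least this clade"). Unrooted input
trees must be rooted on a declared outgroup (`root_on_outgroup()`);
synapomorphy is a rooted concept. Trees come and go as newick via
`ape`.

## The synthetic generator and what it does (not) emulate

`generate_mitogenome()` lays out the 37 genes + control region in the
ancestral arrangement with base probabilities (A .471, T .334, G .074,
C .121) describing the J strand — N-strand genes are drawn from
complemented probabilities, which is what preserves the genome-wide
skews (+0.17 / −0.24 scale). PCGs are clean reading frames under the
mitochondrial code (ATG…TAA, no internal stops); tRNAs draw 60–75 bp,
rRNAs and PCGs use canonical invertebrate lengths; the control region
absorbs the slack to hit the length target exactly. The default
junction plan plants 12 overlaps of 1–8 bp (always eating into a
downstream tRNA, whose sequence is unconstrained) and 4 small spacers.
Forced starts/stops and stop avoidance shift realized frequencies up
to ~1.5% from the i.i.d. targets; tests allow ±2%.

`plant_rearrangement()` swaps two adjacent genes and inserts the TRU
spacer: each unit is the first `remnant_len` bases of the displaced
gene plus one identical random linker, times `n_tru`, plus a partial
unit (a unit prefix). Defaults 6 × (29 + 82) + 44 = 710 bp. The
generator *guarantees the planted truth is well-defined*: the linker
is redrawn until scanning the assembled unit against the record's
tRNAs recovers exactly the planted remnant (no chance extension into
the linker, no incidental second hit), and the optional planted A→G
remnant mutation is placed interior to the remnant. Without this,
roughly one seed in ten produces a fixture whose truth log is simply
wrong on low-complexity AT sequence. `generate_diverged_pair()`
mutates internal codons nonsynonymously (never creating stops, never
touching synonymous sites) at a per-codon rate, with exact counts in
the truth log.

The default study conditions (`study_genome()`) encode the observed
firefly architecture: a 15,836 bp ancestral genome whose planted
trnW/trnC transposition yields a 16,546 bp derived genome with 14
minority-strand genes, 12 overlaps, five spacers, and the
6 × 111 + 44 bp spacer with one mutated remnant in unit 5. Note the
unit arithmetic totals 710 bp although the observed spacer of the real
genome is printed as 702 bp — the published numbers are internally
inconsistent by 8 bp, and the generator follows the unit structure.
Divergence for the Ka analyses is calibrated by inverting the
Jukes–Cantor correction at the published concatenated value (0.20957)
and converting the target $p_N$ into a per-codon rate using the
genome's own nonsynonymous site density.

What the generator does **not** emulate: real tRNA/rRNA secondary
structure, codon usage and amino-acid composition, within-genome
compositional heterogeneity, indel evolution inside repeat units, and
phylogenetically structured divergence. Passing tests therefore
demonstrate correctness of the algorithms on genomes with the stated
architecture, not robustness to every idiosyncrasy of real sequencing
and annotation.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive externally (GenBank convention),
  converted at the parser/serializer boundary only; the remnant BED
  export is 0-based half-open.
* Junction accounting uses consecutive features by start along the
  circle; fully nested features are excluded with a warning; the
  control region participates as a feature, so its flanks are
  junctions rather than one giant spacer.
* Empty sequences, zero-feature tables, saturated divergence,
  single-feature junction reports and not-adjacent spacer requests
  all have defined, tested behavior (error or empty result with a
  message naming the cause).
* All randomness flows through explicit integer seeds; reports are
  byte-identical across reruns on identical inputs.

## Problem sizes

The regression suite runs the full pipeline on complete ~16.5 kb
synthetic genomes; property batteries use 100 seeds for the repeat
null, 50 for the remnant-scan null, 30 single-event classification
trials, all 30 permutations of 3–4 gene windows for TDRL oracle
equivalence, 25 alignment oracle instances up to 200 bp, and 25 Fitch
oracle trees up to 8 leaves. These sizes give stable pass/fail
behavior for the stochastic properties while keeping a full run around
a minute.

## Known limitations

* The tandem decomposer assumes gapless copies; indel-bearing repeat
  units will fracture into shorter decompositions.
* Rearrangement classification covers single events only; multi-event
  histories report `complex` (genome-wide rearrangement distances are
  out of scope).
* TDRL enumeration is exponential in window size and copy count and
  is intended for local windows (≤ 6 genes, ≤ 12 copies).
* Fitch mapping expects bifurcating trees.
* `ng86_ka` reports Ka only; Ks and rate-ratio tests are out of
  scope.
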