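---
title: "Inferring genetic codes and reconstructing gene content in reduced endosymbiont genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring genetic codes and reconstructing gene content in reduced endosymbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiocode)
```

## The problem

Bacteria that live as obligate endosymbionts or parasites of eukaryotic
cells often undergo extreme genome reduction, and strongly reduced,
AT-rich genomes sometimes abandon the standard genetic code: the clearest
recurring change is the reassignment of the stop codon UGA to tryptophan
("UGA=W"), known from *Mycoplasma* and several arthropod endosymbionts.
Annotating such a genome with the wrong translation table truncates open
reading frames at every read-through UGA, so deciding the code is the first
analysis that must be done — and for a novel lineage it must be decided
from the sequence alone.

`symbiocode` implements a conservation-anchored inference of the genetic
code together with the companion analyses used to characterise a reduced
genome: reconstruction of a minimal ancestral proteome from orthogroup
presence/absence, loss accounting, and descriptive statistics (GC content,
GC skew, codon usage, tRNA anticodon-stem length).

## The inference model

The central idea is that a codon's meaning can be read off positions whose
amino acid is essentially frozen across bacteria.

1. **HCAA positions.** Take multiple alignments of widely conserved,
   single-copy marker proteins across a broad reference panel.  A column is
   a *highly conserved amino acid* (HCAA) position when at least 90% of all
   sequences carry the same residue.  The denominator includes gap-bearing
   sequences: this is the conservative reading (a column with many gaps
   must be overwhelmingly uniform in the remaining rows to qualify), and
   ambiguity letters (`X`) never count towards the consensus.  The
   threshold test is inclusive — 9 of 10 qualifies at 0.90.

2. **Translated search.** Each marker family's consensus is aligned
   against all six translation frames of the target genome
   (Smith–Waterman, BLOSUM62, affine gaps open 11 / extend 1).  In-frame
   stops are rendered `*` and score a flat −4 against any residue instead
   of terminating the alignment.  This is the load-bearing numerical
   choice: an ORF interrupted by a reassigned UGA must still align end to
   end, otherwise the very observations that reveal the reassignment are
   lost.  Overlapping hits of one query are reduced to the best-scoring
   hit per locus (ties to the leftmost), reflecting the single-copy nature
   of the markers.

3. **The 64 × 20 matrix.** For every HCAA column that lands inside a hit
   and aligns to a subject residue, one observation pairs the genome codon
   under that residue (reverse-complemented to coding orientation on the
   minus strand) with the column's conserved amino acid.  Observations are
   deduplicated per (family, column, genome codon) so overlapping hits
   cannot double-count.  Accumulated over all families this gives a
   64-codon × 20-amino-acid count matrix.

4. **Calling the code.** Each codon is called independently from its row:
   normalise to a probability vector, and assign the modal amino acid if
   the codon has at least `min_count = 10` observations and the modal
   probability is at least `dominance = 0.8`; otherwise the codon is
   unassigned.  Every assigned codon whose meaning differs from the
   standard bacterial code (translation table 11) is a reassignment; a
   stop codon assigned any amino acid is always a reassignment, and
   unassigned stop codons are presumed to retain termination.  The
   reassignment set selects an NCBI table: none → 11, exactly
   {UGA: stop → Trp} → 4, anything else → "custom" with a warning.

The original analyses of this kind judged the per-codon evidence by eye
from probability-unit sequence logos over ~10,000 sites.  The
`min_count`/`dominance` rule formalises that judgement so it is explicit,
reproducible and overridable; the defaults were fixed once, before any
benchmarking, as the weakest evidence we would accept from a logo (a
clear majority letter backed by a two-digit site count).

## Why the thresholds look the way they do

* `min_count = 10`: with fewer than ten observations a single misaligned
  site can dominate a row; ten is roughly where a 0.8 majority becomes
  distinguishable from noise.
* `dominance = 0.8`: sites that diverged in the target genome contaminate
  rows with the *consensus* amino acid of their column, so even a cleanly
  reassigned codon rarely shows probability 1.0.  Requiring 0.8 tolerates
  that contamination while still rejecting codons with genuinely mixed
  evidence.
* Stop penalty −4: the value BLOSUM62 itself assigns to `*`; large enough
  that spurious read-through alignments are not created, small enough that
  one reassigned stop inside a 300-residue alignment costs little.
* Search score threshold 60 (raw BLOSUM62 units): comfortably above the
  maximum local score seen for shuffled queries against length- and
  GC-matched random sequence, comfortably below the score of any genuine
  marker-gene hit at the divergences considered here (the test suite
  calibrates an empirical null alongside it).

## The ancestral proteome and loss accounting

Gene content is analysed from a binary orthogroup × taxon matrix with
taxa tagged by phylogenetic role on a fixed five-group cladogram:

```
((target1, target2), (sisterA, sisterB, sisterC), (basal1, basal2))
```

The *minimal ancestral proteome* is defined operationally, not by
parsimony or likelihood reconstruction: an orthogroup is ancestral iff it
is present in **at least one basal taxon** and **at least one sister
taxon**.  Presence in the targets plays no role in the definition, which
makes the estimate a lower bound that cannot be inflated by
target-specific gains.  For each target, retained orthogroups are the
ancestral ones it still carries; losses split into *shared* (absent from
every target — parsimoniously placed on the common-ancestor branch) and
*lineage-specific* (absent from one target, present in another).

Retention percentages are **truncated** — not rounded — to one decimal.
With an ancestral set of 2,151 and retained counts of 477 and 402, the
exact values are 22.175% and 18.688%; truncation yields 22.1% and 18.6%,
and it is the only one-decimal convention consistent with both.  The test
suite asserts this arithmetic.

## What the synthetic-data generator emulates

All pipeline inputs can be generated with known ground truth:

* **Marker families** — gap-free alignments with a configurable fraction
  of conserved columns.  Defaults: 10 families × 320 residues × 50 taxa,
  30% of columns conserved at 95% identity.  The family length and
  conserved density mirror a realistic marker set (~100 conserved columns
  per ~320-residue family); a planted column is guaranteed to reach the
  conservation level (the number of deviant taxa is capped), so the truth
  table is exactly recoverable by a 90% column scan.
* **Target genome** — each family consensus is diverged at 10% per
  residue (substitutions uniform over the other 19 amino acids) and
  reverse-translated with synonymous-codon weights ∝ exp(β·GC(codon)),
  β solved numerically so the expected coding GC hits `gc_target`
  (default 0.35, reduced-genome-like); genes are placed on random strands
  with ~100 nt intergenic spacers whose composition matches the target.
  Amino-acid composition bounds the achievable coding GC, so targets
  within 0.03 of that range are clamped to the boundary (the spacers make
  up the difference) and anything further is a parameter error.  Under the
  `uga_trp` code each tryptophan is encoded by TGA with probability 0.7,
  else TGG, so a genome carries both codons as real UGA=W genomes do.
* **Orthogroup matrices** — every orthogroup present at the root of the
  fixed cladogram is lost independently per branch.  Default rates (basal
  tips 0.10, sister stem 0.05, sister tips 0.10, target stem 0.65, target
  tips 0.35/0.45) produce an ancestral set of ~2,000, target retention
  around 20%, and a majority of shared losses — the pattern of a severely
  reduced endosymbiont pair.
* **tRNA arms** — a canonical 7-nt anticodon loop flanked by exactly 4 or
  5 Watson–Crick pairs, with a guaranteed mismatch immediately outside the
  stem.  This exercises the stem-length measurement that distinguishes a
  readthrough-competent 4-bp anticodon stem of tRNA-Trp(CCA) from the
  canonical 5-bp stem.

What the generator deliberately does **not** model: phylogenetic
structure among the reference taxa (no substitution model or branch
lengths — reference sequences are i.i.d. around the column consensus),
insertions/deletions (alignments are gap-free, so gap handling is
exercised by hand-built fixtures instead), multi-copy genes, plasmids,
and correlated loss of functionally linked orthogroups.  Passing tests
therefore show that the machinery is correct under idealised divergence,
not that the thresholds are optimal for any particular real dataset.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere, matching R/Bioconductor
  and GFF3 conventions; minus-strand codons are reported by their
  forward-strand start and reverse-complemented to coding orientation.
* Codons containing `N` translate to `X` in the search frames and are
  discarded (with a count) when accumulating the matrix.
* A conservation tie (possible only at thresholds ≤ 0.5) rejects the
  column: ambiguity yields no consensus.
* Zero-observation codon rows have all-zero probability vectors; rows
  with observations sum to 1 within 1e−9, and scaling all counts by a
  positive integer changes nothing downstream.
* An empty ancestral set reports retention count 0 with an undefined
  (`NA`) percentage.
* G·U wobble counts as pairing in anticodon stems (it is canonical in
  tRNA helices); `allow_gu = FALSE` disables it.  The stem walk stops at
  the first non-pairing position and is capped at 7.
* GC skew windows wrap past the origin by default (circular chromosome);
  windows with G+C = 0 are `NA`, and the profile negates under reverse
  complement.

## Problem sizes used in validation

The bundled validation runs the full simulate → infer cycle at the
default configuration (10 families × 320 residues × 50 taxa, ~960 HCAA
sites per run) across 20 seeds per genetic code, recovers planted genes
at 20% divergence across 100 single-gene genomes, and cross-checks the
conservation scan and the ancestral-set rules against brute-force oracles
on 100 random inputs each.  These sizes were chosen to match the scale of
evidence per codon in the emulated study (tens of observations for the
reassigned codon) while keeping a full validation cycle in minutes on a
single core.

## Known limitations

* The code caller treats codons independently; it will not pool synonymous
  codons or borrow strength across families, by design (the evidence
  object is the 64-row matrix).
* The translated search is exhaustive dynamic programming per frame.  At
  the sub-megabase scale of reduced genomes this is seconds of work; it is
  not intended for large genomes or metagenomes.
* Ancestral reconstruction is the two-criteria rule only.  It cannot see
  orthogroups lost in both the basal and sister groups, and it does not
  attempt Dollo or ML gain/loss inference.
* tRNA handling assumes the cloverleaf anticodon arm geometry; it is a
  measurement of a given arm, not a tRNA finder.
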