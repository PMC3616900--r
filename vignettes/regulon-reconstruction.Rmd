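---
title: "Comparative reconstruction of bacterial TF regulons: models and methods"
author: "regulonr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative reconstruction of bacterial TF regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonr)
```

## The problem

A bacterial transcription factor (TF) recognizes short DNA operators
(TF-binding sites, TFBSs) in the promoter regions of its target operons; the
set of operons it controls in one genome is its regulon, and the union of all
regulons is the genome's transcriptional regulatory network. Direct
experimental mapping exists for only a handful of model organisms.
Comparative genomics closes the gap: across a group of related genomes, true
regulatory sites recur upstream of *orthologous* operons, while spurious
motif matches do not. `regulonr` implements this programme as a pipeline:

1. operon and upstream-region conventions (`predict_operons`,
   `extract_upstream`, `build_workspace`);
2. ortholog clustering of proteomes by bidirectional best hits
   (`build_ortholog_groups`);
3. symmetry-constrained EM motif discovery and PWM scanning
   (`discover_motif`, `build_profile`, `scan_profile`);
4. regulon reconstruction workflows with a cross-genome consistency filter
   (`workflow1_expand`, `workflow2_project`, `workflow3_ab_initio`,
   `consistency_filter`);
5. comparative statistics of the resulting networks (`tf_census`,
   `align_pwms`, `compare_regulon_content`, `detect_displacements`,
   `summarize_network`);
6. a seeded synthetic-genome generator with planted ground truth
   (`synthetic_config`, `generate_genome_set`) used to benchmark every stage.

## Operons and upstream regions

Adjacent genes are joined into an operon when they share a replicon and
strand and the intergenic gap is at most `max_gap` (default 100 bp) — the
standard bacterial heuristic. Upstream regions are taken for operon lead
genes only, spanning −300..+25 relative to the translation start (−1 is the
base immediately 5′ of the start codon). The window covers the operator
space of bacterial promoters while limiting the sequence a false positive
can land in; both numbers are exposed as arguments. By default the region is
truncated at the 3′ edge of the nearest upstream gene so that neighbouring
coding sequence is never scanned. Divergently transcribed operon pairs each
receive their own region, so a shared intergenic stretch may legitimately
appear twice, once per orientation.

## Orthology

All protein pairs within and between genomes are aligned with affine-gap
local alignment (BLOSUM62, gap open 11 / extend 1) through
`Biostrings::pairwiseAlignment`. A hit is reported when identity ≥ 0.3,
the aligned region covers ≥ 50% of the shorter protein and the score is at
least 80; the score floor sits above the empirical null of local alignments
between unrelated random proteins (the test suite verifies that the null
stays below it), so unrelated sequences produce no hits. Two proteins from
different genomes form a bidirectional best hit (BBH) when each is the
other's best-scoring hit, identity is strictly above 50% and the aligned
region is strictly longer than 2/3 of the shorter protein. Within-genome
paralogs that are more similar to a BBH member than the BBH partners are to
each other (compared on score; ties on identity, then gene id) join the
cluster; this paralog rule is applied once, before transitive merging.
Clusters sharing genes are then unioned to a fixpoint (igraph connected
components; the test suite verifies the result against a brute-force
repeated-overlap-scan oracle). Conservation classes within a lineage of
*n* genomes follow the presence count *k*: universal (*k = n*), conserved
(*k > n/2*), sporadic (2 ≤ *k* ≤ ⌊*n*/2⌋), unique (*k* = 1).

## Motif model and scoring

A motif is a position weight matrix (PWM): per-column base counts, a
per-cell pseudocount of 0.5 (small training sets — often under 10 sites —
need regularization), a background distribution, and a symmetry class.
Scores are log-odds in bits: the score of a word is
$\sum_j \log_2 f_j(b_j) / \pi(b_j)$, where $f_j$ is the column frequency
and $\pi$ the background. Most bacterial repressor operators are
palindromic (bound by homodimers); `symmetry_project` enforces this by
averaging the frequency matrix with its reverse complement, which is also
the exact maximum-likelihood estimate under the palindromic constraint.
Direct and inverted repeats are modelled as two tied half-sites with an
optional fixed spacer held at background frequencies.

**Detection threshold.** A scanning profile couples a PWM with the *lowest
score observed in its training set*. This makes every training site
recoverable by construction and is deliberately conservative with small
training sets: the smaller the training set, the higher the expected
minimum, so recall on other genomes degrades gracefully rather than
precision.

**Scanning background.** The threshold and the scan must use the same
background, otherwise the training-set-minimum guarantee breaks: a site
scored at calibration time under one background can fall below threshold
under another. The profile therefore carries a single background (uniform,
or the pooled composition of the training regions) used for both
calibration and scanning; scanning under a different background remains
available as an explicit `background` argument for exploratory use.

## EM motif discovery

`discover_motif` fits a zero-or-one-occurrence-per-region (ZOOPS) model:
each region carries one site with prior probability 0.8, uniformly
positioned over offsets and strands, otherwise it is pure order-0
background estimated from the pooled input regions. The E step computes the
posterior over site positions from the current log-odds; the M step
re-estimates column counts from the posterior, projects them onto the
symmetry class, and adds the pseudocount. The reported objective is the
marginal log-likelihood plus the Dirichlet smoothing term, for which this
projected, smoothed M step is the exact constrained maximiser — so the
objective is non-decreasing at every iteration by construction, and the
implementation asserts this (tolerance $10^{-8}$ relative). Convergence is
declared at a relative objective change below $10^{-6}$ or 500 iterations.

Restarts (default 20) are seeded from randomly drawn w-mers of the input
regions; how the original interactive tools seeded their EM is not
documented, and random-site seeding with multiple restarts is the standard
robust alternative. Across widths (default 14–24 by 2, typical for
palindromic repressor operators) and restarts the solution with the highest
information content per site is kept, ties resolved toward the smallest
width and lowest restart index. All randomness flows from one `seed`
argument; identical inputs and seed give identical output.

## Reconstruction workflows

* **Workflow 1a** (known sites): build a profile from the known site words,
  scan the upstream regions of every genome carrying the TF ortholog,
  consistency-filter the candidates, add the accepted novel site words to
  the training set, rebuild the PWM **once** and rescan. A single update
  avoids motif drift from repeated self-training.
* **Workflow 1b** (known genes only): pool the upstream regions of the
  known genes and their orthologs, run `discover_motif`, then proceed as 1a.
* **Workflow 2** (external model organism): map the external regulon's
  genes into the genome set through an ortholog map; at least 3 genes must
  map (motif discovery on fewer regions is unreliable); then as 1b.
* **Workflow 3** (ab initio): candidate co-regulated genes are those whose
  ortholog groups recur within 5 genes of the TF in at least 3 genomes;
  their pooled upstream regions seed motif discovery.

**Consistency filter.** A candidate interaction (genome, operon) is
accepted when the operon's lead-gene ortholog group collects above-threshold
sites in at least `min_support` genomes (default 3; the filter is
anti-monotone in this parameter), or when the lead gene carries an external
functional-relatedness whitelist label. The filter tests orthologous
*targets*, not position-conserved orthologous *sites*; a strict positional
mode is a possible extension, but target-level consistency is the weaker
and safer reading and matches how candidate regulons are curated in
practice. Lineage-specific motif variation is handled by building one
profile per TF group per lineage rather than one global profile.

Network-level operations follow directly: autoregulation (an accepted site
upstream of the TF's own operon), cascades (a site of TF A upstream of the
operon encoding TF B), and co-regulation (operons carrying accepted sites
of two or more profiles, tagged double/triple/quadruple).

## Comparative analyses

Cross-lineage motif comparison aligns two PWMs over all offsets within ±3
columns and both orientations, maximizing the summed per-column correlation
of frequency vectors; fewer than 8 overlapping columns means "not
alignable". Conserved positions are columns with at least 1.0 bit in both
motifs (half the maximum attainable per-column information), and mismatches
are conserved column pairs with differing consensus bases. Conservation
categories: I (≤ 1 mismatch), II (2–4), III (≥ 5 or not alignable); the
II boundaries are fixed by the field's usage, and the I/II boundary at one
mismatch operationalizes "well conserved or slightly variable". Regulon
content comparison maps targets to ortholog groups: Jaccard ≥ 0.75 is
strictly conserved, an empty intersection is different, anything else is a
core–periphery split; regulons averaging fewer than 3 target operons per
genome are *local*, the rest *global*. Non-orthologous displacement reports,
for each pair of TF groups assigned to one biological subsystem, the overlap
of their presence profiles and a complementarity fraction (share of
subsystem-carrying genomes covered by exactly one TF); complementarity is
reported, not thresholded, and a pair from the same protein family is
flagged as a xenologous replacement.

## The synthetic generator

`generate_genome_set` emulates the statistical structure the pipeline
assumes, with ground truth for every planted feature:

* **Ortholog families** derive from random ancestor proteins (150–400
  residues) independently mutated per genome; the per-site substitution
  rate solves $(1-q)^2 + q^2/19 = t$ for the target pairwise identity $t$
  (default 0.7), verified by the package's own aligner to ±0.03.
* **Genomes** share gene order (synteny), with each TF gene placed next to
  the first member operon of its regulon so that conserved-neighborhood
  inference has signal; one replicon per genome; order-0 background with
  per-genome GC drawn from 0.35–0.45, the typical range for lactic acid
  bacteria.
* **Planted PWMs** hit a prescribed total information content (default 16
  bits over 18 palindromic columns) with unequal minor-base frequencies
  (0.5/0.3/0.2 of the non-consensus mass) — equal minors would quantize all
  site scores onto a coarse lattice and make near-threshold decoys
  unconstructible.
* **Planted sites** are drawn from the PWM *conditional on a functionality
  floor* (default half the motif's information content): real operators are
  under selection to bind, whereas unconditioned PWM draws include words
  indistinguishable from background that no curator would accept as a
  training site. Sites land in the upstream gap at offsets −250..−40.
* **Decoys** are words whose true-profile score lies in
  [threshold − 2 bits, threshold), placed at the configured expected rate
  per upstream region; they are invisible to a perfectly calibrated scan
  and become false positives exactly when threshold re-estimation drifts —
  which is what the consistency filter must absorb.

What the generator does **not** emulate: tree-structured sequence
evolution (mutations are star-shaped from the ancestor), horizontal
transfer, genome rearrangement, multi-replicon genomes, order-1+ background
composition, and operator–promoter spacing constraints. Passing benchmarks
therefore show that the machinery is correct under the stated statistical
assumptions, not that real-genome reconstructions reach the same accuracy.

## The standard benchmark

`run_benchmark` generates 10 single-lineage genomes with 3 planted
palindromic regulons (6 member operons each, presence probability 0.8, one
near-threshold decoy expected per region), reconstructs each regulon with
workflow 1a, and evaluates against truth. The known training regulon pools
the planted sites of two model genomes, mirroring how experimental
knowledge is drawn from several characterized organisms rather than one;
with ~10 training sites the training-set-minimum threshold retains about
$n/(n+1) \approx 0.9$ of site mass, and the measured median interaction F1
across seeds is ≈ 0.88 with filtered precision never below unfiltered
precision. Ortholog groups come from the generator's truth families here,
so the benchmark isolates scanning/thresholding/filtering; orthology is
tested separately against an exact planted-family oracle (5 genomes × 30
proteins, within-family identity 0.7).

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (GFF3 convention); site
  offsets within a region are 0-based, and offsets relative to a
  translation start are negative upstream with −1 adjacent to the start.
* Word scores accumulate column-by-column in double precision on both
  scanner and calibration paths, so "score ≥ threshold" is bit-exact for
  training sites even at the minimum (extended-precision summation in one
  path but not the other can differ by 1 ulp, which is enough to lose a
  site sitting exactly at the threshold).
* Best-hit and EM-solution ties break deterministically (lexicographic ids;
  smallest width, lowest restart).
* Windows containing non-ACGT bases are skipped during scanning; regions
  shorter than the motif are excluded from discovery (an error only if all
  are); an empty training set, an unmappable external regulon, or an
  unconserved TF neighborhood are hard errors with explanatory messages;
  a truncation that empties an upstream region flags the region rather
  than failing.
* Problem sizes in the test and acceptance suites (10-genome benchmarks,
  20 × 200 bp discovery instances, 5 × 30-protein orthology instances,
  50-profile threshold sweeps) were chosen as the smallest sets at which
  the statistical contracts are sharp — binomial confidence intervals
  narrow enough to be informative — while a full run stays comfortable on
  a laptop.

## Known limitations

The paper-scale reconstruction of real genome collections additionally
requires literature-derived training sets, expert curation of functional
relatedness, and TF family annotation from domain databases; `regulonr`
accepts all three as inputs (known-regulon tables, whitelists, TF tables)
and does not attempt to infer them. Phylogenetic footprinting is supported
only as an exported alignment of orthologous upstream regions for manual
review, not as an automated decision step. The packaged reference tables of
collection statistics are shipped for the reporting module's worked
examples; recomputing them from scratch would require the original genome
collection and curation effort.
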