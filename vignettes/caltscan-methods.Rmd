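---
title: "Methods: comparative genomics of CcoA-like transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of CcoA-like transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

CcoA-like transporters (CalT) are Major Facilitator Superfamily (MFS)
proteins related to the bacterial copper importer CcoA, which supplies
Cu to the Cu~B~ center of *cbb*~3~-type cytochrome *c* oxidase.
Experimentally characterised members carry an MxxxM motif in
transmembrane helix 7 and an HxxxM motif in helix 8, and their genes sit
in conserved genomic neighborhoods — sometimes next to *cbb*~3~-oxidase
biogenesis genes, sometimes next to riboflavin-biosynthesis genes, a
pattern that led part of the family to be mis-annotated as riboflavin
transporters.

`caltscan` implements the comparative-genomics side of that story as a
reusable, testable pipeline:

1. **Sequence similarity network.** All-against-all Smith–Waterman
   scoring under BLOSUM62 with affine gaps (a gap of length $k$ costs
   $11 + k$), converted to an *alignment score*
   $-\log_{10} E$ with the Karlin–Altschul expectation
   $E = K \, m \, n \, e^{-\lambda S}$ ($\lambda = 0.267$, $K = 0.041$,
   the standard gapped-BLOSUM62 constants). Edges are kept at alignment
   score $\ge 75$; identical sequences collapse into representative
   nodes; connected components are the clusters, numbered by decreasing
   membership.
2. **Motif/topology screen.** Transmembrane segments are predicted with
   the classical Kyte–Doolittle sliding window (window 19, threshold
   1.6, minimum run 8, merge gap 3). A protein is called a candidate Cu
   transporter in *strict* mode when an MxxxM match lies inside
   predicted segment 7 and an HxxxM match inside segment 8; *relaxed*
   mode only requires both motifs inside some predicted segment, for
   proteins whose predicted segment count is not 12.
3. **Alignment, column filter, logos.** A center-star multiple
   alignment (center = sequence with the best summed global-alignment
   score; merges follow "once a gap, always a gap"), a column-quality
   filter, and observed-frequency sequence logos with the
   small-sample correction
   $R_c = \log_2 20 - H_c - \frac{19}{2 n \ln 2}$, letter heights
   $p_a R_c$.
4. **Distance phylogeny.** p-distances over mutually gap-free columns,
   Saitou–Nei neighbor joining with deterministic tie-breaks, bootstrap
   supports over column resampling, and placement of additional
   sequences into network clusters by mean p-distance (with the margin
   to the runner-up reported).
5. **Gene neighborhoods.** ±3-gene windows around each focal *calT*
   gene in contig gene order (strand ignored; the method counts genes,
   not base pairs), distinct-taxon counts per domain label at the
   genus, family and order ranks, ranking and thresholding at 30
   genera, removal of the large multi-functional transporter families
   (PF07690, PF00005) and configured transcription-factor labels,
   collapsing of the selected neighbors into neighborhoods via a
   co-occurrence graph, and per-focal-gene context flags (riboflavin
   pathway, Cu homeostasis, *ccoNOQP*) plus per-genome presence of the
   CcoN/CcoO/CcoP subunit labels.

Every stage is exercised end-to-end on synthetic pangenomes with
planted ground truth; the truth record is the oracle for the packaged
acceptance checks.

## The synthetic world

`generate_world()` emulates the statistical structure the analysis
assumes, deterministically from one seed. The default world is the
reference condition used throughout the tests:

* Taxonomy: 2 orders × 5 families × 10 genera × 1 species = 100
  genomes, one focal *calT*-like gene per genome.
* Proteins: 5 families × 20 members, per-site substitution probability
  0.2 from the family ancestor, length 423 (12 TM segments of 19
  residues in 15-residue hydrophilic linkers — MFS scale). Three of the
  five families are "Cu-type" and carry the TM scaffold with MxxxM
  planted mid-TM7 and HxxxM mid-TM8; motif anchor positions are
  protected from mutation, so planted positives never lose their
  motifs. Family ancestors are drawn independently (control families
  are uniform-random sequences), so network separation is governed
  solely by the within-family divergence.
* Neighborhoods: planted window-neighbor domains echo the real
  neighborhoods — a ribH-like lumazine synthase (PF00885, 36 genera)
  co-occurring with a BamE-like factor (PF04355, 34), a FabG-like
  reductase (PF13561, 30), an HMA Cu-chaperone domain (PF00403, 28),
  the large MFS_1 family (PF07690, 40, excluded downstream), two
  mid-frequency domains and a CcoN-like label for *ccoNOQP* context.
  Labels sharing a plan group are placed in the same windows; distinct
  groups never share a window; decoy labels inside windows are confined
  to at most two genera each, so background never reaches the
  selection threshold. Planted genus counts are exact by construction
  and re-verified by brute-force recounts in the tests.

Two generator choices deserve explanation:

* **Topology conditioning.** Substitutions inside planted TM segments
  are drawn from the hydrophobic alphabet {A,I,L,M,F,V}, yet an
  unlucky draw (many A/M, plus the H anchor at Kyte–Doolittle −3.2)
  can pull a 19-residue window below the prediction threshold and make
  helix 8 undetectable. Because the world's contract is that every
  Cu-type member carries a *detectable* 12-segment scaffold with
  motifs in segments 7/8, members are drawn by seeded rejection until
  every planted segment keeps mean hydropathy ≥ 2.5 and prediction
  recovers the planted topology. `mutate_sequence()` itself keeps
  plain per-site independent semantics.
* **What passing does not show.** The generator plants no indels, no
  horizontal transfer, no shared signal between families, and decoy
  labels with artificially narrow taxonomic ranges. Perfect cluster
  recovery (ARI = 1) and perfect screen precision/recall on this world
  validate the machinery, not the biological difficulty of the real
  problem, where family boundaries and motif detection are far
  noisier.

## Numerical choices

* **Alignment scores.** The E-value-based edge weight reproduces the
  scale on which 75 is a meaningful threshold; both Karlin–Altschul
  constants are arguments. The optional 4-mer prefilter only skips
  pairs sharing no exact 4-mer; the tests verify exact equivalence of
  the accepted edge set.
* **Column quality.** With gap-free residue frequencies $p$ of a
  column, $s_c = \sum_{a,b} p_a p_b B(a,b)$ is rescaled linearly from
  the BLOSUM62 range $(-4, 11)$ to $(0, 1000)$ and rounded. A conserved
  tryptophan column scores exactly 1000; note that a conserved
  methionine column scores only 600 because BLOSUM62 self-scores
  differ, so the default threshold of 826 retains only near-invariant
  C/W-type columns. On divergent synthetic families this can empty an
  alignment entirely — `filter_alignment()` then errors, and
  `run_pipeline()` falls back to the gap-fraction filter alone for that
  cluster and records the fallback in the report. Columns with more
  than 50% gaps are always dropped; gaps are excluded from the
  frequency estimates.
* **Neighbor joining.** Ties in the Q criterion break on the
  lexicographically smallest pair of subtree labels, making the
  topology independent of input order. Negative branch lengths are
  clamped to zero with the deficit moved to the sister branch, which
  preserves path lengths — on additive matrices the output path-length
  matrix equals the input to machine precision.
* **Trees per cluster.** The pipeline aligns and builds trees per
  network cluster. Synthetic families are unrelated by construction,
  so a joint alignment across clusters carries no signal (p-distances
  saturate) and is not built; bootstrap behaviour across clades is
  validated on explicitly constructed alignments with diagnostic
  columns instead.
* **Degenerate inputs.** Sequences shorter than the hydropathy window
  yield an empty topology with a warning; pairs without comparable
  alignment columns are an error in distance computation but are
  skipped (replicate dropped from the count's numerator) inside
  bootstrap resampling; empty windows yield empty conservation tables.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| network threshold | 75 | $-\log_{10} E$ | edge acceptance |
| gap open / extend | 11 / 1 | score units | BLAST-style, length-k gap costs 11 + k |
| KD window / threshold | 19 / 1.6 | residues / hydropathy | classical plot convention |
| min TM run / merge gap | 8 / 3 | residues | reported segment length |
| column quality | 826 | 0–1000 scale | see scale caveat above |
| bootstrap replicates | 1000 | replicates | tests and acceptance use 100 |
| window half-width k | 3 | genes | neighborhood windows |
| selection threshold | 30 | distinct genera | after the ≥2-genera floor |
| co-occurrence minimum | 2 | windows | neighborhood collapsing |

Problem sizes used by the packaged checks: 100 proteins of length 423
for network and screen validation, alignments of 6–10 rows for logo and
bootstrap checks with 100 replicates, 20 random additive matrices of
5–10 taxa for the NJ oracle, and two full pipeline runs for the
determinism check.

## Limitations

* Hydropathy-window topology prediction is a stand-in for HMM-based
  predictors; helix numbering is de novo from the N-terminus, whereas
  the original analyses may have numbered helices by alignment to
  CcoA. A projection-based numbering is a possible future mode.
* The center-star aligner is a stand-in for a profile aligner
  (COBALT-class) and neighbor joining for maximum-likelihood
  inference; both are chosen because they are fully specifiable and
  testable against closed-form oracles at desk scale.
* Observed-frequency logos (with small-sample correction) replace
  HMM-weighted letter heights.
* The exact quality score behind the published threshold 826 is not
  public; the BLOSUM62 pair-similarity score used here is monotone in
  conservation and hits exactly 1000 for identical columns, which
  makes the printed threshold interpretable, but it is not a
  reimplementation of the original tool's score.
* Cluster boundaries on real data were drawn by expert inspection of a
  tree; this package reports network components and tree bipartitions
  and leaves boundary drawing to the user.
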