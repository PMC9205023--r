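---
title: "Detecting gene conversion between WGD-derived duplicates with homologous quartets"
author: "quartetconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene conversion between WGD-derived duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetconv)
```

## The problem and the model

A whole-genome duplication (WGD) leaves a genome full of paralogous gene
pairs that started out identical and have diverged ever since. Gene
conversion — unidirectional homologous recombination — can interrupt that
divergence by overwriting one copy (the *acceptor*) with its partner's
(the *donor's*) sequence, either over the whole gene (WCV) or over a
short tract (PCV). Converted paralogs look "too young": their synonymous
divergence (Ks) shrinks back toward zero while their divergence from
every other relative is untouched.

The unit of inference is the **homologous gene quartet**: a paralog pair
P1, P2 retained from the WGD in one genome, together with their
respective orthologs S1, S2 in a second genome that shares the WGD but
split from the first *after* it. Absent conversion the expected tree is
((P1,S1),(P2,S2)): orthologs are the younger pairs. Conversion between
P1 and P2 after speciation produces the diagnostic signal — the paralogs
become more similar to each other than each is to its own ortholog,
wholly (WCV) or locally along the alignment (PCV).

The reference application is the Salicaceae: poplar and willow share a
tetraploidization (paralog Ks ≈ 0.25–0.31) and diverged later (ortholog
Ks ≈ 0.12), with the much older core-eudicot hexaploidization visible as
a second intra-genome Ks peak near 1.1–1.3. All defaults in this package
are set to that regime.

## Pipeline

1. **Collinearity** (`filterLargeFamilies`, `chainCollinearPairs`).
   Homolog pairs (an imported all-vs-all protein search; e-value and
   score filters are applied when those columns are present) are chained
   on gene-order coordinates into collinear blocks: strictly monotone
   chains with at most `max_gap = 50` intervening genes on either
   genome, at least `min_block_len = 4` anchors, extracted greedily by
   descending chain length with deterministic tie-breaks. Genes in
   homology families of 50 or more members are removed first. A
   length threshold stands in for ColinearScan's block-significance
   test, which is the stated operational criterion here.
2. **Dating** (`kdeKs`, `fitMinGaussians`, `peaksToEventWindows`).
   Anchor Ks values (NG86, below) are smoothed with a Gaussian kernel of
   bandwidth 0.05 and the density *curve* is fitted with the smallest
   number of Gaussian components reaching a curve-level R² of 0.95 —
   curve-level least squares rather than sample-level EM, because the
   curve is the object the procedure is defined on. Components map to
   events youngest-first (SCT, then ECH intra-genome; the single
   speciation peak inter-genome); when there are more components than
   events, each event is represented by its largest-weight ("principal")
   component. Blocks are labeled by which `mean ± 2·sd` window holds
   their median anchor Ks. Ks values ≥ 3 are treated as saturated and
   excluded from fitting so the old peak stays fittable.
3. **Quartets** (`buildQuartets`, `filterQuartet`). For every anchor
   (P1,P2) of an SCT-labeled block, S1 and S2 are looked up among
   ortholog-block anchors (longest block, then lexicographic id, on
   ties); both genomes are scanned symmetrically. Quartets with any
   pairwise gap fraction > 50% or amino-acid identity < 40% are dropped.
   The paralog pair of the second genome is not itself required to be
   block-anchored — the quartet is defined by the two ortholog pairs —
   but its statistics are always computed.
4. **Distances** (`alignPair`, `ng86`). Each compared pair is aligned
   protein-first (global Needleman–Wunsch, BLOSUM62, gap open 10 /
   extend 0.5) and back-translated, so gaps are whole codons.
   Nei–Gojobori (1986) site counting uses the fractional convention
   averaged over both sequences; multi-difference codons average over
   all minimal substitution pathways, excluding pathways through stop
   codons; raw proportions are Jukes–Cantor corrected,
   d = −(3/4)·ln(1 − 4p/3). Raw proportions ≥ 0.745 are flagged
   saturated and reported missing. The JC-corrected values are reported
   under both the `ka`/`ks` and the `pn`/`ps` column names: in the
   output schema the two pairs of names are aliases for traceability to
   tables that use the latter notation. For the conversion scan all
   four genes share one alignment: S1, P2 and S2 are pairwise-aligned to
   P1 and merged on P1's codon coordinates (insertion slots unioned,
   left-aligned padding) — anchor-based merging keeps the column map to
   acceptor coordinates unambiguous and is deterministic.
5. **WCV** (`detectWcv`). A whole-gene call requires all three of:
   Ks(P1,P2) below both ortholog Ks; the neighbor-joining topology of
   the shared-column JC distance matrix pairing the paralogs; and that
   topology holding in ≥ 95% of 1000 codon-column bootstrap replicates.
   The Ks inequality alone would over-call at low divergence, so the
   tree condition is conjunctive. The acceptor is the copy with the
   larger ortholog Ks; if the two ortholog Ks are within 1.2× of each
   other the elevation is symmetric and both copies are reported
   affected (the both-paralogs-converted scenario). Amino-acid identity
   ratios are computed and reported but not used as a gate.
6. **PCV** (`siteProfiles`, `conversionScoreArray`,
   `maximalScoringSegments`, `bootstrapSegmentP`, `detectPcv`).
   Per-column 0/1 difference profiles are formed for the paralog pair
   and both ortholog pairs over columns where all four genes have
   unambiguous bases. The score per column is the mean ortholog
   difference minus the paralog difference, giving values in
   {−1, −½, 0, +½, +1}: positive exactly where paralogs agree while
   orthologs do not. All maximal-scoring segments (Ruzzo–Tompa) spanning
   ≥ 10 columns are candidates; the best is tested by resampling score
   columns with replacement (B = 1000) and comparing the observed score
   with each replicate's best qualifying segment, with an add-one
   correction so p ≥ 1/(B+1). Significant segments (p ≤ 0.05) are
   emitted, masked to zero, and the scan repeats (up to 10 rounds) to
   expose secondary tracts. Tract bounds are reported 1-based inclusive
   in the acceptor's ungapped coordinates; the direction is resolved by
   which ortholog profile carries the tract's mismatches, with ties
   reported ambiguous. Gapped columns neither score nor count toward
   tract length.
7. **Downstream statistics** (`rate`, `decileConversionRates`,
   `windowDensityCorrelation`, `compareGroups`, `expressionDivergence`,
   `goEnrichment`). Rates are integer-count records with percent =
   round(100·n/d, 2). Chromosomes are cut into length deciles
   (membership by gene midpoint) and into 1-Mb windows laid from both
   termini toward the center; the positional ANOVA uses per-chromosome
   group rates as observations — the natural unit when a single p-value
   per genome is reported, though a per-window ANOVA is equally
   defensible. Group comparisons use the pooled-variance Student t-test
   (the common default reading of "t-test"). Expression analysis removes
   zero-TPM genes, then calls a pair divergent when
   (max + c)/(min + c) ≥ 2 with pseudocount c = 0.1 (the pseudocount
   guards the ratio when one surviving copy is near zero; whether the
   original twofold rule used one is not stated). GO terms are tested
   per term with Pearson's chi-square on the 2×2
   converted-by-membership table, without continuity correction; raw p
   is primary and a Benjamini–Hochberg q column is added for reuse.

## The simulator

`simulateQuartet` evolves a stop-free random ancestral gene along the
quartet topology with branch lengths chosen so the expected NG86 Ks is
`k_par` (default 0.25) for paralog pairs and `k_orth` (default 0.12) for
ortholog pairs. The substitution process proposes single-nucleotide
changes uniformly (a Jukes–Cantor proposal, matching the detector's
distance model); proposals creating stop codons are rejected, synonymous
proposals always fix, and nonsynonymous proposals fix with probability
`ka_ks_ratio` (default 0.3, inside the observed Pn/Ps range). Because
NG86 counts sites by the same uniform-mutation convention, a branch of
length d accumulates d expected synonymous substitutions per NG86
synonymous site — the simulator and the estimator agree by construction,
which the distance-recovery tests verify empirically. Conversion events
overwrite the acceptor's tract with the donor's at a configurable
`time_fraction` of the post-speciation period (0 = at speciation, 1 =
now; real events' timing is unknown, so it is exposed, not assumed);
chimeric edge codons that would create a stop are completed from the
donor. Default PCV tract lengths are drawn from 30–120 nt, bracketing
reported tract scales (e.g. a 41-nt example) while exercising the 10-nt
detection floor.

`simulateGenomePair` lays out homoeologous chromosome pairs with
duplicate pairs present at a (possibly position-dependent) density and
converted independently per genome at a second profile, giving clean
collinear diagonals plus full per-gene and per-pair truth;
`simulateExpression` draws pair-wise log-normal TPM with a smaller
between-copy log-fold spread for converted pairs (defaults chosen so
the divergent-pair fractions sit near the mid-50% range and mean TPM
near 36 vs 47).

What the simulator deliberately omits: indels during divergence
(alignment is exercised separately), codon-usage and GC bias,
transition/transversion asymmetry, tandem duplications, and any
clustering of conversion in time or along chromosomes. Passing tests
therefore validate the machinery under the detector's own model
assumptions; they do not certify performance on real genomes, where
alignment error and rate heterogeneity add noise the null model does
not capture.

## Calibration and power, measured

Two properties of the PCV test are worth stating plainly, because the
package's own experiments quantify them:

* **The column bootstrap is conservative.** The null is built by
  resampling the observed score array itself, so arrays that by chance
  carry a hot tail also generate a hotter null; the measured per-quartet
  false-positive rate on 1,000 conversion-free quartets is ≈ 0.02 at
  α = 0.05 — about half the nominal level. Calls that pass are
  trustworthy; the nominal α overstates the actual risk.
* **Tract boundaries are intrinsically fuzzy.** Inside a converted tract
  the only signal columns are ortholog mismatches (density ≈ 0.15 per
  nt at the default divergences), so the expected gap between the true
  tract edge and the nearest signal column is ≈ 6 nt by itself. For a
  60-nt tract at the default divergences the measured detection rate is
  ≈ 65%, and called boundaries land within ±6 nt of both true edges in
  only ≈ 20% of detections — a property of any detector restricted to
  per-column difference scores, not of the implementation. Whole-gene
  conversion detection, by contrast, is essentially perfect at these
  divergences (100% at time_fraction ≥ 0.5, 0 false calls in 200 null
  quartets).

## Numerical and design notes

* Scoring constants for the PCV scan are not published; the symmetric,
  parameter-free o(i) − p(i) in {−1, −½, 0, +½, +1} is used. α = 0.05
  and B = 1000 follow the general significance and bootstrap usage.
* Coordinates are 1-based inclusive on disk (GFF3 convention) and are
  carried natively by `GRanges`/`IRanges`, which enforce that
  convention internally, so no base-shift conversion layer exists.
* CDS input is assumed strand-resolved (as in standard CDS FASTA
  exports); the strand column is carried but never acted on.
* A terminal stop codon is trimmed before alignment; internal stops are
  an error naming the gene.
* Whether the original Ka/Ks runs used NG86 exactly or an ML variant is
  ambiguous in the methods they describe; NG86 is taken at its word and
  implemented directly, with a brute-force pathway-enumeration oracle
  in the test suite guaranteeing the counting conventions.
* Greedy block extraction breaks ties by the smaller starting order
  index; ortholog-anchor ties by longest block then lexicographic id;
  the max-gap constraint is enforced on both genomes — each choice is
  unstated in the source procedure and fixed here for determinism.
* Problem sizes in the validation suite (e.g. 1,000 null quartets for
  calibration, 200 replicates for power, 100 for mixture recovery,
  4 chromosomes × 40–60 genes for the end-to-end run) were chosen as
  the smallest sizes at which the binomial noise of the measured rates
  is well below the margins being asserted.

## Limitations

Tandem/allelic conversion, dating of individual events, indel-aware
tract calling and absolute-time (MYA) conversion of Ks peaks are out of
scope. Quartet counts are data-dependent outputs, never constants. The
mixture fit reports curve-level R², which is not a model-selection
criterion (no AIC/BIC); it reproduces the published curve-fitting
procedure rather than improving on it.
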