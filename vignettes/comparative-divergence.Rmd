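---
title: "Dating conifer divergence from transcriptome Ka/Ks: models and methods"
author: "pinediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating conifer divergence from transcriptome Ka/Ks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinediv)
```

## The inference chain

`pinediv` implements a comparative-transcriptomics chain for estimating
divergence times and selection patterns across a set of related species from
their assembled transcript sets alone:

1. **Redundancy collapse** — within each taxon, transcripts at global
   identity strictly above 95% are clustered by single linkage and each
   class is represented by its longest member (`collapseRedundant`).
2. **Orthologue pairing** — between two taxa, transcript pairs at global
   identity of at least 90% are reduced to a one-to-one best-hit matching
   (`pairOrthologues`).
3. **Ka/Ks estimation** — each pair is frame-inferred, codon-aligned via
   its protein translation, and rates are counted with the Nei–Gojobori
   (NG86) method plus Jukes–Cantor correction (`inferFrame`, `codonAlign`,
   `ng86`).
4. **Ks peaks** — per species pair, the mode of the distribution of
   pairwise Ks values on a fixed 0.01 grid is the species-pair distance
   (`ksPeak`, `peakMatrix`).
5. **Phylogeny and dating** — neighbour joining on the Ks-peak matrix,
   outgroup rooting, branch-average Ks per split, and a strict molecular
   clock convert distances to ages (`njTree`, `rootWithOutgroup`,
   `branchAverageKs`, `divergenceTime`, `cladeAges`).
6. **Selection screen** — pairs with Ka/Ks strictly above 1 are flagged as
   candidate positive-selection genes and can be joined to user-supplied
   functional annotations (`screenPositive`, `annotateCandidates`).
7. **Markers** — microsatellite scanning with class-specific minimum
   repeat counts and transition/transversion classification of SNP allele
   pairs (`findSSRs`, `classifySNP`, `markerSummary`).

A packaged fixture, `coniferKsPeaks()`, carries the published 13-conifer
Ks-peak matrix (12 *Pinus* species plus *Picea glauca*), so stages 5–6 can
be exercised on real numbers without any sequence data.

## The NG86 estimator

For two aligned coding sequences, each codon contributes synonymous and
nonsynonymous *sites*: at each of its three positions, the fraction of the
possible single-nucleotide changes that preserve the amino acid. Changes
that would create a stop codon are excluded from the possible set, so every
codon contributes exactly 3 sites and $S + N = 3 \times$ (number of counted
codons). Site counts are averaged over the two sequences.

*Differences* within a codon pair are resolved by enumerating every
ordering of the differing positions (1, 2, or 6 minimal mutational
pathways), scoring each step as synonymous or nonsynonymous, and averaging
with equal weights over the pathways whose intermediates are all sense
codons. If every pathway crosses a stop codon — possible for a handful of
sense-codon pairs — all pathways are used rather than dropping the pair.
The proportions $p_s = S_d/S$ and $p_n = N_d/N$ are corrected for multiple
hits with Jukes–Cantor,

$$d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4p}{3}\right),$$

giving $K_s$ and $K_a$. The test suite verifies the per-codon-pair site and
difference counts against an independent brute-force pathway enumerator
over the complete $64 \times 64$ codon table.

Conventions for degenerate outcomes: pairs with no differences report
$K_a = K_s = 0$ and an *undefined* ratio; $K_s = 0$ with $K_a > 0$ is
reported as "> 1" and treated as positive selection by the screen; pairs
with $p_s$ or $p_n \ge 3/4$ are flagged *saturated* and dropped from
downstream aggregation, since the correction diverges there.

## The molecular clock

Branch-average Ks for a split is the arithmetic mean of all cross-clade
Ks-peak entries, reported to 3 decimals. Ages use a strict clock at
$r = 0.68 \times 10^{-9}$ synonymous substitutions per site per year, with

$$\text{age (Mya)} = \frac{K_s}{r \times 10^6}.$$

Note that this divides the *pairwise* divergence by $r$ directly rather
than by $2r$; it is the convention under which the packaged matrix dates
the *Pinus*–*Picea* split (branch-average Ks 0.146) to about 214.7 Mya, the
subgenus split (0.078) to about 114.7 Mya and the section split (0.035) to
about 51.5 Mya. The conventional per-lineage form is available via
`divergenceTime(ks, perLineage = TRUE)` and halves all ages; which
convention is appropriate depends on how the calibration rate itself was
derived.

## Neighbour joining

`njTree` is the classical Saitou–Nei agglomeration: at each step the pair
minimising $Q_{ij} = (r-2)\,d_{ij} - R_i - R_j$ is joined. Because Ks-peak
matrices hold many tied entries (peaks are multiples of 0.01), ties on the
Q-criterion are broken deterministically by the lowest taxon-index pair.
Negative branch lengths, which non-additive matrices can produce, are
clamped to zero with a warning. On additive input the output tree
reproduces the input distances exactly (tested against random trees of up
to 10 taxa); on the packaged matrix the topology agrees with `ape::nj`.
Outgroup rooting places the root at the midpoint of the outgroup's pendant
edge.

## The synthetic-data generator

Downstream stages are validated against simulated data with known truth
(`simulateCodonPair`, `simulateClade`). The generator draws a random
stop-free codon sequence and evolves derived copies under a per-codon
single-nucleotide mutation process: synonymous events accumulate with
expected density `ksTarget` per synonymous site and nonsynonymous events
with density `omega * ksTarget` per nonsynonymous site (event counts are
Poisson; each event picks uniformly among the single-nucleotide changes of
its class available in the current sequence, which is the conditional
distribution of a uniform proposal process with nonsynonymous acceptance
probability `omega`). Changes that would create a stop codon are never
available, multiple hits at a site arise naturally, and sequences evolve
independently along each branch of a user-supplied tree with branch lengths
in Ks units. Decoy sequences — independent random codon strings — probe the
specificity of orthologue pairing.

Deliberately **not** modelled: indels, codon-usage bias, among-site rate
heterogeneity, transition/transversion bias, shared polymorphism, and
read-level sequencing error. Passing round-trip tests therefore show that
the chain is internally consistent and recovers its own generating
parameters; they do not show robustness to assembly artifacts or alignment
error in real transcriptome data.

Default study conditions mirror the scale of the real analysis: genes of
300–500 codons, divergences in the 0.01–0.15 Ks range where the conifer
Ks peaks live, and $\omega$ between 0.2 (typical purifying selection) and
2 (positive selection). Monte-Carlo checks in the test suite use 200
replicates of 500-codon pairs; the end-to-end pipeline test uses a
4-taxon clade with 50 genes of 300 codons, and the species-pair round
trip 120 genes — sizes chosen so each property is measured well inside
its Monte-Carlo error.

## Numerical and design choices

- **Identity definition.** The clustering thresholds are stated upstream
  only as percentages, so the identity measure is defined here explicitly:
  end-to-end global alignment with match +1, mismatch −1, linear gap cost
  2 per column; identity = matching columns / alignment columns, gaps and
  N columns counting as mismatch (N never matches, not even N). Both
  thresholds are configurable; "above 95%" is strict, "90% identity" is
  inclusive.
- **8-mer prefilter.** All-vs-all global alignment is quadratic and
  dominated by hopeless pairs. With $L_a \le L_b$, an alignment at
  identity $\ge t$ has at least $t L_b$ matched columns, so at most
  $L_a - t L_b$ positions of the shorter sequence are unmatched, and each
  unmatched position can destroy at most 8 of its $L_a - 7$ 8-mers; every
  other 8-mer occurs verbatim in the partner. Pairs whose shared 8-mer
  count falls below that bound are skipped without alignment. The bound is
  conservative: it can only discard pairs that provably cannot reach the
  threshold.
- **Frame inference.** Longest stop-free codon run over all six frames
  (minimum 50 codons by default), ties broken toward the forward strand,
  lower offset, earlier start. This replaces database-guided
  directionality assignment and is validated against simulated truth.
- **Ks peak.** Fixed-width histogram (0.01) rather than kernel density:
  peaks are reported on a 0.01 grid, and a histogram mode is exactly
  testable. Ties break toward the lower bin, matching the "< 0.01"
  reporting convention for the shallowest species pairs; values at or
  above the saturation cap (2.0) are excluded. A distribution whose mode
  falls exactly on a bin edge legitimately reports either adjacent bin.
- **Best-hit ties** in pairing break by higher identity, then longer
  alignment, then lexicographic ids — pairing is deterministic.
- **SSR scanning** reports each maximal perfect repeat run once, under its
  smallest repeating unit, truncated to whole units; compound or
  interrupted microsatellites are out of scope. Motifs are reported as
  found, with an optional smallest-cycle-rotation canonical form for
  class grouping.

## Known limitations

- NG86 with equal pathway weights and Jukes–Cantor correction ignores
  transition/transversion bias and codon frequencies; against
  maximum-likelihood codon models its estimates agree only approximately,
  and the Ka/Ks ratio drifts slightly downward as divergence grows beyond
  the range the correction handles well. At the divergences where the
  conifer peaks lie ($K_s \le 0.05$ within *Pinus*) the test suite shows
  recovery unbiased within Monte-Carlo error.
- The selection screen applies the raw ratio with no significance test, so
  short alignments can cross the Ka/Ks = 1 line by chance; candidate lists
  should be read as enrichment input, not as per-gene evidence.
- The clock is strict and single-rate; no fossil calibration or rate
  relaxation is attempted.
- Orthologue pairing is strictly pairwise best-hit at high identity; it
  does not attempt multi-species orthogroup inference and will discard
  genuine orthologues beyond the identity threshold.

## A worked fixture example

```{r fixture}
m <- coniferKsPeaks()
pines <- setdiff(m@taxa, "Picea_glauca")
strobus <- c("P_monticola", "P_lambertiana")

branchAverageKs(m, pines, "Picea_glauca")
divergenceTime(branchAverageKs(m, pines, "Picea_glauca"))

ct <- cladeAges(rootWithOutgroup(njTree(m), "Picea_glauca"), m)
nodeTable(ct)[, c("cladeB", "ks", "ageMya")]
```
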