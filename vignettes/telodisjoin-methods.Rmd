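---
title: "Methods: calibrated ChIP, Hi-C end aggregation and disjunction scoring"
author: "telodisjoin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated ChIP, Hi-C end aggregation and disjunction scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodisjoin)
```

# Scope and scientific setting

Fission-yeast telomeres are bound by the shelterin complex and, during
mitosis, by condensin; loss of condensin function leaves sister telomeres
entangled in anaphase (non-disjunction) and increases telomere–telomere
contact frequencies in metaphase.  `telodisjoin` implements the three
quantitative readouts used to study this biology — spike-in calibrated
ChIP occupancy, Hi-C chromosome-end aggregation, and mitotic focus
counting — as reusable, tested operations, together with synthetic-data
generators that plant known ground truth for each assay.  The package
works on a deliberately small two-species toy reference; it does not
attempt to reconstruct any real genome assembly.

# The toy reference

`build_toy_genome()` lays out `C = 3` chromosomes of 300 kb.  Each end
carries, from the terminus inward, a 2 kb telomeric repeat array, then
sub-telomeric element (STE) blocks (8 kb STE1, 4 kb STE2), then arm
sequence with randomly placed genes and non-telomeric Taz1-island
features; a 10 kb centromere sits mid-chromosome.  The spike-in genome is
one 200 kb chromosome with a single 2 kb control locus, the stand-in for a
budding-yeast calibration amplicon.  Coordinates are 0-based half-open
throughout; 1-based inputs are converted at the boundary
(`coord_0based()`), including boundaries stated as "last included
position", the convention used for the repeat-array quantification limit.

Because repeat arrays genuinely repeat (tandem copies of a configurable
unit; the default unit is a plausible degenerate G-rich octamer, not a
real biological sequence), the per-base calibrated ratio exercises the
repeat-coverage argument for calibration, but no claim is made about any
specific repeat sequence.

# Spike-in calibrated ChIP

## Model

The simulator draws the Total (input) fraction uniformly over both
genomes, each species weighted by `mixing_ratio` × genome length (the
experimental mixing of target and spike-in cells).  IP fragments are
drawn with probability proportional to a per-base enrichment multiplier:
telomere repeats 8×, STE 2×, a random quarter of genes 6×
("gene peaks"), Taz1 islands 4×, spike-in control locus 4×, background 1
(the unit reference).  Fragments are 300 bp (chromatin sheared to
~300 bp), clipped at chromosome ends.  Default depth is 200,000 fragments
per fraction, about 50× coverage of the 1.1 Mb two-species toy — a
realistic desk-scale stand-in for a sequencing run.

The calibration factor is

\[
\alpha = \frac{N^{\mathrm{Total}}_{\mathrm{spike}}}{N^{\mathrm{IP}}_{\mathrm{spike}}},
\qquad
R(b) = \frac{\alpha\,\mathrm{IP}(b) + p}{\mathrm{Total}(b) + p},
\]

with pseudocount `p = 1` by default and positions with Total coverage
below 5 masked as low-coverage.  Scaling target IP by α equalises IP and
Total on the spike-in, so target ratios are reported on a scale where
genome-average spike-in occupancy is 1 and a planted k-fold enrichment
reads out as `R ≈ k`.

## The IP-efficiency contract

A global change in immunoprecipitation efficiency must leave calibrated
ratios unchanged while doubling α when efficiency halves.  With a fixed
emitted depth both requirements cannot hold simultaneously, so the model
is: `ip_depth` is the number of fragments *offered* to the IP; at
`ip_efficiency = 1` (default) all are emitted and depth is conserved
exactly; below 1 the library is binomially thinned.  Calibrated ratios
are then invariant to efficiency within sampling error while
uncalibrated ratios scale with it — the property spike-in calibration
exists to provide.

## Known bias

Coverage counts fragment overlaps, so enrichment steps are smeared by one
fragment length at feature boundaries.  For the 2 kb repeat array next to
a 2× STE block this dilutes the recovered telomere mean by ~4–6%
(recovered ≈ 7.5–7.9 for a planted 8).  This is inherent to overlap
counting, affects IP and Total symmetrically elsewhere, and is well
inside the ±15% recovery band the tests assert.

## qPCR normalization and metagenes

`qpcr_normalize()` divides each locus percent-IP by the spike-in control
locus percent-IP per replicate and reports replicate mean and n−1 sample
SD (SD flagged undefined at n = 1).  `metagene_profile()` rescales gene
bodies to 60 bins with 500 bp flanks in 10 fixed-width bins, reverses
minus-strand genes so the TSS is leftmost, ignores masked positions, and
pads truncated flanks with missing values.  The binning defaults are
package choices; no published binning is claimed.

# Hi-C chromosome-end aggregation

## Simulator

Contacts are sampled multinomially (budget conserved exactly; Poisson and
noise-free variants available) from an expectation with three parts:

* power-law distance decay `s^γ` within chromosomes (γ = −1);
* a constant inter-chromosomal baseline equal to the decay weight of a
  1 Mb separation;
* Rabl clustering terms: bin weights `w = exp(−d/λ)` decay with distance
  `d` to a chromosome end (λ = 20 kb), and a pair's expectation is
  multiplied by `1 + (g − 1)·w_i w_j` where `g` is the intra- or
  inter-chromosomal telomere gain (4 and 2 in the wild-type-like preset),
  and analogously for centromeres (gain 8).

Clustering acts only between *different* chromosome ends (left×right
within a chromosome, any end pair across chromosomes) and different
centromeres.  An earlier draft multiplied all pairs inside end regions —
including a bin's own 5 kb neighbours — which inflated end-bin marginals
about two-fold and made VC_SQRT normalization cancel the planted signal
almost exactly; the corrected model is also what telomere clustering
means physically.  The default budget is 2×10⁶ read pairs (≈120 per
5 kb bin pair), a realistic desk-scale depth.

The condensin-mutant-like preset (`cut14_like_params()`) triples both
telomere gains and attenuates intra-chromosomal contacts beyond 100 kb to
0.6×, emulating reduced arm-range compaction with increased telomere
clustering; centromere gain is unchanged.  All preset values are free
modelling parameters.

## Normalization and aggregation

`vc_sqrt_normalize()` divides each entry by the square root of the
product of its row and column marginal sums, masking zero-marginal rows;
it is exactly invariant to global scaling.  `observed_over_expected()`
divides intra-chromosomal entries by the pooled per-diagonal mean and
inter-chromosomal entries by the pooled inter mean; it feeds the 2D and
differential log2 maps (`differential_map()`, with ε defaulting to the
smallest positive control value).  `distance_decay_curve()` reports the
median contact probability per distance, normalised to sum to 1.

Aggregation (`telomere_aggregate()`) follows the published recipe: 5 kb
bins over a 150 kb distal region per telomere give a 30×30 submatrix per
telomere pair, orientation-normalised so the repeat-proximal corner is at
(1,1); a 21×21 window slides at step 1, yielding (30−21+1)² = 100 frames
per pair; frames are rank-quantized — each cell replaced by
`(rank−1)/(n−1)` with mid-ranks for ties — and aggregated per pair class
by element-wise mean.  Aggregation runs on the VC_SQRT matrix by default
(observed/expected input is equally accepted); the expected-value
transform is reserved for map display because on 300 kb toy chromosomes
the far diagonals are populated almost entirely by telomere-corner cells,
so a per-diagonal expected absorbs the very signal being measured.  This
degeneracy is a property of the toy geometry, not of the method at real
chromosome scale.

## The per-frame statistic

The condition comparison needs one summary per frame.  For the
non-quantized variant this is the frame mean.  For the quantized variant
the frame mean is useless: the mean of `(rank−1)/(n−1)` over a complete
frame is 0.5 by construction.  The package therefore scores a quantized
frame by the mean quantized value over its repeat-proximal quadrant
(10×10 cells) — a location-sensitive rank summary that asks "does the
corner-ward part of this frame out-rank the rest?".

`compare_conditions()` runs a two-sided Mann–Whitney–Wilcoxon on the
per-frame scores of the two conditions, for both variants, with the
significance threshold defaulting to 0.001.  The quantized variant is the
headline decision statistic: absolute VC_SQRT values are not comparable
across libraries (each condition has its own marginal structure and
budget normalisation), and in simulations the non-quantized comparison
duly reports spurious "significance" for centromere pairs whose gains are
identical, while the rank-based comparison does not.  Robustness to scale
is exactly the motivation for quantizing before aggregating, and the toy
world reproduces why.

Within the 150 kb windows of the toy genome the inner edge of every
telomere region reaches the mid-chromosome centromere, so the far corner
of each pair submatrix carries the (condition-invariant) centromere
cluster signal.  Under the wild-type preset that corner can dominate the
aggregate; under the mutant-like preset the repeat-proximal corner wins.
Tests of corner localisation therefore use the strong-clustering preset.

# Mitotic foci and disjunction scoring

Cells are 3D point sets in µm: two spindle pole bodies (SPBs) on the
x-axis and telomere focus ground-truth positions in a nucleus of radius
1.5 µm.  For `C` chromosomes there are 2C telomeres and 4C sister copies:

* interphase — 1–3 peripheral cluster points (Rabl configuration);
* metaphase — up to 2C points, sisters co-located, each telomere leaving
  the cluster with the declustering probability;
* anaphase — each sister pair splits toward opposite poles with the
  disjunction probability, up to 4C points.

`count_foci()` replaces visual counting with single-linkage clustering at
a merge radius (default 0.3 µm, a diffraction-scale stand-in;
complete-linkage optional): any chain of sub-resolution spacings is one
spot, a focus is a cluster, its position the centroid, and at radius 0
distinct points stay distinct.  `classify_stage()` thresholds the spindle
length (SPB–SPB distance) at 4 µm (metaphase/anaphase) and 5 µm
(late-anaphase scoring window), boundary values going to the lower stage.
`disjunction_profile()` reports, with thresholds scaling as (>2C, ≥4C,
≤2C): the separation fraction (anaphase-or-later cells with more than 6
foci for C = 3), the full-disjunction fraction (≥12 foci) and the
non-disjunction fraction (late-anaphase cells with ≤6 foci).

At the default 0.3 µm radius, points drawn independently inside a pole
region occasionally fall within one merge radius, so the wild-type
full-disjunction fraction sits well below 1 even at disjunction
probability 1 — a deliberate model of resolution-limited counting.  Exact
count recovery is asserted at radius 0, and on any instance where the
minimum inter-cluster distance exceeds the radius.

# Determinism, seeds and the scenario runner

Every simulator takes an integer seed and restores the caller's RNG
state.  `run_scenario()` derives one child seed per stage from the master
seed by a documented polynomial hash (`derive_seed()`), keeping seeds in
32-bit range and preventing accidental stream reuse between stages.  The
manifest records parameters, derived seeds and md5 checksums but no
timestamps, so identical config + seed reruns are byte-identical.

# What a green test does and does not establish

The generators emulate the *structure* of the real assays — two-species
fragment mixtures, Rabl-configured contact decay with end clustering,
staged mitotic point sets — with uniform mappability, no PCR or optical
artefacts, no restriction-fragment geometry and no real repeat sequence.
A passing suite establishes that the estimators recover planted truth
under this stated world at stated tolerances; it says nothing about
alignment, peak calling, image segmentation, or any particular published
dataset.  Statistical acceptance checks are stochastic orderings over
100 fixed seeds (≥95/100), never re-tuned after observation.

# Numerical choices

* pseudocount 1, Total floor 5 (configurable); pseudocount 0 makes scale
  invariance exact.
* Exact Mann–Whitney for pooled n ≤ 20 by full enumeration over the
  observed multiset, mid-ranks for ties; two-sided exact p is the null
  probability of `|U − n₁n₂/2|` at least as extreme; the normal branch
  uses tie-corrected variance with continuity correction.  A constant
  pooled sample yields p = 1 with an all-ties flag.
* Rank quantization maps an all-tied window to 0.5 everywhere and keeps
  missing cells missing.
* Differential-map ε defaults to the smallest positive control entry.
* Trailing partial Hi-C bins are kept and flagged.
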