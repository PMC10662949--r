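# telodisjoin

Quantitative analytics for condensin-dependent sister-telomere
disjunction in fission-yeast-like genomes: spike-in calibrated ChIP
occupancy, Hi-C chromosome-end aggregation with rank quantization, and
mitotic focus counting — each paired with a synthetic-data generator that
plants known ground truth, so every estimator is testable end to end at
desk scale.

## Who this is for

Chromosome-biology groups quantifying SMC-complex behaviour at telomeres
face three recurring measurement problems:

1. **Occupancy at repeats.** Telomeric repeat arrays bias input coverage,
   so plain IP/Total ratios misestimate occupancy there.  Spike-in
   calibration — mixing in cells of a second species carrying a tagged
   control protein — puts the ratio on an absolute scale where the biases
   cancel.
2. **Contacts between chromosome ends.** Telomere–telomere Hi-C signal is
   faint and scale-confounded between libraries.  Aggregating end-region
   submatrices over all telomere pairs, after within-window rank
   quantization, makes the comparison robust to library scale.
3. **Disjunction in anaphase.** With C chromosomes, up to 2C telomeric
   foci appear in metaphase and up to 4C in anaphase; counting foci
   against spindle length (SPB–SPB distance) scores sister-telomere
   separation, full disjunction and non-disjunction.

## The statistics at the core

* Calibrated occupancy at base *b*:
  `R(b) = (α·IP(b) + p) / (Total(b) + p)` with
  `α = Total_spike / IP_spike`, pseudocount `p`, and masking of
  low-coverage or boundary-excluded positions.
* VC_SQRT normalization: `M'(i,j) = M(i,j)/√(r_i r_j)` with `r` the
  marginal sums; observed/expected divides by the pooled per-diagonal
  mean (intra) or pooled inter mean.
* End aggregation: 150 kb / 5 kb → 30×30 submatrix per telomere pair,
  repeat-proximal corner at (1,1); 21×21 windows sliding at step 1 (100
  frames per pair); rank quantization `(rank−1)/(n−1)` with mid-rank
  ties; element-wise mean aggregate per pair class (intra/inter); frame
  scores compared between conditions by a two-sided
  Mann–Whitney–Wilcoxon (exact by enumeration for pooled n ≤ 20,
  tie-corrected normal approximation otherwise), significance at 0.001.
* Focus counting: single-linkage clustering of telomere point objects at
  a merge radius (default 0.3 µm); stages from spindle length with 4 µm
  and 5 µm thresholds; scores scale with chromosome number as
  (>2C separation, ≥4C full disjunction, ≤2C non-disjunction).

## Worked example

```r
library(telodisjoin)

genomes <- build_toy_genome()              # 3 x 300 kb target + spike-in

## 1. calibrated ChIP: recover a planted 8x telomere enrichment
sim   <- simulate_chip(genomes, enrichment_profile(), seed = 1)
ip_t  <- coverage_from_fragments(sim$ip_target,    genomes$target,  "IP")
tot_t <- coverage_from_fragments(sim$total_target, genomes$target,  "Total")
ip_s  <- coverage_from_fragments(sim$ip_spike,     genomes$spikein, "IP")
tot_s <- coverage_from_fragments(sim$total_spike,  genomes$spikein, "Total")
alpha <- calibration_factor(ip_s, tot_s)
rt    <- calibrated_ratio(ip_t, tot_t, alpha)
round(feature_class_means(rt, genomes$target), 2)
#> telomere_repeat             STE            gene      background
#>            7.56            1.98            2.09            1.04

## 2. Hi-C: condensin-mutant-like vs wild-type-like telomere contacts
wt <- vc_sqrt_normalize(simulate_hic(genomes$target, hic_sim_params(), seed = 1))
mu <- vc_sqrt_normalize(simulate_hic(genomes$target, cut14_like_params(), seed = 2))
cmp <- compare_conditions(telomere_aggregate(mu, genomes$target),
                          telomere_aggregate(wt, genomes$target))
cmp[cmp$variant == "quantized",
    c("pair_class", "score_a", "score_b", "p.value", "significant")]
#>   pair_class score_a score_b  p.value significant
#> 1      intra   0.322   0.220 1.77e-33        TRUE
#> 3      inter   0.554   0.522 7.34e-35        TRUE

## 3. foci: full disjunction in anaphase gives 12 resolvable foci
cells <- simulate_mitotic_cells(genomes$target,
                                mitotic_sim_params(n_cells = 200,
                                                   disjunction_prob = 1),
                                seed = 1)
disjunction_profile(cells, merge_radius = 0)
#> mitotic_profile: 200 cell(s); separation 1.00, full disjunction 1.00,
#> non-disjunction 0.00
```

Reading the numbers: the calibrated ratio puts occupancy on a scale where
spike-in occupancy is 1, so the telomere-repeat mean of 7.56 recovers the
planted 8× within the documented fragment-edge smearing; the mutant-like
Hi-C condition raises the rank-based telomere aggregate scores in both
pair classes at p < 0.001 while centromere aggregates (equal gains) stay
non-significant; and anaphase cells with certain disjunction of all 6
sister-telomere pairs show exactly 4C = 12 foci.

## End-to-end scenario and CLI

```r
res <- run_scenario(scenario_config(master_seed = 1), out_dir = "run1")
res$summary      # per-condition ChIP fold + disjunction fractions
```

A thin command-line wrapper is installed under `exec/`:
`telodisjoin run --out-dir DIR --seed N`, plus `genome build`,
`sim chip|hic|cells`, `hic aggregate` and `foci profile` subcommands.
Scenario runs are byte-identical for identical config and master seed
(checksummed, timestamp-free manifests).

## Package layout

* `R/genome_model.R`, `R/genome_io.R` — toy two-species reference, masks,
  telomere pair enumeration, FASTA/BED I/O.
* `R/synthetic_chip.R`, `R/synthetic_hic.R`, `R/synthetic_cells.R` —
  generators with planted truth.
* `R/calibrated_chip.R` — coverage, calibration, ratio tracks, qPCR
  normalization, metagenes, bedGraph.
* `R/contact_matrix.R`, `R/hic_telomere.R` — matrix container + TSV I/O,
  VC_SQRT, O/E, decay curves, differential maps, aggregation,
  comparisons.
* `R/foci_analysis.R` — focus counting, staging, disjunction scores.
* `R/stats_core.R` — Mann–Whitney–Wilcoxon, replicate summaries.
* `R/pipeline.R`, `R/cli.R` — scenario runner, seed splitting, CLI.

See `vignettes/telodisjoin-methods.Rmd` for the full model description,
parameter rationale and known limitations.
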