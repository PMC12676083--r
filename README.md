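# phyllotorsion

Quantitative analysis of phyllotaxis — the arrangement of lateral organs
around a stem axis — for plant developmental biologists working on
*Arabidopsis*-style rosettes, inflorescences and meristems.

Most flowering plants place successive organs at the golden angle
(δ ≈ 137.5°), and deviations from that spiral carry information about both
organ initiation at the meristem and what happens to the pattern afterwards.
This package implements the full measurement-to-inference chain:

* **Divergence-angle statistics** — chirality assignment from per-step
  rotation directions (strict majority; ties discarded), normalization of
  world-frame angles into each plant's own spiral frame, 2D binning of
  consecutive angle pairs (angle *i* vs angle *i + 1*) into heatmaps with a
  3-bin golden-angle window, per-plant window fractions, M-shaped motif
  detection (the triplet signature `δᵢ ≥ 202.5°, δᵢ₊₁ > 180°, δᵢ₊₂ ≥ 202.5°`
  of an organ-order permutation), per-leaf-pair rosette profiles and
  extreme-angle fractions.

* **Stem-torsion displacement model** — axial twisting of the stem carries an
  organ along an arc, displacing its divergence angle by

  δf = δi + s · tan(α) · I / r · 180/π   (mod 360)

  where α is the torsion angle per internode (counterclockwise positive),
  *I* the internode length (mm), *r* the local stem radius (mm), and
  s = +1 / −1 for counterclockwise / clockwise spirals. A seeded generative
  simulator builds in-silico inflorescence populations from this model
  (per-position internode distributions, quadratic radius profile,
  per-internode torsion draws) and sweeps internode and torsion scales.

* **Statistics harness** — chirality-stratified divergence-vs-internode
  binned regression (the slope estimates ±(180/π)·tan(α)/r in deg/mm),
  Welch's t, Wilcoxon rank-sum, ANOVA + Tukey, two-proportion z-tests with
  Yates continuity correction, Benjamini–Hochberg adjustment, and growth
  metrics (plastochron, bolting, height-synchronized elongation).

* **Bulk-segregant filter** — mapping a recessive EMS allele from two-pool
  sequencing: in a BC1F2 design the expected wild-type allele frequency at
  the causal locus is 2/3 in the phenotype-negative pool and 0 in the
  phenotype-positive pool (and (2 − c)/3, c at map distance d with Haldane
  recombination c = ½(1 − e^(−2d))). The filter chain keeps biallelic,
  non-parental variants with per-pool depth in [10, 500], phenotype-negative
  WT frequency in [0.30, 0.90] and phenotype-positive WT frequency < 0.05.

Synthetic-data generators emulate the statistical structure of measured
plants and pools, so every stage runs end to end without external data.

## Worked example

Simulate a strongly twisting mutant (counterclockwise torsion 3.2°), quantify
its phyllotactic regularity and recover the torsion signal from the
chirality-split regression:

```r
library(phyllotorsion)

tab <- generate_inflorescence_dataset(genotype_preset("tor2_t56i"),
                                      n_plants = 100, n_organs = 31, seed = 11)
res <- run_regress(tab, internode_bin_width = 0.5, min_per_bin = 4)
res$CW
#> <div_intern_fit> CW: slope -2.184 deg/mm (SE 0.160), r = -0.916, p = 7.74e-16, 38 bins (2010 pairs)
res$CCW
#> <div_intern_fit> CCW: slope 2.243 deg/mm (SE 0.222), r = 0.869, p = 1.28e-11, 35 bins (831 pairs)
```

Clockwise plants show a negative slope and counterclockwise plants a positive
one — the signature of one shared counterclockwise torsion acting on both
spiral handednesses — and the magnitudes agree with the model's closed form
(≈ (180/π)·tan(3.2°)/r deg/mm for stem radii r of 0.4–1.0 mm).

A noisier mutant-like population loses golden-window regularity:

```r
tab <- generate_inflorescence_dataset(genotype_preset("plt"),
                                      n_plants = 50, n_organs = 25, seed = 11)
q <- run_quantify(tab, bin_width = 22.5)
q$grid
#> <bin_grid2d> 22.5 deg bins (16 x 16), 1150 pairs; golden window [101.25, 168.75): 73.4% of pairs
```

i.e. 73.4% of consecutive angle pairs have both members within one bin of the
golden angle (per-plant fractions in `q$window_fractions`).

And the bulk-segregant filter isolates a planted recessive variant:

```r
pools <- generate_bsa_pools(seed = 11)   # 30-plant pools, mean depth 100
run_bsa(pools)$candidates[, c("chrom", "pos", "ref", "alt",
                              "wt_af_minus", "wt_af_plus")]
#>   chrom      pos ref alt wt_af_minus wt_af_plus
#> 7  Chr1 12500004   C   T    0.728972          0
```

The single surviving candidate is the planted causal variant, with the pool
allele frequencies a recessive BC1F2 design predicts.

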