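---
title: "Models and methods: divergence angles, stem torsion and bulk-segregant filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: divergence angles, stem torsion and bulk-segregant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllotorsion)
```

This vignette is the package's own account of the science it implements: the
measurement model for phyllotactic regularity, the stem-torsion displacement
model and its simulator, the statistics harness, and the bulk-segregant
filter — together with the numerical choices, parameter defaults and known
limitations a user should understand before trusting an analysis.

## The measurement model

### Angles, chirality, normalization

A plant's phyllotaxis is recorded as an ordered series of divergence angles
(degrees in [0, 360)), one per consecutive organ pair, measured in a single
fixed world rotation sense viewed from above. Plants spiral either clockwise
(CW) or counterclockwise (CCW); the chirality of a plant is the **strict
majority** of its per-step rotation directions (`assign_chirality()`), and an
exact tie makes the plant *ambiguous* — it is discarded from every
chirality-stratified analysis rather than guessed at.

Because a golden-angle step on a CCW plant reads as 360 − 137.5 = 222.5° in a
CW measurement frame, angles are reflected into each plant's own spiral frame
before any pooled statistic (`normalize_divergence()`): for a plant opposing
the measurement sense the angle becomes (360 − x) mod 360. The reflection is
an involution, and 0° is its fixed point. Pooled heatmaps use normalized
angles; this is what gives a single mode near 137.5° instead of two
chirality-split modes.

### 2D binning and the golden window

Regularity is summarized by binning consecutive angle *pairs*: the bin of
angle *i* indexes the row and the bin of angle *i + 1* the column of a square
count matrix (`bin_pairs()`). Bin centers sit at integer multiples of the bin
width starting at 0°, with half-open intervals [c − w/2, c + w/2). Three
widths are in routine use: 22.5° (inflorescences), 12.5° (rosettes) and 6.25°
(meristems).

Two numerical choices deserve note:

* **Non-tiling widths.** 360 is not an integer multiple of 12.5 or 6.25. The
  grid therefore carries ⌈360/w⌉ centers and the leftover arc just below 360°
  folds into the bin centred on 0°. The irregularity affects only the
  immediate neighbourhood of 0°/360°, never the golden-angle region; for
  widths that do tile 360 exactly the rule coincides with circular
  nearest-center assignment, which the test suite verifies against a
  brute-force oracle on 10^5 random angles.
* **The golden window** is defined by one rule at every width: the bin
  containing 137.5° plus one neighbour on each side. That single rule yields
  [101.25°, 168.75°) at 22.5°, [118.75°, 156.25°) at 12.5° and
  [128.125°, 146.875°) at 6.25° — the same three ranges whether one labels
  the window by its outer bin centers or its outer edges. The per-plant
  regularity statistic (`window_pair_fraction()`) is the fraction of
  consecutive pairs with **both** members inside the window.

### M-shaped motifs

A permutation in the initiation order of two organs leaves a characteristic
triplet in the angle series: swapping the azimuths of organs k and k + 1
turns (d, d, d) near the golden angle into roughly (275°, 222.5°, 275°). The
detection criterion is a triplet with angle i ≥ 202.5°, angle i + 1 > 180°
(strict), angle i + 2 ≥ 202.5°, scanned greedily left-to-right without
overlap (`flag_m_motifs()`). The filter is applied **only** in the
divergence-vs-internode analysis, where a permuted pair would attach wildly
wrong angles to its internodes; binning heatmaps keep all angles, because
there the motif is part of the pattern being described.

## The stem-torsion displacement model

Organ positions set at the meristem are modified after initiation by axial
twisting of the elongating stem. A torsion of α degrees per internode acting
over an internode of length *I* on a stem of local radius *r* carries the
upper organ along an arc of length I·tan(α), i.e. an arc angle of
tan(α)·I/r **radians** (the model's only unit subtlety: the arc-angle term is
converted to degrees before being added). In the plant's own spiral frame the
displacement is signed by chirality:

δf = δi + s · tan(α) · I/r · 180/π (mod 360), s = +1 (CCW) / −1 (CW)

so one world-frame torsion direction (counterclockwise, say) pushes CW
spirals to smaller normalized angles and CCW spirals to larger ones. This
sign convention is what produces the chirality-split, opposite-slope
divergence-vs-internode regressions, and it makes three exact properties
available to the test suite: zero-torsion identity, linearity in *I*, and
antisymmetry under chirality or torsion-sign flips.

### The population simulator

`simulate_population()` draws, per inflorescence: a chirality
(Bernoulli(0.5) by default — how a simulated plant acquires handedness is a
modelling choice, not a measurement), 30 initial angles δi ~
Normal(137.5°, sd), 30 internode lengths from per-position truncated normals
(negative draws are **rejected and redrawn**, not clamped, so the shape near
zero is preserved), per-position radii from a quadratic profile, and one
torsion angle per internode from Normal(α̅, sd). Each inflorescence consumes
its own RNG stream derived from the master seed, so populations are
bit-reproducible and insensitive to evaluation order.

Parameter defaults (`preset_torsion_params()`), chosen once as field-typical
values — the fitted experimental distributions behind the original analysis
are not published as tables:

| parameter | wild-type-like | mutant-like | units | basis |
|---|---|---|---|---|
| δi mean | 137.5 | 137.5 | deg | golden angle |
| δi sd | 10 | 17 | deg | package default |
| internode means | 15 → 2, linear | ×1.35 | mm | basal-long → apical-short; default |
| internode sd | 20% of mean | same | mm | package default |
| radius profile | quadratic 1.0 → 0.4 over 30 positions | same | mm | package default |
| torsion mean | +0.6 (CCW) | +0.6 | deg | measured value |
| torsion sd | 0.3 | 0.3 | deg | package default (no published sd) |
| population | 101 × 30 internodes | same | — | matches the original simulations |

The torsion-mutant presets in `genotype_preset()` carry measured torsion
means of +1.7°, +3.2° and −1.1°. One torsion draw **per internode** (rather
than one per plant) is adopted; it weakens within-plant angle correlation
relative to a per-plant draw, a consequence noted but not resolved here.

`sweep_parameters()` rescales the internode means and the torsion mean over a
grid, reusing the base seed in every cell so cells differ only through the
scales. Along the torsion axis the golden-window fraction decreases
monotonically (zero torsion is maximal); with internode length doubled under
counterclockwise torsion the CW subpopulation's modal bin moves toward 90°
and the CCW one toward 180° — apparent "alternative patterns" generated
purely post-initiation.

## The statistics harness

`divergence_vs_internode()` pairs each divergence angle with the internode
**separating its two organs** (the geometrically meaningful pairing for the
displacement model, which the generators also use), optionally removes
M-motif triplets (all three angles of a flagged triplet are excluded), bins
internode lengths (0.1 mm bins with ≥ 4 pairs per bin at inflorescence
scale; 0.01 mm and ≥ 2 at meristem scale — both exposed as parameters), and
regresses per-bin mean angle on bin-center length by unweighted OLS — the
regression is fit to bin means, as such data are plotted, with raw-pair
regression available as an option. Bins are unweighted because occupancy
weighting is an open choice; the slope estimate is unbiased either way.
Under the displacement model with constant radius the slope has the closed
form ±(180/π)·tan(α)/r deg/mm, which the test suite recovers within 3
standard errors at 10^4 simulated internodes for α from 0.3° to 3.2°.

Group comparisons use Welch's t (unequal variances) for normal groups,
Wilcoxon rank-sum otherwise, ANOVA + Tukey for multiple normal groups;
proportions use two-proportion z-tests with Yates continuity correction
(with the degenerate equal-boundary case 0/n vs 0/n defined as p = 1);
families of comparisons are Benjamini–Hochberg adjusted. Tails are a
required argument — the harness never infers a testing direction from the
data. BH is monotone and order-preserving but **not** idempotent
(re-adjusting adjusted values can only raise them), so adjusted p-values are
never fed back through the adjustment.

`growth_metrics()` reduces organ-count/height time series to a plastochron
(elapsed days per organ initiated over a stated organ range), bolting day,
leaves at bolting, and an elongation rate after re-zeroing time at the first
observation ≥ a synchronization threshold (so plants bolting on different
days are comparable).

## The bulk-segregant filter

A recessive EMS allele is mapped by sequencing two BC1F2 pools: a
phenotype-positive pool (homozygous mutants only) and a phenotype-negative
pool (wild-type plus heterozygous). At the causal locus the expected
wild-type allele frequency is 0 in the positive pool and 2/3 in the negative
pool; at map distance d (Haldane recombination c(d) = ½(1 − e^(−2d)), i.e. a
no-interference assumption) the expectations relax to c and (2 − c)/3, both
tending to the unselected 1/2.

`filter_candidates()` applies the chain: biallelic only (multi-allelic
records are dropped, not decomposed), not in the backcross parent (exact
chrom/pos/ref/alt match), per-pool total read depth within the inclusive
window [10, 500] (the stricter per-pool reading of a depth window; a
`depth_mode` flag switches to per-allele), negative-pool WT frequency within
the inclusive [0.30, 0.90], positive-pool WT frequency strictly below 0.05.
Zero-depth variants are excluded with a reason rather than erroring.
Tightening any threshold can only remove candidates (monotonicity, tested).

### Resolution of the filter, and the generator's halo

The strict positive-pool cutoff does not isolate a point: with 30-plant
pools (60 chromosomes) and read depth near 100, a non-causal marker at
distance d passes with probability roughly
E[P(Binom(100, n_wt/60) ≤ 4)] with n_wt ~ Binom(60, c(d)) — about one half
at d = 5 cM, ~10% at 10 cM, negligible only beyond ~25 cM. The filter
therefore defines a **linkage window**, and a single-candidate outcome
requires the causal region to be clean of other segregating variants.
`generate_bsa_pools()` consequently keeps a default exclusion halo of
0.25 Morgan between the causal variant and any other simulated SNP
(`causal_halo_morgans`, reducible to probe the linkage window itself),
placing the remaining EMS-like SNPs (C→T/G→A, the EMS spectrum) uniformly
over a five-chromosome map and simulating each BC1F2 individual as two
recombinant gametes under Haldane linkage, followed by Poisson depths and
binomial allele counts. With the defaults the filter recovers the planted
variant as the *only* candidate in ≥ 99% of seeds (tested over 200 seeds).

## What the generators emulate — and what they do not

The synthetic tables reproduce the statistical structure the analyses
assume: golden-angle spirals with genotype-dependent initiation noise, rare
decussate episodes (alternating ~90°/~180° runs, per-plant probability 0.10
in the mutant-like preset), organ-swap M-motifs satisfying the detection
criterion by construction, basal-long → apical-short internode profiles,
quadratic radius decay, chirality-dependent torsion displacement, raw
world-frame angles with per-step directions (so chirality assignment and
normalization are exercised end to end), and BC1F2 pool allele-frequency
structure. Rosette convergence uses a damped-oscillation form
δn = 137.5 + A·e^(−λ(n−1))·cos(πn + φ) + ε with A = 42.5 and φ = π so the
first pair sits near 180° (the first two true leaves arise nearly opposite);
λ = 0.65 (wild-type-like) vs 0.35 (mutant-like) encodes slower convergence.
Only the qualitative ordering (mutant noisier and slower-converging) is
calibrated; no published oscillation amplitudes exist to match.

They do **not** emulate: meristem hormone dynamics, any mechanical origin of
torsion (cortical microtubule arrays enter only as the numeric torsion
parameter), measurement error of protractor or image-based angle reading,
sequencing error or mapping artefacts in the pools, or environmental
covariates. Passing tests on synthetic data therefore demonstrate that the
*inference chain is correct under its own model*, not that the model captures
every feature of real plants; with real measurement tables the same entry
points (`read_measurements()`, `run_quantify()`, `run_regress()`,
`read_pool_vcf()`, `run_bsa()`) apply unchanged.

## Degenerate inputs and edge rules

* Fewer than 2 angles: window fraction is refused (undefined, signalled).
* Fewer than 3 surviving internode bins: regression refused.
* Chirality tie → ambiguous → plant dropped with a message, never silently.
* Angle exactly on a bin edge: belongs to the upper bin (half-open
  intervals); 137.5° itself is a bin center at 12.5° and 6.25° widths and
  falls in the 135° bin at 22.5°.
* Extreme-angle cutoffs (110°, 165°) and the positive-pool frequency cutoff
  (0.05) are strict; the negative-pool window [0.30, 0.90], the depth window
  [10, 500] and the M-motif 202.5° comparisons are inclusive.
* SEM at a leaf-pair index observed in one plant is NA, not 0.

## Problem sizes used in the shipped checks

The test suite exercises: 10^5 random angles for the binning oracle, 10^4
simulated internodes per torsion level for regression recovery, populations
of 101 × 30 (the standard simulation size) for sweep monotonicity, 500
plants for the decussate-rate calibration, and 200 seeds for the
bulk-segregant recovery property; the whole suite runs in well under a
minute on one core.

## Known limitations

* Regression of angle on internode length treats angles as linear quantities;
  this is safe near 137.5° but would need circular regression if
  displacements approached ±180°.
* The simulator draws torsion per internode independently; real stems twist
  with serial correlation along the axis.
* The BSA model omits sequencing error, so the positive-pool frequency at the
  causal locus is exactly 0; real data would show a small error floor, which
  the 0.05 cutoff tolerates but the generator does not produce.
* Presets marked "package default" are modelling choices, not measurements;
  analyses of real data should fit their own internode, radius and torsion
  parameters (`fit_radius_profile()` is provided for the radius).
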