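---
title: "Classifying snow-derived invaders and colonists in soil microcosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying snow-derived invaders and colonists in soil microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(microcolonize)
library(dplyr)
```

## The experimental system

Snowmelt deposits airborne and snow-adapted bacteria into the soil beneath.
The microcosm design this package analyses mimics that process: soil
columns receive melted snow (treatment arms) or sterile water (control
arms) at controlled rates, and snow, soil and flow-through (FT) communities
are sequenced along a fixed schedule — field sampling (`DS`), microcosm
set-up (`D-10`), experiment start (`D0`), then `D5`, `D9`, `D14` (last day
of input), `D20` and `D29`. Arms come in triplicate; with four arms per
experiment the design has `microcosms_per_experiment(4, 3) = 12` columns
per experiment set. Day labels are categorical and ordered (`day_levels()`)
so `DS` and `D-10` sort before `D0`; `day_offsets()` holds numeric
positions for plotting only.

A design utility converts snowmelt rates into pump volumes:
`melt_rate_to_volume(rate, inner_diameter_mm)` is
$\mathrm{rate} \times \pi (d/2)^2 / 1000$ ml/day, rounded half-up to one
decimal. The column inner diameter is not a measured quantity of the data
but a design parameter; the default of 30 mm is the unique round value for
which the two standard design volumes both come out right
(9 mm we/day → 6.36 → 6.4 ml/day; 35 → 24.74 → 24.7). Both the diameter
and the rounding convention are exposed as arguments.

## The classification chain

The scientific core is a presence/absence argument over the time course.
Let $S$ be the set of ASVs detected in any snow sample, $C$ the set
detected in any control-microcosm sample, and $P$ the set detected in any
soil sample from the pre-treatment days (`DS`, `D-10`, `D0`, both arms).
Then:

* **candidate pool** $= S \setminus (C \cup P)$ — snow-derived material
  that cannot be explained by the resident soil community or by
  contamination of the controls;
* **invader** (per experimental unit) — a pool member detected in that
  unit's treated soil on ≥ 1 post-start day (`D5`–`D29`);
* **potential colonist** — an invader detected on ≥ `min_days` (default 2)
  distinct post-start days, pooled over replicates;
* **potentially successful colonist** — a potential colonist also detected
  on the final day (default `D29`) in any replicate.

Two deliberate readings are built in. First, detection gaps do not
disqualify: a taxon seen on `D5` and `D29` only is still a successful
colonist, because taxa can fall below the detection threshold and
reappear — abundance fluctuation is expected of new community members, and
abundance *trends* play no role in any status. Second, "detected in the
control microcosms" is read broadly as any compartment of a control
microcosm, including its flow-through; the narrower soil-only reading is
available via `include_control_ft = FALSE`, since control FT detections
could alternatively be viewed as plumbing artefacts.

The pool is computed dataset-wide and classification is per unit, so one
ASV can be a colonist of several units. `D0` counts as pre-treatment: a
detection there means the taxon was in the soil before any snow was
delivered.

The detection rule itself (`presence_matrix()`) is count ≥ threshold, with
threshold 1 by default — "identified" simply means present in the ASV
table. The threshold is a parameter because deeper-sequenced datasets may
warrant a stricter rule. One subtlety, found while testing: the invader
count is only guaranteed monotone in the threshold **with the pool held
fixed**. Recomputing the whole chain at a higher threshold also shrinks
$C$ and $P$, which can admit new pool members and occasionally *increase*
the invader count. The package therefore lets you pass a precomputed
`pool` to `classify_colonists()`, and the invariant tests pin the pool at
the base threshold.

For replicate-level inference (`replicate_colonist_counts()`), the same
definitions are re-applied *within* each replicate separately — a
replicate's colonist must recur within that microcosm. This is one of
several defensible readings of a per-replicate count (the pooled
definitions do not dictate one); it is the strictest and makes replicates
independent units for the one-way ANOVA in `colonist_counts_anova()`.

## Preprocessing decisions

Contaminant identification (`filter_contaminants_prevalence()`) scores
each ASV's 2×2 presence table (negative controls vs true samples) with the
one-sided exact hypergeometric tail probability of seeing at least the
observed number of negative-control detections. At desk scale the exact
tail is preferable to the chi-square approximation that reference
implementations fall back on for larger counts, and it is what the test
suite can verify by brute-force enumeration (all margins ≤ 12). The
classification threshold defaults to 0.1, the conventional default of
prevalence-based contaminant screening; an ASV detected *only* in
negatives is a contaminant regardless of score. Kit and sequencer blanks
are pooled as one negative batch — per-batch scoring would need batch
labels the metadata schema does not carry.

Control-abundance curation (`curate_control_abundance()`) discards ASVs
whose *mean relative abundance* is strictly higher in laboratory controls
than in other samples. Means of relative abundances (rather than maxima,
or raw counts) make the comparison robust to the large depth differences
typical between blanks and real samples.

Rarefaction curves use the closed-form hypergeometric expectation
$E[S_d] = \sum_i (1 - \binom{N-N_i}{d}/\binom{N}{d})$, computed on the log
scale for stability at sequencing depths — no resampling noise, exact
monotonicity, and a 10,000-draw Monte-Carlo cross-check in the tests.

## Community statistics

Bray–Curtis, PCoA, PERMANOVA and the dispersion test are implemented from
first principles (vegan serves only as an independent oracle in the test
suite):

* **PERMANOVA** partitions the Gower-centered matrix
  $G = -\tfrac12 J D^{(2)} J$ sequentially (Type-I): term SS are successive
  differences of $\mathrm{tr}(H_k G)$ over nested hat matrices, so term
  order is the user's formula order, matching the order-dependent
  semantics of the classical implementations. p-values use the add-one
  estimator $(1 + \#\{F^* \ge F\})/(1 + N)$ — a permutation p of exactly 0
  is impossible — with a seeded generator for bit-reproducibility, or
  exhaustive enumeration of all $n!$ permutations for $n \le 8$.
* **Dispersion homogeneity** embeds samples by PCoA, keeping
  negative-eigenvalue axes as imaginary components whose squared
  contributions subtract from the distance to the group *centroid*
  (centroids, not spatial medians — the choice is logged in the result and
  medians would be a natural extension), then permutes group labels of the
  distances under a one-way F.
* **PCoA** reports negative eigenvalues but applies no Cailliez/Lingoes
  correction, and drops those axes from the coordinates.
* **Shannon diversity** is in nats, the ecology-package convention.
* Factorial ANOVA (`anova_sequential()`) and Tukey HSD wrap `stats::aov`
  and `stats::TukeyHSD`; sequential SS is exactly base R's decomposition,
  so re-implementing it would add nothing but risk. Aliased terms are
  rejected by an explicit rank check instead of being silently dropped.
  `tukey_hsd(n_families = m)` multiplies Tukey-adjusted p-values by the
  number of response families screened (capped at 1) — an unusual but
  conservative combination used when qPCR, richness and diversity are
  tested side by side.

Bray–Curtis is a semimetric; the triangle inequality is not guaranteed and
deliberately not asserted anywhere.

qPCR normalisation is
$\mathrm{copies/rxn} \times (V_\mathrm{eluate}/V_\mathrm{template}) /
\mathrm{denom}$, with the denominator in grams of soil or millilitres
filtered.

## The simulator: what it emulates, and what it does not

`simulate_microcosm()` generates the post-denoising state of such an
experiment: an ASV count table, metadata, qPCR quantities and per-taxon
ground truth. Choices, with rationale:

* **Background communities** are log-normal rank-abundance draws per
  compartment (`sdlog` 1.5), compositionally stable across days up to
  small multiplicative jitter — snow communities in particular cluster
  tightly over a month-long course. Defaults of 300 soil, 120 snow and 30
  shared taxa give realistic detection sparsity at the default depth
  without inflating runtime.
* **Depth** is fixed at 30,114 reads per sample (the study-scale average)
  by exact multinomial sampling; depth variance is orthogonal to the
  classification logic and off by default.
* **Planted invaders** (default 20) arrive in treated soils on `D5`,
  persist to each subsequent sampled day with probability
  `survival_prob` per replicate (death is permanent — a Markov chain whose
  final-day latent survival is $s^k$ over the $k = 4$ remaining sampled
  intervals, the property the tests check against a binomial tolerance),
  and are never latently present in control arms or pre-treatment soils.
  Multinomial sampling can only remove detections, so observed data obey
  the same exclusion. Washout under fast flow is emulated by lowering
  `survival_prob`, encoding "pushed out by higher flow" as a testable
  parameter. The base latent relative abundance of 1e-3 puts a planted
  taxon around 30 expected reads at full depth: reliably detected when
  present, yet far from dominant.
* **Detection probability** thins a planted taxon's presence per sample
  before sampling, emulating capture losses; at 1 (the default) recovery
  of the planted truth through the full pipeline is exact, which is the
  package's end-to-end acceptance surface (`truth_confusion()`).
* **Contaminants** (5 taxa) dominate the two lab-control samples and leak
  into true samples sporadically at trace abundance, giving the
  prevalence filter a realistic target.
* **qPCR** draws log-normal copies per unit around compartment means —
  40.2 copies/ml for snow (the study-scale figure), with soil (1e7/g) and
  FT (1e4/ml) set orders of magnitude higher as observed in such systems;
  FT copies spike five-fold on `D5`, a qualitative stand-in for the
  washout of relic DNA and unattached cells. The spike magnitude is not a
  calibrated quantity.
* **Truth labels** are derived from the realized latent trajectories
  pooled over replicates, using the same day-counting rules as the
  classifier, so truth and calls are directly comparable at every noise
  level.

What the simulator does **not** model: percolation physics, nutrient
pulses, pH chemistry, taxon interactions, variable depth, or snow
community drift (configurable but off). Passing recovery tests therefore
show that the *classification logic* is faithful to its definitions under
the stated noise model — not that the pipeline is robust to every
pathology of real amplicon data.

## Numerical conventions

* Printed-volume rounding is half-up (half away from zero), matching the
  design volumes above; base R's `round()` rounds half to even and would
  not.
* Hypergeometric tails come from `phyper` on the log-safe
  parameterisation; rarefaction binomials via `lchoose`.
* One-way F statistics treat sums of squares below a relative tolerance of
  1e-12 as zero, so numerically constant responses give F = 0 rather than
  0/0 noise; the fully degenerate all-zero dispersion case is reported as
  such (`degenerate = TRUE`) rather than as a number.
* All permutation procedures take a seed and are bit-reproducible;
  `simulate_microcosm()` restores the RNG state afterwards
  (`withr::with_seed`).

## Problem sizes in the test-suite and acceptance runs

The suite validates on simulations of 40–120 background taxa, depths of
300–30,114 reads, triplicate arms and the full eight-day schedule; the
permutation-test calibration uses 500 null datasets of 10 samples at 199
permutations; the contaminant-score enumeration covers all 2×2 tables with
margins ≤ 12; power of the replicate-count ANOVA is estimated over 100
seeded runs with planted rates of 10 vs 2 invaders. These sizes were
chosen so each property is measured with useful resolution while the whole
suite stays quick enough to run habitually.

## Known limitations

* Type-I (sequential) SS only; marginal (Type-III) tests are out of scope.
* The dispersion test permutes distances to fixed centroids rather than
  re-estimating centroids per permutation (the classical default); for
  balanced designs the difference is small.
* No Chao1/Faith's PD, NMDS or db-RDA; no frequency-based (concentration)
  contaminant mode — only prevalence.
* Taxonomy is annotation only; no sequence-level analysis of invaders.
* BIOM input supports the JSON flavour via the biomformat package.
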