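---
title: "Methods: CITE-Seq antibody titration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CITE-Seq antibody titration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`citetitrate`: what each pipeline stage computes, what the synthetic-data
generator emulates, and where the design was genuinely open and a choice
had to be frozen.

# The experiment being analyzed

A whole antibody panel (192 oligo-tagged antibodies: 188 against surface
targets plus 4 isotype controls) is titrated on human PBMCs in a single
sequencing run. The cell material is split into four tubes, each stained
with the full panel at one concentration — 2x, 1x, 0.2x or 0.04x of the
manufacturer-recommended amount — then hashed with a tube-specific hashtag
oligonucleotide (HTO), pooled, and processed through a droplet protocol
that records three feature classes per droplet: gene expression (RNA),
antibody capture (ADT) and multiplexing capture (HTO).

The analysis must answer, per antibody: at which concentrations is the
target detectable, and what is the lowest concentration with no loss of
staining quality? Aggregated over the panel, that yields an optimized panel
and its antibody-amount saving.

# Pipeline stages and their rules

## Droplet quality control (`run_qc`)

Four independent filters; a droplet is kept iff it passes all of them and
is an HTO singlet:

* viability: mitochondrial UMI fraction strictly greater than 0.10 removes
  the droplet (zero-RNA droplets are removed too);
* staining quality: total ADT strictly below 200 or strictly above 100,000
  removes it (boundaries kept — the rules are strict inequalities, a frozen
  reading since inclusive boundaries are equally defensible);
* hashtag call: max hashtag count at or below 20 is *negative*; otherwise
  max/mean strictly above 3 is a *doublet*; otherwise a *singlet* of the
  arg-max hashtag (ties broken at the lowest index for determinism);
* an optional external doublet-flag vector stands in for a
  transcriptome-based doublet caller, which this package deliberately does
  not reimplement.

Removal attribution follows the fixed order viability → staining →
doublet → HTO-negative, so the QC report is reproducible; a droplet failing
several filters is counted once. The kept *set* is order-invariant (the
tests assert this).

## Normalization

ADT counts are centered log-ratio transformed per droplet over all panel
features, `clr_i = ln(x_i + 1) − mean_j ln(x_j + 1)` — the pseudocount-one
centered form, frozen because popular toolkit variants differ (e.g.
geometric mean over positive entries only) and reproducibility matters more
than the variant choice. Column-wise centering removes per-droplet ADT
depth. RNA uses the standard `ln(1 + 10000 · x / depth)` transform.

A consequence worth noting: CLR is *compositional*. When total ADT depth
rises with concentration, the CLR of an already-saturated antibody can
stay flat or even fall. Dose–response slopes on the CLR scale are therefore
positive only where saturation has not set in — the tests assert positive
slopes exactly for the antibodies whose detection floor is at 0.2x or
above.

## Two-component mixture (`fit_population_model`)

The workhorse for gating and thresholding is a univariate two-component
Gaussian mixture fitted by EM:

* **homoscedastic fit.** With free variances, the maximum-likelihood
  2-component fit of a skewed background distribution is often a split of
  the background itself (narrow core + wide tail component), which masks a
  genuinely separated small positive population. A shared (pooled) variance
  makes that solution unattractive while leaving real splits intact.
* **separation.** Ashman's D is computed from the per-component *empirical*
  standard deviations of the assigned values, not from the shared fitted
  variance: the fitted variance is a fitting device and would hide the
  widening of a heterogeneous (sub-saturated) positive population — the
  very signal that distinguishes "works at this dilution" from "degraded".
* **initialization.** Three deterministic quantile initializations
  (25/75, 50/99 — for rare upper populations — and 1/50) plus ten seeded
  random restarts; the best log-likelihood wins. No global RNG state is
  consumed or left behind.
* **degenerate input** (all values numerically identical) returns a
  zero-separation fit rather than an error.

## Gating (`derive_gate_thresholds`, `assign_major_type`)

Per arm and marker, the threshold is the **minimum-misclassification
boundary**: the point between the component means where the weighted
component densities cross (midpoint fallback when either component has
fewer than 20 cells or the fit is degenerate). The original experiment set
these gates manually on biaxial plots, i.e. in the valley between the
populations; the density crossing is the automated equivalent. A rank-based
percentile of the negative population was rejected for gating because it
leaves a fixed share of negative cells above it *by construction*, which
systematically inflates rare populations (a B-cell gate at the negatives'
95th percentile absorbs ~5% of all non-B cells — roughly doubling a 4.9%
population).

The hierarchy is the literal reading of the biaxial scheme: CD3+ cells
split by CD4/CD8; CD3− cells into CD19+ B, then CD14+CD16− classical
monocytes, then CD14−CD56+ NK. Double positives and contradictory
combinations are conservatively "remaining" and excluded from downstream
analyses. CD16 is thresholded like the other markers even though it only
serves as an exclusion gate.

## Thresholding and detectability (`call_detectability`)

Per antibody and arm, on the CLR values of all gated major-type cells of
that arm (detectability is a per-antibody call; per-type positivity is a
separate metric):

1. If at least `u_min = 0.9` of cells exceed the isotype background (the
   95th percentile of the pooled isotype-control CLR values of the same
   arm), the antigen is **ubiquitous**: no negative population exists,
   whatever internal structure the mixture found, and the threshold is the
   5th percentile of all values (`positive5`). This rule is evaluated
   first: an EM split *within* an all-positive population must not
   masquerade as a negative/positive split.
2. Otherwise, a **clear split** requires Ashman's D ≥ `s_min = 2` (the
   classical bimodality cut), positive fraction ≥ `f_min = 0.005` (so
   antigens confined to rare types — classical monocytes are 2.6% of
   cells — remain callable), and a positive-component mean at least
   `min_above_background = 0.4` CLR units (≈1.5-fold) above the isotype
   background. The threshold is the 95th percentile of the
   negative-component values (`negative95`). The background-margin clause
   exists because discrete low-count background (ambient means well below
   one count per antibody at 0.04x) splits into "zeros" and "ones"
   components with arbitrarily large D; its upper component sits *at* the
   isotype ceiling, whereas any genuine positive population clears it by
   whole CLR units. Without this clause the isotype controls themselves
   would be called detectable, which is contradictory by definition.
3. Otherwise the antigen is **not detectable** at this concentration.

Binarization is strict: a cell is positive iff its CLR is strictly above
the threshold (thresholds are the *upper limits* of negative populations).
Manual overrides replace individual thresholds and are marked as such.

## Panel optimization (`select_optimal_concentration`)

Optimal is the lowest-factor arm that is detectable and retains at least
`q_frac = 0.8` of the antibody's best separation across arms. Two frozen
interpretations:

* the quality reference is the **best** separation across detectable arms,
  not the 1x separation: with a 1x reference the criterion is vacuous at 1x
  (any value retains 100% of itself) and the 2x class would be unreachable
  for antibodies detectable at 1x — yet antibodies that need 2x are
  precisely those whose 1x separation is degraded relative to 2x;
* the criterion applies only to `negative95` calls: separation is
  undefined for a ubiquitous antigen, whose optimal is simply its lowest
  detectable arm.

Isotype controls are always retained at 1x (they are the background
yardstick and are not titrated). The relative antibody amount is
`Σ factor(class) / n_panel` with weights 2 / 1 / 0.2 / 0.04 / 0; amounts
are reported to 2 decimals and percent differences to integers, with full
precision kept internally.

# The synthetic-data generator

The generator produces droplet-level data under the study conditions: four
arms at factors 2 / 1 / 0.2 / 0.04, 2000 droplets per arm, cell types drawn
from the 1x composition (B 4.9%, CD4 T 52.1%, CD8 T 12.1%, CM 2.6%, NK
14.1%, remaining 14.2%), and a 192plex panel with 4 isotype controls.

## Ground truth: detection floors and optimal tiers

Each antibody carries two distinct truth attributes, because per-arm
detectability and optimal concentration are different quantities: 124
antibodies are detectable at 1x but only 76 are *best* at 1x. The **floor**
is the lowest detectable arm, with marginals chosen to reproduce the
per-arm detectable totals 64 (0.04x) / 116 (0.2x) / 124 (1x) / 124 (2x);
the **tier** is the optimal class with marginals 8 / 33 / 76 / 7 (plus 64
undetectable). The joint split (e.g. how many tier-1x antibodies have floor
0.04x) is not constrained by any printed total; the default plan fixes it
as 43 / 32 / 1 across floors 0.04 / 0.2 / 1 for tier 1x, and 13 / 20 for
tier 0.2x, which satisfies both marginals. Expression categories (16
antigens in all five types — three of them ubiquitous, CD45-like — 21
exclusive to B, 17 to CM, 5 to NK, the rest in fixed multi-type subsets
covering at most ~75% of cells) are assigned deterministically so sharing
analyses have exact ground truth.

## Signal model

The mean ADT signal of antibody $a$ in an expressing cell at concentration
factor $c$ is a steep saturation-binding curve

$$\mu_a(c) = S_{max}\,\frac{c^h}{c^h + K_a^h},\qquad S_{max}=500,\ h=5,\ K_a = \mathrm{floor}_a/1.2 .$$

The steep Hill exponent encodes avidity/cooperativity of bivalent antibody
binding and — more importantly for the design — makes the signal *collapse*
just below the floor arm while staying saturated at it. A plain hyperbolic
curve cannot produce detectability loss on dilution at all: with signal
$\propto c/(c+K)$ and ambient background $\propto c$, the
signal-to-background ratio $S/(b(c+K))$ *rises* as $c$ falls, so separation
would only improve. Detectability loss on dilution is fundamentally a
small-count phenomenon, and the steep curve is what brings the counts down.

Below an antibody's *tier* arm, staining is sub-saturating and
heterogeneous: each expressing cell's signal is multiplied by an efficiency
drawn log-uniformly from (0.02, 0.5). This spreads the positive population
evenly across the log-intensity range — the smeared ridge a titration
experiment actually shows at insufficient concentration — degrading
separation (and hence the quality criterion) without flipping
detectability. The log-uniform form matters: a linear-uniform draw
concentrates mass at the top of the range and barely widens the population
on the log scale.

Ambient background is 8 counts per antibody at 1x, scaled linearly with
$c$ (free-antibody encapsulation). All ADT and RNA counts are negative
binomial with size 6 — strongly overdispersed relative to Poisson
(CV ≈ 0.4 at saturation) while keeping the positive populations coherent;
at size 2 the lower tail of a saturated positive population reaches any
sensible gate and per-type recall collapses.

## Hashtags, doublets, negatives

Hashtag counts are own-signal (NB mean 500, size 200) plus a per-droplet
ambient floor on *every* hashtag (NB mean 90, size 30). Ambient hashtag
material scales with droplet volume, not cell number, so a same-arm doublet
doubles its own-hashtag signal but not its ambient floor — that is what
lifts its max/mean ratio above 3 while singlets stay below. Two
consequences are documented rather than hidden: (i) with only four
hashtags, a max/mean rule *requires* a substantial ambient floor — with
near-zero off-target counts a clean singlet has ratio ≈ 4 and would be
called a doublet; (ii) cross-arm doublets (available behind a flag for
stress tests) have two high hashtags and *lower* their ratio, so a max/mean
rule cannot detect them; the sensitivity property tested refers to same-arm
doublets, which is also the default chemistry (hashing happens per staining
tube before pooling).

HTO-negative droplets (2%) have all hashtags at mean 4; doublets are 5% of
droplets; 3% of cells draw their mitochondrial fraction from a
low-viability Beta(8, 32) component (mean 20%) instead of the viable
Beta(3, 80) (mean ≈ 3.6%). RNA gives each major type 10 exclusive marker
genes (NB mean 30 in-type vs 0.05 out-of-type) over 50 housekeeping genes
and 10 mitochondrial genes, so transcriptome-side marker finding is
exercisable.

## What the generator does and does not establish

The recovery experiments show that the pipeline's rules — mixture
thresholding with the isotype yardstick, crossing-point gates, the
lowest-sufficient-concentration rule — reconstruct a known design from
realistic droplet-level noise: detectable counts per arm, optimal-class
counts, composition, sharing categories and doublet flags are all recovered
within small tolerances on the default configuration (see
`tests/testthat/`). They do not certify performance on real data: the
generator draws types from a fixed composition (no clustering structure
beyond markers), has no ambient-RNA contamination, no empty droplets, no
batch or donor effects, no UMI collisions, and its dose–response family is
a single parametric form per antibody. The observed ADT depth ratios across
arms are an emergent property of the saturation-plus-linear-background
model and are only qualitatively comparable to a real experiment (rising
above 1 at 2x, far below proportional at 0.04x); they are deliberately not
fitted to any particular measured values.

# Problem sizes and runtime

The default configuration (8000 droplets, 192 antibodies, 4 arms, 120
genes) runs the full pipeline in roughly two minutes on one core; the
dominant cost is the 768 mixture fits of the thresholding stage. The test
suite shares one cached default run across recovery tests. These sizes are
the package's chosen defaults — matching the emulated experiment's ~2000
cells per arm — not a constraint of the method; `generator_config()` scales
everything.

# Known limitations

* The "clearly separated" judgment is operationalized as Ashman's D ≥ 2
  with an isotype-background margin; the original judgment was visual and
  has no unique numeric equivalent. `threshold_params()` exposes all cuts,
  and sensitivity to `s_min` should be examined rather than assumed.
* The 95th/5th-percentile thresholds inherit a built-in error rate at the
  binarization stage (~5% of negative cells exceed a negative-population
  95th percentile by construction); per-cell antigen counts are accordingly
  biased upward by a few false positives per cell, exactly as in the
  original thresholding scheme.
* The dose–response fit (least squares on per-arm mean CLR under a log
  link, means clipped at zero) is a display-grade characterization, not an
  inference procedure; CLR compositionality caps slopes of saturated
  antibodies near zero.
* `percent_correctly_identified` is undefined for a type absent at 1x
  (reported as missing, not infinity).
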