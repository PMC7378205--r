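---
title: "Methods: miniaturized C. elegans screening analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miniaturized C. elegans screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nemascreen` implements the analytics of a miniaturized, liquid-culture
*Caenorhabditis elegans* screening platform with two readouts:

1. **Vital Nile red fluorescence** as a proxy for fat stores. Nile red fed
   with the bacterial diet accumulates in the worms' lysosome-related
   organelles and fluoresces strongly in that lipid-rich environment; the
   readout is the total white-pixel area ("fluorescent units") of a
   binarized, masked micrograph of a single worm.
2. **Survival (DT50)** — the day at which half of a well population is
   dead. DT50 rather than full lifespan keeps observation times short and
   adds a toxicity pre-screen for free.

Extracts are scored per concentration: a significant drop in Nile red
fluorescence together with a significant DT50 extension is the top
category (*dual-active*); a significant DT50 reduction is *toxic*.

The package also ships a synthetic-data module. It is first-class, tested
code: it generates ground-truth micrographs and simulated plate and
survival experiments with the statistical structure the analysis assumes,
so every downstream stage is validated offline without microscope data.

# Image quantification chain

For each single-worm RGB TIFF:

1. `to_grayscale()` — 8-bit luminance conversion (BT.601 weights).
2. `classify_pixels()` — per-pixel worm/background decision by a pruned
   decision tree over texture features.
3. `remove_small_regions()` — delete every connected region smaller than
   3,000 px (bacteria, debris); a region of exactly 3,000 px is retained.
4. `normalize_image()` — affine brightness/contrast standardization of the
   grayscale original.
5. `apply_mask()` — multiply the surviving mask into the normalized image.
6. `binarize_default_threshold()` — isodata (intermeans) threshold computed
   on the mask interior; pixels strictly above the threshold are white.
7. `quantify_fluorescence()` — fluorescent units = white-pixel count.

## Classification and normalization are parallel branches

The classifier sees the *unadjusted* grayscale original; the normalized
image is the photometric reference that the surviving mask is multiplied
into. This is a deliberate design choice with a concrete payoff: the
normalization's affine coefficients depend on global image moments, so any
bright object anywhere in the frame shifts every normalized value. Had
classification run on the normalized image, sub-threshold artifacts
outside the worm would perturb boundary pixels of the worm mask and hence
the measurement. With the split design, and because the isodata rule is
equivariant under affine intensity maps with positive gain, adding
artifacts below the size filter changes the measured units by exactly
zero. The test suite asserts this bit-exact invariance.

## Normalization targets

The normalization targets default to mean 1.2 and SD 6.6 *in percent of
the full 8-bit range* (3.06 and 16.83 on the 0-255 scale): a very dark
background with a narrow stretched band, the regime a fluorescence
micrograph of one bright worm is pushed into before measurement. The pair
of dimensionless targets is not tied to a unique intensity scale, so the
scale convention is declared and configurable
(`normalization_spec(scale_convention = "percent" | "intensity")`), and
the achieved pre-clipping moments are recorded as attributes for audit.
Because the final threshold is computed on mask-interior values only and
is affine-equivariant, the measured units are insensitive to this
convention; it matters only for interoperability of intermediate images.

## Texture features and the classifier

The default feature vector per pixel is the raw intensity plus local
Shannon entropy (bits) of the 32-bin intensity histogram over circular
windows of radii 2, 4 and 8 px (`feature_spec()`). Entropy carries the
texture contrast — the speckled worm body has high local entropy, the
smooth background low — and is computed by per-bin indicator convolution,
with windows clipped at the image border. The radii are a deliberately
minimal pyramid around the named entropy feature; they are configurable,
and the window radius used by any given analysis is recorded in the model
object.

The classifier is a CART decision tree with the entropy (information)
split criterion and cost-complexity pruning (via cross-validated `rpart`),
i.e. a pruned axis-aligned tree of the C4.5 family. Training subsamples
pixels per image, stratified by class so a small worm is not swamped by
background, and is deterministic given images, masks and seed. The tree
and its feature specification serialize to a single file and reload with
identical predictions.

A texture classifier cannot locally distinguish a bright bacterial clump
from a bright organelle focus — both are small, bright, speckled blobs.
That is precisely why the pipeline's size filter exists: artifact regions
are *expected* to be classified as worm and are deleted because they are
smaller than 3,000 px. Accuracy is therefore assessed after size
filtering.

## Numerical choices

* Connected components use 8-connectivity (configurable to 4), implemented
  in-package because the labeling available in the installed image stack
  is 4-connected.
* The isodata iteration starts at the midpoint of the occupied intensity
  range. The intermeans rule can have several fixed points when a dominant
  dark mode coexists with a small bright mode; a mean-start iteration can
  stall inside the dark mode (and noise then decides the basin), while the
  range-midpoint start — the convention of the common "default threshold"
  implementations — lands in the inter-mode gap and is stable. The
  returned threshold always satisfies the fixed-point equation, which the
  tests verify against an exhaustive 256-candidate scan.
* Tie-break at the threshold: pixels strictly greater than T are white.
* Masked-out zeros are excluded from threshold computation; including them
  would make the threshold a function of worm size rather than intensity
  structure.
* If more than one region survives the size filter, all are kept and a
  warning is emitted; an optional largest-region mode exists. Automated
  hygiene must not silently drop signal, so dropping is never the default.
* Pixel coordinates are row-major throughout; images are 0-255 numeric
  arrays in memory and 8-bit TIFFs on disk.

# The synthetic micrograph generator

`generate_worm_image()` renders one curved worm — a random heading-walk
backbone with slowly varying curvature and an elliptically tapered width
profile — carrying punctate bright foci inside the body, on a noisy dark
background with optional small bright artifacts. Defaults: 256×256 px,
8,000 px body at intensity 70 with speckle SD 12, foci at intensity 210
with speckle SD 20, background 12 with noise SD 3, artifacts ≤ 400 px at
0.9× focus intensity. The rendered body area is matched to the configured
target *from above* (within [A, 1.05 A]) by bisecting a global width
scale, so a worm configured at the minimum legal area (3,000 px) always
survives the size filter. Foci share the artifacts' speckled texture: as
argued above, local indistinguishability of foci and bacteria is a feature
of the domain, and the generator preserves it.

Two ground-truth channels are recorded. The worm mask is the rendered
body. The true fluorescent units are defined *operationally*: the
measurement chain (normalize, mask with the true mask, isodata binarize,
count) applied to the noise-free rendering. Pushing the noise-free image
through the pipeline with an ideal mask therefore recovers the truth
exactly — a real plumbing check of normalization, masking and
thresholding, not a tautology on stored noise.

Artifacts are drawn from an RNG stream seeded independently of the
worm/noise stream, so two configs differing only in `n_artifacts` are
bit-identical outside the artifact pixels; and they are placed with a
20 px clearance around the worm so that no texture window straddles worm
and artifact. Without that clearance the exact-invariance property could
not hold, because entropy windows near the worm boundary would see
artifact pixels.

What the generator does **not** emulate: point-spread functions,
vignetting, autofluorescence gradients, partial-volume (soft) worm edges,
touching or overlapping worms, or focal drift. Passing tests therefore
demonstrate correctness of the measurement chain under the generator's
assumptions, not robustness to every optical artifact of a real
microscope; on real data the classifier would be retrained on
hand-labelled pixels exactly as the in-silico one is trained on truth
masks.

# Survival analysis

`simulate_survival()` draws per-worm death times from a Weibull
distribution parameterized by its median and shape. The Weibull covers the
exponential (shape 1) through sharp-threshold regimes and is the standard
parametric family for worm survival; treatments scale the median
multiplicatively. Defaults: control median 10 d at 25 °C, shape 4 (death
times concentrated around the median, as worm survival curves are
sigmoidal), 5-18 worms seeded per well, triplicate wells, observations
three times a week (days 2, 4, 7 of each week) after the day-0 baseline.

`build_survival_curves()` produces per-well fractions alive (condition
level pools wells weighted by worm counts). `estimate_dt50()` returns the
exact observed day if a fraction sits at 0.5, otherwise linearly
interpolates between the bracketing observations; curves that never reach
0.5 are censored (flagged, never a number). Interpolation avoids the
±1-observation-day quantization of a step rule; the step rule is available
as a sensitivity mode. Extension is the literal percentage formula
100·(treated − control)/control on mean DT50s, computed from full
precision (published tables that round means to two decimals can disagree
with their own extension column in the last digit, which is why the
worked-example checks carry a 0.2-point slack).

The replicate unit for statistics is the well; the screening design uses
nine wells per condition — three parallel experiments of triplicate wells,
which is also what reconstructs the published per-condition worm totals
(roughly 100-140 worms at 5-18 per well). Testing is one-way ANOVA
followed by Dunnett's many-to-one comparisons against the vehicle control
(multivariate-t, equal variances, via `multcomp`); the multivariate-t
integration is evaluated under a locally fixed RNG state so identical
inputs give byte-identical results. Worms lost mid-assay are the caller's
responsibility to remove from `n_total` from that day forward; the
validator enforces monotone alive counts.

# Nile red plate statistics

Per-worm fluorescent units are log-normal in the simulator (areas are
strictly positive and right-skewed) with a per-worm coefficient of
variation of 0.3 by default — substantial worm-to-worm spread in staining
and body size. The analysis aggregates to condition means per independent
experiment, normalizes each experiment to its vehicle control (= 100%),
and reports cross-experiment mean ± SD over at least three experiments.
Statistics run on experiment-level values only; worms are never pooled
across experiments, which would pseudo-replicate.

Because the normalization pins the control at exactly 100% with zero
variance, a pooled ANOVA contrast that includes the control underestimates
the error and inflates false positives (a Monte-Carlo null puts its
family-wise error well above nominal). The calibrated form of "each
condition versus control" under this normalization is a contrast against
the constant 100 whose error is the within-condition variance pooled over
the non-control conditions; raw p-values from that t statistic are
Bonferroni-adjusted over the family of all non-control conditions,
p_adj = min(1, m·p_raw), with significance tiers at 0.05/0.01/0.001. The
test suite verifies family-wise error control by simulation. Whether wells
or worms are the replicate unit *within* one experiment is not pinned by
the assay description; the package aggregates worms within an experiment
(wells enter through the plate map) and treats the experiment as the unit
of inference, the conservative reading.

# Hit calling

Per extract × concentration, effect flags are derived from the post-test
adjusted p-values at α = 0.05 and the effect directions. The category
table is total over all flag combinations:

| lifespan | fat | evaluable | category |
|---|---|---|---|
| reduced* | any | any | toxic |
| not reduced* | any | no | not_evaluable |
| extended* | reduced* | yes | dual_active |
| not extended* | reduced* | yes | fat_reducer |
| extended* | not reduced | yes | lifespan_extender |
| otherwise | | yes | inactive |

(* = significant.) Toxicity takes precedence: a drastically
lifespan-shortening extract is reported as toxic even when its
fluorescence could not be read. A fat *increase* is not a hit category in
this screen and maps to inactive. "Not evaluable" is triggered when fewer
than half of a condition's imaging wells contain at least one living worm
on the imaging day (day 5 of treatment) — a numeric rule standing in for
the narrative "most worms were already dead"; the 50% threshold and the
imaging day are configurable in `screen_config()`.

# Validation problem sizes

The shipped validation uses: 3 training + 20 assay micrographs at
256×256 px spanning worm areas 3,000-20,000 px (mask IoU and
units-vs-truth correlation); 100 random histograms and 100 random masks
against exhaustive oracles; 200 replicate simulations of a 1.4× lifespan
effect at 3 wells × 50 worms (recovered extension within [30, 50]%);
2,000-replicate Monte-Carlo nulls for both post-tests' family-wise error;
and 50 seeded end-to-end screens with one planted dual-active extract
(0.5× fluorescence, 1.4× lifespan) among eight. These sizes were chosen as
the smallest that make the stochastic checks statistically meaningful.

# Known limitations

* The normalization targets' intensity scale is a documented convention,
  not a certified setting of the original analysis; the measured units are
  insensitive to it, intermediate images are not.
* The entropy-filter radius of the original analysis is unknown; the
  default pyramid {2, 4, 8} is a reasonable minimal choice.
* Exact replication of a particular published screen's per-extract
  verdict counts would require the underlying raw data; the planted-effect
  simulations cover that logic qualitatively instead.
* The simulator draws worms-per-well uniformly over the stated range and
  has no between-experiment (batch) variance component beyond sampling
  noise; real plates show day effects that the per-experiment
  normalization absorbs only partially.
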