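---
title: "Models and methods behind phenodrought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenodrought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodrought)
```

phenodrought re-implements, as a tested and reusable pipeline, the analysis
of a high-throughput drought phenotyping trial on a conveyor-type imaging
platform: a diversity panel (by default 60 chickpea genotypes, balanced for
the *desi* and *kabuli* market types) grown in two experiments with two
biological replicates per genotype and treatment, imaged daily over DAT
1–42 (days after transfer), with drought imposed from DAT 8 by lowering the
plant-available water (PAW) target from 70% to 10%, re-watering in two
steps (a fixed 300 mL on DAT 29, back to 70% PAW from DAT 30), and
photosystem-II measurements on DAT 6, 13, 20, 27 and 34. This vignette
documents the models, the conventions that were genuinely open choices, the
numerical decisions, and what the synthetic-data generator does and does
not emulate.

## Image-derived traits

Each imaging event produces one top view and three side views. After HSV
segmentation against a uniform low-saturation background, five traits are
computed:

* **Estimated biovolume (EB, voxels).** With $s$ the mean of the three
  side-view silhouette areas and $t$ the top-view area (pixels),
  $\mathrm{EB} = \sqrt{s^2\,t} = s\sqrt{t}$. This is the unique reading of
  the platform convention with volume-like dimensionality (area × length);
  it is invariant to permuting the side views and scales as $k^3$ when all
  images scale by $k$. EB is rescaled to $10^{-5}$-voxel reporting units
  exactly once, at the reporting layer (`scale_eb()`), so that a panel-mean
  biovolume prints as, say, 85.1 rather than $8.51\times 10^6$.
* **Plant height (PH, mm).** The vertical foreground extent of a side
  view times the mm-per-pixel scale; across the three views the maximum is
  taken — a plant's height is its tallest silhouette. (The platform
  convention does not specify the aggregation; the maximum is the choice
  here.)
* **Mean colour value (MCV, hue).** The mean HSV hue of plant pixels in
  the top view, on $[0,1]$; a healthy green canopy sits near 0.23. A
  20-bin hue histogram is returned alongside. Grayscale pixels (saturation
  0) have no defined hue and are excluded. Two MCV conventions are
  implemented — per-pixel mean (default) and histogram-weighted bin
  centres — because platform documentation leaves this ambiguous.
* **Colour ratios (r2g, y2g).** Pixels are classified by hue: red
  $[0°,30°) \cup [330°,360°)$, yellow $[30°,75°)$, green $[75°,165°)$.
  The boundaries are configurable; these defaults make a healthy canopy
  give r2g on the ~0.005 scale. The ratios are pixel-count ratios
  red/green and yellow/green (`ratio_mode = "to_green"`); fractions of all
  plant pixels are available as `"of_total"` because the field's naming
  ("ratio" vs "percentage of pixels") is used inconsistently.

Segmentation is plain HSV thresholding with an optional
largest-connected-component filter; the package deliberately does not
reproduce a machine-learned or platform-internal segmentation pipeline.

## The watering model

PAW is a two-point linear scale on pot weight: the weight at substrate
field capacity is 100%, at the permanent wilting point 0% (the published
substrate calibration constants are not restated in the trial reports, so
the linear two-point model is an explicit assumption, with both calibration
weights exposed in the configuration). A balance-watering station can only
add water: the daily amount raises the pot exactly to the target weight, or
is zero if the pot is at or above target; 1 mL ≡ 1 g. The DAT-29 recovery
event is a fixed 300 mL volume, not a PAW target.

## Mixed models: outliers, variance components, heritability, BLUEs

All statistics operate per DAT × treatment × trait slice of the long trait
table.

* **Outlier screening** fits genotype as fixed and experiment and
  genotype × experiment as random (lme4 REML), and flags observations with
  absolute standardized conditional residual above 3. The threshold and the
  single-pass (no re-fitting) convention are documented assumptions: the
  trial reports state only that the mixed model was used. Conditional
  residuals are shrunken (cell size two), so clean 240-observation slices
  essentially never produce false flags at threshold 3, while a 10-SD
  contaminant stands out; a contaminant can additionally swamp its
  replicate partner in the same genotype × experiment cell, which the audit
  table makes visible. Flags are propagated to the irrigation records
  before water-use computations.
* **Variance components** treat genotype, experiment and their interaction
  as random. The default backend is lme4 REML whose derivative-free
  optimum is then polished by average-information REML iterations
  (analytic gradients, Fisher scoring with active-set handling of the zero
  boundary, written in `ai_reml_polish()`); the polish sharpens the optimum
  from ~1e-6 to ~1e-10 so that on balanced slices the estimates coincide
  with the closed-form expected-mean-squares (EMS) ANOVA estimators to
  numerical identity. The EMS closed form (`ems_variance_components()`) is
  boundary-aware: a negative experiment or interaction estimator pools its
  stratum into the next one, which is the exact non-negativity-constrained
  solution for balanced layouts. Negative components are truncated at zero
  and flagged. The polish is applied for slices up to 1200 observations
  (it builds dense covariance matrices); beyond that the lme4 optimum is
  used as is.
* **Broad-sense heritability** is
  $H^2 = V_G / (V_G + V_{G\times E}/n_{exp} + V_e/(n_{rep}\, n_{exp}))$,
  reported per DAT and treatment.
* **BLUEs** (genotype fixed; experiment and genotype × experiment random)
  feed all downstream analyses. For a fully balanced slice the
  generalized-least-squares solution equals the plain across-experiment
  genotype mean regardless of the variance components, so the default
  `method = "auto"` uses that exact shortcut and falls back to REML
  whenever outlier removal or missing days unbalance the slice. The tests
  assert the equality of both routes on balanced data and check the
  unbalanced route against a small-matrix GLS oracle.

## Derived traits

* **Relative growth rate**: $(\ln v_i - \ln v_{i-1})/(d_i - d_{i-1})$ on
  consecutive BLUE days after linear interpolation of internal gaps. The
  excluded days (DAT 1 in experiment 1, DAT 14 in experiment 2) affect one
  experiment each, so the BLUE for those days is computed from the other
  experiment; only genuinely missing internal days are interpolated. DAT 1
  has no left flank, and interpolating it is an error by contract.
  Telescoping holds exactly: phase-summed RGR equals
  $\ln(\mathrm{EB}_{end}/\mathrm{EB}_{start})$.
* **Drought loss**: $(1 - \mathrm{trait}_{drought}/\mathrm{trait}_{control})
  \times 100$, computed on panel-mean BLUEs for headline values and per
  genotype for ranking. Negative losses mean the stressed value exceeds the
  control, as for the senescence colour ratios.
* **Phase water-use efficiency**: the drought phases are DT (DAT 8–28),
  DR (29–42) and DA (8–42), endpoints inclusive. WUE is the difference of
  the EB BLUEs (reporting scale) between the phase's last and first day,
  divided by the irrigation summed over the phase after per-genotype,
  per-DAT averaging across replicate plants; a phase sum of exactly zero
  milliliters is replaced by 1 mL so stressed plants that received no water
  keep a defined (large) WUE.
* **CV** is the sample ($n-1$) standard deviation over the mean, in
  percent; the convention is configurable because the source formula
  ($\sigma/\mu$) does not specify the denominator.
* **ΦPSII plasticity** is the low-light over high-light operating
  efficiency ratio.

## Panel analysis

Deviations are genotype BLUE minus the panel mean, per treatment and day or
phase (they sum to zero by construction and are translation-equivariant).
The selection screen uses ten criteria: EB at the last drought day and the
last experiment day, and WUE in DT, DR and DA — each in both treatments.
Tier 1 ("better than mean") requires a strictly positive deviation on every
criterion of the focal treatments; tier 2 ("superior") requires it on every
criterion in both treatments. Ties (deviation exactly zero) fail, a
deliberate strict-inequality convention; genotypes with a missing criterion
are excluded and flagged, and the full pass/fail matrix is returned so any
relaxation can be audited. Group comparisons (market type, biological
status) run one-way ANOVA with Tukey HSD and 95% confidence intervals; the
two-group case runs through the same path. Trait correlations are Pearson
over genotype BLUEs in a window; the PCA standardizes per-genotype phase
means to unit variance before decomposition because the traits carry
incommensurate units (voxels, mm, hue, ratios).

## The synthetic-data generator

The generator defines the study conditions under which every stage is
verified.

**Trait tables.** EB follows daily logistic growth,
$B_{t} = B_{t-1}\exp\{r(1 - B_{t-1}/K)\,m(t) - s(t)\}$, with
$B_0 = 2\times10^5$ voxels, $r = 0.139$/day and $K = 5\times10^8$ voxels.
Under drought the multiplier $m(t)$ decays from 1 towards 0.58 with a
6-day time constant, a senescence term $s(t)$ ramps in after 12 days of
stress (maximum 0.10/day, 2-day ramp), and after the second re-watering
step both relax back at 0.35/day. These values were fixed once, at design
time, so that the panel-mean trajectory reproduces the canonical stress
pattern the pipeline must handle: control near 85 and drought near 18.5
(reporting units) on the last drought day — a ~78% biovolume loss — with
the drought RGR dipping slightly negative under advanced stress and growth
resuming after re-watering. $K$ is set high enough that the control panel
stays in the quasi-exponential regime through DAT 42; a strongly saturating
panel would make late biovolume gains anti-correlated with plant size, an
artefact that would distort water-use-efficiency rankings. PH is allometric
in EB ($3.5\,B^{0.25}$ mm). MCV, the colour ratios and ΦPSII follow
piecewise-linear stress-response anchors (see `default_color_anchors()`):
r2g near 0.005 control vs 0.013 drought and y2g near 0.029 vs 0.069 at the
last drought day, MCV rising ~6% under advanced stress, ΦPSIIh dipping ~7%
and ~20% after 13 and 19 days of stress, all relaxing after re-watering.

Genotype effects are phase- and treatment-specific: each genotype draws
independent log-scale multipliers of the growth rate (SD 0.10) and of daily
water use (SD 0.12) for the stress window and the recovery window of each
treatment, plus a shared vigour term (SD 0.05) and per-trait effects for
the colour and ΦPSII traits. Experiment, genotype × experiment and residual
noise are added at the observation level — multiplicative on EB, PH and the
colour ratios (keeping them positive and RGR well defined), additive and
clipped on MCV and ΦPSII. Every genotype and every plant owns a hash-derived
random substream of the master seed, so subsetting the panel never
reshuffles the draws of the remaining genotypes, and a fixed seed gives
byte-identical output.

"Planted" superior genotypes are constructed deterministically: +2 SD on
every growth axis and −2 SD on every water-use axis. The acceptance
property asks that such genotypes are recovered into the top selection
tier in at least 95% of panels. Exact set equality (no extra tier-2
genotypes) is *not* a realistic demand at panel scale: the ten selection
criteria are arithmetically linked (EB at DAT 42 accumulates EB at DAT 28;
the DA-phase water budget is the sum of the DT and DR budgets), so an
unplanted genotype with a lucky draw on a few latent axes passes all
criteria with non-negligible probability — about one extra tier-2 genotype
per 60-genotype panel under the default parameters, which mirrors how real
panels yield a handful of all-round superior genotypes rather than zero.
The audit matrix makes such extras inspectable.

**Watering records** are simulated closed-loop against the irrigation
targets: daily water loss is evaporation (15 g/day) plus transpiration
(0.6 g/day per reporting-unit EB), throttled below 30% PAW by stomatal
closure, with per-genotype water-use multipliers and lognormal day-to-day
noise. Control pots are restored to exactly 70% PAW at every watering.
Drought pots draw down slowly enough that the 10% target almost never
binds — they receive essentially no water during the stress phase, so the
zero-irrigation 1 mL rule governs the drought DT WUE, reproducing the
regime where stressed WUE exceeds control WUE by two orders of magnitude.
A consequence worth noting: simulated drought pots level off near 20–35%
PAW rather than exactly 10%, i.e. the stress signal in the generator is
time-keyed, not PAW-emergent.

**Rendered images** are rectangle "billboards": a top-view rectangle whose
red/yellow/green pixel counts realise the requested colour ratios and mean
hue, and three identical side rectangles whose width and height realise the
requested biovolume and height. Quantization to integer pixels means the
achieved traits differ slightly from the request, so the generator returns
the exactly achieved values (from the rendered pixel counts) as ground
truth; extraction must then agree exactly on EB, PH and the colour ratios,
and within half a histogram bin on MCV (8-bit PNG rounding perturbs hue by
well under that). No leaf-level morphology, occlusion, lighting gradients
or support structures are rendered.

**What passing therefore shows — and does not.** Green tests demonstrate
that every formula, convention and edge rule operates as specified, that
the estimators recover known parameters at the study's design size, and
that the pipeline is deterministic end to end. They do not show that the
generator's trajectories are botanically faithful, nor do they reproduce
the data-dependent statistics of the real panel (its per-day heritability
traces, correlation magnitudes, PCA percentages or named genotype lists),
which depend on the unreleased raw dataset.

## Numerical choices and problem sizes

Tolerances: REML vs closed form 1e-8 (achieved ~1e-13); RGR telescoping
and the 1 mL rule at machine precision; MCV round trip half a bin (0.025).
Degenerate inputs: zero-residual slices are routed to the exact closed
form; singular outlier fits yield no flags with a warning; constant traits
are dropped from the PCA with a warning; a control value of zero makes the
loss undefined rather than infinite. The test and acceptance runs use the
study's design sizes where a property prescribes them — 200 simulated DAT
slices for heritability recovery, 100 panels for the water-use-efficiency
ordering and the selection power, 1000 replicates for the type-I error,
50 rendered image sets — and smaller panels (4–20 genotypes) for
pipeline-level contract checks, keeping the full suite within a few
minutes on one CPU.

## Known limitations

The watering model has no evapotranspiration physics and no
vapour-pressure-deficit coupling; transpiration is a biomass-proportional
heuristic. The renderer's billboard geometry cannot probe segmentation
robustness to occlusion or lighting. The mixed models fit no spatial or
row-column corrections and no pedigree/kinship structure. The outlier rule
is a single-pass threshold on conditional residuals; iterative schemes
would flag differently near the threshold. Genotype effects in the
generator are uncorrelated across phases and treatments by design — real
genetic correlation structures will make the selection tiers more
populated and less specific than the synthetic power results suggest.
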