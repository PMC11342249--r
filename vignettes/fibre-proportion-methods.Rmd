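---
title: "Methods: the long-range fibre proportion and its association with post-stroke cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the long-range fibre proportion and its association with post-stroke cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibreprop)
library(dplyr)
```

## The scientific question

After a left-hemisphere stroke, lesion size and location explain only part of
the variability in aphasia severity and non-verbal cognition. A candidate
source of the remaining variance is the integrity of the white-matter network
*beyond* the lesion, and in particular of long-range association fibres,
which are metabolically expensive and disproportionately vulnerable to
ischaemic injury. `fibreprop` implements a whole-brain structural-connectome
analysis of this hypothesis: it summarises each subject's connectome by the
ratio of long-range to short-range connections and asks how much behavioural
variance that ratio explains beyond established covariates (age, years post
stroke, lesion volume, and damage to behaviourally critical regions).

## From streamline counts to the fibre proportion

The input per subject is a raw region-by-region streamline-count matrix from
probabilistic tractography (any tool; distance correction is assumed already
applied upstream). Three steps turn it into the summary statistic.

**Volume-corrected connectome.** Counts for the two tracking directions are
averaged (diffusion tractography is undirected) and divided by the sum of the
two endpoint region volumes:
$w_{ij} = \frac{(c_{ij} + c_{ji})/2}{v_i + v_j}$.
Self-connections are zeroed.

**Percentile thresholding.** Weights below the subject's 20th percentile are
considered possibly spurious and set to zero. The percentile population is
the subject's *nonzero* upper-triangle weights: including structural zeros
would drive the cutoff to zero for sparse matrices and disable the step
entirely. The cutoff is the nearest-rank order statistic
(`ceiling(p n)`-th of the sorted weights) for exact reproducibility; linear
interpolation is available via `method = "interpolate"`. Removal is strict
("lower than"), so ties at the cutoff survive, and a uniform rescaling of all
weights leaves the surviving support unchanged.

**Distance banding and the ratio.** Euclidean distances between region
centroids are computed for *all* unordered pairs of the atlas, so the band
cutoffs are a property of the parcellation, identical across subjects. Pairs
with distance at or below the first quartile are short-range, above the third
quartile long-range, otherwise medium. Quartiles are the usual
linear-interpolation sample quantiles (`stats::quantile` type 7); with this
convention a unit square's four sides fall in the short band and its two
diagonals in the long band, and a population of 28 distinct distances puts
exactly 7 pairs in each outer band. The summary statistic is

$$\text{proportion of long-range fibres} = \frac{\#\,\text{surviving long-band connections}}{\#\,\text{surviving short-band connections}},$$

a count ratio by default ("number of fibres" = surviving edges); a
weight-sum variant is available with `mode = "weights"`. A subject with no
surviving short-band connection has an undefined ratio and is reported as an
explicit error, never a silent division.

## Lesion-symptom mapping and the key-damage covariate

For each behavioural measure, every candidate region (by default the
left-hemisphere regions, since all lesions are left-hemispheric) is tested
with a simple linear regression of the score on the region's damage fraction.
The test is one-tailed in the negative direction — the working assumption is
that lesions produce worse performance. Regions lesioned in fewer than
`min_affected = 10` subjects are excluded before testing, standard ROI-LSM
practice to avoid degenerate tests; Benjamini–Hochberg FDR at q = 0.05 is
applied across the tested regions only. The per-subject mean damage over the
significant regions is the "key damage" covariate. When no region survives
correction the covariate is undefined and the downstream model drops it —
the analysis of measures with no lesion correlate simply proceeds without a
key-damage term.

## Variance beyond the covariates

Each score is regressed on age, years post stroke, lesion volume and (when
defined) key damage, by ordinary least squares with intercept. The
standardized residuals (residual divided by the residual SD; an internally
studentized variant is available) are then correlated with the fibre ratio.
The squared correlation is reported as $\Delta R^2$, the additional variance
explained by the fibre proportion; two-tailed p-values are BH-corrected
across the family of measures (default: the four measures analysed
together). A one-way ANOVA of the ratio across stroke aetiologies
(ischaemic / haemorrhagic / other) is run first as a confound check;
aetiology groups with fewer than two subjects are merged into "other" with a
warning rather than failing the run.

Two association modes are provided. The default, `"literal"`, is the exact
two-step procedure of saving the outcome residuals and correlating them with
the raw ratio. `"partial"` residualizes the ratio on the same covariates
first, giving the partial correlation. The two coincide when the ratio is
orthogonal to the covariates; otherwise the literal correlation is attenuated
by the ratio–covariate overlap. The exact link is the Frisch–Waugh relation:
with the ratio also residualized,
$r_{\text{partial}}^2 = (R^2_{\text{full}} - R^2_{\text{cov}})/(1 - R^2_{\text{cov}})$,
which the test suite verifies numerically.

## The synthetic cohort generator

No public dataset accompanies this analysis, so the package ships a
first-class generator whose defaults encode the study conditions the
pipeline is meant to handle:

* **Cohort structure**: n = 87; age ~ N(60.5, 11.2) truncated to 21–80;
  years post stroke 1 + Gamma (mean ≈ 3.9, wide spread); aetiology sampled
  in 57:23:7 proportions, sex 52:35.
* **Atlas**: mirrored hemispheric boxes on an MNI-like mm scale (~140 mm
  extent), log-normal region volumes (median ≈ 6 cm³); 10 regions per
  hemisphere by default — large enough for quartile banding and ROI mapping,
  small enough for thousands of simulated cohorts in the test suite.
* **Lesions**: a seed region is drawn preferentially near the left-hemisphere
  centre (`focality_mm = 25`), mimicking the peri-Sylvian concentration of
  middle-cerebral-artery strokes; damage decays around the seed
  (`extent_mm = 45`) with subject severity ~ Beta(1.2, 0.9). These values
  were chosen so that the most-affected regions show cohort mean damage
  around 0.3 with SD around 0.25, the magnitudes clinical per-ROI damage
  tables report; fractions below 0.01 are floored to zero.
* **Connectomes**: expected streamline counts decay exponentially with
  centroid distance (`decay_mm = 40`, `base_count = 3000`), are attenuated
  by endpoint damage, and drawn as overdispersed negative-binomial counts
  (`dispersion = 8`) independently per direction. Overdispersion (rather
  than Poisson) makes the percentile threshold do real work. Long-band pairs
  receive an extra subject-level attenuation
  $\alpha_s = \exp(-\kappa\,\text{load}_s + \varepsilon_s)$, the generative
  counterpart of the heightened vulnerability of long-range fibres. The
  coupling default $\kappa = 6$ was set with care: endpoint damage alone
  preferentially thins *short* local connections (both endpoints sit inside
  the lesion), which pushes the ratio *up* with lesion size; at $\kappa = 6$
  the long-range pathway dominates and the net ratio–lesion-volume
  correlation is approximately zero to slightly negative, as the phenomenon
  being emulated requires.
* **Behaviour**: each score is a linear function of age, years post stroke,
  lesion volume, damage to three planted critical regions, and the
  *measured* fibre ratio, plus Gaussian noise, clipped to its scale (0–100
  for the aphasia-quotient-like score, etc.). Key-region effects are planted
  for the two language measures only, so lesion mapping typically finds
  regions for those and nothing for the semantic and reasoning measures.
  The ratio effect is specified as a target partial correlation: the raw
  coefficient is derived per cohort from the noise SD and the SD of the
  ratio residualized on the covariate design,
  $\beta = \frac{r}{\sqrt{1-r^2}}\,\frac{\sigma_\varepsilon}{\sigma_{e_x}}$,
  so the planted effect lives on exactly the scale the association stage
  estimates. Default targets are 0.33 / 0.25 / 0.30 / 0.40 for the four
  measures.

Everything is deterministic per seed (one cohort seed drives every stage),
and the full generative parameter set is stored as ground truth beside each
cohort.

**What the generator does not emulate.** Centroids are uniform in boxes, not
anatomically arranged; damage follows a smooth radial decay rather than
vascular-territory geometry; streamline counts are conditionally independent
across pairs given damage and attenuation; scores are linear with Gaussian
noise. Passing tests therefore demonstrate that the pipeline measures what
it claims under a known generative model of the right shape — not that the
substantive neuroscience holds in any particular clinical sample.

## Calibration and recovery experiments

The test suite runs the following experiments (sizes chosen to keep the full
suite in the minutes range):

* **Oracle equivalence**: percentile cutoffs, band labels and band counts
  match brute-force enumeration on 200 random instances of up to 15 regions;
  BH flags match an all-thresholds scan on 500 random p-vectors.
* **Null calibration**: over 200 seeded cohorts with no planted ratio effect
  (n = 90), the share of cohorts with any FDR-significant residual–ratio
  association stays near the nominal 5% family-wise level, and ROI mapping
  of pure-noise behaviour flags anything in at most 10% of cohorts.
* **Recovery**: over 100 seeded cohorts with a planted partial correlation
  of 0.40, the mean recovered partial correlation is within 0.05 of truth
  and every generative coefficient is recovered within two Monte-Carlo
  standard errors of its mean. These recovery cohorts generate scores on an
  unbounded scale: clipping to the bounded test range violates the linear
  generative model and attenuates the planted correlation, which is a
  property of bounded scores, not of the estimator. The lesion-mapping
  sensitivity experiment plants three critical regions with a slope of 1.5
  noise-SDs per unit damage on the contiguous lesion model and requires 80%
  recovery; the package's default behavioural coupling is weaker (chosen for
  realistic effect-table magnitudes, not for detection power), so detection
  of the default key regions is not guaranteed at that rate.

## Numerical choices and degenerate inputs

* Nearest-rank percentile for the weight threshold (exactly reproducible);
  type-7 interpolation for distance quartiles; ties: short is inclusive of
  Q1, long exclusive of Q3.
* An all-zero connectome, a constant behaviour vector, a constant covariate,
  a rank-deficient design, an undefined ratio (no short-band survivors), and
  a region set absent from the damage matrix each raise a distinct, located
  error rather than propagating NaN.
* Atlases with all pair distances equal are allowed but warn (every pair is
  then short-range).
* Missing behavioural scores are dropped per measure (complete case), with
  counts logged.
* All numeric CSV output is formatted at 12 significant digits, making
  pipeline reruns with one seed byte-identical.

## Limitations

The ROI-level mapping statistic (per-region regression t on continuous
damage) and the minimum-overlap default of 10 subjects are standard choices,
but field toolboxes differ in their defaults, and results near the
significance boundary can differ accordingly. The literal two-step
association underestimates the partial correlation whenever the ratio
overlaps the covariates; both modes are reported so the difference is
visible. Education is not modelled as a covariate, voxelwise and
connectome-based lesion mapping are out of scope, and the graph-theoretic
repertoire is deliberately limited to the band counts and their ratio.
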