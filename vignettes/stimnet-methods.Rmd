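---
title: "Network embedding of stimulation sites and memory change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network embedding of stimulation sites and memory change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimnet)
```

## The scientific problem

Direct electrical stimulation of the human cortex can enhance episodic
memory, but the behavioral effect varies widely across stimulation sites and
individuals. A network-level account holds that a stimulation site is
effective to the degree that it is *embedded* in the white-matter and
functional architecture of the memory system: stimulation recruits axons
near the electrode, so its influence propagates along structural pathways,
and it translates into better encoding when those pathways converge on the
verbal-encoding network. `stimnet` implements the full analysis chain needed
to test this account, and a synthetic-data generator with planted effects so
that every stage can be validated end to end without patient data.

The chain is:

1. **Structural embedding (ChaCo).** A stimulation site is modeled as a
   sphere (default radius 12 mm). Against a normative tractogram, the
   pairwise ChaCo (Change in Connectivity) ratio of a parcel pair is the
   proportion of its streamlines that intersect the sphere; the cumulative
   ChaCo score of a parcel sums its pairwise ratios over all partners.
2. **Functional embedding.** Seed-based Pearson correlation between the
   site's task time series (mean of parcels whose centroid falls in the
   sphere) and every parcel, averaged over a normative subject panel.
3. **Memory change.** Per session,
   \(\Delta = (R_S - R_{NS})/R_{NS} \times 100\), where \(R_S\) and
   \(R_{NS}\) are average recall on stimulated and non-stimulated lists;
   the first three (never-stimulated) lists are excluded from the baseline
   and sessions below an average of one recalled word per list are
   excluded.
4. **Association maps.** Parcelwise correlation of connectivity with
   \(\Delta\) (Kendall's \(\tau_b\) for the zero-inflated structural
   values, Pearson's r for the near-normal functional values), with
   family-wise error control by max-statistic permutation.
5. **Structure-function congruence.** Dice overlap between the site's
   thresholded cumulative-ChaCo mask and the thresholded encoding-network
   mask; Spearman correlation between per-site Dice and \(\Delta\), swept
   over a 10 x 6 threshold grid with Benjamini-Hochberg FDR.
6. **Path models.** PLS path modeling with bootstrap inference for the
   moderation (connectivity x stimulation mode), mediation (white-matter
   proximity through structural connectivity), and multivariate models.

## Geometric conventions

Coordinates are millimetres in an arbitrary right-handed frame; no template
registration is performed. Streamline-sphere intersection is computed
exactly as the minimum point-to-segment distance over the polyline - a
resolution-free analogue of the voxelized mask intersection used by
atlas-based lesion-network tools, and labeled as such: the two differ only
at the voxel-quantization scale. Pairs with no streamlines have pairwise
ratio 0 by convention; the zero-inflated distribution this produces is the
reason \(\tau_b\) (tie-corrected) is the default structural statistic.
Parcel membership in the seed sphere is decided by centroid distance
(parcel-level, not voxel-level, extraction); when no centroid falls inside
the sphere, the nearest parcel is used. Subject FC maps are averaged on the
raw r scale by default - the plain reading of "averaged across subjects" -
with Fisher-z averaging available as a flag.

## The synthetic-data generator

The generator produces what the real study measures but at desk scale, with
effect structure planted where the study reports it:

* **Atlas.** `generate_atlas()` draws parcel centroids uniformly in a
  140 x 110 x 90 mm box with a minimum separation of 8 mm (60 parcels by
  default; 438 supported).
* **Tractogram.** For each parcel pair a streamline count is zero with
  probability `connection_sparsity` (default 0.5) and otherwise shifted
  geometric with mean `streamline_density` (default 5), giving the
  zero-inflated, overdispersed counts typical of probabilistic
  tractography. Each streamline is a quadratic Bezier with jittered
  endpoints and one random control point (at least 8 vertices), so curvature
  makes the intersection test non-trivial.
* **Task time series.** A shared on/off task boxcar loads on the positive
  encoding-network parcels, plus spatially correlated Gaussian noise whose
  correlation decays exponentially with centroid distance (range 120 mm).
  The long range was chosen so that the distribution of seed-FC values
  across parcels is approximately normal (Shapiro-Wilk not rejected at
  \(\alpha = 0.01\) in well over 90% of runs), the regime in which Pearson
  correlation is the appropriate map statistic. Task regressors are
  deliberately not removed - task-evoked coactivation is the signal of
  interest.
* **Cohort.** Default 39 closed-loop and 22 random sessions, mirroring the
  study composition. Sites are placed near random parcels; white-matter
  proximity is drawn from a gamma distribution coupled to total structural
  connectivity with rank correlation `effect_wmp_sc` (default -0.4, i.e.
  better-connected sites sit closer to white matter).
* **Behavior.** Each session simulates 25 lists x 12 words of Bernoulli
  recall; the first 3 lists are never stimulated and half of the remaining
  22 are. In the closed-loop arm the latent memory change of a site is
  coupled through a Gaussian copula to (i) its Dice congruence with the
  encoding network at the representative thresholds (planted rank
  correlation `effect_sc_memory`, default 0.6) and (ii) baseline recall
  (planted correlation `effect_baseline`, default -0.48); the random arm
  is pure noise around zero. Latent memory change has mean 12.4% and scale
  `noise_sd` = 20 percentage points, chosen so the *observed* closed-loop
  dispersion (~26-28%) matches the published cohort once binomial recall
  noise is added.

Two compensations make the planted values recoverable on the observed
scale, and both are computed analytically in `plan_planted_effects()`:
binomial measurement noise in \(\Delta\) and in baseline recall attenuates
any latent correlation, so the copula coefficients are pre-inflated by the
predicted attenuation; and because \(R_{NS}\) appears in the denominator of
\(\Delta\), sampling error in the baseline induces a negative
baseline-change correlation (about -0.2 under the defaults) even with
nothing planted, so only the remainder of `effect_baseline` is planted. A
requested combination whose implied copula coefficients leave no room for
residual noise raises an "infeasible planted-correlation combination"
error. Residual attenuation from ties in the discrete Dice values is not
compensated; in 200-replicate runs the planted 0.6 is recovered at about
0.55, within the 0.15 tolerance the validation uses.

What the generator does **not** emulate: electrode geometry and bipolar
montages, iEEG signals and the encoding-state classifier, spatial
autocorrelation of recall across lists, word-level effects (serial
position, semantic clustering), and individual reorganization of memory
networks. Passing tests therefore certify the statistical machinery, not
the neuroscience of any particular dataset.

## Statistical machinery

**Max-statistic permutation.** Each permutation reassigns \(\Delta\) across
sites jointly for all parcels (connectivity held fixed, preserving the
inter-parcel correlation structure), recomputes all parcel statistics on
the same scale as observed (\(|\tau_b|\) or \(|r|\), not converted to
t/z), and retains the maximum absolute statistic. Corrected p-values use
the add-one estimator \((1 + \#\{\max \ge |obs|\})/(1 + n_{perm})\), which
never returns zero and is exact-permutation valid; uncorrected p-values
come from each parcel's own permutation distribution, so corrected \(\ge\)
uncorrected holds by construction. Under a global null the family-wise
error rate calibrates to ~0.04 at \(\alpha = 0.05\) (500 replicates).

**Congruence grid.** Ten encoding-network thresholds \(0.1, \dots, 1.0\)
(fractions of positively weighted parcels, ceiling rounding, ties broken
by parcel id) crossed with six structural thresholds. Only the endpoints
0.001 and 50 and the count are fixed by the design being reproduced; the
six values are spaced log-like as {0.001, 0.01, 0.1, 1, 10, 50}, which
contains the representative value 1 (about the 80th-90th percentile of a
site's cumulative scores under the default geometry). Structural
thresholding is strict (score > tau). Degenerate cells - empty or
variance-free Dice vectors - are flagged and excluded from the BH family
rather than given arbitrary p-values.

**PLS path models.** Outer estimation is Mode A (reflective blocks), inner
weighting is the path-weighting scheme, convergence is a maximum outer
weight change below \(10^{-7}\) (at most 1000 iterations; mixed blocks
such as connectivity-plus-proximity can converge slowly and need several
hundred). Latent scores
are standardized and oriented so the majority of each block's loadings is
positive. Structural coefficients are OLS on latent scores; with
single-indicator blocks the engine degenerates exactly (to \(10^{-6}\)) to
standardized OLS path analysis, which is the closed-form oracle used in
testing. Moderation is two-stage: the interaction regressor is the
standardized product of the moderator and predictor scores. Bootstrap
inference resamples observations (5,000 resamples by default), reports
normal-theory p (\(\beta\)/bootstrap SE) alongside percentile intervals,
applies no sign-change correction, and fails loudly if more than 5% of
resamples do not converge. The indirect effect of every two-step chain is
the product of its bootstrap path draws. BIC is the regression BIC
\(n \log(SSE/n) + (k+1)\log n\) of the standardized structural equation of
the endogenous construct - one convention among several for variance-based
SEM, stated here explicitly because the comparison it feeds (mediating
model vs. proximity alone) only needs a consistent definition.

**Behavioral statistics.** Baseline stratification assigns a site exactly
at the 30% threshold to the high group (conservative, since the low group
is the one expected to benefit). The two-sample test is Welch by default;
the pooled test is available because published degrees of freedom for the
low/high contrast imply pooling. Baseline recall used in correlations is
\(R_{NS}\) itself, the same quantity as the \(\Delta\) denominator.

## Problem sizes used in validation

The test suite and the acceptance script run the full pipeline at the
study scale (60 parcels, 39 + 22 sessions) and validate calibration with
500 replicates x 100 permutations (FWER), 400 replicates at 200 bootstrap
resamples (type-I), 120 replicates of the 60-cell grid (FDR), and 200
replicates for parameter recovery. The one-command pipeline
(`run_pipeline("all")`) uses 5,000 permutations and 5,000 bootstrap
resamples, matching the published analysis settings.

```{r, eval = FALSE}
cfg <- pipeline_config()            # default synthetic study
run_pipeline("all", cfg, out_dir = "stimnet_out")
```

## Known limitations and open choices

* The sign printed for the multivariate baseline-memory coefficient is
  ambiguous in the source material; `stimnet` reports the computed sign.
  Likewise a random-arm group summary is printed with inconsistent sign
  (+0.92% with t = -0.20); `one_sample_t()` reports the computed sign.
* A power analysis of the mode-moderation test at the default cohort sizes
  (39 + 22) shows that even a perfectly measured closed-loop-only
  association of 0.6 yields only ~67-70% detection probability at
  \(\alpha = 0.05\); with recall noise and latent measurement the realized
  rate is lower. The moderation test is therefore reported with this
  caveat: at this sample size it is informative but not high-powered.
* The exact voxel-level intersection and per-subject normalization of
  atlas-based lesion-network tools are approximated by the exact segment
  geometry described above.
* No covariance-based SEM (ML fit indices), no missing-data handling, no
  preprocessing of time series (motion, filtering, confound regression) -
  inputs are assumed clean by construction.
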