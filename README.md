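# stimnet

Structural and functional network embedding of brain-stimulation sites,
and its relation to stimulation-linked memory change.

`stimnet` is an R package for the analysis chain used in closed-loop
memory-stimulation studies: intracranial stimulation sites in lateral
temporal cortex are profiled against normative connectivity data, and
those profiles are related to the percent change in free-recall
performance that stimulation produced. It is written for researchers in
network neuroscience and neuromodulation who want the statistical
machinery of this analysis — ChaCo streamline profiling, max-statistic
permutation mapping, Dice structure–function congruence, PLS path models —
as tested, reusable functions, plus a synthetic-data generator that makes
the whole pipeline verifiable end to end.

## The analysis

A stimulation site is a sphere of radius 12 mm. Its **structural
embedding** against a tractogram is measured by ChaCo (Change in
Connectivity): for each parcel pair the ratio of connecting streamlines
intersecting the sphere,

    pairwise[p, q] = (# streamlines between p and q hitting the sphere)
                     / (# streamlines between p and q)

and per parcel the cumulative score `cum[p] = Σ_q pairwise[p, q]`. Its
**functional embedding** is the seed-based Pearson map of the site's task
time series against every parcel, averaged over a normative subject panel.
**Memory change** per session is

    Δ = (R_S − R_NS) / R_NS × 100

with `R_S`/`R_NS` the average recall on stimulated / non-stimulated lists,
the first three (never-stimulated) lists excluded from the baseline, and
sessions below `R_NS = 8.33%` (one word in twelve) excluded.

Connectivity–memory association maps use Kendall's τ-b (structural values
are zero-inflated) or Pearson's r (functional values are near-normal), with
family-wise error control by max-statistic permutation: each permutation
shuffles Δ across sites, recomputes all parcel statistics, and retains the
maximum |statistic|. Structure–function congruence is the Dice overlap
between the site's strong-connectivity mask (cumulative ChaCo > τ) and the
top fraction of the verbal-encoding network, related to Δ by Spearman
correlation and swept over a 10 × 6 threshold grid under BH-FDR. Finally,
PLS path models with 5,000-bootstrap inference quantify moderation by
stimulation mode, mediation of the white-matter-proximity effect through
structural connectivity (with proportion mediated and ΔBIC), and the
multivariate model with mode and baseline memory as simultaneous
predictors.

## Worked example

Simulate the default synthetic study (60-parcel atlas, 39 closed-loop and
22 random sessions, planted congruence effect 0.6 and baseline effect
−0.48) and run the main analyses:

```r
library(stimnet)

cfg     <- synth_config()                       # study conditions
atlas   <- generate_atlas(cfg$n_parcels, cfg$seed)
tract   <- generate_tractogram(atlas, cfg, cfg$seed + 10L)
weights <- generate_encoding_network(atlas, seed = cfg$seed + 20L)
cohort  <- generate_cohort(atlas, tract, weights, cfg)

prof <- attr(cohort$sites, "sc_profiles")       # sites x parcels ChaCo
rownames(prof) <- cohort$sites$site_id
out  <- memory_change(cohort$sessions, cohort$sites)
cl   <- out$mode == "closed" & out$included

one_sample_t(out$delta[cl])                     # group memory change
congruence_association(prof[out$site_id[cl], ], weights, 0.3, 1,
                       out$delta[cl])           # representative thresholds
pearson_r(out$r_ns[cl], out$delta[cl])          # baseline dependence
maxstat_correct(prof[out$site_id[cl], ], out$delta[cl],
                "kendall", n_perm = 2000, seed = 3)
```

This prints (seed 1):

```
closed-loop: mean delta = 13.4% (SEM 3.68), t(38) = 3.63, p = 0.0008
congruence vs delta: Spearman rho = 0.67, p = 3.3e-06 (n = 39)
baseline vs delta: r = -0.33, p = 0.0398
structural map: 3 of 60 parcels FWE-significant
```

i.e. closed-loop stimulation improves recall on average, the benefit is
larger at sites whose structural connectivity is congruent with the
encoding network, poorer-baseline participants gain more, and a few
parcels survive family-wise correction — the planted effect structure,
recovered by the pipeline. The same chain is available as one command,

```r
run_pipeline("all", pipeline_config(), out_dir = "stimnet_out")
```

which writes TSV/CSV artifacts and JSON manifests per stage (subcommands
`simulate`, `chaco`, `fc`, `behavior`, `map`, `congruence`, `plsem`; a
thin CLI wrapper lives in `inst/cli/stimnet-pipeline.R`).

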