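# ppnconn

Seed-based resting-state fMRI functional connectivity for a **multi-voxel
brainstem seed** (the pedunculopontine nucleus, PPN), with the seed signal
learned per subject by partial least squares (PLS).

## The problem and who this is for

The PPN is a small cholinergic brainstem nucleus implicated in gait and
balance impairment in Parkinson's disease. Measuring its resting-state
connectivity is hard: the seed spans a handful of noisy voxels, and
template registration of the brainstem is unreliable, so analysis should
stay in each subject's native space. This package implements, as tested
reusable building blocks, a pipeline for exactly that setting — for
example, studies asking whether galvanic vestibular stimulation (GVS,
stochastic or sinusoidal) modulates PPN connectivity in Parkinson's
disease and how connectivity relates to disease severity (UPDRS) and
medication load (LEDD).

Because subject-level imaging data for such studies are typically not
shareable, the package also ships a synthetic cohort generator with known
ground truth, so every stage — and the pipeline end to end — is testable.

## The method

Per subject and seed side, with `X` the t x 58 ROI-panel time series and
`Y` the t x n seed voxel time series (both cleaned and centered), NIPALS
PLS2 computes

```
X = T P' + E,    Y = U Q' + F
```

with score pairs of maximal covariance. Across subjects, one-sample
t-tests on the first-component loadings `P[,1]` pick the regions that
covary with the seed; the candidate set is the union over left and right
seeds. The first Y-score (first column of `U`) is the subject-specific
representative seed signal — `Q[,1]` acts as a learned spatial filter over
seed voxels. Connectivity per condition is the partial correlation between
the representative signal and each selected region, conditioning on the
other selected regions; *overall connectivity* is the sum of |r| over
significant connections of both sides. Group inference contrasts
stimulation against rest on paired differences, regresses baseline
connectivity on LEDD/UPDRS/assessment-state, and correlates it with UPDRS.

## Worked example

```r
library(ppnconn)

spec <- demo_cohort_spec()          # 23 subjects, planted couplings,
cohort <- generate_cohort(spec)     # stimulation effects, severity link
res <- analyze_cohort(cohort, pipeline_config(spec))
print(res)
```

```
Seed connectivity analysis
  candidate regions (union of both seeds): 19
noisy-rest (overall, n = 23): mean diff 0.5067, t = 1.060, p = 0.3008 (increase)
sinusoidal-rest (overall, n = 23): mean diff 0.5579, t = 1.160, p = 0.2585 (increase)
  severity correlation (rest): r = -0.308, p = 0.153 (n = 23)
  LEDD regression effect: p = 0.9678
  significant per-connection changes:
    noisy-rest left seed ~ ctx-lh-superiorparietal: t = 3.74, p = 0.001124 (increase)
    noisy-rest left seed ~ Left-Thalamus-Proper: t = 5.43, p = 1.89e-05 (increase)
    noisy-rest right seed ~ Right-Thalamus-Proper: t = 3.85, p = 0.0008775 (increase)
    sinusoidal-rest left seed ~ ctx-lh-postcentral: t = 4.25, p = 0.0003302 (increase)
    sinusoidal-rest right seed ~ ctx-rh-precentral: t = 3.65, p = 0.001421 (increase)
    ...
```

Reading this: the 19 candidate regions contain the 6 planted rest
couplings, the stimulus-recruited regions, and a few chance selections;
both stimulation conditions *increase* overall PPN connectivity (positive
mean differences); baseline connectivity falls with disease severity
(negative r); medication load has no significant effect; and the
per-connection contrasts recover the planted stimulus-specific
recruitment (thalamic, superior-parietal, postcentral/precentral) with
the right signs. On synthetic draws the magnitudes fluctuate — the
directions and the recruited-connection hits are the stable, designed-in
signal (the vignette explains why the overall-contrast t is bounded near
2 under this signal model).

The same run is available from a config file, writing
`selection.tsv/json`, `connectivity.tsv`, `overall.tsv`, `contrasts.tsv`,
`regression.json`, `severity.json`:

```r
run_pipeline(system.file("extdata/demo_config.yaml", package = "ppnconn"),
             out = "results/demo")
```

A thin command-line wrapper lives at `inst/cli/ppnconn.R`
(`Rscript ppnconn.R run --config demo_config.yaml --out DIR --seed 1`).

## Documentation

The methods vignette (`vignettes/ppn-connectivity-methods.Rmd`) describes
the model, the estimators, the synthetic-data generator and its
assumptions, the numerical choices, and known limitations.
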