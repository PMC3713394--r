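# stochsig

Stochastic Gamma-plane signatures from wearable accelerometry.

Continuous smartphone accelerometry during daily living yields streams of
maximal deviations from the mean acceleration whose statistics are skewed
and non-stationary.  `stochsig` is for movement scientists and digital-
biomarker researchers who want to track those statistics *as they change*
rather than average them away.  The method:

1. reduce each (X, Y, Z) max-deviation reading to its Euclidean magnitude;
2. fit each consecutive 100-reading **data entry** with the Gamma density
   `f(x | a, b) = x^(a-1) exp(-x/b) / (b^a Γ(a))` by maximum likelihood
   (entries failing a dip test of unimodality at p < 0.01 are discarded);
3. follow the fitted (shape `a`, scale `b`) point on the **Gamma plane**
   in acquisition order — a stochastic trajectory per person;
4. compute the trajectory's speed (Euclidean shift per acquisition step;
   shifts below 0.002 are stochastic rest) and collect the **speed peaks**
   above 1, the Exponential range of the plane;
5. Gamma-fit each person's peaks: that (shape, scale) point is the
   person's **stochastic signature**, and its variance-to-mean ratio (the
   **Fano factor**) equals its scale exactly;
6. analyse the cohort scatter: power-law fit `b = α·a^β`, k = 2 city-block
   k-medians clustering validated against NC/PD labels, regression of PD
   Fano factors on L1 distance to the control centroid, age-on-shape
   regression in controls, and rank-sum group tests.

Low shape / high scale signatures sit in the random, noisy corner of the
plane (late-stage Parkinson's disease); normal aging moves signatures
toward the predictable right side.

## Worked example

The per-participant signature table of the published 15-person cohort
(6 normal controls, 9 Parkinson's patients) ships with the package, so the
cohort stage runs without the original raw streams:

```r
library(stochsig)
rep <- referenceReport(seed = 1)
```

which prints, via the report fields:

```
cohort power fit: a = 6.362, b = -1.908 (R2 0.8942)
NC exponent -1.643, PD exponent -1.955
misclassified: 3 ids: Daisy, Cherry, Dafo
Fano medians: NC 0.78615, PD 6.0915; ranksum p 0.0076
FF-distance slope 0.8600 adjR2 0.9886; age-shape slope 14.20 intercept 22.05
```

Read: scale falls off shape roughly as `a^-1.9` across the cohort, with a
shallower decay (−1.64) among controls; blind k = 2 clustering recovers
the diagnosis for 12 of 15 participants (one control clusters with the
patients, two early-stage patients with the controls); a patient's Fano
factor — the dispersion, hence unreliability, of their signature — grows
almost perfectly linearly with their distance from the control centroid;
and among controls age tracks the signature shape (slope 14.2 years per
shape unit), i.e. normal aging moves people toward more predictable
statistics.

The full pipeline on synthetic data (no real streams required):

```r
cfg <- pipelineConfig(personas = defaultCohortSpec(seed = 1), seed = 1,
                      outDir = "run1")
res <- runPipeline(cfg)   # writes signatures.csv, person_signatures.csv,
                          # cohort_report.json, run.log under run1/
```

Per-entry estimation on your own magnitudes:

```r
set.seed(1)
fitGammaMLE(rgamma(100, shape = 2, scale = 1.5))
#> GammaEstimate: shape 2.4673 [1.9012, 3.2019], scale 1.1391 [0.8532, 1.5207]
#>   n = 100, Fano = 1.1391, dip p = not screened
```

Session files are delimited text with header
`t,x_maxdev,y_maxdev,z_maxdev` (mean columns optional), laid out as
`<participant>/<day>/<session>.csv`; see `readSession()`,
`magnitudeSeries()`, `entrySignatures()`, `buildTrajectory()`,
`personSignature()` for the stage-by-stage interface, and
`inst/scripts/stochsig-cli.R` for a shell front end
(`simulate`, `run-all`, `replicate-reference`).

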