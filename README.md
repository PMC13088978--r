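# iterscreen

Machine learning-guided iterative screening for RNA-binder discovery, in R.

## The problem

Thermal-shift screens against structured RNA motifs label a compound
*active* when it raises the RNA's melting temperature by more than 1 °C
(ΔTm > 1 °C), and hit rates sit far below 1% — in a typical dual-motif
campaign, a few hundred actives among ~70,000 valid compounds (0.30% and
0.36% per motif, with 0.21% active against both). Screening everything is
mostly wasted effort. Iterative screening tests the library in batches:

1. measure a MaxMin-diverse initial subset (10% of the library, picked on
   Tanimoto distance over fingerprints);
2. train a class-balanced random forest (50 trees, depth ≤ 20) on all
   tested compounds, using fingerprint + physicochemical-descriptor
   features;
3. measure the top-5% of the untested library by predicted probability of
   activity; retrain and repeat.

Progress is judged by the enrichment factor

    EF = (Actives_sample / N_sample) / (Actives_total / N_total)

with totals over the full valid library, and by recovery curves
(cumulative fraction of actives found versus fraction screened) compared
with six-seed random baselines. A second question matters for medicinal
chemistry: whether the loop preferentially recovers *clustered* actives —
chemotypes with structural neighbors, which support structure–activity
analysis — over one-off singletons.

`iterscreen` implements the full workflow: melt-curve → Tm → ΔTm → active
calls with QC (`estimate_tm`, `delta_tm`, `classify_active`);
featurization and Tanimoto geometry (`featurize`, `tanimoto_distance`);
the selection loop and baselines (`iterative_screen`, `random_screen`);
evaluation (`enrichment_factor`, `recovery_curve`, `cluster_recovery`,
`overlap_analysis`, `classification_metrics`); and a synthetic campaign
generator (`generate_library`) that reproduces the statistical structure
of such campaigns — rare clustered actives, dual-motif overlap, ΔTm
distributions, QC failures — at desk scale, since real campaign tables of
this kind are proprietary.

## A worked example

```r
library(iterscreen)

camp  <- generate_library(synth_config(seed = 1))   # 5000 compounds, ~0.3% hit rate
cfg   <- screen_config(stop_fraction = 0.35)        # 10% seed + 5% batches to 35%
trace <- iterative_screen(camp$library, camp$table, motif = 1, cfg)
summary(trace)
```

```
  iteration      mode n_selected n_active cum_active fraction_screened fraction_recovered ef_cumulative
1         0 diversity        500        2          2            0.0998              0.118          1.18
2         1     model        250        5          7            0.1504              0.412          2.74
3         2     model        250        5         12            0.2012              0.706          3.51
4         3     model        250        4         16            0.2514              0.941          3.74
5         4     model        250        0         16            0.3008              0.941          3.13
6         5     model        250        0         16            0.3502              0.941          2.69
```

The diverse seed finds 2 of 17 actives; the first trained forest pulls 5
more into a single 250-compound batch (EF ≈ 7 for that batch), and by 35%
screened the loop holds 16/17 actives (94.1%) against a 37.3% mean for six
random baselines run on the same schedule:

```r
baselines <- random_screen(camp$library, camp$table, motif = 1, cfg)
report    <- evaluate_screen(trace, baselines, camp$library, camp$table)
report$cluster_recovery$clustered_recovery   # 1.00  (every clustered active found)
report$cluster_recovery$singleton_recovery   # 0.67  (singletons lag behind)
plot(trace, baselines = baselines)           # recovery curve vs baseline band
```

Raw melt curves work the same way at the front of the pipeline:

```r
fit <- estimate_tm(simulate_melt_curve(61, noise_sd = 0.02, seed = 1))
fit$tm          # 60.84 degC, qc_status "ok"
hit_rate(216, 71653)$percent   # 0.30 (% of valid data)
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/iterscreen` (`synth | melt | screen | evaluate | run`), and
`run_pipeline()` drives the whole chain from a YAML configuration,
emitting JSON-lines traces, a JSON report, and a seed-complete manifest
that makes reruns byte-identical.

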