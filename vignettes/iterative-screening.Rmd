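---
title: "Model-guided iterative screening for RNA binders: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided iterative screening for RNA binders: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iterscreen)
```

## The problem

High-throughput screens against structured RNA motifs measure, for every
compound, the shift in the RNA's melting temperature (ΔTm) in a FRET
thermal-shift assay: a dual-labeled RNA is heated through its unfolding
transition, donor fluorescence rises as donor and quencher separate, and a
compound that stabilizes the fold moves the transition upward. Compounds
with ΔTm strictly greater than 1 °C are called *active*. Hit rates in such
campaigns are far below 1%, so screening an entire library is mostly wasted
effort. Iterative (active-learning) screening tests the library in batches:
a structurally diverse initial subset is measured, a classifier is trained
on the accumulated labels, the top-scoring fraction of the untested library
is measured next, and the model is retrained after every batch. The outputs
of interest are how much faster actives accumulate than under random
selection (enrichment factor, recovery curves), and whether the recovered
actives form coherent chemotype clusters usable for structure–activity
analysis.

This package implements that workflow end to end: melt-curve analysis,
compound featurization, the selection loop, the evaluation statistics, and
a synthetic campaign generator that makes the whole pipeline testable at
desk scale.

## Melting-temperature estimation and quality control

A melt curve is modeled as a rising sigmoid. `estimate_tm()` smooths the
trace with a symmetric moving average (default window 3 grid points),
takes discrete first and second derivatives on the temperature grid, and
locates the inflection as the linearly interpolated zero crossing of the
second derivative nearest the first-derivative maximum. By default
(`tm_control(refine = TRUE)`) that derivative-based estimate then
initializes a local least-squares fit of a two-state Boltzmann sigmoid to
the raw trace, and the fitted midpoint is reported as Tm — it is still the
curve's inflection, now of the fitted sigmoid rather than of discrete
differences. The refinement matters on the coarse 2 °C assay grid: at 5%
amplitude noise the two-point interpolated crossing alone places only
about two-thirds of estimates within 0.5 °C of a dense-grid reference,
whereas the refined estimator reaches ≈94% — which is essentially the
information limit of the fixture (a Cramér–Rao computation at these exact
settings bounds *any* estimator near 94.7%). Over the assay's operating
range (noise up to 5% of amplitude) 97–98% of estimates land within
0.5 °C, and noiseless curves are recovered exactly. The refinement is
discarded (falling back to the interpolated crossing) if the fit fails,
leaves the measured grid, or moves more than `refine_window` (6 °C) from
its initialization. The light default smoothing is deliberate: wider
windows visibly bias the derivative localization on a 2 °C grid.

Failures are encoded in a QC status rather than raised as errors, because
a screening table must record *why* a well was excluded:

* `nonsigmoidal` — post-smoothing amplitude below `snr_min` (default 5)
  times the residual noise, or the trace's net rise is less than
  `monotone_min` (default 0.5) of its total variation;
* `irregular` — a secondary first-derivative peak at least
  `secondary_ratio` (default 0.5) of the main peak, separated by a genuine
  valley: two transitions of comparable size;
* `no_inflection` — no second-derivative zero crossing, a crossing only
  within `boundary_exclude` (default 2) grid points of either end of the
  ramp, or a first-derivative maximum inside that boundary zone (a
  transition the ramp did not fully capture cannot be located reliably —
  without this rule, a curve melting below the ramp start can sneak
  through QC on spurious noise crossings in its flat tail).

These thresholds are declared package defaults, configurable through
`tm_control()`: the assay literature names the failure taxonomy but no
quantitative cutoffs, so the numbers here are our own operating points and
are treated as such. ΔTm is sample Tm minus the matched compound-free
reference Tm, defined only when both curves pass QC; compounds lacking a
valid ΔTm for either motif are excluded from the "valid data" universe and
from every numerator and denominator downstream.

## Featurization

Compounds are represented as a binary fingerprint block concatenated with a
numeric descriptor block. Two modes are first-class:

* **Abstract mode** (default throughout the tests and generator):
  fingerprints and descriptors are supplied directly. The selection loop is
  agnostic to where the bits came from, which keeps the machine-learning
  machinery testable without any chemistry toolkit.
* **Structure mode**: SMILES are canonicalized and featurized with Open
  Babel (via ChemmineOB): 1024-bit FP2 path fingerprints and a small frozen
  descriptor set (`default_descriptors()`: MW, exact mass, logP, MR, TPSA,
  two HBA counts, HBD, fluorine count). Circular Morgan-style fingerprints
  are the common choice in this field; no installed R backend computes
  them, so the package's structural fingerprint is FP2, documented as such.
  Any user-supplied descriptor list is accepted, and the list in force is
  recorded in the run manifest. Nothing in the evaluation statistics
  depends on the specific fingerprint algorithm.

Non-finite descriptor values are imputed with the median of the *tested*
compounds only, so no information flows from untested rows. No feature
scaling is applied: tree ensembles are scale-invariant. Tanimoto distance
(1 − shared/union bits, with distance 0 between two empty fingerprints) is
the metric for diversity picking and chemotype clustering.

## The selection loop

`iterative_screen()` runs the campaign against one motif:

1. **Iteration 0** — a MaxMin-diverse subset of `initial_fraction`
   (default 10%) of the library: the first pick is seeded-uniform, each
   later pick maximizes its minimum Tanimoto distance to the picked set,
   ties broken by smallest compound id.
2. **Iterations 1, 2, …** — a random forest (50 trees, maximum depth 20,
   probability output; fixed across iterations) is trained on all
   tested-and-valid compounds after class balancing, every untested
   compound is scored, and the top `batch_fraction` (default 5%) *of the
   full library* is tested next. The loop stops at `stop_fraction`
   (default 35%) of the library.

Batch sizes are fractions of the full library, not of the shrinking
remainder, and the final batch truncates; this matches the enrichment
bookkeeping in which totals are always defined over the full valid
library. Labels are revealed only for selected compounds — a property the
test suite enforces by replaying a finished campaign with the hidden
labels of never-tested compounds permuted and checking that every batch is
identical.

**Class balancing.** The default policy (`"oversample"`) builds a 1:1
training set the size of the original: the minority class is oversampled
with replacement and the majority undersampled, mirroring the balancing
behavior of the AutoML tooling this workflow descends from ("relative
rows after balancing = 1"). A strict `"undersample"` policy (majority cut
to the minority count) is also provided. Undersampling is the textbook
reading, but at desk scale it is ruinous: with ~15 actives in a
5000-compound library the first training set often holds one to three
actives, and undersampling 500 rows down to 2–6 yields a forest with a
constant score (held-out AUC ≈ 0.5). Oversampling keeps every inactive
example in play while weighting the few actives up, and is what makes the
loop learn from a single discovered chemotype. If the tested labels are
single-class the iteration falls back to a seeded random batch and is
flagged `degenerate` in the trace.

**The random baseline.** `random_screen()` runs the same schedule with
uniform batches, six seeds by default. By default the baselines *share*
the model arm's diversity-picked initial subset (`initial = "shared"`), so
the two arms differ only in how post-initial batches are chosen — a paired
design that attributes any recovery difference to model guidance alone.
`initial = "random"` gives the fully uniform screen, whose expected
recovery at screened fraction *f* is *f*; the test suite checks that
against a 10,000-draw hypergeometric Monte-Carlo oracle.

**Determinism.** All randomness flows from named seeds (diversity, model,
baseline list, generator); forests are fitted single-threaded with a fixed
seed; every tie anywhere is broken by smallest compound id. Two runs from
one configuration are byte-identical down to the serialized trace files
(the run manifest carries the only timestamp).

## Evaluation

* `enrichment_factor()` — (actives_sample/n_sample) /
  (actives_total/n_total), with totals over the full valid library,
  previously tested compounds included.
* `recovery_curve()` — cumulative fraction of valid actives found versus
  fraction of the valid library tested, one point per iteration.
* `classification_metrics()` — precision, recall, F1, with `NA` as an
  explicit undefined marker for empty denominators.
* `delta_tm_split_summary()` — mean/median/N of ΔTm for recovered versus
  unrecovered actives, optionally with a Wilcoxon rank-sum comparison;
  the diagnostic for preferential enrichment of stronger binders.
* `cluster_recovery()` — sphere-exclusion (Butina-style) clustering of the
  actives' fingerprints at a Tanimoto-distance cutoff (default 0.4, on the
  same fingerprints the loop uses), centroids in order of descending
  neighbor count with ties by id; reports per-cluster and singleton
  recovery. The clustered-versus-singleton contrast is deliberately
  operationalized this way because the qualitative published evidence
  (2-D embeddings) does not define a grouping procedure; the cutoff sits
  in configuration.
* `overlap_analysis()` — two-motif selectivity counts (per-motif totals,
  shared, motif-preferential), for full and recovered active sets.

Report output rounds percentages half-up to two decimals and EF to one
decimal; full precision is kept internally and in serialized artifacts.

## The synthetic campaign generator

Real dual-motif HTS tables of this kind are proprietary, so
`generate_library()` builds campaigns with the statistical structure the
analysis assumes, at desk scale:

* **Library**: 5000 compounds (default), 256-bit abstract fingerprints
  with on-bit density 0.1 and 16 descriptors.
* **Actives**: per-motif hit rate 0.003. Motif-1 actives are 3 chemotype
  clusters of 3–6 members plus 3 singletons; cluster members are a random
  prototype with 2% per-bit flip noise (within-cluster Tanimoto distance
  ≈ 0.15–0.2 versus ≈ 0.95 background), and singletons are placed at
  distance > 0.6 from every prototype. Descriptors of cluster members
  scatter (sd 0.5) around a cluster mean drawn from N(0, 1.5); background
  descriptors are standard normal.
* **Second motif**: each motif-1 active carries over with probability 0.7,
  and independent extra actives top motif 2 up to its base rate —
  reproducing the published overlap pattern in which roughly 70% of one
  motif's actives hit the other.
* **ΔTm**: actives draw `1 + |N(2, 3)|` °C, plus a 1.5 °C boost for
  clustered actives (clustered chemotypes are the stronger binders);
  inactives draw N(0, 0.3) truncated below 1 °C, so labels and shifts are
  consistent by construction. These distributions are declared: published
  exemplar actives span roughly 0.7–16.6 °C, which the defaults cover.
* **Invalid data**: 2% of compounds are marked invalid for both motifs;
  when raw curves are generated (`generate_melt_curves()`), those
  compounds get flat, biphasic, or boundary-inflection traces so the QC
  taxonomy is exercised, and one compound-free reference curve is emitted
  per 384-well plate-equivalent and motif at Tm 62 °C. Valid compounds'
  curves round-trip through `estimate_tm()`/`delta_tm()` to within the
  estimator tolerance.

What the generator does *not* emulate: realistic medicinal-chemistry
property distributions, assay drift and plate effects beyond per-plate
references, correlation between fingerprint similarity and descriptor
similarity in the background, and the true (unknowable) cluster-size and
ΔTm distributions of any proprietary library. Passing tests on synthetic
campaigns therefore demonstrate that the machinery is correct and that the
loop exploits cluster structure when it exists — not that any particular
real library will yield the same enrichment.

## Desk-scale study conditions and what they imply

The package's standard experiment (used by the acceptance suite) runs ten
default campaigns, screening motif 1 to 35% with the default schedule, and
compares against the six-seed shared-initial random baseline; problem
sizes were chosen so the full experiment completes in minutes on one CPU.
Two properties are asserted: the model arm's recovery is at least the
baseline mean at every iteration endpoint, with the first trained model's
5% batch reaching an enrichment factor of at least 3, in at least 8 of 10
campaigns; and clustered actives are recovered at a higher rate than
singletons in at least 8 of 10. Both hold, but the margin is real, not
decorative: with ~15 actives in 5000 compounds the initial 10% subset
contains zero actives in roughly a third of campaigns (MaxMin visits a
tight cluster about once, so actives behave as ~6 effective entities), and
such campaigns must first stumble on an active at random before the model
can engage. This is the honest desk-scale analogue of a regime the
full-scale campaign never enters (its 10% subset contains dozens of
actives), and it is the binding constraint on how strong the desk-scale
enrichment claim can be.

## Numerical and degenerate-input policy

Grids with fewer than 5 points are rejected at construction, not given QC
codes. Batch-size arithmetic uses round-half-up for platform stability.
All-zero fingerprints have distance 0 to each other by convention.
Single-class training sets raise a typed condition that the loop converts
into a flagged random batch. EF is undefined (a typed error) when the
library has no actives or the sample is empty; precision/recall return
`NA` markers rather than silent zeros. Score ties in batch selection and
distance ties in MaxMin resolve by smallest compound id, which makes every
trace replayable.

## A worked desk-scale example

```{r example, eval = FALSE}
camp <- generate_library(synth_config(seed = 1))
cfg <- screen_config(stop_fraction = 0.35)
trace <- iterative_screen(camp$library, camp$table, motif = 1, cfg)
baselines <- random_screen(camp$library, camp$table, motif = 1, cfg)
summary(trace)
plot(trace, baselines = baselines)
report <- evaluate_screen(trace, baselines, camp$library, camp$table)
report$cluster_recovery
```

## Limitations

The forest hyperparameters are fixed (as in the published operating
point), not re-tuned per iteration; alternative learners and acquisition
functions beyond greedy top-fraction selection are out of scope. The
structure-mode fingerprint backend differs from circular fingerprints and
will group chemotypes somewhat differently. The Tm estimator assumes a
single rising transition; thermodynamic curve fitting and dose–response
analysis are not implemented. Desk-scale enrichment results quantify the
mechanism, not the magnitude, of full-scale campaign gains.
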