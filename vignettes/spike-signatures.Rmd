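---
title: "Spike-train signatures of cerebellar movement disorders: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-train signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesig)
```

# The analysis in one paragraph

Awake extracellular recordings from cerebellar nuclei neurons are summarized
by twelve interspike-interval (ISI) parameters, a coarse decision tree maps
each neuron's parameter vector to a phenotype *signature* (control, ataxia,
dystonia, tremor), and cohort-level statistics compare how signatures
distribute across disease models. All parameter estimates assume 30-s
recordings: rate and pause statistics are strongly duration-dependent, so
`featurize()` refuses other durations unless explicitly overridden.

# The twelve parameters

ISIs are stored in milliseconds; instantaneous firing rates (IFR = 1/ISI) in
Hz. The parameters fall in four families:

* **Rate** — firing rate (spike count / duration; the count is deliberately
  not reduced by one), mean IFR, median IFR.
* **Irregularity** — CV (sd/mean of the ISI distribution) and CV2 (mean of
  `2|ISI_n - ISI_{n-1}| / (ISI_n + ISI_{n-1})` over consecutive pairs).
  CV responds to anything that broadens the ISI distribution, including slow
  firing-rate drift across the 30 s; CV2 compares neighbours only and is
  nearly immune to drift. That distinction is not cosmetic: it is the reason
  the classifier can separate genuinely regular (ataxic) firing from firing
  that is locally regular but drifts.
* **Pauses** — percentage of ISIs strictly above 25 ms and 100 ms
  (instantaneous rate below 40 Hz / 10 Hz), the mean duration of ISIs
  exceeding five times the mean ISI (0 when no ISI qualifies: 0 is
  unattainable for a qualifying mean, so it is unambiguous and keeps feature
  tables dense), and the modal-bin mass of the ISI histogram.
* **Rhythmicity** — an autocorrelogram-based index and the number of
  accepted oscillation peaks (next section).

Decisions where the definitions left latitude, all fixed here once:

* CV uses the sample (n−1) standard deviation, the default of standard
  statistical tooling.
* The threshold fractions use strict `>`; a 25.000-ms ISI does not count.
* The skewness index `2(median IFR − rate)/(median IFR + rate)` is bounded
  in (−2, 2) and is 0 for any renewal process whose median ISI equals its
  mean ISI; gamma-like ISIs give small positive values (≈0.115 for a
  shape-3 gamma), bursty trains approach 1 and beyond.
* The modal-bin statistic needs a discretization: 1-ms bins `[k, k+1)`,
  ties to the smaller edge. 1 ms is the coarsest grid on which a perfectly
  regular train keeps 100% of its mass in one bin. Binning adds a 1-ns
  guard before `floor()` so that floating-point representation of exactly
  periodic timestamps cannot scatter one true bin across two.

# Autocorrelogram and rhythmicity

`autocorrelogram()` counts ordered spike pairs in 5-ms bins of forward lag up
to 1 s. Only positive lags are kept (the negative half mirrors them) and
counts stay raw, because the acceptance thresholds below are count-relative.
The **baseline** is the mean bin count in the 0.96–1 s tail window and
`tail_sd` its standard deviation — the tail is the only lag region treated as
rhythm-free reference.

`rhythmicity()` walks peaks and troughs alternately. The first peak is the
highest bin with left edge in `[10 ms, 1.5 × mean ISI]`; the trough paired
with a peak at lag L is the lowest bin in `(L, L + L1]` (L1 = first-peak
lag); the next peak is searched in `(previous trough lag, previous peak lag
+ L1 + 10 ms]`. In these windows the quantities named after the first peak
are *lag times* — reading them as heights yields no well-formed windows. A
pair is accepted when peak height above baseline plus trough depth below
baseline exceeds 4 tail-SD, or when the peak clears baseline + 2 SD while
the trough falls below baseline − 2 SD; the walk stops at the first
rejected pair or when a window runs off the 1-s autocorrelogram. The index
is Σ(aᵢ+bᵢ)/z with `z = |n_spikes − baseline|` (the absolute value guards
degenerate very short trains where a tail bin can exceed the spike count).

Two honest properties of this procedure deserve emphasis:

* A **perfectly periodic** train is *rejected*: its tail bins alternate
  between ~n and 0 counts, so the tail SD is enormous and no pair passes.
  Real trains pass because their rhythm decays by 1 s of lag. Tests
  therefore assert accepted peaks on jittered rhythmic trains, and assert
  peak *detection* (the first peak's bin contains the period) separately.
* For **fast bursting** cells the first-peak window `[10, 1.5 × mean ISI]`
  ends well before the burst period (30 ms vs. 100 ms for a 10-Hz burster at
  50 spikes/s), so the first accepted peak is the intra-burst peak, not the
  cycle peak. The cycle rhythm is still visible directly in the
  autocorrelogram (the package tests it on lags beyond 50 ms), and such
  cells still score `oscillation_peaks ≥ 2`; but the *location* of the
  first accepted peak should not be over-interpreted for bursting cells.

# The coarse tree

`train_coarse_tree()` is greedy best-first CART: Gini's diversity index,
counts-weighted (so empirical class priors are implicit), at most three
splits, candidate thresholds at midpoints between consecutive distinct
values, `< threshold` left / `≥ threshold` right, no surrogate splits (a
missing feature at prediction time is an error). Exact ties in impurity
decrease are resolved to the feature earliest in the canonical feature-table
column order, then to the smaller threshold — the same convention as the
column-order behavior of common tree toolboxes, and fixed rules make the fit
invariant to row order (a tested property). The numeric tie tolerance is
1e-9 on the counts-weighted decrease: algebraically equal splits differ by
float noise well below it, and genuinely different splits differ by at least
one misplaced cell, orders of magnitude above it. Leaf labels are the
majority class, ties resolved to the class with the larger training prior,
then to the fixed order control < ataxia < dystonia < tremor. Coarseness is
deliberate: the twelve parameters are strongly correlated, and three splits
cannot overfit correlated features the way deeper trees do; no other
classifier family is offered.

`run_model_selection()` implements the 12-split protocol: stratified
training sets of 25/20/20/20 cells (control/ataxia/dystonia/tremor) and
validation sets of 8/4/4/4, resampled independently per split from seeds
derived from one master seed (recorded in the report). The original
validation sets cannot all have been disjoint (33 control cells cannot host
twelve disjoint 8-cell sets), so independent resampling is the only
reproducible reading; the historical partitions are not recoverable and not
needed. The best model is the one with maximal validation accuracy, ties
going to fewer distinct features, then the lower split id. With 20-cell
validation sets accuracy is granular, so ties are common and some selected
models legitimately use `median_ifr` instead of `isi25` at the
dystonia/tremor node when their training subset happened to lack the
slow-bursting tremor cells; downstream closure analyses therefore fix one
classifier — the first fitted model that recovers the canonical split
variables — and use it throughout, mirroring a selection protocol that keeps one
consistent model for all downstream comparisons.

# Cohort statistics

The two-proportion z-test is the pooled form without continuity correction:
`z = (p1 − p2)/sqrt(p(1−p)(1/n1 + 1/n2))`. This exact form is validated by
the published comparisons (z = 2.1128 and z = −2.094 on the 15/23 vs 7/21
and 7/23 vs 13/21 signature counts); note the corresponding printed
p-values (0.0349, 0.0366) sit ~3·10⁻⁴ away from the exact two-sided normal
p of those z values (0.0346, 0.0363) — the package reports the exact
values. Enrichment uses the one-vs-rest 2×2 chi-square (df 1, no
correction), whose statistic is identically z² — an identity the test suite
checks on a thousand random tables. The exact contingency construction
behind the published enrichment p-values is not stated anywhere; one-vs-rest
on both margins is this package's choice. ANOVA and Tukey–Kramer are the
standard `aov()`/`TukeyHSD()` path with studentized-range p-values
(all-identical data short-circuits to F = 0, p = 1 rather than NaN). Tremor
power is a single full-segment Hann periodogram (no Welch averaging —
none is specified for this analysis), normalized so summed power
approximates signal variance, with the peak searched on (0, 30] Hz and the
DC bin excluded.

# The synthetic generator

The generator exists so every stage is testable without recordings. Each
phenotype has a **core** model:

* *control*: gamma-renewal ISIs, per-cell shape 2.4–6 and mean 10.5–15.5 ms,
  a small (<1.5%) admixture of ~50-ms pauses;
* *ataxia*: gamma-renewal with shape 40–120 (near-clockwork local firing),
  mean 10.5–14 ms;
* *dystonia*: slow mixture renewal — main component gamma(1.2–2.2) with
  mean 24–30 ms, plus 13–20% pause intervals of mean 110–160 ms;
* *tremor*: a cycle process at 8.5–10.5 Hz firing one decelerating burst of
  1 + Poisson(3.4–5.5) spikes per cycle (intra-burst ISI means growing
  geometrically, 5–35% per step), cycles skipped with probability 0.1–0.4.

All renewal cells additionally carry slow sinusoidal firing-rate drift
(depth 5–45%, period 8–25 s), applied by time-rescaling so local statistics
(CV2) are preserved while the pooled ISI distribution broadens (CV) — the
signature of awake-state arousal drift, and the reason CV2 is the
informative irregularity measure. Tremor cycle onsets use *accumulating*
period jitter (sd 8 ms per cycle): clock-locked jitter would keep the
autocorrelogram coherent out to 1 s of lag, inflating the tail SD and
defeating the peak-acceptance rule; accumulating jitter makes the rhythm
decay with lag exactly as in real recordings.

Parameters are drawn per cell because real cohorts are heterogeneous — with
fixed parameters nearly every feature would separate the phenotypes
perfectly, which no real dataset does, and the fitted tree's choice of
split variables would be a tie-breaking artifact. On top of the core
ranges, `generate_archetypal_cohort()` mixes in a small, fixed fraction of
documented atypical cells per cohort, mirroring the within-cohort diversity
real confusion matrices imply (in the recordings this analysis emulates, only 54% of tremor-cohort
cells carried the tremor signature, and 79% of ataxia-cohort cells the
ataxia signature):

* control: ~8% locally irregular cells (low gamma shape) and ~4% cells with
  rare very long (~0.4 s) firing arrests — together they give the control
  cohort a high-CV, high-CV2 tail without raising its skewness;
* ataxia: ~10% cells with deep (65–80%) rate drift — locally regular, but
  with control-range CV;
* dystonia: ~5% fast-bursting cells (sub-exponential ISI shape, short main
  mean) with near-unity skewness;
* tremor: ~15% cells drawn from the slow end of the dystonia model (the
  cells a classifier genuinely confuses with dystonia), ~5% slow regular
  bursters (long intra-burst ISIs, heavy cycle skipping — dystonia-range
  median IFR and firing rate at tremor-range ISI>25), and ~5% non-skipping
  fast bursters (control-range firing rate and CV2, near-zero ISI>100).

This composition is what makes the archetypal experiment reproduce the
published classifier structure rather than an arbitrary equally-pure
alternative: each atypical type overlaps specific competitor features across
cohorts while skewness, CV2 and ISI>25 remain the best separators at their
respective nodes. The contract each core phenotype is tested against
(≥95/100 seeded draws): control — rate 60–95 spikes/s, CV2 0.4–0.8,
skewness 0–0.25, ISI>25 < 15%; ataxia — CV2 < 0.2, |skewness| < 0.1;
dystonia — skewness 0.3–0.8, ISI>25 > 25%; tremor — skewness > 0.5,
ISI>25 10–25%. The dystonia parameters were re-derived from these contracts
and from the reported archetypal skewness scale (population mean ≈ 0.4–0.55)
rather than taken from a single fixed mixture, which lands outside its own
contract box.

What the generator does **not** emulate: spike-sorting noise and unit
contamination, non-stationary behavioral state changes beyond smooth drift,
refractory-period structure, correlations between simultaneously recorded
cells, and any waveform-level information. Passing tests on synthetic
cohorts therefore demonstrates the pipeline's correctness and the internal
consistency of the signature definitions — not classifier performance on
real recordings, which is noisier (the synthetic held-out diagonals run
~95–100% for control/ataxia/dystonia where real data gave 85/79/88%).

# Optogenetic paradigms

`opto_waveform()` builds the light schedules exactly as delivered: ataxia —
continuous 50 Hz square pulses (10 ms on/off); dystonia — ≥1 s blocks of
the 50 Hz train, each followed with 75% probability by a 250-ms pause;
tremor — 100 Hz pulses (5 ms on/off) amplitude-modulated by a 10-Hz
envelope (50 ms parabolic rise/fall, 50 ms off).

`opto_modulated_train()` maps light to an effective inhibition drive before
thinning: the raw waveform is integrated by a causal exponential filter
(τ = 8 ms, the GABA-A IPSC decay timescale) and saturated at 15% of the
sustained full-power drive. The saturation encodes the experimental
protocol: stimulation used the minimal power that modulated the cell, at
which pulse trains of 50–100 Hz silence nuclei firing for their duration —
so square-pulse carriers act as sustained inhibition and the tremor
envelope survives as the modulating waveform. Without this step the 50%
duty cycle of the carriers would halve the effective inhibition and no
paradigm could silence a cell, contradicting the recordings the paradigms
are modeled on. The spike train itself is a gamma(3) renewal process (the
control-like regime; baseline 100 spikes/s by default) time-rescaled through
`r(t) = base_rate · (1 − gain · s_eff(t))` — at gain 0 this is exactly the
unmodulated base process, a tested identity. Rebound firing after release
from inhibition is deliberately not modeled; inhibition acts by thinning
only.

# Problem sizes and reproducibility

The test suite and the acceptance script size their simulations for
desk-scale runs: contract boxes at 100 seeded draws per phenotype,
tree-structure reproduction over 10 cohorts of 85 cells, held-out
classification at 24 cells per class, the optogenetic closure at 50
simulated recordings per paradigm, oracle sweeps at 1000 random ISI
sequences / 2×2 tables and autocorrelogram checks up to 2000 spikes. Every
random draw in the package flows through explicit seeds: cohorts derive
per-cell seeds from one master seed and record them, and the 12-split
protocol records its per-split seeds in the validation report.

# Known limitations

* Real per-cell recordings and the published per-cell parameter tables are
  not bundled; quantitative claims about real data (the 85/79/88/54%
  assignment rates, archetypal skewness means) are emulated in regime, not
  refit.
* The rhythmicity walk inherits the quoted window rules; as discussed, its
  first accepted peak is the intra-burst peak for fast bursters, and
  perfectly periodic inputs are rejected by the tail-noise rule.
* The classifier is intentionally limited to one family (coarse Gini trees);
  no ensembles, no discriminant analysis.
* Optogenetic modeling is inhibition-by-thinning with a saturating synaptic
  drive; rebound dynamics, short-term plasticity and network effects are out
  of scope.
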