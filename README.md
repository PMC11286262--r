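# spikesig

Cerebellar nuclei neurons fire differently in mice with ataxia, dystonia and
tremor: ataxic models fire with unusual regularity, dystonic models slowly and
irregularly with long pauses, tremor models in rhythmic ~10 Hz bursts.
`spikesig` implements the spike-signature analysis behind this observation for
anyone working with extracellular single-unit recordings: it turns 30-second
spike trains into twelve interspike-interval (ISI) parameters, fits a coarse
decision tree that assigns each neuron a *spike signature* (control, ataxia,
dystonia or tremor), and runs the cohort-level statistics used to compare
disease models. A synthetic spike-train generator emulating the four
archetypal phenotypes (and the optogenetic stimulation paradigms that induce
them) makes the whole pipeline testable without any recordings.

## The model

Each neuron is summarized by twelve parameters of its ISI sequence
(ISI_n = t_{n+1} − t_n, in ms):

| parameter | definition |
|---|---|
| firing rate | spikes / s |
| mean, median IFR | mean(ISI⁻¹), median(ISI⁻¹) (Hz) |
| CV | sd(ISI) / mean(ISI) |
| CV2 | mean over pairs of 2·\|ISI_n − ISI_{n−1}\| / (ISI_n + ISI_{n−1}) |
| skewness | 2·(median IFR − firing rate)/(median IFR + firing rate) |
| ISI>25, ISI>100 | % of ISIs above 25 ms / 100 ms |
| interburst pause | mean of ISIs exceeding 5 × mean(ISI) |
| mode fraction | % of ISIs in the modal 1-ms bin |
| rhythmicity index | Σ (aᵢ + bᵢ)/z over accepted autocorrelogram peak/trough pairs |
| oscillation peaks | number of accepted autocorrelogram peaks |

The rhythmicity analysis uses a 5-ms-binned autocorrelogram up to 1 s of lag,
with baseline and noise SD taken from the 0.96–1 s tail window, and an
alternating peak/trough walk whose pairs are accepted against 4 tail-SD (or
±2 SD) thresholds.

The classifier is a *coarse tree*: CART with Gini's diversity index, at most
three splits, no surrogate splits. On archetypal cohorts it recovers the
published structure — skewness at the root (separating control/ataxia from
dystonia/tremor), CV2 separating control (higher) from ataxia (lower), and
ISI>25 separating dystonia (higher) from tremor (lower).

Cohort statistics: pooled two-proportion z-tests (no continuity correction),
one-vs-rest enrichment chi-square, one-way ANOVA with Tukey–Kramer post hoc
comparisons, and Hann-window periodogram peak power in the 0–30 Hz tremor
band for accelerometer traces.

## Worked example

```r
library(spikesig)

co    <- generate_archetypal_cohort(seed = 20240101)   # 25/20/20/20 cells
feats <- featurize_cohort(co$cohort)
tree  <- train_coarse_tree(feats[, feature_names()], feats$group_label)
tree
#> <signature_tree> 3 split(s)
#> skewness < 0.3789
#>   cv2 < 0.3058
#>     * ataxia (control=0 ataxia=20 dystonia=0 tremor=0)
#>   cv2 >= 0.3058
#>     * control (control=25 ataxia=0 dystonia=0 tremor=0)
#> skewness >= 0.3789
#>   isi25 < 28.63
#>     * tremor (control=0 ataxia=0 dystonia=0 tremor=17)
#>   isi25 >= 28.63
#>     * dystonia (control=0 ataxia=0 dystonia=20 tremor=3)
```

The fitted thresholds say: a neuron whose median instantaneous rate is well
above its mean rate (skewness ≥ 0.38) carries a disease signature of the
bursty kind; among those, more than ~29% of ISIs longer than 25 ms marks the
slow dystonic pattern, fewer marks rhythmic tremor bursting. On the regular
side, CV2 below ~0.31 is the ataxia signature.

Applying the tree to an independently generated cohort (24 cells per group):

```r
held    <- generate_archetypal_cohort(c(control = 24, ataxia = 24,
                                        dystonia = 24, tremor = 24),
                                      seed = 777)
summary <- classify_cohort(tree, featurize_cohort(held$cohort))
summary
#> <cohort_summary> counts (origin x signature)
#>           signature
#> origin     control ataxia dystonia tremor
#>   ataxia         0     24        0      0
#>   control       24      0        0      0
#>   dystonia       0      0       24      0
#>   tremor         0      0        4     20
```

Control, ataxia and dystonia cohorts are assigned their own signature almost
perfectly; the tremor cohort's only confusion is with dystonia (4/24 cells),
the same direction seen in real recordings, because a minority of
tremor-model cells fire in slow irregular patterns. Comparing signature
proportions between two cohorts uses the pooled z-test:

```r
z <- two_proportion_z(15, 23, 7, 21)
sprintf("z = %.4f, p = %.4f", z$z, z$p.value)
#> "z = 2.1128, p = 0.0346"
```

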