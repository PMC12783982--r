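---
title: "Single-unit and population analysis of odour-evoked spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-unit and population analysis of odour-evoked spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odourpop)
```

## The problem

Mitral and tufted cells of the main olfactory bulb (MOB), and their
targets in the anterior olfactory nucleus (AON), carry odour identity in
their spiking. A standard experimental design probes this code with a
small panel of chemically ordered stimuli — here six monomolecular
aldehydes identified by their carbon chain length (3–8) — delivered for
500 ms, 19 trials each, in random order, while sorted single units are
recorded across sessions. Two complementary questions are asked of such
recordings:

* **Single-unit coding.** Which units respond to which odours, with what
  sign (excitation vs suppression), amplitude, latency and width, and how
  discriminable are odour pairs in single-unit spike counts?
* **Population coding.** Do the trial-by-trial population vectors of
  spike counts separate odours geometrically (Euclidean distances), and
  how well can odour identity be decoded from subsampled
  pseudopopulations?

`odourpop` implements this full analysis chain, plus a synthetic
spike-train generator that emulates the experimental design so that every
stage can be exercised, calibrated and regression-tested without any
recorded data. The numbered scripts under `analysis/` run the workflow
end to end on simulated control and mutant populations.

## The generative model

`generate_session()` simulates sorted single units as inhomogeneous
Poisson processes (thinning sampler, `sample_inhomogeneous_poisson()`).
Trials are laid out back-to-back, 10 s per trial epoch, with the odour
onset 5 s into each epoch so the −2.5 to −0.5 s baseline window is always
in-session. Each unit draws:

* a baseline rate `b` from a log-normal distribution (MOB preset: median
  10 Hz, log-sd 0.6 — mitral/tufted cells in awake animals fire tonically
  at ~5–30 Hz; AON preset: median 4 Hz);
* responsiveness with probability `p_responsive`, and a polarity
  (inhibited with probability `p_inhibited_given_responsive`);
* a gain `A` (normal, truncated at 0.1), a kernel latency and width.

An excited unit's rate during a trial of odour `o` is
`b (1 + A_o g(t))`, an inhibited unit's `b (1 − s_o g(t))`, where `g` is
a peak-normalised Gaussian bump with the unit's latency (time-to-peak)
and full width at half maximum, supported on `[0, latency + 4 sd)` so
rates are exactly baseline before onset. The per-odour gain decays with
chemical distance from the unit's best odour,
`A_o = A exp(−|c_o − c_best| / λ)`; `λ = ∞` gives flat (untuned)
responses. Inhibited gains are mapped through `s = A / (1 + A)` so
suppression stays in `[0, 1)` and rates never go negative.

### Genotype presets and calibration constants

`genotype_preset()` encodes the qualitative contrast the pipeline is
designed to detect: the control preset has finite tuning decay
(`λ = 1.2` carbon units), gain mean 3.0, fast narrow kernels and intact
inhibited responses (40% of responsive units); the mutant preset has flat
tuning (`λ = ∞`), fewer responsive units (0.25 vs 0.5), smaller gains
(1.5), fewer inhibited responses (20%) and slower, broader kernels. All
magnitudes are calibration constants of the simulator — chosen once so
the downstream contrasts (responsive fractions, chain-distance ANOVA,
decoding curves) emerge reliably at ~100 units per genotype — not
measurements. The simulator emulates the design (trial counts, windows,
randomised order, genotype contrasts), not the biology it abstracts away:
no respiration-locked firing, no sniff-phase coding, no concentration
series, no electrode drift, no correlated noise across units. Passing
tests therefore validate the analysis code, not claims about real
recordings.

## Single-unit analysis

All windows are half-open `[a, b)` relative to odour onset and bin
timestamps are bin centres (`analysis_windows()`). PSTHs use 50 ms bins;
the z-scored trace uses 100 ms bins. For each unit-odour pair the trials
are averaged first and the binned rate trace is standardised by the
baseline window (−2.5 to −0.5 s): `z_t = (FR_t − FR_base) / sd_base`. A
pair is *excited* if the mean z over the five odour-window bins
(0–0.5 s) exceeds +1.96 — the two-sided 95% standard-normal critical
value — and *inhibited* below −1.96. Because the mean of five
approximately standard-normal bins has standard deviation ~1/√5, this
threshold is conservative; under a stationary Poisson null fewer than 5%
of pairs are labelled responsive (property-tested). Pairs with zero
baseline variability are flagged degenerate and excluded rather than
patched with an epsilon.

Response features (`peak_features()`) are computed on the 100 ms z-trace
(the trace the classification itself uses): the peak is the largest local
maximum within 0–1 s of onset (responses can outlast the 500 ms
stimulus), latency is its bin centre, and width is measured at half
prominence with linear interpolation between bin centres, clipped at the
search-window edges when the trace never falls below the half level.
Inhibited responses are analysed on the negated trace and reported with
their original sign.

Pairwise discriminability uses `d′ = |μ_A − μ_B| / σ_RMS` on
odour-window spike counts, with `σ_RMS = sqrt((sd_A² + sd_B²)/2)`;
zero-variance pairs with equal means give 0, with unequal means they are
flagged infinite and excluded from distribution summaries. Feature
comparisons between genotypes use a normality gate (Shapiro–Wilk at
α = 0.05 on both groups → Welch t test, otherwise two-tailed
Mann–Whitney). A single normality test is used where common practice
sometimes stacks two; the gate is exposed and can be bypassed.

## Chemical-similarity coding

`relative_responses()` defines response strength as the raw
trial-averaged rate in the odour window — not baseline-subtracted and not
|z| — so relative strengths lie in [0, 1] by construction; the
alternatives change only the normalisation and are easy to substitute
upstream. Ties for the best odour break to the lower carbon number
(deterministic). The ranked curve averages relative strengths by
within-unit rank; the chain-distance curve averages them by
`|Δ carbon|` from each unit's best odour, with unequal cell counts
because each unit's best odour fixes which distances it can contribute.

The genotype × chain-distance comparison uses a fixed-effects two-way
ANOVA with interaction and Type II sums of squares (`car::Anova`), the
standard realisation of proportionally-weighted marginal hypotheses for
unbalanced tables; the ranked curve uses a repeated-measures two-way
ANOVA across ranks 2–6 (rank 1 is identically 1) with the unit as the
subject stratum. Post-hoc pairwise comparisons across the non-genotype
factor use Welch t tests with Šídák adjustment
(`p_adj = 1 − (1 − p)^m`).

Note that the strict monotone decline of the pooled chain-distance curve
is a property of the tuned (excited, finite-λ) subpopulation: with
realistic fractions of untuned and inhibited units, the pooled curve's
tail differences at Δ = 3–5 fall below sampling noise at a few hundred
units, while the ANOVA main effect remains highly reliable. The tests
separate these two claims.

## Population analysis

`build_pseudopopulation()` pools units across sessions into one trials ×
units count matrix, aligning rows by within-odour trial index (the first
19 trials of each odour). Units recorded on the same tetrode in
subsequent sessions of one animal are removed first (`dedup_units()`;
the pipeline applies the rule within genotype groups, since different
genotypes are different animals).

`cross_odour_distances()` computes all pairwise Euclidean distances
between trial population vectors and partitions them into 6 within-odour
groups (171 distances each) and 15 cross-odour groups (361 each). The 21
groups are compared with Welch's heteroscedastic ANOVA by default — the
Brown–Forsythe statistic is available and agrees with Welch for two
equal-sized groups — followed by Games–Howell post-hocs (Welch-df t
statistics referred to the studentized range, `ptukey`). The reported
grid compares each odour's within distribution against each of its cross
distributions.

### The decoder

`decode_accuracy()` is the headline procedure: for each population size
(steps of 10 by default) and iteration (500 by default), it samples that
many units without replacement, holds out one random trial, reduces the
training rows to 4 principal components, fits the classifier on the
projected training rows, and scores the projected held-out trial;
per-size accuracy is tested against chance (1/6) with a one-sided exact
binomial test.

Two design points deserve explanation:

* **Covariance structure.** The Gaussian classifier fits one mean per
  odour class and, by default, a single full covariance pooled across
  classes (a Gaussian mixture with known labels and shared covariance;
  diagonal regularisation 10⁻⁶ × mean variance). With per-class
  covariances (`covariance = "class"`), leave-one-trial-out evaluation is
  systematically biased *below* chance on odour-independent data: the
  held-out trial's own class is the only one whose mean and covariance
  were fitted without it, so its parameters are repelled from the test
  point while the 4-dimensional covariance deflates along its direction.
  At 18–19 trials per class this anti-learning is large (~5 percentage
  points). The pooled form is chance-calibrated, estimates far fewer
  parameters from 113 training trials, and matches the overfitting
  concern that motivates the 4-dimensional projection in the first place.
* **Projection order.** By default the PCA is fitted on the training rows
  only and the held-out trial is projected into it (no leakage);
  `pca_on_train_only = FALSE` reproduces the literal
  reduce-everything-then-hold-out order. With the pooled covariance both
  orders are chance-calibrated; the no-leakage order is the default.

A further point matters when interpreting calibration numbers: on one
fixed dataset the 500 iterations re-decode the same 114 trials, so the
accuracy estimate inherits that dataset's realised class-mean
separations and varies across datasets with a standard deviation of
roughly 0.04–0.05 — far more than the binomial error of 500 independent
draws. Calibration checks therefore pool held-out draws across several
independently generated null populations, which restores the binomial
error model for the pooled estimate.

The control classifier is a one-vs-one error-correcting output codes
model over binary k-nearest-neighbour learners (k = 5, Euclidean metric,
15 learners for six classes), decoded by vote count; prediction ties
break to the lowest carbon number in both classifiers. Decoding curves
are compared per size with two-proportion tests, Šídák-adjusted across
sizes — a deliberately simple substitute for mixed-effects modelling of
accuracy curves, which is out of scope.

## Spike detection

The preprocessing chain for raw voltage traces is included to validate
its formulas on synthetic traces (`synthesize_raw_traces()`): common
average referencing, a zero-phase 300–5000 Hz Butterworth band-pass
(design order 4 passed to the band-pass designer, i.e. four pole pairs;
forward–backward filtering over an odd-reflection-padded trace so startup
transients decay outside the returned segment), and amplitude
thresholding at 7.5 × a median-based noise estimate. "Median deviation of
the absolute values" is read literally as `median(|x|)` by default; the
conventional Gaussian-consistent `median(|x|)/0.6745` is available as
`scaled_median_abs`. Detection polarity defaults to negative
(extracellular somatic spikes). Threshold crossings collapse to the
extremum sample, and events closer than 1 ms merge, keeping the larger
excursion. Spike sorting is deliberately absent: synthetic sessions are
born sorted, and the AON inclusion rule (mean rate > 0.5 Hz,
`filter_units_by_rate()`) plus tetrode deduplication cover the
unit-selection steps.

## Statistical notes and numerical choices

* `welch_anova()` and `brown_forsythe_anova()` are implemented from their
  defining formulas (Welch–Satterthwaite and Satterthwaite denominator
  df); base R's `oneway.test` serves as an independent oracle in the test
  suite, and simulated type-I error for both (and Mann–Whitney) is held
  inside [0.035, 0.065] at α = 0.05.
* `mann_whitney_u()` enumerates the exact null distribution of the rank
  sum (a subset-sum count over observed midranks, valid under ties) when
  `n_a·n_b ≤ 200`, and otherwise uses the tie-corrected normal
  approximation with continuity correction.
* Note an identity often misremembered: Welch's F equals the classical
  one-way F for equal sizes and equal sample variances only at k = 2;
  for k > 2 Welch's denominator correction differs from 1 even then.
* Games–Howell p-values use R's `ptukey` (studentized range), accurate to
  well below the 10⁻⁴ target.
* Degenerate inputs are surfaced, not patched: zero-variance groups and
  all-identical ANOVA inputs are errors; σ_baseline = 0 unit-odour pairs
  and infinite d′ pairs are flagged and excluded from summaries.

## Problem sizes

The shipped workflow and test suite run at sizes chosen to exercise the
design while staying desk-scale: sessions of 100 units per genotype (the
study-scale contrast harness uses 10 seed replicates, decoding at sizes
10 and 100 with 200 iterations per size), a 500-unit session for
parameter recovery of the classification stage, 2000 replicates for
type-I calibration, and 500 pooled held-out draws over 10 populations
for decoder chance calibration. The full-resolution settings (sizes in
steps of 10 up to the population size, 500 iterations per size) are the
package defaults.

## Limitations

* The generator's independence across units makes population decoding
  easier than in real recordings with correlated noise; accuracy numbers
  on synthetic data are best treated as upper bounds.
* The repeated-measures ANOVA uses the classical univariate stratum
  partition without sphericity correction.
* The kNN/ECOC control classifier fixes one-vs-one coding and k = 5;
  both are exposed but not tuned.
* Raw-trace synthesis stores channels × samples in memory, so it is
  intended for short validation segments, not full-length sessions.
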