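---
title: "Methods: individual baroreflex-chemoreflex testing from repeated phenylephrine boli"
author: "baroN1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual baroreflex-chemoreflex testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroN1)
```

## The physiological question

Arterial baroreflexes buffer blood-pressure fluctuations; carotid-body
chemoreflexes, activated by hypoxia, raise sympathetic outflow and interact
inhibitorily with the baroreflex at the brainstem. Group averages hide the
fact that individuals differ widely in how chemoreflex activation changes
their baroreflex function — a difference that matters when selecting
patients for baroreflex- or chemoreflex-targeted interventions. The design
this package supports treats each subject as their own trial (an N-of-1
design): many identical phenylephrine boli are given under normoxia and
under normocapnic hypoxia, each bolus yielding one replicate measurement of
two quantities:

* **Cardiovagal baroreflex sensitivity (BRS)**, in ms/mmHg: the slope of the
  regression of RR interval on systolic blood pressure (SBP) during the
  drug-induced pressure rise — the pharmacological Oxford technique. The
  regression pairs each systolic value with the RR interval of the
  *following* beat, the conventional one-beat lag for vagally mediated
  responses.
* **Pressor sensitivity (ΔSBP)**, in mmHg: the systolic rise from the
  pre-bolus baseline to the post-bolus maximum. Larger rises for a fixed
  dose indicate weaker baroreflex blood-pressure buffering.

## Per-bolus extraction

For each bolus the package computes, on the beat-indexed series:

* **Baseline SBP** — the arithmetic mean of the 10 beats immediately
  preceding the injection. "Readings" in a beat-to-beat record are beats,
  so the window is defined in beats, not seconds.
* **Peak SBP** — the maximal mean of 3 *consecutive* systolic values among
  post-bolus beats within 60 s of the injection; ties break to the earliest
  window. ΔSBP is peak minus baseline, exactly.
* **BRS** — ordinary least squares of RRI(i+lag) on SBP(i) over the rise
  phase, with `lag = 1` by default (`0` and `2` are available). The
  regression keeps its intercept: a zero-intercept fit of raw RR interval
  on raw pressure would be physiologically meaningless. A slope is accepted
  only when Pearson's r **strictly** exceeds 0.5; rejected boli are carried
  with `accepted = FALSE`, never dropped, so the number of analyzable boli
  can differ between the BRS and ΔSBP metrics.

**Rise-phase definition.** Published descriptions of the technique rarely
state an onset criterion. Here the rise phase starts at the first
post-bolus beat whose SBP exceeds baseline + 2 × SD of the baseline beats
(an objective, reproducible threshold) and ends at the central beat of the
winning peak window; at least 5 pairs are required (`min_pairs`,
configurable). With noise-free input the threshold degenerates to
"first beat above baseline", and the estimator returns the generator's
true slope exactly — a property the test suite asserts.

## Individual and group inference

Per subject and metric, the per-bolus values of the two conditions are
compared with an unpaired t test. Welch's unequal-variance form is the
default (safest when bolus-to-bolus variability differs between
conditions); the pooled form is available via a flag, and the two coincide
when SEMs and n match. `welch_t_from_summary()` computes the same test
from printed mean/SEM/n rows, which makes published per-subject tables
directly checkable. Classification at α = 0.05: *decreased* / *increased*
when significant (by the sign of hypoxia − normoxia), else *unchanged*.
No multiple-testing correction is applied by default, matching per-subject
reporting at 0.05; Holm adjustment is available.

At cohort level each subject-condition is condensed to the **median** of
its boli (robust to outlier boli) for the paired t test, while **means ±
SEM** are used for table display — both conventions appear in published
summaries of this design, so both are computed and labelled.
`correlate_changes()` tests whether per-subject BRS changes and pressor
changes travel together (with the packaged reference summaries they do
not: r ≈ 0.16, p ≈ 0.69, recomputed by the test suite).

## The synthetic-data generator

The simulator exists so that every downstream stage is testable without
recordings. It generates beats sequentially: beat k+1 occurs RRI(k+1) ms
after beat k; SBP(i) = baseline + pressor(t) + white noise; the RR interval
ending at beat i+1 is `60000/HR + b × (SBP_i − baseline) + noise`. Because
the RR interval responds to the *realized* (noisy) pressure — as the reflex
itself does — the downstream regression is structurally unbiased, with no
errors-in-variables attenuation.

Choices a user should know about:

* **Transient shape**: a gamma-like kernel `(t/35)^3 exp(3(1 − t/35))`
  peaking at 35 s and truncated at 180 s. Only amplitude and the 60-s peak
  window are constrained by the protocol; the shape parameters are
  configurable and the extraction never depends on them.
* **Bolus-to-bolus dispersion**: each bolus draws its own pressor amplitude
  (normal around `dsbp_true`, truncated below at 5 mmHg) *and its own true
  slope* (normal around `brs_true`). Real repeated-bolus data show
  per-bolus slope SDs of 3.6–13 ms/mmHg (SEM × √n of the reference
  summaries) — far more than white RRI noise transmits to a regression over
  a ~25-beat rise. Attributing the whole dispersion to beat-level noise
  would push per-bolus correlations below the r > 0.5 acceptance threshold
  for the noisier subjects and reject most of their boli, which is not what
  the reference data show (8–20 accepted boli per subject-condition).
  Splitting the dispersion into a dominant bolus-level component plus
  moderate beat-level noise (defaults: RRI 25 ms, SBP 3 mmHg, typical
  beat-to-beat variability) reproduces both the per-bolus slope SD and
  realistic acceptance counts.
* **Default cohort** (`reference_cohort_spec()`): nine subjects whose true
  per-condition BRS and ΔSBP equal the published per-subject means, with
  dispersions SEM × √n; baselines use the published group values (SBP
  133/135 mmHg, HR 63/76 bpm in normoxia/hypoxia), 20 boli every 240 s.
  Generated RR intervals and pressures saturate at physiological bounds
  (300–2000 ms, 50–300 mmHg), a rare event under defaults.
* **Reproducibility**: per-subject substreams are derived from the master
  seed and a hash of the subject id, so cohort composition and order never
  perturb another subject's data; identical spec + seed gives bit-identical
  output.
* **What is not simulated**: intra-beat waveforms, ECG, the 10-min hypoxia
  onset ramp (conditions are stationary; all boli fall after the ramp),
  pharmacokinetics, and closed-loop SpO2 control. Respiratory sinus
  arrhythmia is off by default but can be enabled (`rsa_amplitude`) to
  probe ventilatory entrainment of the estimator. Passing tests on
  simulated data therefore validate the *pipeline's statistics*, not
  device- or artifact-robustness on raw recordings.

A deliberate consequence of the 3-beat max-window peak statistic is a small
positive bias of extracted ΔSBP under beat noise (the maximum of noisy
window means exceeds the noise-free peak); with zero noise ΔSBP equals the
injected amplitude up to beat discretization. The bias largely cancels in
condition *differences*, which is what the inference layer tests.

## Repetition planning

`sensitivity_curve()` answers "how many boli per condition?" by
simulation. For each candidate n it draws responder individuals (true
difference ~ Normal(6, 3²) ms/mmHg by default, the empirical effect
distribution for hypoxia-induced BRS change) and non-responders (difference
0), gives each n noisy boli per condition (per-bolus SD defaulting to the
median SEM × √n of the reference summaries, ≈ 6.5 ms/mmHg), and measures
detection two ways:

* **ttest_power** — the fraction of responders with Welch p < α. With the
  effect SD set to 0 this is ordinary power, and the suite cross-checks it
  against the exact noncentral-t closed form (`closed_form_power()`); the
  pooled-test variant is used for that comparison because the closed form
  *is* the pooled test's power, while Welch is marginally conservative at
  small n.
* **roc_mean_classifier** — the observed mean difference as a score, with
  sensitivity read at the Youden-optimal point of the responder /
  non-responder ROC curve (AUC reported alongside).

A published analysis of this design reported an optimal repetition number
of ten boli at a sensitivity of 0.96 from an ROC procedure whose inputs and
operating point were not described; that figure is therefore treated as a
qualitative surface, not a numeric target. Both readings implemented here
are printed side by side so users can locate which assumptions reproduce a
given operating point. Under the defaults above, the t-test reading yields
a sensitivity near 0.5 at ten boli and the ROC-Youden reading near 0.75 —
sensitivity at a fixed specificity closer to 1 would be lower still, which
illustrates how strongly the answer depends on the unreported operating
point.

## Respiratory chemoreflex metrics

The hypoxic ventilatory response per subject is
`100 × (Ve_hypoxia − Ve_normoxia) / ΔSpO2`. The ×100 convention is
adopted because recomputing the published per-subject chemoreflex column
from its own ventilation and desaturation cells requires it (the printed
unit label "(l/min)/%" notwithstanding — the table's arithmetic is taken
as authoritative); `scale100 = FALSE` gives the plain ratio. A consistency
check flags rows where minute ventilation deviates from rate × tidal
volume by more than 20% (device-derived summaries need not multiply
exactly).

## Numerical and testing choices

* Slopes use the closed-form covariance ratio; the suite checks equality
  with `lm()` and with an explicit sum-of-squares formula to 1e-9, and the
  peak search against brute-force enumeration of all 3-beat windows.
* Degenerate inputs are explicit: both-SEMs-zero summary tests return t = 0
  (equal means) or ±Inf with p = 0; zero-variance regressions and
  sub-minimum rise phases return reasoned no-slope results; paired tests on
  constant differences set a `degenerate` flag.
* Monte-Carlo problem sizes in the test suite were chosen to keep the whole
  suite around two minutes while leaving comfortable statistical margins:
  the parameter-recovery study runs the full nine-subject cohort over 100
  seeds, the type-I calibration uses 2000 null replicates (17 boli per
  arm), and the power cross-check uses 3000 replicates per cell of a 3 × 3
  (effect, n) grid with binomial-exact tolerances.
* The per-subject unpaired test reconstructs almost all published
  per-subject t values to ~1% from the printed summaries; one subject's
  printed BRS t statistic (subject 06) is not recoverable from its own
  mean/SEM/n row under either the Welch or pooled form, though its
  significance classification is. The reconstruction is reported as
  computed.

## Limitations

The package analyzes beat-indexed tables; it does not detect beats from raw
pressure or ECG waveforms, and upstream beat-detection errors will
propagate. The simulator's normality assumptions (per-bolus amplitudes and
slopes, beat noise) mirror the t-test machinery downstream; heavy-tailed
real data would be better served by the median-based group layer than by
the individual t tests. Crossover carry-over effects are not modeled —
condition order is randomized and can be inspected, matching the
descriptive treatment such designs typically receive.
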