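---
title: "Screening severe pediatric OSA from home sleep apnea tests: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening severe pediatric OSA from home sleep apnea tests: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedosa)
```

## The screening problem

Severe obstructive sleep apnea (OSA) in children — an obstructive
apnea–hypopnea index (AHI) of 10 or more events per hour on in-laboratory
polysomnography — benefits from early adenotonsillectomy, but
polysomnography is scarce and poorly tolerated by children. `pedosa`
implements a screening analysis for habitually snoring children aged 5–12
built from measurements a clinic and a caregiver can obtain at home:

* **Pulse oximetry**: the 3% oxygen desaturation index (ODI3) over a
  90-minute window after the first snore;
* **Snoring sound analysis**: the snore index (SI, snores per hour) and
  snoring sound energy (SSE, dB) in five bands (21–200, 201–400, 401–600,
  601–800, 801–1000 Hz);
* **Anatomy**: Brodsky tonsil grade (1–4) and the adenoidal-nasopharyngeal
  ratio (ANR) from lateral radiography;
* **Questionnaire**: the OSA-18 total score (18–126).

Each predictor is dichotomized at an operating cut-off (ODI3 ≥ 6.0 events/h,
ANR ≥ 0.78, tonsil grade = 4, SSE of 801–1000 Hz ≥ 22.0 dB, OSA-18 ≥ 77;
tonsil uses *equality*, the most hypertrophic grade, not ≥). Three screening
models combine them:

* **anatomical**: positive with ≥ 1 of {ANR ≥ 0.78, tonsil = 4};
* **home sleep apnea test (HSAT)**: positive with ≥ 1 of {ODI3 ≥ 6.0,
  SSE 801–1000 ≥ 22.0 dB};
* **combined**: score = 3·(ODI3 ≥ 6.0) + 2·(tonsil = 4) + 1·(ANR ≥ 0.78),
  positive when the score is ≥ 4.

The combined weights and threshold are *fixed constants* of the model; the
bootstrapped LASSO in this package justifies the choice of the three
variables (they are the first three selected, with the highest bootstrap
selection frequencies) but does not re-derive the integer weights, because
no unambiguous mapping from penalized coefficients to 3/2/1 exists. An
integer score admits only seven thresholds, and Youden's index on the score
can re-derive ≥ 4; `score_cohort()` plus `youden_dichotomize()` will do
this, but the shipped `model_spec("combined")` keeps the fixed threshold.

## Oximetry processing

`clean_trace()` marks samples invalid when they are 0 (sensor dropout),
below 50% (non-physiological), or jump more than 4 percentage points per
sampling step from the last valid sample (motion artifact). True
desaturations at 0.5 Hz descend ~1–2 points per sample, so the jump rule
does not clip genuine events. `select_window()` extracts the 90 minutes of
wall-clock time following the first snore — early-night recording is when a
caregiver can re-attach a dislodged sensor, and it covers at least one
sleep cycle. QC requires ≥ 75 *valid* minutes inside the window.

A desaturation event is operationalized in `compute_odi3()` as: SpO2 falls
≥ 3 points below the running baseline (the maximum valid SpO2 over the
preceding 30 s), lasts ≥ 4 s, and ends on recovery to within 1 point of the
baseline frozen at onset. The denominator is valid time, not elapsed time,
because artifact and wake data are excluded before analysis. Both choices
are isolated behind this one function so an alternative event definition
can be swapped in. Nominal 0.5 Hz sampling is assumed, with 1 Hz accepted
and ±10% timestamp jitter tolerated; no resampling is performed.

## Snoring sound analysis

Audio is mono PCM-16 at 44.1 kHz. Processing order: (1) `lowpass_1k()`
removes everything above 1000 Hz — room reflections dominate up there — as
an FFT brick-wall, which is exact for offline analysis (complete stop-band
suppression, untouched passband; an IIR design meeting the same contract at
44.1 kHz would need an impractically high order). (2) `window_energies()`
computes per-0.25-s-window RMS and a rectangular-window FFT power spectrum;
with no zero padding the bin width is exactly 4 Hz and Parseval holds to
machine precision. (3) `find_baseline()` bootstraps the background-noise
reference once: provisional baseline = RMS of the first 60 s, provisional
first snore located with it, final baseline = the 60 s immediately
preceding that snore. (4) `detect_snores()` marks a window as a snore epoch
when its RMS is ≥ 2× the baseline RMS. The 6 dB phrasing and the 2×
phrasing of this criterion differ by 0.02 dB; the implementation uses the
exact 2× amplitude form so both descriptions agree. A snore is a maximal
run of consecutive epochs lasting 0.5–3 s; longer runs are sustained noise
(or merged snoring) and are discarded whole rather than split, which would
invent event boundaries. No gap tolerance is applied: "consecutive" is
taken literally.

SI is snores per hour of analyzed time (the full protocol analyzes 360 min
after the first snore; QC requires ≥ 300). SSE per band is the mean
snore-epoch power in that band in dB over the baseline's same-band power,
floored at 0 dB. The dB reference is deliberately noise-relative: reported
group summaries bottom out at exactly 0 dB, consistent with a floored
noise-relative measure, and it makes SSE invariant to recording gain.
Band membership is (lo, hi] on the 4-Hz bin grid; the nominal analysis
range starts at 41 Hz in one description and 21 Hz in the band tables, so
the implementation keeps every bin above 20 Hz and lets the first band be
(20, 200]. SI is reported in events/h (the tables' unit), although one
methods sentence says events/min; the tables win.

## The synthetic-data module

No recordings are public, so the generator is a first-class module that
emulates the *statistical structure* the analysis assumes, with planted
ground truth for detector validation.

**Cohorts** (`generate_cohort()`): severity labels by quota (exact group
sizes — the case-matched design) or Bernoulli draws. Continuous features
are drawn from two-piece ("split") distributions matched exactly to the
requested median and quartiles on a transformed scale: log for strictly
positive right-skewed rates (ODI3, SI, AHI, AI), logit for bounded ratios
and scores (ANR on (0,1), OSA-18 on (18,126)), identity for BMI z-score,
age, and the SSE bands — SSE is already a decibel quantity, so modelling it
log-normally would double-exponentiate the tail; on the dB scale it is
floored at 0 and capped at 55 dB, which also keeps simulated bursts inside
16-bit PCM headroom. A plain two-parameter log-normal cannot reproduce the
asymmetric quartile triples reported for these cohorts (e.g. ODI3 22.2 with
IQR 16.7–33.9), which is why the two-piece family is used; it is exact at
all three quantiles at the cost of a density kink at the median, which
nothing downstream sees. Tonsil grade is categorical over 1–4 with
probabilities chosen to reproduce the reported per-group quartiles.
Obstructive AHI is truncated at the 10 events/h boundary so the severity
label invariant (severe ⇔ AHI ≥ 10) holds by construction; the truncation
shifts AHI quartiles (most visibly the non-severe upper quartile), so
quantile-fidelity guarantees apply to the unconstrained features, not AHI.
Features are drawn independently given severity — real predictors are
correlated (ANR with ODI3, tonsil with SSE), so simulated *joint* model
performance is not expected to reproduce published joint statistics; what
passing tests show is that each marginal mechanism and every estimator is
correct, not that the generator recreates the study's dependence structure.

**Oximetry traces** (`simulate_spo2_trace()`): square dips of known depth
and duration with one half-depth ramp sample on each side (so cleaning's
jump rule tolerates them), planted after the first snore plus a 60-s
baseline lead, separated by ≥ 30 s so events cannot merge, at a rate
defined relative to the plantable span so a windowed analysis measures the
requested rate back. Artifacts (dropouts to 0, downward spikes of 8–20
points) are isolated from each other and from events. Square dips are
deliberately non-physiological: they make the planted truth unambiguous
for detector testing.

**Snore audio** (`simulate_snore_audio()`): Gaussian noise floor plus
bursts that start on the 0.25-s analysis grid. Each burst is one 0.25-s
in-band noise segment, spectrally shaped so each SSE band carries
`10^(gain/10) − 1` times the expected noise band power (total in-band
power during the burst is then exactly `gain` dB over baseline), tiled
over the burst duration — every 4-Hz-grid component is periodic in 0.25 s,
so the tiling is continuous at block boundaries and each analysis window
sees the calibrated band powers without leakage; the resulting
quasi-periodicity is snore-like. Burst edges get 50-ms raised-cosine
ramps, because an abrupt in-band onset has wideband spectral splatter that
the 1-kHz brick-wall would otherwise turn into ringing tails that bridge
adjacent snores at high gains. Known limitation: when one band is planted
tens of dB louder than a neighbor, edge leakage can still bias the quiet
neighbor's measured energy upward by a couple of dB; recovery is within
~0.5 dB when planted gains are within ~20 dB of each other. The simulator
refuses gain vectors too weak for the 2× detection criterion rather than
planting undetectable snores.

## Statistical estimators

`youden_dichotomize()` evaluates candidate cut-offs at midpoints between
sorted unique values (plus ±∞) — midpoints avoid the direction ambiguity
of thresholding at observed values — and maximizes J = sensitivity +
specificity − 1, breaking ties toward higher specificity (a screening
false positive costs a polysomnography slot). AUC is the tie-corrected
Mann–Whitney statistic. `fit_univariate_logistic()` is a maximum-likelihood
fit whose odds ratio provably equals the 2×2 cross-product for a binary
predictor; a zero cell (separation) triggers the Haldane–Anscombe +0.5
correction with a Woolf CI, flagged. `lasso_bootstrap()` delegates the
L1 path to glmnet (50-point grid from the all-zero penalty down to 0.001
of it, standardized predictors) and reports, for 100 bootstrap resamples
of size 50, how often each predictor is active at the reference penalty —
the largest penalty at which the full-data path carries exactly three
predictors, the size of the combined model. `hodges_lehmann()` is the
median of all pairwise between-group differences with a distribution-free
CI at the Mann–Whitney critical ranks. `cohens_kappa()`, `odds_ratio()`,
`confusion_metrics()` are the standard estimators; ratios with zero
denominators are reported missing, never 0. Display rounding is half away
from zero (whole percentages; OR to 1 decimal; kappa and AUC to 2), the
convention of clinical tables.

`reconstruct_cm()` inverts a printed table row: whole-percent sensitivity
and specificity plus the two group sizes determine the integer confusion
matrix exactly, from which the remaining columns (predictive values,
accuracy, odds ratio, kappa) can be recomputed. Two internal
inconsistencies surface and are flagged rather than hidden: the tonsil-size
odds ratio (printed 10.0, reconstructed 5.5), and the combined model's
sensitivity (printed 91%, but its own counts give 19/21 = 90%).

## Numerical and design choices

* Logistic fits use `stats::glm` defaults (IRLS); glmnet handles the
  penalized path. Bootstrap resamples are redrawn until both classes are
  present (size-50 resamples of a ~54% prevalence cohort rarely need it).
* The epoch threshold is the exact 2× amplitude form; the reference
  penalty falls back to the largest penalty with ≥ 3 active predictors if
  the path never pauses at exactly 3.
* QC rules are the protocol's two exclusions only: < 75 valid oximetry
  minutes, < 300 analyzed audio minutes. `run_pipeline()` keeps exclusion
  bookkeeping exact (analyzed + excluded = enrolled) and is deterministic
  given its seed, including byte-identical written reports.
* Pipeline signal mode simulates per-patient recordings at reduced
  durations (100-min traces, 2.5-min audio by default) and caps planted
  event rates at what the separation constraints can hold (55 desaturation
  events/h, 2000 snores/h); targets beyond the caps are truncated, which
  only matters far above every operating cut-off.
* Problem sizes in the test-suite: quantile fidelity at n = 5,000–10,000
  draws; ODI3 recovery over 100 planted traces; acoustic recovery over 20
  seeds; Youden cut-off recovery on cohorts of 500, where the estimator's
  sampling spread fits inside the (5.3, 7.5) inter-quartile gap around the
  operating cut-off (at the study's own n = 39 the Youden maximizer is far
  too variable to pin one decimal); LASSO selection over 20 seeds of a
  designed problem with the three informative predictors' margins taken
  from the discovery table plus two label-independent noise predictors.

## Limitations

The generator does not model sleep-stage architecture, respiratory effort,
airflow, room acoustics, or inter-feature correlation; oximetry events are
square; snore bursts are stationary band noise. Consequently the package
validates *methods* — detectors against planted truth, estimators against
brute-force oracles, printed-table arithmetic against reconstruction — and
cohort-level joint statistics on synthetic data are illustrative, not
replications. Scoring raw polysomnography, administering OSA-18, and
measuring ANR from radiographs are upstream of this package: their outputs
are its inputs.
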