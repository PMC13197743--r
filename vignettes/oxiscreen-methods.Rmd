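---
title: "Methods: oximetry parameters, screening models, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oximetry parameters, screening models, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oxiscreen)
```

# Scope and signal model

`oxiscreen` operates on nocturnal SpO2 traces reduced to a canonical
1 Hz representation. A recording is a value vector plus a per-sample
validity mask; samples below 40% or above 100% are physiologically
implausible oximeter artifacts and are masked automatically, and every
computation downstream consumes valid samples only. Time is 0-based
and sample-indexed with half-open 1-second windows, so sample *k*
covers `[k, k+1)` seconds. Higher native rates (oximeters in sleep
labs commonly sample at hundreds of Hz) are reduced by per-second
arithmetic means of valid samples: averaging is robust to sampling
jitter and preserves threshold statistics such as T90 better than
decimation, which can alias a single outlying sample into a whole
second. A 1-second window with no valid native sample is itself
masked. Recordings qualify for analysis when they carry strictly more
than 4 hours of valid signal; clinical practice precedes this rule
with manual review, which has no algorithmic specification, so the
mask-based count is a declared stand-in.

Total sleep time (TST) normalizes ODI and ST90; total recording time
(TRT) normalizes the hypoxic burden. Without sleep staging — home
sleep apnea testing, and all synthetic data here — TST is taken equal
to TRT. This biases ODI and ST90 slightly downward relative to a
staged recording with wake time; it affects OSA and non-OSA subjects
alike and is the standard concession of oximetry-only screening.

# Desaturation events

Event delineation follows a rainwater-trapping scheme on the 1 Hz
trace:

1. **Candidacy.** Local minima (plateaus collapse to their first
   sample; masked samples break extremal runs) with prominence of at
   least 2% against the nearest preceding local maximum become
   nadirs. The 2% floor is a package choice — the protocol states no
   floor — and exists to keep oximeter noise out of the burden
   integral while still admitting sub-4% desaturations; the 4% ODI
   rule is applied downstream on delineated events, never here.
2. **Merging.** Adjacent nadirs with no 75% recovery between them are
   one physiological event; such runs merge onto their deepest nadir.
   Without this, flank noise splits deep desaturations and inflates
   ODI by 15–20% at realistic noise levels (measured during
   development at noise SD 0.3%).
3. **Windows.** From each nadir, the window extends to the nearest
   samples on either side recovering at least 75% of the preceding
   peak-to-nadir amplitude, clipped at run edges and at midpoints
   between adjacent nadirs so windows stay pairwise disjoint and no
   deficit is counted twice.
4. **Refinement.** After a first pass, windows longer than twice the
   pass-one mean duration are clipped symmetrically about their nadir
   to that cap. The source protocol says only that boundaries are
   "adjusted based on the mean event duration"; the 2×-mean symmetric
   cap is a declared interpretation.
5. **Baseline.** The maximum SpO2 in the 100 s preceding the window
   start ("event onset" is read as window start, not nadir — the more
   conservative choice, since the nadir-anchored window would overlap
   the event's own descent). An empty prefix falls back to the
   preceding peak value.
6. **Area.** The trapezoidal integral of `max(0, baseline − SpO2)`
   across the window's sample nodes. Trapezoid rather than a
   rectangle sum: it is the exact integral for piecewise-linear test
   events and the convention the package's own oracle checks demand.
   Event depth is the maximal in-window deficit — equal to baseline
   minus the nadir value on clean signals, and guaranteeing
   `area ≤ depth × duration` under noise.

Hypoxic burden is the summed area over all events, converted to
%·min, divided by TRT in hours. ODI counts events of depth ≥ 4% per
TST hour; no minimum event duration is imposed (the 1 Hz grid implies
a 1 s floor). Both statistics share one delineation; whether ODI
should instead use an independent moving baseline is not specified by
the protocol, and sharing avoids two inconsistent event definitions.

# Summary parameters

**Attention entropy.** Local maxima and minima define four interval
streams (max→max, min→min, max→next-min, min→next-max). Each stream's
intervals, binned at the native 1-second resolution, give an
empirical distribution; the statistic is the mean of the four
streams' Shannon entropies in nats. The underlying construction does
not pin down the base of the logarithm or the aggregation across
streams, and published cohort values differ between devices by
factors incompatible with any single convention, so absolute levels
are implementation-specific. Within one pipeline the statistic is
consistent: periodic signals score 0, fragmented ones score higher,
and a constant offset changes nothing.

**Ultradian band power.** The Lomb–Scargle periodogram of the
mean-removed valid samples — chosen because it needs no uniform grid,
so masked gaps are handled natively — is integrated over
0.014–0.035 Hz (30–70 s cycles, the periodicity of repetitive
obstructive desaturations) on a ≥ 200-point grid and reported as
`10·log10(P + 1e-12)`; the floor keeps constant signals finite at
−120 dB. The dB reference is arbitrary, so comparisons use in-band
*fractions* of spectral power, never absolute dB. For fraction checks
against an out-of-band tone the denominator integrates a range wide
enough to contain the tone; restricting the denominator to 0–0.05 Hz
would make the fraction a ratio of two leakage residuals and
meaningless.

# Synthetic cohorts — the stated world

The generator emulates exactly what the screening method consumes: a
per-subject baseline drawn once from Normal(96, 0.8)% (clipped at
100), non-overlapping desaturation dips with Poisson onsets at a
configurable rate, raised-cosine shape (smooth nadirs give the 75%
recovery rule well-defined flanks; a piecewise-linear option exists
for exact-area oracles), depths and durations drawn per event
(defaults 8 ± 2% and 30 ± 5 s, typical scored-event magnitudes), and
additive Gaussian noise (default 0.3%, a realistic oximeter noise
floor). Labels derive from the nominal event rate by the same
≥ 5 events/h rule that defines OSA from the AHI. Demographics default
to about 75% male with internal/external median ages of 45/60,
mirroring the qualitative cohort structure of the motivating study
design. Recording length defaults to 8 h; tests shorten it (0.5–4 h)
to stay inside their runtime budgets — length only scales the number
of events, not the per-second signal statistics.

What the generator does **not** emulate: sleep architecture and wake
time, airflow/effort channels, device transfer functions,
position-dependent baselines, and the long-tailed comorbidity-driven
covariance between parameters seen clinically. A green test therefore
establishes algorithmic correctness and protocol fidelity on the
stated world — it does not certify clinical performance figures, and
the package deliberately reports no reproduced clinical metric.

# Modeling protocol

Scaling is z-score with population-SD divisors; constant features map
to zero. The scaler is fitted per training fold. The source text
normalizes before cross-validation while also asserting leakage
prevention; per-fold fitting is the reading consistent with that
principle, and `scale_in_fold = FALSE` provides the literal ordering
for replication. SMOTE (k = 5, the technique's canonical default;
reduced when the minority class is smaller) interpolates minority
samples on segments toward minority neighbours, is applied only to
scaled training folds, and balances classes exactly; validation folds
keep the original distribution.

The six classifier families are in-package implementations written
against the protocol's fixed hyperparameters, because no external
boosting/SVM/forest library is available in the target environment:
L2-penalized logistic regression by IRLS (C = 1, tol 1e-4); an
RBF-kernel SVM fitted by simplified SMO (C = 1, gamma = "scale") with
Platt-scaled probabilities; a 100-tree gini random forest with sqrt
feature sampling; and three second-order (Newton) gradient boosters
sharing one exact-greedy split core — level-wise growth to depth 6
(learning rate 0.3, L2 lambda 1), leaf-wise growth to 31 leaves
(rate 0.1, min 20 samples per leaf), and oblivious/symmetric trees of
depth 6 on 64-bin quantized features (rate 0.03, leaf regularization
3, log-loss). Ordered target statistics — the remaining signature of
the ordered-boosting family — apply to categorical features, of which
this feature space has none, so the symmetric-tree structure is the
operative distinction. Unlisted hyperparameters sit at implementation
defaults and are recorded in the run manifest.

Evaluation at threshold 0.5 (unstated in the protocol; the standard
cut) produces the seven confusion metrics; AUC is the rank-based
concordance probability with half-credit ties. Fold metrics are
averaged (not pooled — "average performance across validation folds").
Subset search enumerates C(8,k) subsets for the requested sizes and
ranks by mean F1, tie-broken by mean AUC then lexicographic feature
names (a deterministic total order, since the protocol states none).
Sizes ≥ 5 are excluded by default — larger subsets add only marginal
gains — but remain available. The winner is retrained on the full
internal cohort *without* oversampling and validated on the external
cohort scaled by the internal scaler.

# Interpretation

**Nonlinearity.** Restricted cubic splines are natural cubic splines
(linear in the tails); the logistic fit uses a df = 5 basis with
knots at equally spaced quantiles — the protocol states only the
degrees of freedom — against the nested linear fit, giving a 4-df
likelihood-ratio test. Raw p-values are reported without
multiple-testing correction across the eight parameters, matching the
protocol. Calibration is verified by simulation: under a correctly
specified linear logit the rejection rate at nominal 0.05 must land
in [0.01, 0.10]; under a threshold-shaped logit, at or above 0.80
(n = 2000, 200 replicates).

**Attribution.** Tree families use exact path attribution: walking
each tree, the change in node value at every split is credited to the
split feature, so base value plus row sums equals the model margin
(logit for boosters, probability for the forest) to machine
precision. This is the path ("Saabas") scheme, not the interventional
TreeSHAP polynomial algorithm; it satisfies the additivity identity
exactly and ranks features equivalently in this low-dimensional
setting. Logistic and SVM models use seeded permutation sampling
against a ≤ 100-row background with a recentring step that restores
exact additivity. Normalized importance is mean |attribution| scaled
to sum to 1, hence scale-invariant.

**Subgroups.** Sex strata and age strata split at 60 years, with 60
itself in the older stratum. Strata that lose a class or fall below
5 subjects per class are skipped with machine-readable warning
records rather than silently dropped.

# Numerical conventions and degenerate inputs

Empty event sets give HB = ODI = 0. All-invalid signals and empty
files raise degenerate-input errors. Constant features z-score to 0;
single-class SMOTE input and out-of-range nadir indices raise
contract errors; single-class AUC is NA with a warning while the
threshold metrics remain. The SMO uses tolerance 1e-3 with a pass
guard; IRLS stops at step 1e-4; boosting hessians are floored at
1e-16. All randomness — cohort draws, fold assignment, SMOTE
interpolation, forest bootstraps, SMO index picks, sampling
attribution — flows from R's RNG under explicitly passed seeds, and
one master seed fans out to fixed per-stage seeds, which is what makes
two pipeline runs byte-identical.

# Known limitations

- Oximetry-only hypoxic burden: events are not coupled to scored
  airflow, so the burden differs from respiratory-event-anchored
  definitions on recordings with non-hypoxic apneas.
- Absolute AttnEn and TotalPower levels are convention-dependent;
  only within-pipeline contrasts are meaningful.
- The step-3 window refinement and the ODI baseline convention are
  declared interpretations of an under-specified protocol (see the
  delineation section).
- The learners are compact reimplementations: faithful to the stated
  hyperparameters and validated on separable synthetic cohorts, but
  not line-for-line ports of the large public libraries; exact
  clinical metric values from those libraries are out of scope.
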