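---
title: "Methods: routine formation and peri-event calcium dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: routine formation and peri-event calcium dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routinometry)
```

# The analysis problem

A mouse on a fixed-ratio-1 schedule learns, within a session, to repeat one
action sequence — poke the active hole (rNP), enter the magazine to collect
the reward (ME), exit (MX), return to the hole — with fewer and fewer
detours. `routinometry` quantifies that *routine formation* from timestamped
event logs, and asks whether simultaneously recorded bulk calcium activity
(fiber photometry, one ΔF/F trace per subject-session) is modulated by how
routinized the behavior currently is, over and above nuisance covariates.

The package covers the full chain: event segmentation, the routine index,
ΔF/F preprocessing, peri-event alignment, per-timepoint regression with
cluster-based permutation inference, post-hoc AUC tests, nested mixed-model
comparison, shuffle-null validations, and a synthetic cohort generator with
known ground truth so every stage can be verified without animal data.

# Behavioral segmentation

**Blocks** are transitions between adjacent action events. With the three
retained event kinds (rNP, ME, MX; non-rewarded pokes are dropped before
pairing because they do not occur in recording sessions), five block types
arise: the *cycle blocks* rNP-ME, ME-MX, MX-rNP needed to harvest a reward,
and the *non-cycle blocks* rNP-rNP (repeat poke) and MX-ME (magazine
re-entry). Adjacent pairs matching no named type (e.g. ME-ME, which cannot
occur in a well-formed log) are skipped and counted in a diagnostics
attribute rather than silently discarded. Tied timestamps produce
zero-duration blocks whose velocity is undefined; they are dropped with a
warning.

**Cycles** are the stretches between successive rNP-ME blocks — one
reward-to-reward unit. Two boundary conventions are defensible: measuring
from rNP to rNP (action to action) or from ME completion to ME completion
(reward receipt to reward receipt). The default is ME → ME, because the
routine index frames behavior as *cycle completion*, which ends with reward
receipt; `segment_cycles(anchor = "rNP")` switches to the alternative. A
cycle's member blocks are everything strictly between the delimiting rNP-ME
blocks plus the terminal rNP-ME block, so the minimal routine cycle has 3
blocks; `include_terminal = FALSE` gives the exclusive count.

Each block carries **session elapsed** (SE, onset time divided by session
duration — where the animal is in the session) and **block velocity**
(BV = 1/duration, 1/s — how fast the transition was executed). Both serve as
nuisance covariates downstream.

`choice_proportions()` and `blocks_per_cycle_curve()` summarize routine
formation behaviorally, binning by session elapsed. The bin count defaults
to 10 equal-width bins; published figures of this kind rarely state their
smoothing, so the bin width is an explicit argument, not a hidden constant.

# The routine index

For a cycle of duration $T(C)$ seconds,

$$\mathrm{RI}(C) = f\!\left(\frac{L}{T(C)}\right), \qquad L = 60\ \text{s/min},$$

with $f$ a normalizing transformation, by default the square root. The index
grows as cycles complete faster: $\mathrm{RI} = 1$ at one cycle per minute,
2 at 15 s cycles, 0.5 at 4 min cycles. Every block inherits the index of its
enclosing cycle ($\mathrm{RI}(x) = \mathrm{RI}(C)$); blocks before the first
or after the last reward belong to no cycle and are excluded from
regressions.

**Transformation selection.** Downstream analyses prefer an approximately
normal index. `select_transformation()` applies each candidate
transformation (linear, logarithmic, reciprocal, square root) to $L/T$ per
subject, measures the one-sample Kolmogorov–Smirnov distance between the
standardized transformed sample and the standard normal CDF, and selects the
transformation minimizing the group-mean distance. Two choices deserve
note:

* The reference normal uses the sample's *own* mean and SD
  (Lilliefors-style standardization), because the index's location and
  scale are arbitrary; and since only the *statistic* is compared across
  transformations — never its p-value — the Lilliefors null-distribution
  correction is unnecessary.
* Alternatives are compared against the square root by paired t-tests with
  a Dunnett-style adjustment implemented as max-|t| sign-flip resampling
  over the joint contrasts (closed-form multivariate-t machinery buys
  nothing here and resampling makes the assumptions explicit). Plain paired
  p-values are reported alongside.

# ΔF/F preprocessing

Raw fluorescence drifts slowly (bleaching, fiber coupling), so ΔF/F is
computed against a *sliding minimum-of-mean* control signal:

1. $F_{\mathrm{AVG}}(t)$: mean of $F_{\mathrm{RAW}}$ over the trailing
   0.75 s window ending at $t$;
2. $F_{\mathrm{BASELINE}}(t)$: minimum of $F_{\mathrm{AVG}}$ over the 3 s
   window ending at $t$;
3. $\Delta F/F(t) = (F_{\mathrm{RAW}}(t) - F_{\mathrm{BASELINE}}(t)) /
   F_{\mathrm{BASELINE}}(t)$.

Window alignment is causal (trailing) throughout, consistent with the
baseline being defined over the window *preceding* each frame; a centered
averaging window is available by flag. Leading frames with incomplete
windows use the available partial window rather than being dropped, so the
outputs have the same length as the input and no session time is lost; the
first ~3 s of baseline are accordingly less conservative. The whole pipeline
is scale-free: multiplying the raw trace by any positive constant leaves
ΔF/F unchanged (verified to 1e-12 in the tests).

ΔF/F is then smoothed with an exponentially weighted moving window of decay
constant τ = 0.2 s truncated at width ω = 1 s. With both a decay constant
and a width given but no kernel equation, the implementation reads this as a
truncated one-sided (causal) exponential kernel, renormalized over the
frames actually available so a constant signal is a fixed point even at the
edges; a symmetric variant is selectable. Finally the trace is z-scored by
the session-wide mean and SD (population SD — the session is the reference
population), so peri-event excerpts are comparable across subjects.

**Signal quality.** `snr_shuffle_test()` scores trial-aligned activity by a
variance-explained ratio: variance over time of the across-trial mean trace,
divided by the mean within-trial residual variance. No standard name-brand
formula exists for "the" SNR of evoked bulk signals, so this definition is
stated prominently rather than implied. Its null is built by independently
permuting timepoints within each trial (a circular-shift variant preserves
autocorrelation); p-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, so they are never exactly
zero.

# Peri-event alignment

`align_blocks()` builds the $K \times T$ matrix $Y$ of z-scored activity for
the $K$ blocks of one type, anchored at the block's initial event
(head-fixed) or terminal event (tail-fixed). The window length defaults to
half the mean block duration of that type, which keeps adjacent alignments
from overlapping. Numerical conventions, chosen so results are bit-exactly
reproducible:

* Event times (10 ms grid) map to the *nearest* 30 fps frame; exact
  half-frame ties round down.
* Window endpoints are inclusive on the frame grid: a ±0.5 s peri-event
  window at 30 fps spans 31 columns, and a 0.5 s AUC interval spans 16.
* Blocks shorter than the window are retained by default — their windows
  extend into adjacent behavior exactly as any fixed-window design allows —
  with `strict = TRUE` to exclude them.
* Rows whose window leaves the recording are dropped and reported, never
  silently truncated.

`interval_auc()` sums (not integrates) each row over an inclusive frame
interval, keeping values in frame units; AUCs over a partition of the axis
add up to the row sum exactly.

# Statistical inference

**Per-timepoint regression.** For one subject and block type,
$Y(:,t) = \beta_0(t) + \beta_{SE}(t)\,SE + \beta_{BV}(t)\,BV +
\beta_{RI}(t)\,RI$ is fitted by OLS independently at each timepoint
(one QR decomposition serves all timepoints). At least 8 blocks are
required to fit 4 coefficients with margin, and a rank check names the
collinear covariate pair on failure.

**Cluster-based permutation test.** Subjects' $\beta_{RI}(t)$ series are
stacked into $B_{RI} \in \mathbb{R}^{N_S \times T}$ and tested for deviation
from zero while controlling family-wise error over time. The construction
is the standard one-sample cluster permutation recipe, with every choice a
config key because no single convention is universal:

* cluster-forming rule: two-sided one-sample t per timepoint at
  $\alpha_{\mathrm{forming}} = 0.05$;
* cluster statistic: mass $= \sum |t|$ over each maximal supra-threshold
  run;
* null: random sign-flips of whole subject rows (the exchangeability unit
  under $H_0: \mathbb{E}\beta = 0$), recording the maximal cluster mass per
  permutation; $10^4$ permutations by default;
* p per observed cluster by the add-one estimator.

Sign-flips only change column means, not column sums of squares, so each
permutation costs one matrix product — $10^4$ permutations on an
$11 \times 50$ matrix take well under a second.

**Post-hoc AUC tests.** Over each significant interval, per-subject OLS of
summed activity on the same covariates gives one weight per subject per
covariate; a one-sample Wilcoxon signed-rank across subjects (exact null up
to $N_S = 25$, normal approximation with continuity correction beyond)
tests each covariate. Eleven same-signed weights give the exact two-sided
floor $p = 2 (1/2)^{11} \approx 9.77 \times 10^{-4}$, which the tests assert.

**Pre/post comparison.** Mean activity in $[-0.5, 0]$ vs $[0, 0.5]$ s around
rewarded magazine entry, averaged within subject, compared across subjects
by a two-sided paired Wilcoxon signed-rank test.

**Routine-index validation.** `shuffle_r2_validation()` computes, per
subject, the $R^2$ between the routine-index curve and a behavioral measure
curve over common session-elapsed bins, then re-pairs behavior curves with
*other* subjects' index curves and compares the mean $R^2$ against that
null. Re-pairing uses derangements by default — under self-pairing the
"null" would contain the very signal being tested; a full-permutation
variant exists for comparison. Subjects with fewer than 3 common occupied
bins are dropped with a warning.

**Nested model comparison.** Whether each covariate earns its place is
tested by fitting four nested linear mixed models to long-format activity
(subject, block, timepoint):

| model | fixed effects | parameters |
|---|---|---|
| RI | ri\*time | 6 |
| RI + SE | ri\*time + se\*time | 8 |
| RI + BV | ri\*time + bv\*time | 8 |
| Full | all three | 10 |

each with a per-subject random intercept, fitted by maximum likelihood (not
REML — the comparisons differ in fixed effects), and compared to the full
model by likelihood-ratio chi-square tests. Time enters as a *continuous*
covariate interacting with each behavioral metric: with categorical time the
parameter counts would balloon with the bin count, whereas the continuous
form gives exactly the 6/8/8/10 parameter ladder above (ΔDF 4, 2, 2) — the
df accounting this table structure implies. A random RI slope is available
by flag. Restricted log-likelihoods never exceed the full model's, which the
tests assert on every fitted dataset.

# The synthetic cohort generator

`simulate_cohort()` produces multi-subject sessions whose ground truth is
known exactly, emitting the same CSV dialects the file pipeline reads.

**Behavior.** The k-th cycle duration is

$$T_k = \left(T_{\min} + (T_0 - T_{\min})\,e^{-k/\kappa}\right) \cdot
\mathrm{LogNormal}(0, \sigma_T),$$

a decaying mean with multiplicative jitter on the *whole* duration. The
jitter placement matters: applied to the decay term alone, late-session
durations would become deterministic and the routine index would lose all
identifiable variation once the routine is formed — a regression on RI would
have nothing to estimate. Real animals stay variable; the generator does
too. Within a cycle, magazine dwell (log-normal, ~4 s) and poke-to-magazine
latency (~1.2 s, matching the training criterion that trained mice approach
within 2 s) have roughly duration-invariant scales, and the travel segment
absorbs the remainder. Non-routine blocks (repeat pokes, magazine
re-entries) are inserted with probabilities decaying logistically in session
elapsed, reproducing the qualitative choice-proportion and blocks-per-cycle
trends. Sessions end at 60 rewards or the configured duration, whichever
comes first. All times land on the 10 ms grid.

**Fluorescence.** Raw signal = bleach drift × (1 + transients + effects +
noise). Transients are GCaMP6s-like double exponentials (0.2 s rise, 1.5 s
decay — a shape choice, with no claim of biophysical fidelity) locked to
every event with log-normal amplitude jitter. Each *effect* entry adds
activity proportional to a behavioral covariate inside a fixed window around
rewarded magazine entries — the ground truth the regression should recover.
Effects enter at the ΔF/F level (inside the multiplicative envelope), so
the fitted $\beta_{RI}$ is directly comparable to the injected amplitude
after accounting for the smoothing kernel. Subject-level log-normal gains
on amplitude and initial cycle duration create between-subject variability.

**Default conditions.** 11 subjects, 3600 s sessions capped at 60 rewards,
$T_0 = 90$ s, $T_{\min} = 20$ s, $\kappa = 10$ cycles, $\sigma_T = 0.5$,
insertion probabilities decaying 0.45 → 0.15, 30 fps, 1% frame noise, and a
positive routine-index effect of 0.06 ΔF/F per RI unit in the 0–1.1 s
post-entry window plus 0.04 in the −0.5–0 s pre-entry window. The effect
amplitudes are deliberately clear of the noise floor: the default cohort is
the pipeline's *positive control*, and $\sigma_T = 0.5$ reflects realistic
cycle-to-cycle variability while keeping RI distinguishable from session
elapsed (under a smooth schedule the two are nearly collinear and the
regression, though unbiased, becomes uninformative). `null_effect_config()`
strips the effect map for negative-control cohorts.

**What the generator does not emulate:** isosbestic/hemodynamic artifacts,
movement artifacts, inter-day learning, astrocyte-specific kinetics, or any
circuit mechanism. Passing tests on synthetic cohorts demonstrates that the
*statistical machinery* recovers what was injected under the stated noise
model — not that any biological claim about real recordings is reproduced.

# Problem sizes and numerical tolerances used by the test suite

Oracle-equivalence checks (segmentation, ΔF/F, smoothing, AUC) run at
1e-12 tolerance against literal nested-loop reimplementations. Calibration
checks use 1,000 null weight matrices ($N_S = 11$, $T = 50$, 500
permutations each) for the cluster test's type-I error, 100 runs for
localized power, 100 cohorts (21 subjects × 30 cycles) for transformation
selection, 100 simulations for mixed-model LRT rates, and 200 simulations
for the SNR test. End-to-end cohort checks use the default 11-subject
configuration for positive controls and 40 ten-subject, 900 s null cohorts
for negative controls — session length shortened because a null cohort only
needs enough blocks per subject (≥ 8) to run the regression, and the
negative-control property is a per-cohort error rate, not an effect
estimate.

# Known limitations

* The cluster-forming threshold, cluster statistic, and permutation scheme
  are conventions; different choices change sensitivity. All are exposed as
  parameters and recorded in the results bundle.
* The SNR definition is a declared surrogate for an unstated quantity;
  compare only within, not across, definitions.
* The exponential-smoothing kernel is a reading of "time constant plus
  width"; original acquisition software may differ in edge handling.
* Mixed models default to a random intercept; strong per-subject slope
  heterogeneity calls for the random-slope option and more subjects.
* With fewer than ~8 usable blocks of a type per subject, that subject is
  excluded from that block type's analysis; very short or very disrupted
  sessions can thin the cohort below the 5-subject minimum for group
  inference.
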