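# routinometry

Linking operant routine formation to fiber-photometry calcium dynamics.

When a mouse works a fixed-ratio-1 schedule, its behavior condenses over a
session from varied exploration into a tight reward-seeking routine: poke
the active hole (rNP), enter the magazine for the reward (ME), exit (MX),
return to the hole. `routinometry` measures that condensation from
timestamped event logs and tests whether simultaneously recorded bulk
Ca²⁺ activity (ΔF/F from fiber photometry) tracks it. It is written for
behavioral-neuroscience analysts who have (a) Med-PC-style event logs at
10 ms resolution and (b) one fluorescence trace per subject-session at
30 frames/s — or who want to validate this class of analysis end-to-end on
synthetic data with known ground truth.

## The core quantities

**Blocks and cycles.** Behavior is segmented into *blocks* (transitions
between adjacent action events; five types: rNP-ME, ME-MX, MX-rNP, and the
non-routine rNP-rNP and MX-ME) and *cycles* (the block sequence between
successive rNP-ME blocks — one reward-to-reward unit).

**Routine index.** For a cycle of duration *T(C)* seconds,

    RI(C) = f( L / T(C) ),   L = 60 s/min,  f = √ by default

so faster cycle completion ⇒ larger RI. The transformation *f* is selected
by minimizing the per-subject Kolmogorov–Smirnov distance from normality of
the transformed index (`select_transformation()`).

**Peri-event regression.** Activity aligned around blocks of one type is
regressed, per timepoint, on session elapsed (SE), block velocity (BV) and
the routine index (RI):

    Y(:,t) = β₀(t) + β_SE(t)·SE + β_BV(t)·BV + β_RI(t)·RI

and the per-subject β_RI(t) series are tested at the group level with a
cluster-based permutation test (sign-flip null, cluster mass = Σ|t|, 10⁴
permutations), followed by Wilcoxon post-hoc tests on interval AUC weights
and likelihood-ratio comparison of nested mixed models.

## Worked example

Simulate a cohort with a known positive routine-index effect around
rewarded magazine entry, then run the whole analysis in memory:

```r
library(routinometry)

cfg    <- simulation_config(n_subjects = 8, session_duration = 1800, seed = 3)
cohort <- simulate_cohort(cfg)
result <- analyze_cohort(cohort$sessions, params = list(n_perm = 2000, seed = 3))
print(result)
#> <pipeline_result> 8 subject(s)
#>   rNP-ME (tail_fixed, window 0.58 s): 1 significant cluster(s)
#>     [-0.500, 0.000] s  mass 179.4  sign +1  p = 0.005997
#>   ME-MX (head_fixed, window 2.45 s): 1 significant cluster(s)
#>     [0.033, 1.567] s  mass 448.9  sign +1  p = 0.005997
#>   pre/post magazine entry: p = 0.007813
#>   routine-index transformation: logarithmic
```

Reading this: activity in the half-second before reward receipt (tail-fixed
rNP-ME alignment) and in the ~1.5 s after it (head-fixed ME-MX alignment)
carries significant positive routine-index weights — blocks executed while
behavior is more routinized come with higher peri-reward activity — which is
exactly what this cohort's generator injected (windows −0.5–0 s and
0–1.1 s; the detected cluster extends slightly past 1.1 s because the
causal smoothing kernel smears the injected box forward). The pre/post
p-value flags the mean activity change across magazine entry. The
transformation line reports which normalizing transformation minimized the
cohort's K–S distance (on real cohorts this is typically the square root;
a synthetic schedule need not match).

Individual stages are plain functions on plain objects:

```r
es <- cohort$sessions[[1]]$stream
blocks <- segment_blocks(es)
cycles <- segment_cycles(blocks)
routine_index(cycles$duration[1:3])
#> [1] 1.421 0.760 0.763
```

File-driven runs use `pipeline_config()` / `run_pipeline()`, which read the
events/trace CSV dialects (`time_s,event` and `time_s,f_raw`), write a
results bundle (`results.json`, beta-series and cycle CSVs), and are
byte-reproducible given the same config and seed.

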