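---
title: "Ignition, node-metastability and the synthetic disease continuum: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ignition, node-metastability and the synthetic disease continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ignitr)
```

## The measurement model

`ignitr` quantifies how broadly spontaneous regional events recruit the rest
of a parcellated brain network, from resting-state BOLD alone.

Per subject, the chain is:

1. **Band-pass** each region's signal to 0.01–0.09 Hz with a second-order
   Butterworth filter run forwards and backwards (`signal::filtfilt`), so the
   phase response is zero and event times are not displaced. The low edge
   removes scanner drift; the high edge removes respiratory/cardiac leakage.
   With a TR of 3 s the Nyquist frequency is 0.167 Hz, so the band is
   feasible; `bandpass()` refuses infeasible bands.
2. **z-score** each region over time. A region with zero temporal variance
   has no meaningful z-transform; `zscore()` raises a degenerate-signal error
   naming it rather than emitting NaNs.
3. **Detect events** as upward threshold crossings: `events[i,t] = 1` iff
   `z[i,t] > θ` and `z[i,t−1] ≤ θ`. The crossing definition (not
   above-threshold occupancy) makes an event a discrete ignition, and the
   first volume can never host one because its predecessor is unobserved.
4. **Window and integrate.** Each event (driver *i*, time *t*) opens a window
   of `window_trs` TRs that includes the trigger. Regions with ≥ 1 event in
   the window form the active set; the co-activation matrix is the clique on
   that set; **integration** is the largest connected component of this
   graph as a fraction of regions. Because the graph is a clique plus
   isolated nodes, integration equals the active fraction — an identity the
   test suite verifies exhaustively for all activity patterns up to 8
   regions, which lets `ignition_profile()` use the active-count shortcut
   instead of materializing one adjacency matrix per event. The general
   `integration()` routine (breadth-first search; checked against union-find
   and igraph on random graphs) remains available for arbitrary graphs.
5. **Summarize per region**: ignition = mean, node-metastability = standard
   deviation of that region's integration records.

Cohorts are compared through subject-level summaries (for example the mean
node-metastability over regions), cohort **hierarchies** (regions ranked by
cohort-mean node-metastability) and the **hierarchy disruption factor**,
`HDF(a, b) = sqrt(Σ_r (a_r − b_r)²)` over rank-aligned sorted values.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `threshold_theta` | 1.0 | z-units | canonical choice of the point-process threshold method; exposed because no single value is privileged |
| `window_trs` | 4 | TRs | the time integration takes to return to baseline at TR = 3 s |
| `band_low_hz`, `band_high_hz` | 0.01, 0.09 | Hz | standard resting-state BOLD band |
| `n_permutations` | 10,000 | — | p-value resolution ~1e-4 with the add-one correction |
| `alpha`, `fdr_q` | 0.05, 0.05 | — | conventional levels |
| `n_features` | 10 | — | fixed mRMR budget for comparability across problems |
| `k_range` | 2–5 | neighbours | small-cohort kNN; read inclusively because tuned optima at both endpoints are legitimate |

Three conventions are deliberate and switchable or documented:

* **Window anchoring.** The window starts at the trigger TR (`[t, t+3]`),
  and events whose window would overrun the scan are dropped, not truncated,
  so every record integrates the same window length.
* **Standard-deviation convention.** Node-metastability uses the population
  (n-denominator) standard deviation, matching common reference
  implementations of the framework; `ignition_profile(..., sd = "sample")`
  switches to the n−1 convention. At realistic event counts the difference
  is below one part in a hundred.
* **HDF takes the square root.** An "l2 norm" admits both `Σδ²` and
  `sqrt(Σδ²)` readings; only the rooted form satisfies
  `HDF = δ·sqrt(N)` for a uniform gap δ, which reproduces the scale of
  published whole-cohort values (a 0.024 gap over 379 regions gives 0.467).
  The rooted form is also a metric, which the suite tests (symmetry,
  triangle inequality).

## The synthetic cohort generator

Real cohort data for this analysis are access-restricted, so validation runs
on a generator whose ground truth is analytic.

**Clique events.** Global ignition events occur at Bernoulli-thinned TRs
with rate `event_rate`, separated by a refractory gap of `refractory_trs`
(default 3) TRs so that no 4-TR window straddles two events — each
integration record is then identified with exactly one generating event.
Per event, a recruitment fraction `f ~ Beta(recruit_alpha, recruit_beta)` is
drawn and every region activates independently with probability `f`; one
uniformly chosen nominal driver is always active. This model was chosen over
coupled-oscillator dynamics because it has a closed-form node-metastability
target: a region's records exist only at events that recruited it, which
size-biases `f` (a Beta(α, β) fraction becomes Beta(α+1, β)), and with `f*`
that size-biased fraction,

```
Var(I) = ((n−1)² Var(f*) + (n−1) E[f*(1−f*)]) / n²
```

(`clique_meta_sd()`). For Beta(2,2) at n = 100 this gives 0.2029; the
neglect of size-biasing would instead predict 0.228, and simulation sides
with the former — the acceptance suite checks 2% agreement at ≥ 10⁴ events.

**Severity.** Disease stage enters as shrinkage of `f` towards its mean,
`f' = μ + (1 − severity)(f − μ)`: it reduces exactly the variance that
node-metastability measures while leaving mean recruitment (hence ignition)
essentially unchanged. `severity_for_target()` inverts the closed form, and
`simulate_cohort()` defaults to severities that put cohort means at
0.094 / 0.087 / 0.070 for 17 HC / 9 MCI / 10 AD subjects at 379 regions —
the scale of the disease continuum the package models. Full shrinkage leaves
the binomial recruitment noise floor `sqrt((n−1) μ(1−μ))/n`, so targets
below that floor are rejected with the attainable range in the message.

**BOLD mode.** `raster_to_bold()` convolves each region's event train with a
canonical two-gamma haemodynamic kernel (positive lobe peaking at 6 s,
undershoot at 16 s, amplitude ratio 1/6, sampled at the TR) and adds
Gaussian noise, so the full chain — filtering, z-scoring, thresholded
detection — can be exercised end to end; with noiseless input the detector
recovers ≥ 95% of planted events within ±1 TR.

**Burden tables.** `generate_burden_tables()` draws per-region amyloid-β and
tau SUVR from log-normal distributions whose group means rise along the
continuum (1.31/1.52/2.01 for amyloid-β, 1.53/1.80/2.46 for tau, the scale
of cerebellum-referenced SUVR in such cohorts; regional log-sd 0.15), then
regenerates node-level metastability from a linear mixed-effects model with
known coefficients, a subject random intercept and i.i.d. residuals. The
default planted amyloid slope is −0.002 per SUVR unit; network-specific tau
slopes can be planted per RSN label.

**What the generator does not emulate.** Subjects within a cohort are
i.i.d.: there is no trait variance, no head motion, no spatial
autocorrelation, no structural connectome, and recruitment is exchangeable
across regions. Between-subject spread of whole-brain metastability is
therefore pure sampling noise — tighter than in real cohorts — so passing
cohort-level tests demonstrates correctness of the machinery under the
stated statistical structure, not robustness to real-data artefacts.

## Experiment sizes

Cohort-level experiments (the severity-ordering study in the acceptance
suite and `scripts/acceptance.R`) use 3,000-TR scans at event rate 0.15/TR,
i.e. roughly 300 global events per subject. The choice makes the sampling
standard deviation of subject-level whole-brain metastability about 2–5% of
its mean — comparable to, or tighter than, the between-subject spread
printed for real cohorts — so the planted HC > MCI > AD ordering is
detectable by permutation tests at the study's own group sizes (17/9/10).
These tests use 999 permutations per contrast; a 0.001 p-value floor is
ample for decisions at α = 0.05. The closed-form recovery experiment uses
100 regions and ~10⁴ events; mixed-effects recovery uses 100 replicates of
36 subjects × 100 regions (whole-brain) and × 70 regions in 7 networks
(RSN model).

## Statistical machinery

* **Permutation test**: two-sided difference of group means under label
  shuffling, `p = (1 + #{|Δperm| ≥ |Δobs|}) / (n_perm + 1)`. The add-one
  correction keeps p strictly positive; a tolerance of 1e-12 relative to the
  observed difference guards tie comparisons against floating-point jitter.
  Calibration (type-I rate within [0.03, 0.07] at α = 0.05) is asserted over
  1,000 null replicates.
* **FDR**: Benjamini–Hochberg via `stats::p.adjust`; the suite checks it
  against an independently hand-rolled step-up on random p-vectors.
* **Cohen's d** uses the Bessel-corrected pooled standard deviation.
  Recomputing d from printed group summaries (0.094 ± 0.0044, n = 17 vs
  0.070 ± 0.0037, n = 10) gives 5.767; printed values near 5.79 are
  consistent with rounding of the printed means.
* **Minimum detectable effect**: normal-approximation two-sample formula
  `d = (z_{1−α/2} + z_{power})·sqrt(1/n_a + 1/n_b)`, with an optional
  Wilcoxon ARE adjustment (÷ sqrt(0.955)). For 17 vs 10 at α = 0.05 and
  power 0.8 this brackets 1.12–1.14.

## Mixed-effects models

The whole-brain model is `metastability ~ abeta * tau + (1 | subject)`,
fitted by REML with Satterthwaite degrees of freedom (lmerTest). Diagnosis
has only three levels, so it is not used as a grouping factor.

The RSN-resolved syntax `meta ~ ABeta*Tau*RSN + (1 + RSN | ID/RSN)` found in
applied work is not fully well-formed; we read it as fixed three-way
interactions plus a subject random intercept and random RSN offsets nested
in subject, `(1 | subject) + (1 | subject:rsn)`. At n ≈ 36 subjects that
structure is fragile: if it fails to converge or is singular the fit is
downgraded to the random-intercept-only form and the result flags
`fallback = TRUE` rather than failing silently. Per-network burden effects
are evaluated as contrasts (main effect + interaction) with Satterthwaite
t-tests (`rsn_contrast()`); `SUBCORT` regions are excluded from the RSN
model throughout, and a single-network table degenerates gracefully to the
whole-brain model. Coverage of planted coefficients (95% CIs covering truth
in ≥ 90 of 100 replicates) is asserted for both the whole-brain amyloid
slope and a DAT-specific tau slope. The planted RSN slope in that experiment
is −0.02 per SUVR unit: with log-normal SUVR the tau and amyloid×tau columns
are strongly collinear, inflating per-network contrast standard errors to
~5e-3, and a slope of that size is what an a-priori power calculation puts
well above the detection floor.

## Classifier

Features are the four regional measures (ignition, node-metastability,
amyloid-β, tau) concatenated per subject. mRMR ranks features by mutual
information with the class label minus mean mutual information with already
selected features (the difference scheme), with mutual information estimated
on 4 equal-frequency bins — a coarse but stable estimator at n ≈ 30
subjects. Selection is deterministic; score ties resolve to the lower column
index, and constant features are excluded with a warning.

The evaluation is nested: leave-one-subject-out outside; inside each outer
fold, 20 repeated stratified 75/25 splits tune k ∈ {2, 3, 4, 5} by
validation accuracy (ties to the smaller k). Feature selection and tuning
see only the outer-fold training subjects, which the suite asserts directly:
corrupting a held-out label changes nothing about that fold's selection.
Test accuracy and AUC are computed from the pooled held-out scores — with
leave-one-out, pooling is the only way to obtain one ROC — and train metrics
come from refitting the tuned model on each full training fold (reported as
such, since averaged inner-fold metrics would be systematically lower). kNN
standardizes features by training-fold statistics, scores by neighbour vote
fraction, and breaks vote ties towards the alphabetically smaller class
label. Feature attribution is permutation importance (mean leave-one-out
accuracy drop when one feature's values are shuffled), recorded in the
output as `permutation_importance`; it is model-agnostic, which is the
contract here — exact Shapley-value estimation is deliberately not
reimplemented.

## Reproducibility

All randomness flows from one master seed: each stochastic stage derives a
substream seed via `stage_seed(master, stage_name)`, so stages are
reproducible independently of how much randomness other stages consume.
`run_pipeline()` with a fixed seed is byte-reproducible, which the suite
checks file by file. Tables are TSV with one header line; numeric cells are
written with 17 significant digits so write/read round trips are bitwise
lossless. Region order is the canonical alignment key, and mismatches raise
alignment errors naming the offending regions.

## Known limitations

* Phase-based (Hilbert) ignition variants and time-resolved integration
  curves are out of scope.
* The event-level co-activity definition uses threshold crossings within the
  window; above-threshold occupancy is a plausible alternative reading that
  would yield systematically higher integration. The crossing definition is
  the implemented one.
* The RSN label transfer matches volumetric centroids, not surface
  geodesics; ties go to the lowest source index.
* With 197-TR scans (a single standard acquisition) per-region event counts
  are small and subject-level metastability is noisy; cohort inferences at
  that scan length need the between-subject spread to dominate, which the
  generator does not emulate. Synthetic validation therefore uses longer
  scans, as stated above.
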