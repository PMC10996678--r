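# ignitr

Intrinsic ignition analysis of parcellated resting-state BOLD dynamics, for
studies of the Alzheimer's disease continuum (healthy controls, mild
cognitive impairment, Alzheimer's disease) and, more generally, for any
cohort comparison of whole-brain dynamical complexity.

## What it computes

The intrinsic ignition framework asks how broadly a spontaneous event in one
brain region recruits the rest of the network:

1. Each region's BOLD series is band-passed (0.01–0.09 Hz), z-scored, and
   converted to a point process: a **driving event** is an upward crossing of
   a threshold θ (default 1 z-unit), i.e. `z[i,t] > θ` and `z[i,t−1] ≤ θ`.
2. For every driving event, regions with at least one event inside a 4-TR
   window starting at the trigger form the simultaneously active set; the
   binary co-activation matrix links every pair of them.
3. **Integration** of the event is the size of the largest connected
   subcomponent of that graph as a fraction of regions.
4. Per region, **ignition** is the mean and **node-metastability** the
   standard deviation of its events' integration values.
5. A cohort **hierarchy** ranks regions by cohort-mean node-metastability;
   the **hierarchy disruption factor** between cohorts a and b is the l2
   distance between their rank-aligned hierarchies,
   `HDF(a,b) = sqrt(Σ_r (a_r − b_r)²)`.

Around that core the package provides Monte-Carlo permutation tests with
Benjamini–Hochberg FDR control and Cohen's d; minimum-detectable-effect
calculation; nearest-centroid transfer of the seven canonical resting-state
network labels; linear mixed-effects models linking node-metastability to
regional amyloid-β and tau SUVR
(`metastability ~ abeta * tau + (1 | subject)` at whole-brain level, with an
RSN-resolved three-way interaction variant); and a disease-stage classifier
(mRMR feature selection, kNN with nested leave-one-out cross-validation,
permutation feature attribution).

A synthetic cohort generator with an analytically known node-metastability
target (see the methods vignette) exercises the entire chain with ground
truth, including a haemodynamic BOLD mode.

## Worked example

```r
library(ignitr)

spec   <- synthetic_spec(n_regions = 379, n_timepoints = 3000, event_rate = 0.15)
cohort <- simulate_cohort(spec = spec, seed = 1)    # 17 HC, 9 MCI, 10 AD
m <- vapply(cohort$subjects, function(s)
  mean(ignition_profile(s, 4)$node_metastability, na.rm = TRUE), numeric(1))
groups <- split(m, cohort$manifest$diagnosis)[c("HC", "MCI", "AD")]
round(vapply(groups, mean, numeric(1)), 4)
#>     HC    MCI     AD
#> 0.0933 0.0866 0.0692
compare_groups(groups, n_perm = 999, seed = 2)
#>   group_a group_b    observed     p p_adj rejected  cohen_d
#> 1      HC     MCI 0.006683849 0.001 0.001     TRUE 2.494004
#> 2      HC      AD 0.024039749 0.001 0.001     TRUE 9.704917
#> 3     MCI      AD 0.017355900 0.001 0.001     TRUE 9.015746
```

The three cohorts are generated with decreasing recruitment variability, so
mean node-metastability declines along the disease continuum (here 0.0933 →
0.0866 → 0.0692) and every pairwise permutation test survives FDR correction —
the group means, the p-value floor of 999 permutations and the large effect
sizes are exactly what the printed numbers above show. `run_pipeline()`
chains every stage (profiles, hierarchies, HDF, RSN comparisons, LME models,
classification) and writes one TSV per result plus a JSON parameter log.

From printed summary statistics alone:

```r
cohen_d_from_stats(0.094, 0.0044, 17, 0.070, 0.0037, 10)  # 5.767
hdf(rep(0.094, 379), rep(0.070, 379))                     # 0.4672
min_detectable_d(17, 10)                                  # 1.1165
```

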