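# hconnica

Joint decomposition of functional and structural brain connectomes into
robust, task-sensitive **hybrid connectivity traits**.

## The problem

Functional connectivity (FC; Pearson correlations between regional fMRI
time courses) and structural connectivity (SC; streamline-weighted
white-matter networks from diffusion tractography) describe the same brain
in two modalities. `hconnica` asks what joint functional-structural
patterns are shared across a cohort and how strongly each individual
expresses them — in particular, which patterns track the task a subject is
performing.

Each subject-condition profile is modeled as a linear mixture

    x_p = Σ_k a_pk · t_k + ε

where `x_p` concatenates the FC upper triangle with the masked
structural-correlation edges, `t_k` are group-level **hybrid traits** and
`a_pk` per-profile **weights**. The pipeline:

1. `log10(1 + w)` transform of raw SC; **structural correlation** of each
   connected node pair (Pearson r between its two SC rows), restricted to
   the population **common-edge mask** (pairs nonzero in every subject) —
   placing SC in the same [-1, 1] range as FC;
2. hybrid matrix assembly (profiles × FC‖SC edges);
3. PCA reconstruction at 90% explained variance;
4. FastICA (tanh, symmetric decorrelation), repeated over bootstrap
   cohorts (default 100 runs, 10 subjects per condition); components
   recurring at |r| ≥ 0.5 in ≥ 50% of runs become **robust traits**
   (sign-aligned member means);
5. task sensitivity scored by one-way intraclass correlation,
   `ICC = (MSB − MSW) / (MSB + (k0 − 1)·MSW)`, of weights grouped by
   condition;
6. brain mapping via the **joint FC-SC mask** (edges outside the [5, 95]
   percentile window in *both* halves of a trait) and its nodal strength;
7. a degree-preserving edge-swap **null model** (50,000 accepted swaps)
   to verify traits are not FC-driven artifacts.

A synthetic cohort generator with planted traits (`synthetic_spec()`,
`generate_hybrid_population()`, `generate_raw_connectomes()`) makes every
stage testable end to end without any imaging data.

## Worked example

```r
library(hconnica)

spec <- synthetic_spec(n_nodes = 40, n_conditions = 4,
                       n_subjects_per_condition = 6,
                       k_traits = 3, k_sensitive = 1, seed = 2026)
cohort <- generate_raw_connectomes(spec)

cfg <- pipeline_config(
  decomposition_config(n_components = 6, n_runs = 20, seed = 2026))
res <- run_pipeline(cohort$fcs, cohort$scs, cfg)
print(res)
#> <pipeline_result> 24 profiles, 40 nodes, mask 107 edges (13.7%)
#>   3 robust trait(s), 1 task-sensitive
res$sensitivity
#>   trait frequency        icc       msb      msw task_sensitive
#> 3     3         1 0.69965802 32.820740 2.191376           TRUE
#> 1     1         1 0.06042368  8.101212 5.845633          FALSE
#> 2     2         1 0.05102230  7.023838 5.310656          FALSE
```

All three planted traits are recovered at full run frequency; only the
condition-modulated one crosses the ICC threshold (0.70 vs ~0.05). Against
the generator's ground truth:

```r
evaluate_recovery(cohort$truth, res$decomposition, block = "fc")
#>   true_trait sensitive trait_r icc_recovered
#> 1          1      TRUE   0.999         0.700
#> 2          2     FALSE   1.000         0.051
#> 3          3     FALSE   0.998         0.060
```

`trait_r` is the |Pearson r| between each planted trait and its matched
robust trait (FC half); `icc_recovered` reproduces the planted design:
the sensitive trait was planted with a condition-mean spread implying
ICC ≈ 0.69. Mapping the sensitive trait back to the brain:

```r
jm <- res$masks[[which.max(res$sensitivity$icc)]]
jm
#> <joint_mask> [5, 95] percentiles: FC 78, SC 12, joint 1 edge(s)
head(sort(nodal_strength(jm), decreasing = TRUE))
#>  n7 n14  n1  n2  n3  n4
#>   1   1   0   0   0   0
```

The joint mask keeps the node pairs extreme in both the functional and the
structural half of the trait; nodal strength counts joint edges per
region.

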