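---
title: "Extracting joint functional-structural connectome traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting joint functional-structural connectome traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hconnica)
```

## The problem and the model

A brain connectome comes in two modalities. Functional connectivity (FC) is
the Pearson correlation between regional fMRI time courses — square,
symmetric, signed, in [-1, 1]. Structural connectivity (SC) is the
streamline-weighted white-matter network from diffusion tractography —
square, symmetric, sparse, non-negative, spanning orders of magnitude.
`hconnica` extracts *hybrid traits*: group-level patterns that live jointly
in FC and SC edge space, each paired with one weight per subject-condition
profile quantifying how strongly that profile expresses the trait. Traits
whose weights shift systematically with the task a subject is performing
are *task-sensitive*.

The generative assumption is the linear mixing model of ICA. Writing
`x_p` for the vectorized hybrid profile of subject-condition `p`
(FC upper triangle concatenated with the masked SC block),

```
x_p = sum_k a_pk * t_k + noise,
```

where `t_k` are the hybrid traits and `a_pk` the subject weights. The
pipeline is:

1. **SC normalization.** Raw streamline weights are mapped through
   `log10(1 + w)`, then each structurally connected node pair (i, j) is
   replaced by the Pearson correlation of rows i and j of the
   log-transformed SC — the *structural correlation*, a matching-index-like
   similarity of connection profiles. This puts SC in the same [-1, 1]
   range as FC, which matters because ICA on concatenated blocks is only
   meaningful when their scales are comparable.
2. **Common-edge mask.** Structural correlations are only retained on
   pairs with nonzero streamline weight in *every* subject (intersection
   semantics). Elsewhere the structural architecture is not shared across
   the population and the correlation would be an artifact of the dense
   correlation transform.
3. **Hybrid assembly.** Each profile contributes one row: `n(n-1)/2` FC
   edges followed by the masked structural-correlation edges. Column order
   is immaterial to the decomposition; the package fixes a row-major
   canonical order so outputs are reproducible and de-vectorizable.
4. **PCA denoising.** The hybrid matrix is column-centered and
   reconstructed from the smallest number of leading principal components
   reaching 90% cumulative explained variance (means added back), then the
   reconstruction is passed to ICA.
5. **Multi-run FastICA.** Fixed-point FastICA (tanh contrast, symmetric
   decorrelation) is run many times (default 100), each run on a bootstrap
   cohort of distinct subjects (default 10 per condition). Components
   recurring across runs at |r| >= 0.5 in at least 50% of runs are
   clustered into *robust traits*; each robust trait is the sign-aligned
   member mean and its weights the per-profile mean over member runs.
6. **Task sensitivity.** One-way random-effects intraclass correlation,
   ICC(1,1) = (MSB - MSW) / (MSB + (k0 - 1) MSW), of a trait's weights
   grouped by condition. Conditions act as raters, weights as scores.
7. **Brain mapping.** A trait is split back into its FC and SC matrices;
   edges outside the [5, 95] percentile range of each half are marked
   extreme, and the *joint mask* is the AND of the two extreme sets — the
   circuit where functional and structural signatures coincide. Nodal
   strength (masked edges incident to each node) summarizes the circuit.
8. **Structural null model.** Degree-preserving double-edge swaps (default
   50,000 accepted swaps) randomize each SC while conserving size, density
   and degree sequence; re-running the pipeline on randomized SCs tests
   whether joint FC-SC structure is real or an FC-driven artifact.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `variance_fraction` | 0.90 | PCA cutoff; controls denoising strength |
| `n_components` (M) | 10 | ICA model order, clamped to the post-PCA rank |
| `n_runs` | 100 | FastICA repetitions for robustness |
| `r_thresh` | 0.5 | cross-run component match threshold (absolute Pearson r) |
| `freq_thresh` | 0.5 | minimum fraction of runs a robust trait appears in |
| `n_per_condition` | 10 | bootstrap cohort size per condition |
| `icc_threshold` | 0.5 | task-sensitivity flag on ICC |
| `lo`, `hi` | 5, 95 | percentile window for extreme-value masks |
| `n_swaps` | 50,000 | accepted swaps in the structural null |

Model order is data-dependent; `select_model_order()` scans a range of M
and scores each by the number of robust traits passing the ICC threshold
(ties: higher mean ICC, then smaller M). That lexicographic rule is our
concrete reading of "maximize robustness and task sensitivity jointly",
which admits several formalizations.

## Numerical choices

* **`log10(1 + w)` rather than `log10(w)`.** Tractography weights can be
  fractional (SIFT2-style cross-section multipliers) or zero; the +1 offset
  keeps zeros at zero, preserves sparsity and monotonicity, and maps counts
  up to ~1e5 into the 0-5 range typical of log-scaled streamline
  connectomes. For integer counts >= 1 it differs from a plain log10 by at
  most log10(2).
* **Structural correlation uses full rows by default** (including the
  pair's own entry and the zero diagonal); `exclude_pair_entries = TRUE`
  switches to the matching-index convention that drops columns i and j
  first. Masked pairs touching a constant row raise an error rather than
  propagating NaN.
* **Symmetrization tolerance 1e-9, then exact averaging** with the
  transpose; diagonals forced to zero on load. Correlation matrices are
  symmetric up to float noise; anything larger is a data error.
* **ICA scale and sign ambiguity** is fixed by unit-normalizing every
  trait vector (scale lives in the weights) and sign-aligning cluster
  members to their seed component. Cross-run matching uses |r|, since
  ICA signs are arbitrary.
* **Clustering is greedy**: seed with the unclustered component matched in
  the most other runs, take at most one (best) member per run, repeat.
  A full similarity-matrix clustering (ICASSO-style) is deliberately out
  of scope.
* **Percentiles use linear interpolation** (`quantile` type 7), strict
  inequalities outside the bounds; the convention is tagged in every
  `joint_mask`. For values 1..100 at (5, 95) this selects exactly the ten
  extreme values.
* **Model order is clamped to the post-PCA rank**: the reconstructed
  matrix cannot support more independent directions than it has, so a
  requested M above the rank is reduced (with a message) instead of
  whitening against numerically zero eigenvalues.
* **Weights for a robust trait are averaged only over member runs that
  sampled the profile**; profiles never sampled get `NA`, not zero, and
  ICC drops them.
* **Seeds.** Every stochastic step (bootstrap cohorts, ICA initialization,
  edge swaps, generators) derives child seeds deterministically from one
  master seed, so any result is reproducible bit-for-bit.

## What the synthetic generator emulates

`synthetic_spec()` describes a cohort mirroring the reference design:
8 conditions (rest + 7 tasks) x 10 subjects = 80 hybrid profiles, K = 5
planted traits of which 2 are task-sensitive, i.i.d. edge noise with sd
0.2 x trait scale, and a shared sparse SC topology from a stochastic block
model over eight canonical resting-state networks (within-network edge
probability 0.5, between 0.1, ~15-20% overall density, in the vicinity of
the ~21% common-edge density seen on real tractography cohorts).

Construction details that are deliberate modeling choices:

* **Disjoint block supports.** Planted trait k owns the within-RSN block
  of its primary network plus one between-RSN block, with no edge set
  shared between traits. ICA assumes independent sources; overlapping
  supports would make the planted sources statistically dependent and the
  ground truth itself ill-posed for any ICA-family method.
* **Equalized expression variance.** Each trait's realized weight variance
  is fixed to the same value (subject-level deviations are residualized
  against the condition design for sensitive traits and sd-standardized
  throughout). A robust but task-insensitive trait is not a weak trait;
  without this, random variance fluctuations let the 90% PCA cutoff
  occasionally truncate a planted trait, which would test the luck of the
  draw rather than the method.
* **Orthogonal condition contrasts.** Sensitive traits are modulated along
  mutually orthogonal condition profiles (normalized polynomial contrasts,
  random choice and sign) with spread `sensitive_shift = 1.5` in units of
  the subject sd. The implied population ICC is
  `1.5^2 / (1 + 1.5^2) ~ 0.69`, the magnitude reported for task-sensitive
  traits on real task-fMRI cohorts.
* **FC realism by clipping.** Mixed FC values are clipped to [-1, 1]; a
  warning fires if clipping touches more than 1% of entries, since heavy
  clipping breaks the linearity of the planted model.

What the generator does **not** emulate: empirical FC spectra and
distance-dependent correlation structure, subject-specific parcellation
differences, head-motion and physiological artifacts, and any biophysical
coupling between the planted FC and SC halves — the raw-SC generator
shares topology across subjects but does not invert the
structural-correlation transform, so end-to-end (raw-cohort) recovery is
assessed on the FC half only (`evaluate_recovery(..., block = "fc")`).
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated generative model, not performance on real
neuroimaging data.

## Problem sizes used in validation

The shipped validation suite runs the reference design (80 profiles,
60 nodes, ~2,000 hybrid edges) with 20 ICA runs over 20 master seeds for
recovery, 100 replicates at 10 runs for sensitivity discrimination, a
200-node SC at the full 50,000 swaps for the null model, and a 40-node,
24-profile raw cohort over 20 seeds for the randomization control (1,000
swaps per subject — enough to scramble each individual topology; the
population intersection of independently randomized graphs collapses
rapidly, which is itself the effect the control measures). These sizes were
chosen so the whole suite validates every claim in minutes on a laptop
while staying in the regime where the method's asymptotics (edges >>
profiles) hold.

## Known limitations

* The greedy robustness clustering depends on seed-component choice order;
  with thresholds far from 0.5 its clusters can differ from full
  similarity-based clustering.
* ICC is the one-way random-effects form; with unbalanced groups the
  effective group size `k0` correction is used, but crossed designs
  (subject x task) are out of scope.
* The structural null randomizes each subject independently; after many
  swaps the population common-edge mask shrinks toward empty, so the
  randomized-control comparison is dominated by mask collapse — consistent
  with the claim being tested, but not a graded dose-response.
* Recovery guarantees are for the planted linear model. Real hybrid
  cohorts violate independence and linearity to an unknown degree.
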