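---
title: "Estimating symptom networks of stress and mental distress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating symptom networks of stress and mental distress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distressnet)
```

## The model

distressnet estimates a *Gaussian graphical model* (GGM) over the items of
an ordinal symptom questionnaire such as the DASS-21, in which every item
is a node and an edge between two items is their partial correlation —
their association after conditioning on all other items. Zero entries in
the precision (inverse covariance) matrix correspond to conditional
independencies, so a sparse precision matrix is a parsimonious map of
which symptoms hang together directly rather than through intermediaries.

The pipeline has four statistical stages.

**1. Nonparanormal transformation.** Ordinal 0–3 scores are mapped to the
standard-normal scale through a Winsorized empirical CDF: average ranks
become probabilities $u_i = r_i/(n+1)$, truncated at
$\delta_n = 1/(4 n^{1/4} \sqrt{\pi \log n})$, then passed through
$\Phi^{-1}$. This is the Gaussian-copula (nonparanormal) estimator: it is
invariant to any monotone recoding of an item and keeps all transformed
values finite. Pearson correlations of the transformed columns feed the
graphical model. A polychoric backend would model the thresholds
explicitly; we keep the rank-based transform because it is the standard
choice in the symptom-network literature and is assumption-light, but see
*Limitations* for what this costs on 4-category data.

**2. EBIC-selected graphical LASSO.** The precision matrix is estimated by
maximizing the $\ell_1$-penalized Gaussian log-likelihood

$$\log\det K - \operatorname{tr}(RK) - \lambda \lVert K \rVert_{1,\text{off}},$$

with the penalty applied to off-diagonal entries only, solved by block
coordinate descent (compiled, warm-started) over a path of 100 penalties
log-spaced from $\lambda_{\max} = \max_{i<j} |r_{ij}|$ down to
$0.01\,\lambda_{\max}$. The model on the path minimizing the Extended BIC,

$$\mathrm{EBIC}_\gamma = -2\ell + E \log n + 4 E \gamma \log p,$$

is selected, with $\gamma = 0.50$ by default — the conventional
sparsity-leaning choice for symptom networks. $E$ counts upper-triangle
nonzero off-diagonals; ties are broken toward the sparser model. Edge
weights are partial correlations
$w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$.

**3. Network description.** With communities pre-assigned from the
instrument (Stress, Anxiety, Depression subscales of seven items each for
the DASS-21 preset — communities are *not* detected from data):

* *strength*: $s_i = \sum_j |w_{ij}|$;
* *bridge strength*: the same sum restricted to edges crossing community
  boundaries, with the exact decomposition
  `strength = bridge_strength + within_strength`;
* *bridge betweenness*: over all node pairs from different communities,
  the fraction of shortest paths (edge length $1/|w|$) passing through
  each intermediate node, with fractional credit shared equally among tied
  geodesics. Fractional (Brandes-style) counting was chosen over
  single-path counting because it is deterministic and independent of node
  order; bridge closeness is deliberately not computed by default, since
  distance-based indices are rarely stable at questionnaire sample sizes;
* *predictability*: per node, the share of variance explained by all other
  nodes, $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ against the intercept-only
  model, from a nodewise LASSO regression on the transformed scale with
  its penalty selected by EBIC at $\gamma = 0.25$ (the convention of
  nodewise network estimation). Values are clipped to $[0, 1]$.

All centrality indices are also reported as z-scores (sample-SD
standardization across the $p$ nodes), the form in which they are usually
plotted.

**4. Case-dropping bootstrap stability.** Each index is re-estimated on
`B` subsamples drawn without replacement at each drop proportion in a grid
(default 0.05–0.75 in steps of 0.05), re-running the entire pipeline per
subsample. The Pearson correlation between subsample and full-sample index
vectors summarizes robustness, and the CS-coefficient is the largest
proportion at which at least 95% of replicates retain a correlation of at
least 0.7. CS below 0.25 is read as insufficient stability, 0.25–0.50
(inclusive) as acceptable, and above 0.50 as preferred. The 0.7 threshold
is the standard default of the case-dropping bootstrap literature and is
configurable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.50 | EBIC edge-count penalty for network selection (dimensionless; larger = sparser) |
| `gamma_pred` | 0.25 | EBIC penalty for the nodewise predictability regressions |
| `n_lambda`, `lambda_min_ratio` | 100, 0.01 | penalty path resolution and depth |
| `proportions` | 0.05–0.75 by 0.05 | case-dropping grid; the conventional CS values all lie on this lattice |
| `B` | 1000 | bootstrap replicates per proportion (250 is adequate for desk-scale work) |
| `cor_threshold`, `confidence` | 0.7, 0.95 | CS-coefficient definition |

## The synthetic-data generator

Because symptom-survey microdata are typically available only on request,
the package ships a generator that emulates the study conditions end to
end: `make_truth()` builds a 21-node, 3×7-community partial-correlation
truth with within-community edges at partial correlation 0.25 placed on a
random half-dense within-block pattern, and two cross-community bridge
edges per community pair at 0.15 — magnitudes at which a network of this
size is estimable yet sparse at $n \approx 318$, mirroring the
dense-within / sparse-between topology reported for DASS-21 networks. The
target precision is repaired to positive definiteness by uniform diagonal
inflation and the realized truth re-derived, so the recorded `W` is always
exactly the partial-correlation image of the recorded `K` (note the
inflation shrinks the realized edge weights below their nominal targets).
`sample_ordinal()` draws latent multivariate-normal vectors from the
implied unit-diagonal covariance and cuts each item at thresholds
(0.3, 1.0, 1.8), giving right-skewed category frequencies
(≈ 62/22/12/4%) typical of symptom endorsement; `sample_latent()` exposes
the continuous layer for estimator validation.

What the generator does *not* emulate: demographic covariates and
subgroup structure, non-response and selection bias, item-specific
thresholds or wording effects, and any departure from the Gaussian copula.
Passing tests on this generator therefore demonstrates that the estimators
are correct under the model's own assumptions, not that real survey data
satisfy those assumptions.

## Numerical choices

* Coordinate descent converges when the largest weight update falls below
  `1e-4` times the mean absolute off-diagonal correlation; the inner lasso
  threshold is ten times tighter. Warm starts run from the sparsest model
  down the path, so edge counts are monotone along it up to tolerance.
* Borderline non-positive-semi-definite correlation inputs are repaired by
  clipping eigenvalues at `1e-8` and re-normalizing the diagonal, with a
  message.
* An edge is declared absent only when both of its nodewise lasso
  coefficients are exactly zero; the two estimates are averaged otherwise,
  keeping `K` exactly symmetric.
* The bootstrap derives one RNG stream per (proportion, replicate) cell
  from the master seed, so results are independent of execution order and
  of which indices are run together. Dropping zero cases keeps the full
  sample unpermuted, making the proportion-0 correlation exactly 1 by
  computation rather than by fiat.
* Ties in EBIC selection go to the sparser model; constant index vectors
  z-standardize to all zeros with a warning; degenerate (constant) items
  are rejected by name at the transform stage.
* Percentages in descriptive tables are rounded half-away-from-zero to two
  decimals, matching how such tables are conventionally printed (base R's
  `round()` rounds half to even).

## Problem sizes used in validation

The test suite exercises the full pipeline at the study's scale
($n = 318$, $p = 21$), edge-recovery at $n = 2{,}000$ across ten
replicates, closed-form predictability checks at $n = 10{,}000$, and a
case-dropping bootstrap with $B = 250$ over the full 0.05–0.75 grid —
sizes at which every stage's statistical behavior is measurable while the
whole suite stays desk-scale.

## Known limitations

* **Ordinal attenuation.** On 4-category items the rank-based transform is
  just a monotone recoding, so the resulting Pearson correlations estimate
  the correlation of the *binned* values, not the latent correlation: for
  a latent correlation of 0.40 under the default thresholds the estimate
  converges to ≈ 0.31. All edge weights and predictability values are
  therefore attenuated relative to the latent scale (mean predictability
  on ordinal scores runs ≈ 0.10 below the latent-scale closed form).
  Relative structure — which edges exist, which nodes are strongest — is
  far less affected, which is why the rank-based pipeline remains the
  field's standard. A polychoric backend would remove the attenuation at
  the cost of stronger distributional assumptions.
* **False-positive creep.** EBIC-glasso is not model-selection consistent:
  as $n$ grows with a dense truth, the selected $\lambda$ must fall far
  enough to capture all weak true edges, and small spurious edges (here
  with weights around 0.01–0.03) enter alongside them. At $n = 2{,}000$ on
  the default generator, sensitivity is essentially 1 while specificity
  plateaus around 0.75–0.82. Interpreting small edges individually is
  therefore discouraged; strength rankings remain accurate (rank
  correlation ≈ 0.94).
* Stability indices re-run the entire pipeline thousands of times;
  at $n = 318$, $p = 21$ a three-index bootstrap at $B = 250$ takes a few
  minutes on one CPU.
* The analysis is cross-sectional and population-level: edges are
  conditional associations, not causal pathways, and no individual-level
  dynamics are modeled.

## A worked run

```{r, eval = FALSE}
model <- make_truth(seed = 1)
x <- sample_ordinal(model, 318, seed = 2)
res <- run_pipeline(
  x, communities = "dass21", out_dir = "distressnet-out",
  stability_indices = c("strength", "bridge_strength", "predictability"),
  B = 250, seed = 3
)
res$network
head(res$metrics)
res$cs
```

The output directory then holds `edges.csv` (long-format weighted edge
list), `node_metrics.csv` (all centrality and predictability columns, raw
and z-standardized), `stability.csv` (per-replicate bootstrap
correlations), `summary.json` (every headline number, each recomputable
from the stage CSVs), and `run.log` (all resolved defaults).
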