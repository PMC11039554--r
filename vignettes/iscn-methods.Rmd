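---
title: "Individualised structural covariance networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualised structural covariance networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

A group-level structural covariance network correlates regional morphometry
*across* subjects and therefore yields one network per cohort. The
individualised alternative implemented here builds one network *per
subject* by comparing the distributions of modulated grey-matter-volume
(GMV) values across the voxels of each atlas region:

1. **Regional density estimation.** For each region, the voxel GMV values
   are treated as draws from an unknown density, estimated by Gaussian-kernel
   KDE evaluated at 512 points. The bandwidth follows Silverman's rule of
   thumb on the region's own voxels (`stats::bw.nrd0`); the rule is
   deliberately simple, documented, and overridable, since morphometric
   similarity results should not hinge on bandwidth tuning.
2. **Edge weights.** For regions $i, j$ with densities $P, Q$ on a shared
   grid, the edge weight is the Kullback–Leibler similarity
   $\mathrm{KLS} = e^{-\mathrm{KLD}(P,Q)}$, where
   $\mathrm{KLD}(P,Q) = D(P\|Q) + D(Q\|P) = \sum_k (p_k - q_k)\ln(p_k/q_k)\,\Delta_k$
   is the symmetric (Jeffreys) divergence, integrated by the trapezoid rule.
   KLS is 1 iff the distributions coincide and decays to 0 as they separate.
3. **The network.** Over all unordered pairs this yields a symmetric
   $R \times R$ matrix in $(0, 1]$ with zero diagonal (self-similarity is
   excluded from every analysis).

## Numerical choices

* **Shared grid per pair.** Divergences require a common support. Each pair
  uses 512 equally spaced points spanning the pooled sample range of the two
  regions, padded by 3 pooled-sample bandwidths per side. A pair-pooled grid
  (rather than one global grid) preserves resolution for low-variance
  regions; a `global_grid` flag exists for sensitivity analysis.
* **Flooring.** Densities are floored at $10^{-10}$ and renormalised before
  the divergence, keeping KLD finite and stable across grid resolutions
  when supports barely overlap.
* **Exact-sum KDE.** The kernel sum is evaluated exactly (no FFT binning),
  with a compiled kernel for the $O(R^2)$ pair loop. Kernel support is
  truncated at 8 bandwidths, four orders of magnitude below the density
  floor, so the truncation is invisible after flooring. Accumulation uses
  extended precision, which also makes the network bit-invariant to voxel
  order. A pure-R reference path computes the same quantities and the test
  suite checks the two agree.
* The Gaussian closed form
  $\mathrm{KLD}_{\mathrm{sym}}(\mathcal N(\mu_1,\sigma^2), \mathcal N(\mu_2,\sigma^2)) = (\mu_1-\mu_2)^2/\sigma^2$
  anchors the numerical pipeline in the tests.

# Topology over dynamic thresholds

Each network is binarised by *density*: at threshold $K\%$ exactly
$\mathrm{round}(K/100 \cdot R(R-1)/2)$ strongest edges are kept (round half
away from zero; ties broken by ascending $(i,j)$ index — both conventions
documented because results must be bit-reproducible). Density thresholding
equalises edge count across subjects, which is what makes binary topology
comparable between groups.

The retained range of $K$ is selected from the data: the lower bound is the
smallest $K$ at which every subject's network is one connected component;
the upper bound is the largest subsequent $K$ at which every subject's
small-worldness $\sigma = (C/C_{\mathrm{rand}})/(L/L_{\mathrm{rand}})$
exceeds 1.1. $C_{\mathrm{rand}}, L_{\mathrm{rand}}$ are means over 20
degree-preserving Maslov–Sneppen rewired surrogates ($10|E|$ swap attempts
each). The scan window is 1–50%: beyond half of all possible edges the
binary graph leaves the sparse regime in which these metrics are
interpretable. Surrogate seeds derive deterministically from (base seed,
subject, $K$), so selection and any later re-verification reproduce
exactly.

Five global metrics (global efficiency, mean clustering, $\sigma$,
Louvain modularity, degree assortativity) and three nodal centralities
(degree, betweenness, eigenvector) are computed at every retained $K$ and
integrated as the un-normalised trapezoid AUC over the range, removing
single-threshold bias. Conventions: efficiency averages $1/d$ over ordered
pairs with unreachable pairs contributing 0; betweenness is normalised by
$(R-1)(R-2)/2$; eigenvector centrality is the principal eigenvector of the
adjacency (dense symmetric eigendecomposition, absolute values scaled to
max 1); degree is left raw. Modularity maximisation is NP-hard; we report
the best of 10 Louvain restarts with randomly permuted vertex order, which
the tests show attains the exhaustive optimum on the vast majority of small
graphs and never exceeds it.

# Harmonisation

Multi-site data carry additive and multiplicative site effects. Features
(topology AUCs and the $R(R-1)/2$ edge weights, as two separate matrices)
are harmonised with parametric empirical-Bayes ComBat written from first
principles: standardise against the pooled model fit, shrink per-site
location/scale toward moments-matched normal / inverse-gamma priors
(iterated conditional estimation, relative tolerance $10^{-4}$), remove the
site terms, re-add the biological design. Diagnosis, age and gender are
protected as biological covariates by default (the protected design is an
argument, so diagnosis can be dropped from it). The
test suite checks the implementation against the reference Bioconductor
implementation to $10^{-6}$ and verifies parameter recovery on data
generated from the ComBat model itself. Note that the additive site term
$\gamma$ is identifiable only relative to the weighted grand mean, so
recovery is assessed on centred values.

An interaction worth knowing about: for region pairs whose GMV
distributions barely overlap, KLS is astronomically small and its variance
is dominated by the *scale* part of the site effect (KLS
$\approx e^{-\Delta\mu^2/\sigma^2}$ is very sensitive to $\sigma$).
Harmonisation then removes nearly all of such an edge's variance — which is
correct, but means clinical couplings are only identifiable on edges that
retain biological variance after harmonisation (high-similarity edges, like
the thalamus–insula edge that carries the symptom association in the
motivating study).

# Group inference

* **GLM.** Per feature, OLS of `feature ~ group + age + gender`; two-tailed
  t test of the group contrast; Cohen's d = adjusted contrast / residual SD
  (matching the GLM framing); Bonferroni within declared families — the 5
  global metrics as one family, each centrality type's $R$ regions as one
  family (a $3R$ family is available; the $R$ default is recorded as an
  open choice).
* **NBS.** Edge-wise GLM t statistics; suprathreshold edges at two-tailed
  $p < 0.001$, separately for positive and negative contrasts (the two
  directions are reported separately, so each direction gets its own
  permutation null); connected components by breadth-first search;
  familywise control by permuting group labels only (covariates stay
  attached to subjects — the classic NBS scheme; Freedman–Lane residual
  permutation was considered and not implemented, as the label scheme is
  the one the motivating literature describes) and
  recording the maximal component *edge count* per permutation. The
  identity permutation is always included, bounding corrected p below by
  $1/n_{\mathrm{perm}}$. Component size is edge count because extent in the
  motivating literature is reported as connection counts; node counts are
  descriptive. The t statistics are computed via Frisch–Waugh
  residualisation, which turns the whole permutation loop into one matrix
  product and makes $10^4$ permutations on thousands of edges a
  sub-second operation.
* **Clinical association.** Partial Pearson correlation (residualise both
  sides on age and gender), $n - k - 2$ degrees of freedom, Bonferroni over
  the topology family and the edge family separately.

# Classification

Linear SVM ($C = 1$, no hyperparameter search — deliberately plain),
stratified seeded 10-fold cross-validation, features standardised with
training-fold statistics only (the silent alternative — standardising once
on all data — leaks test information and is avoided). Pooled test-fold
predictions give accuracy/sensitivity/specificity; AUC comes from pooled
decision scores; the 95% CI of accuracy is mean ± 1.96·SE across folds
(the motivating study's presentation; at small fold counts it can exceed
[0, 100] and is left unclamped). Mean absolute weights across folds are
aggregated to regions: topology mode averages a region's three centrality
features (global metrics excluded from mapping); connectivity mode
averages the $R-1$ incident edges. Global metrics stay in the feature
vector itself — only the region *mapping* excludes them.

# The synthetic cohort generator

The generator is the package's ground-truth instrument, not a fixture. It
emulates: per-region Gaussian voxel distributions (means spread over
[0.35, 0.85], SD 0.08 — the plausible modulated-GMV range), additive site
shifts (±0.03) and multiplicative site scales (0.85–1.15) typical of
multi-scanner consortia, linear age decline (−0.001/year) and a small
gender offset, group effects on designated regions (mean shifts) and edges
(one region's distribution pulled toward its partner's by a stated
fraction), and a HAMD-17 score (mean 30, SD 6, clipped to the 18–52
inclusion window) coupled to one designated edge's *realised* KLS. The
coupling orthogonalises the noise in-sample so the patient-level partial
correlation equals the target exactly up to clip/round attenuation —
giving the association stage an exactly known target. The Gaussian voxel
model is chosen because Gaussian KLD has a closed form, yielding analytic
oracles for the network stage.

What it does **not** emulate: spatial autocorrelation of smoothed MRI,
atlas geometry, non-Gaussian GMV distributions, scanner-specific
nonlinearities, or realistic effect topographies. Passing tests therefore
demonstrate that the pipeline recovers what it claims to recover under its
stated statistical model — not that the biological findings of any real
study are reproduced.

# Problem sizes and determinism

Desk-scale defaults — 60 regions, 200 voxels/region, 40–120 subjects,
3 sites — keep a full cohort build near a minute and the end-to-end
analysis in minutes, while the same code paths support 246-region atlases.
The test suite scales some simulation sizes to where the tested property is
actually decidable (e.g. 150 subjects/site for harmonisation null-pass-through,
whose spurious-adjustment noise shrinks as $1/\sqrt{n}$; 1000 instead of
10 000 NBS permutations across 200 null cohorts). Every stochastic step
takes an explicit seed, randomness is locally scoped (the caller's RNG
state is never touched), and repeated runs of the whole pipeline are
bit-identical.

# Known limitations

* VBM preprocessing (bias correction, segmentation, normalisation,
  smoothing) is upstream and out of scope; inputs are GMV maps or extracted
  regional samples, and atlas/image grids must already match voxel-exactly.
* Louvain modularity is a heuristic lower bound on max-modularity.
* Weighted-graph metric variants, rich-club and participation coefficients
  are not implemented.
* KLS edges between non-overlapping regional distributions are numerically
  near zero; analyses of such edges are dominated by floor effects (see the
  harmonisation note above).
* Non-parametric ComBat priors and longitudinal variants are not provided.
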