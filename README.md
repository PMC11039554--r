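# iscn — individualised structural covariance networks from grey-matter volume distributions

Group-level structural covariance networks correlate regional brain
morphometry across subjects and therefore produce a single network per
cohort — useless for individual prediction or brain–behaviour analysis.
`iscn` implements the individualised alternative for case-control
morphometry studies (the motivating application is major depressive
disorder in multi-site consortium MRI): each subject gets their own network
whose nodes are atlas regions and whose edges measure how similar two
regions' grey-matter-volume (GMV) distributions are.

For regions *i*, *j* with voxel-GMV densities *P*, *Q* (Gaussian-kernel KDE,
512 evaluation points, Silverman bandwidth) the edge weight is the
Kullback–Leibler similarity

```
KLS(i, j) = exp( − [ D(P‖Q) + D(Q‖P) ] )   ∈ (0, 1]
```

On top of the per-subject KLS matrices the package provides the full
analysis pipeline:

* **Dynamic-threshold topology** — binarisation at density K% (equal edge
  count per subject), automatic selection of the K range over which every
  network is connected and small-world (σ > 1.1 against Maslov–Sneppen
  rewired surrogates), five global metrics and three nodal centralities
  integrated as AUC over the range;
* **ComBat harmonisation** — parametric empirical-Bayes removal of
  additive/multiplicative site effects, preserving diagnosis, age and
  gender (validated against the Bioconductor reference to 1e-6);
* **Group inference** — per-feature GLMs with Bonferroni families, and
  network-based statistics (NBS): suprathreshold edges at p < 0.001,
  connected components, familywise correction by permutation of the
  maximal component size, with Yeo-7 functional-network summaries;
* **Individual-level classification** — linear SVM, stratified 10-fold CV,
  leakage-free standardisation, feature weights mapped to the top-10
  contributing regions;
* **Clinical association** — partial correlation of HAMD-17 with every
  network measure, controlling age and gender;
* **A synthetic multi-site cohort generator** with exact ground truth
  (site effects, regional and edge-level group effects, covariate effects,
  symptom–edge coupling with known partial correlation), so every stage
  has a recovery test without access to consortium data.

Inputs are NIfTI GMV maps plus an integer parcellation
(`extract_regional_samples()`), or a plain-text regional voxel-sample
archive; phenotypes and lookup tables are TSV.

## Worked example

The `analysis/` directory is a numbered end-to-end study on a simulated
3-site cohort (20 patients / 20 controls, 60 regions) with planted ground
truth: a GMV deficit in region 30, a clique of strengthened patient edges
among regions 10–14, and a HAMD-17 score coupled (partial r = 0.3) to edge
(7, 9).

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + phenotype + ground truth
Rscript analysis/02_build_networks.R    # per-subject KLS matrices
Rscript analysis/03_topology.R          # threshold range, AUC metrics, GLM
Rscript analysis/04_connectivity.R      # ComBat + NBS + Yeo summary
Rscript analysis/05_classification.R    # linear-SVM diagnosis models
Rscript analysis/06_clinical_association.R
```

Output tables land in `results/`. The run prints, among other things:

```
retained density range: 16-50% (min sigma 1.351)
increased component 1: 72 edges / 28 nodes, p = 0.0001
decreased component 1: 27 edges / 12 nodes, p = 0.0003
topology:     accuracy 100.0% (95% CI 100.0-100.0), AUC 1.000
connectivity: accuracy 90.0% (95% CI 79.2-100.8), sens 90.0%, spec 90.0%, AUC 0.980
coupled edge edge_r007_r009: partial r = 0.325 (truth 0.30), p = 0.1876 (n = 20 patients)
```

Reading this: the density scan keeps 16–50% (every subject connected and
small-world throughout); NBS finds a significant component of increased
patient connectivity containing the planted clique (its top contributing
regions, 10–14, also dominate the connectivity-SVM weight map); the
planted symptom coupling is re-estimated at 0.325 — close to the true 0.3,
though at 20 patients the single-edge test is underpowered after Bonferroni
correction, which is exactly how such a cohort should behave.

Equivalent programmatic entry point: `run_pipeline(simulation_spec(...),
iscn_config(...))`.

## Layout

```
R/                  package code (cohort IO, generator, network builder,
                    topology, ComBat, inference, classification, pipeline)
src/                compiled KDE/KLS pair kernel (Rcpp)
analysis/           numbered study drivers (see worked example)
scripts/acceptance.R
tests/testthat/     unit, property and end-to-end validation suites
vignettes/iscn-methods.Rmd   the model, parameters and design choices
```
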