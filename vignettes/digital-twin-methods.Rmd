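---
title: "Methods: simulated multiomic trajectories and knowledge-graph interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated multiomic trajectories and knowledge-graph interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dtwin)
```

## The problem this package addresses

Type 2 diabetes (T2D) progresses heterogeneously: two patients with the same
intake labs can diverge sharply within a year. A digital-twin style analysis
asks two questions of longitudinal multiomic data. First, *prediction*: from
a patient's intake (t0) demographics, clinical labs, proteomics and
metabolomics, can we forecast the change in key clinical variables — HbA1c,
fasting glucose, fasting insulin, HOMA-IR and eGFR — at roughly six months
(t1) and one year (t2)? Second, *interpretation*: when a sparse model puts
weight on particular proteins, what do those proteins have to do with the
disease? The package answers the first with cross-validated L1-regularized
models over nested feature sets, and the second by placing the top-weighted
predictors on a typed biomedical knowledge graph and applying shortest
paths, an approximate Steiner tree, and topic PageRank.

Real deeply-phenotyped cohorts and production knowledge graphs are
access-restricted, so the package ships *generators* for both, with planted
ground truth. The generators are first-class, tested components: they define
the study conditions under which every downstream claim is verified.

## The synthetic cohort and its planted structure

`generate_cohort()` draws baseline values per feature and then generates the
*changes* of the clinical targets from a linear-Gaussian model on z-scored
baseline features. For target $y$ with baseline standard deviation $s_y$:

$$\Delta y \;=\; s_y\Big(\sum_f \beta_f\, z(x_f) \;+\; \gamma_y\, z(y_0)
\;+\; \varepsilon\Big), \qquad \varepsilon \sim N(0, \sigma^2),$$

and follow-up values are $y_0 + \Delta y$ per horizon. Effect sizes
$\beta_f$ are therefore *standardized*: target-SDs of change per feature-SD.
Design notes:

* **Baseline distributions.** Defaults approximate a generally healthy
  wellness cohort: HbA1c $5.51 \pm 0.43$ %, glucose $93 \pm 12$ mg/dL,
  insulin $10.7 \pm 7.3$ µIU/mL, eGFR $90 \pm 15$ mL/min/1.73m²; 1,131
  subjects of whom 639 (56.5%) have a 1-year visit; 262 proteins, 710
  metabolites, and 70 clinical/demographic variables.
* **HOMA-IR is derived, never drawn.** At every timepoint HOMA-IR equals
  glucose(mg/dL) × insulin(µIU/mL)/405, the standard convention. Planting an
  effect directly on HOMA-IR is rejected as a configuration error — drive it
  through glucose or insulin, as physiology would.
* **Insulin mean reversion.** The insulin delta model carries
  $\gamma = -$`insulin_reversion_rate` (default 0.3): subjects with high
  baseline insulin tend to fall toward the population mean. This is the one
  deliberately asymmetric dynamic among the targets, and it is what makes
  the baseline-insulin coefficient of the change classifier reliably
  negative.
* **Noise.** `noise_sd` defaults to 0.6 baseline-SDs per target, chosen once
  so simulated 6-month delta SDs sit near the ratio observed in real
  wellness cohorts (for insulin, a delta SD of roughly two-thirds of the
  baseline SD).
* **Floors.** Follow-up glucose, insulin, HbA1c and eGFR are floored at 0.1
  so relative binarization stays defined; at default noise this touches a
  negligible fraction of subjects.
* **Missingness** is injected separately (`inject_missingness()`),
  completely at random per feature kind. Default rates (0.1% clinical,
  0.05% protein, 2% metabolite) were set once so the strict
  any-missingness subject filter removes roughly the fraction of subjects a
  heavily-filtered real cohort loses (about 40%). MCAR is a simplification:
  real platform missingness is batch- and abundance-dependent, and the
  generator makes no attempt to model informative dropout.

`sex` is encoded 0/1 and demographics are never missing. The planted truth
(effect map plus noiseless deltas) is returned alongside the cohort so
recovery can be scored exactly.

## The preprocessing cascade

`run_preprocessing()` applies six ordered steps: (1) keep subjects with all
four data kinds at ≥ 2 timepoints; (2) drop subjects missing any of the five
targets at the first two timepoints; (3) drop clinical/protein/metabolite
features with > 10% missingness; (4) drop subjects with > 10% missingness in
the remaining metabolites or *any* missingness in remaining
proteins/clinical labs; (5) impute remaining metabolite gaps; (6) drop
subjects with HbA1c > 12, glucose > 200, or insulin > 60.

Choices that were genuinely open:

* **Pooling window.** Feature missingness (step 3) is computed over the
  first two timepoints pooled across retained subjects. The subject filter
  (step 4) pools over *all* timepoints a subject attends, so that after
  metabolite imputation the output is guaranteed NA-free — restricting
  step 4 to the first two timepoints would let follow-up-visit gaps in
  proteins or clinical labs survive the cascade.
* **Order matters and is fixed.** Filtering features before subjects can
  rescue a subject whose missingness was concentrated in a dropped feature.
  The test suite asserts on an adversarial fixture that swapping steps 3
  and 4 changes the survivor set.
* **Outlier limits** are checked at every attended timepoint, not only
  baseline; a transiently extreme value is treated as disqualifying either
  way.

**Imputation.** `impute_metabolites()` is an iterative random-forest
imputer in the missForest style: initialize gaps at per-feature medians,
then repeatedly regress each incomplete metabolite on all other features
(stacking all attended subject-timepoint rows), refreshing imputed cells in
order of increasing missingness. Iteration stops when the relative squared
change of the imputed cells drops below $10^{-3}$, when it stops
decreasing, or at `max_iter` (default 10). Forests are seeded and
single-threaded, so imputation is bit-reproducible. Imputation quality
benchmarking is a non-goal; the tests verify only that a deterministic
planted relation (one metabolite exactly twice another) is recovered within
10%.

## Changes, and the 5% rule

`compute_deltas()` emits one record per (subject, target, horizon) with
$\Delta = v_{\text{horizon}} - v_{t0}$. `binarize_deltas()` labels a record
positive when the change moves at least 5% in the *adverse* direction
**relative to baseline**: an increase for HbA1c, glucose, insulin and
HOMA-IR; a decrease for eGFR, since falling kidney function is the adverse
event. A "5% change" could also be read as an absolute
percentage-point change for variables measured in percent; the relative
reading is the only one that applies uniformly across five variables with
different units, so it is the default, with `mode = "absolute"` available.
Records with non-positive baselines cannot be labeled under the relative
rule and are excluded with a warning.

## Prediction models

Seven nested feature sets are compared per task — baseline only;
demographics (age, sex, BMI); a 15-variable selected clinical panel; full
clinical; proteomics; metabolomics; everything — and each set always
includes the predicted target's own baseline value, because clinical labs
are strongly autocorrelated and baseline is the single best predictor of
change (negatively, via regression to the mean).

`cross_validated_fit()` uses 10-fold cross-validation. Per outer fold:
z-score normalization is *fit on the training fold only* and applied to
both folds (the held-out fold never influences the statistics — a leakage
test asserts this); an L1-penalized linear or logistic model is fit with
the penalty chosen by inner 5-fold cross-validation over glmnet's
logarithmic grid, again on the training fold only; the held-out score is
R² for regression and F1 for classification. Decisions the underlying
papers of this genre usually leave open, fixed here:

* Outer folds are seeded and, for classification, stratified by label.
* F1 is computed for the positive (adverse-change) class, the
  event-detection reading; a held-out fold containing a single class has
  undefined F1 and is excluded from the mean with a warning.
* `evaluate_feature_sets()` makes *one* fold assignment per task and reuses
  it across feature sets, so per-fold scores are paired.
* Predictor ranking (`rank_features()`) orders by mean |standardized
  coefficient| across folds, annotates the cross-fold coefficient range and
  nonzero-fold count, and breaks ties by feature id so output is
  bit-reproducible. The membership of the selected clinical panel is
  configurable; its default is a documented draw from the registry, not a
  claim about which 15 variables matter clinically.

## The knowledge graph

The typed graph container mirrors a production biomedical knowledge graph
at miniature scale: node types {Protein, Gene, Compound, Disease}, edge
types {interacts (P–P, undirected), binds (C→P), downregulates (C→P),
treats (C→D), associates (G→D), encodes (G→P)}. Deliberately, there is no
direct protein–disease edge type: proteins reach diseases through compounds
or genes, which is exactly why intermediate nodes on shortest paths are
interpretable (e.g. a compound that both binds a predictor protein and
treats the disease).

`generate_synthetic_kg()` plants two structures in an otherwise random
graph: a set of "measured seed" proteins densely interconnected by
interaction edges (the analogue of top predictive features, which real
cohorts show to be densely connected), and disjoint "hidden causal"
proteins, each wired to at least `min_seed_links` seeds (default 3) and
placed within two hops of the disease node via a dedicated bridging
compound. Hidden proteins emulate disease-relevant molecules the assay
panel never measured; recovering them from the seed set is the
interpretation stage's planted-truth test. The protein–disease component is
made connected so that Steiner trees and shortest paths exist for every
seed.

## Graph algorithms

All algorithms run on the simple undirected unit-weight view of the typed
multigraph, and distances are hop counts. Real knowledge-graph figures mix
edge types and directions in one subgraph without specifying traversal
semantics; the undirected view is the most permissive reading and keeps
every algorithm's output independent of edge-type ordering. Weighted or
type-aware (metapath) walks are non-goals.

* **Shortest paths** (`shortest_paths_to_target()`): breadth-first paths
  from each seed to the disease node, with all distinct shortest paths
  enumerated and their union exported as a subgraph. Verified against an
  independent unit-weight Dijkstra oracle.
* **Steiner tree** (`steiner_takahashi()`): the nearest-terminal insertion
  heuristic — grow from the lexicographically smallest terminal, repeatedly
  attach the closest unconnected terminal along a shortest path. Cost is
  within $2(1 - 1/t)$ of optimal for $t$ terminals; the suite checks this
  bound against an exhaustive-search oracle on 200 random instances and
  exactness on all 2-terminal instances. Ties (equidistant terminals,
  equal-length paths) break by smallest id / lexicographically smallest
  node sequence, making the tree bit-reproducible. The *expansion* adds
  every graph edge between tree nodes, giving the approximately smallest
  subgraph containing all nodes of interest.
* **Topic PageRank** (`topic_pagerank()`): power iteration of
  $p \leftarrow \alpha (M^{\top} p + d^{\top}p \cdot r) + (1-\alpha) r$
  with $M$ the degree-normalized adjacency, $r$ uniform over the seed set,
  and degree-zero nodes redistributing their mass to $r$. Damping
  $\alpha = 0.85$ and L1 tolerance $10^{-10}$ are the field's conventions,
  not tuned values. Scores sum to one and match a direct dense linear solve
  to $10^{-8}$ on randomized instances. `prioritize_nodes()` ranks
  non-seed proteins by score (ties by id) — seed exclusion is the default
  because the interesting output is what the walk finds *beyond* the
  measured panel.

## What the synthetic conditions do and do not show

Passing tests demonstrate that the pipeline recovers *planted* linear
effects, ranks planted proteins highly, reproduces a planted
regression-to-the-mean sign, and retrieves planted disease-proximal
proteins from a planted graph — all under Gaussian features, MCAR
missingness, and independent predictors. They do not demonstrate
performance under correlated omics blocks, informative dropout, platform
batch effects, non-linear dynamics, or real graph topology; on real data
the same code paths apply but none of the recovery guarantees transfer.
Problem sizes in the test suite (cohorts of 80–1,000 subjects, graphs of
up to 2,000 nodes, 200 Steiner oracle instances, 50 PageRank oracle
instances) were chosen as the smallest scales at which the statistical
claims are comfortably away from their thresholds.

## Reproducibility

Every stochastic component takes a seed, and every stage of
`run_pipeline()` reads only the previous stage's serialized artifacts —
cohort CSVs, delta TSVs, edge-list TSVs, JSON reports — writing an MD5
manifest; two runs of one configuration are bit-identical, which the test
suite asserts. Because stage boundaries are plain files, a real cohort
table or a real edge list can replace the corresponding generator output
without code changes.

## Known limitations

Besides the synthetic-data caveats above: the iterative forest imputer is
validated for correctness and determinism, not imputation accuracy; exact
Steiner solving is capped at 16 nodes (it is a test oracle, not a tool);
the classifier threshold is fixed at 0.5 rather than calibrated; and
multiple-testing control across targets and horizons is out of scope — the
package reports per-task cross-validated scores, not significance claims.
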