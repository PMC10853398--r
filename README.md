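# t2dtwin

Digital-twin components for type 2 diabetes (T2D) trajectory modeling in R:
simulate a longitudinal multiomic cohort with planted ground truth, run a
filtering/imputation preprocessing cascade, train cross-validated
L1-regularized models that predict 6-month and 1-year changes in five
clinical variables, and interpret the top-weighted predictors on a typed
biomedical knowledge graph.

## The science in brief

**Prediction.** For each clinical target $y \in$ {HbA1c, glucose, insulin,
HOMA-IR, eGFR}, the package models the *change*
$\Delta y = y_{t_1} - y_{t_0}$ (and the 1-year analogue), either as a
regression on intake features or as a binary classification of an adverse
change of at least 5% relative to baseline — an increase for four targets,
a *decrease* for eGFR, since falling kidney function is the adverse event.
Models are L1-penalized linear/logistic regressions under 10-fold
cross-validation, with z-score normalization and penalty selection done on
the training folds only, compared across seven nested feature sets
(baseline → demographics → clinical → proteomics → metabolomics → all),
each always including the target's own baseline value.

**Interpretation.** The top-weighted protein predictors become query nodes
on a typed knowledge graph (Protein/Gene/Compound/Disease nodes; edge types
like *interacts*, *binds*, *treats*). Three algorithms connect them to a
disease node: breadth-first shortest paths (candidate mechanistic routes),
an approximate Steiner tree by the Takahashi nearest-terminal heuristic
(cost within $2(1-1/t)$ of optimal for $t$ terminals) expanded to the
node-induced subgraph, and topic PageRank — a random walk restarting at the
query set, whose stationary probabilities prioritize *unmeasured* proteins
proximal to the predictors.

Because real deeply-phenotyped cohorts and production knowledge graphs are
access-restricted, the package ships seeded generators for both, with
planted effects (known sparse feature→delta coefficients, a
regression-to-the-mean dynamic for insulin, hidden disease-proximal
proteins) so every claim is testable against known truth. See the methods
vignette (`vignettes/digital-twin-methods.Rmd`) for models, assumptions and
design decisions.

## Worked example

```r
library(t2dtwin)

cfg <- cohort_config(n_subjects = 400, n_proteins = 40, n_metabolites = 30,
                     n_clinical = 10,
                     effect_map = list(HbA1c = c(prot_0001 = 0.5,
                                                 prot_0002 = 0.4)),
                     seed = 42)
gen    <- generate_cohort(cfg)
cohort <- inject_missingness(gen$cohort, cfg)
pp     <- run_preprocessing(cohort, impute_n_trees = 25, seed = 42)
deltas <- binarize_deltas(compute_deltas(pp$cohort))
sets   <- build_feature_sets(pp$cohort$features, "HbA1c")
ev     <- evaluate_feature_sets(pp$cohort, deltas, "HbA1c", "6mo",
                                feature_sets = sets[c("demographics_only",
                                                      "proteomics")],
                                seed = 42)
aggregate(score ~ feature_set, ev$scores, mean)
#>         feature_set     score
#> 1 demographics_only 0.0000000
#> 2        proteomics 0.5267615
rank_features(ev$reports$proteomics, k = 3)
#>   rank   feature    kind  mean_coef mean_abs_coef   coef_min    coef_max nonzero_folds
#> 1    1 prot_0001 protein  1.2274103     1.2274103  1.1313187  1.40930684            10
#> 2    2 prot_0002 protein  0.9222197     0.9222197  0.8003506  1.03356590            10
#> 3    3 prot_0012 protein -0.1746789     0.1746789 -0.2495423 -0.07676358            10
```

The two planted proteins dominate the ranking with nonzero coefficients in
all 10 folds, and the mean held-out F1 of the proteomics set (0.53) beats
demographics-only (0.00 — with no informative features the sparse
classifier predicts the majority class, so positive-class F1 collapses).

Interpretation on a synthetic knowledge graph with 10 measured "seed"
proteins and 5 hidden disease-proximal proteins:

```r
kg <- generate_synthetic_kg(kg_config(n_proteins = 200, n_genes = 80,
                                      n_compounds = 120, n_diseases = 30,
                                      seed = 42))
pr <- topic_pagerank(kg$graph, kg$planted$seed_proteins)
head(prioritize_nodes(pr, k = 5), 5)
#>   rank      node    type       score seed_adjacency
#> 1    1 prot_0013 Protein 0.016056627              5
#> 2    2 prot_0014 Protein 0.011762941              5
#> 3    3 prot_0011 Protein 0.011395245              4
#> 4    4 prot_0015 Protein 0.011226081              4
#> 5    5 prot_0012 Protein 0.009438045              3
recovery_metrics(prioritize_nodes(pr, k = 20), kg$planted$hidden_proteins)
#> $recall
#>  recall_at_5 recall_at_10 recall_at_20 recall_at_50
#>            1            1            1            1
#> $mrr
#> [1] 0.4566667
```

All five hidden proteins (`prot_0011`–`prot_0015`) top the non-seed
ranking: the walk concentrates on nodes wired to several query proteins.

The full pipeline (simulate → preprocess → deltas → train → graph →
interpret, with an MD5 manifest making runs bit-reproducible) runs from a
config object or YAML file:

```r
run_pipeline(demo_pipeline_config(seed = 1), "demo_run")
summarize_run("demo_run")
```

or from the shell via the thin wrapper
`inst/scripts/t2dtwin-cli.R` (`run`, `report`, `interpret` verbs).

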