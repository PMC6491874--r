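# modnet

Subtype-aware gene-module ensemble models for cancer prognosis.

## What it does

Predicting survival risk from bulk expression data is hard because a single
cancer hides several transcriptional subtypes, and because prognosis is
driven by groups of co-acting genes rather than single markers. `modnet`
builds a prognostic classifier that takes both facts seriously:

1. **Subtype discovery** — K-means over the top-variance genes (default
   top 15%), with the cluster count K chosen by the Dunn index
   DI = min centroid separation / max within-cluster spread, scanned over
   K = 2..6. New samples are routed to the nearest subtype centroid.
2. **Per-subtype co-expression networks** — each gene links to its top-n
   (default 4) most-correlated partners (Pearson r); the union of
   selections is the network. Degree distributions are checked against a
   power law on the log-log scale.
3. **Community mining** — a faithful reimplementation of MCODE
   (k-core-based vertex weighting, seeded greedy expansion, 2-core filter,
   haircut) extracts dense gene communities from each network.
4. **The ensemble** — each community trains a nearest-centroid classifier
   for the 3-year prognosis classes (death within 3 years = high risk,
   survival beyond = low risk, censored within = unlabelled);
   sub-classifiers with leave-one-out accuracy ≥ 0.56 vote by majority,
   one committee per subtype.

Around the core, the package provides the standard evaluation apparatus:
quantile normalization, t-test/Cox-ranked control classifiers, a
Cox-coefficient-sign risk score (sum of positive-sign gene expressions
minus negative-sign ones) with median split, Kaplan–Meier/log-rank
survival analysis, AUC/MCC/ACC metrics, hypergeometric drug–target
screening of communities, and a synthetic cohort generator with planted
subtypes, correlated modules and module-driven survival so the whole chain
is testable without external data.

## Worked example

```r
library(modnet)

ds  <- generate_dataset(seed = 42)          # 1000 genes x 150 samples, 3 subtypes
res <- run_pipeline(ds$expression, ds$clinical,
                    pipeline_config(seed = 7, threshold_grid = NULL))
print(res)
#> Pipeline result: 1000 genes x 150 samples (124 labelled, 26 excluded)
#> Chosen K = 3; communities per subtype: 42, 48, 45
#> Sub-classifiers per subtype: 16, 21, 14
#> Training (LOOCV votes): AUC 0.9143  MCC 0.6884  ACC 0.8468
```

The pipeline recovered the three planted subtypes (K = 3; the assignments
match the generator's truth exactly, adjusted Rand index 1), mined 42–48
communities per subtype network, kept 14–21 of them as sub-classifiers at
the 0.56 accuracy bar, and the pooled leave-one-out vote separates the
3-year risk classes at AUC 0.91. Predict new samples with
`ensemble_predict(res$model, sample_vector)` — the result carries the
routed subtype, the high-risk vote fraction (the continuous score) and the
label.

A thin command-line front end over the same functions lives at
`inst/cli/modnet.R` (subcommands: synth, preprocess, subtype, network,
community, train-ensemble, survival, riskscore, screen-drugs).

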