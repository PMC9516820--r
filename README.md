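# pathgnn

Pathway-topology-aware graph neural networks for long-term-survival
classification from bulk transcriptomes, with integrated-gradients pathway
attribution and survival follow-up — implemented in pure R on a small
reverse-mode autodiff engine shipped with the package.

## The problem and who this is for

Prognostic signal in tumour transcriptomes is not only a property of single
genes: co-expression *along curated molecular interactions* within a pathway
can separate long-term survivors (LTS, > k years, default k = 3) from
non-survivors even when every gene's marginal distribution is identical
between the groups.  Models that treat expression as a flat gene vector —
dense networks, random forests, logistic regression, and pathway-masked
networks (PGDNN) whose first layer merely pools member genes — are blind to
that structure.

`pathgnn` is for computational biologists who want to

- encode each patient's pathways as graphs (genes = nodes, interactions =
  edges, expression = node features) from standard GMT + edge-list +
  expression + clinical files,
- classify survival with a hierarchical graph encoder, and
- find out *which* pathways drove the prediction, with a survival sanity
  check on each candidate.

## The model

One shared encoder (Subnetwork 1) maps every pathway graph to a scalar
score: `n_blocks` of GraphSAGE convolution
(`h'_v = W_self h_v + W_nbr · mean_{u∈N(v)} h_u + b`; GCN/GAT variants for
ablation) followed by SAGPool self-attention pooling (keep
`⌈ratio·n⌉` top-scored nodes, gate by `tanh(score)`), a Set2Set
attention readout after each block (add/mean variants), graph normalisation
between blocks, and a tanh scoring head, so each pathway score
`S_i ∈ (−1, 1)`.  Subnetwork 2 classifies `[S, clinical]` through a
128/32-unit ReLU MLP with 40% dropout and softmax, trained with
cross-entropy, Adam (0.001 for 150 epochs then 0.0005, batch 60) under
stratified fivefold cross-validation with AUC as the metric.

Interpretation: integrated gradients of the short-survival logit with
respect to the pathway scores (zero baseline, midpoint quadrature, clinical
covariates removed), aggregated per pathway as the signed mean attribution
over the risk-class samples (see the methods vignette for why the cohort
mean cancels), z-transformed across pathways; pathways with z > 1.96 are
candidates, each followed up by a median-split log-rank test and
Kaplan–Meier curves with Greenwood bands.

The synthetic-data module plants a purely *topological* class signal:
causal-pathway genes are correlated along the pathway's true edges in one
class and along a degree-preserving rewiring in the other, with matched
marginals — so only edge-aware models can see it.

## Worked example

```r
library(pathgnn)

# a simulated cohort whose signal lives only in edge-wise co-expression
dir <- tempfile()
write_fixture_bundle(dir, preset = "topological", seed = 11)
ds <- load_fixture_bundle(dir)
print(ds)
#> PathGNN dataset: 20 pathways, 234 samples ( 98 LTS / 136 nonLTS ), 66 excluded
#>   clinical features: (none)

tc <- train_config(epochs = 35, batch_size = 60, lr_phase1 = 0.01,
                   lr_phase2 = 0.005, lr_milestone = 21, seed = 1, restarts = 2)
cv <- run_cv(ds, tc = tc,
             config_args = list(n_blocks = 1, seed = 1,
                                block = block_config("sage", hidden_dim = 8)))
print(cv)
#> CV AUC: 0.906 +/- 0.118  (folds: 0.673, 0.956, 0.969, 0.996, 0.936)
```

The per-fold AUCs are held-out discrimination between long- and short-term
survivors; ~0.9 on a signal that is invisible marginally (a random forest
on the same folds stays near 0.5) is the topology premium.  Interpretation
then recovers the planted pathways:

```r
pp  <- fit_preprocess(ds$expression, ds$preprocess, ds$cohort_used$sample_id)
d   <- prepare_model_data(ds, preproc = pp)
fit <- train_model(d, cv$config, tc)
res <- interpret_model(fit, d, survival = ds$cohort_used)
imp <- res$importance
head(imp[order(-imp$z), ], 3)
#>    pathway_id aggregate     z selected logrank_p
#> 1       PW001     1.197 2.809     TRUE  7.67e-14
#> 2       PW002     1.102 2.558     TRUE  6.04e-35
#> 16      PW016     0.425 0.773    FALSE        NA
```

`PW001` and `PW002` — the two causal pathways recorded in `truth.json` by
the generator — are the only pathways clearing the z > 1.96 cut-off, and
their median-split log-rank p-values confirm that the attribution separates
survival.  Recovery is stochastic in the training seed: across twenty
seeded refits of this cohort, both planted pathways clear the cut-off in
16/20 runs (the property the test suite asserts).

A shell entry point wraps the same functions
(`simulate`, `build`, `train`, `benchmark`, `ablate`, `interpret`, `km`):

```sh
$(Rscript -e 'cat(system.file("cli", "pathgnn", package = "pathgnn"))') \
  simulate --preset topological --out run/sim --seed 1
```

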