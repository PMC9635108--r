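# dtiline

Drug–target interaction (DTI) prediction from heterogeneous biomedical
networks, for computational biologists and cheminformaticians who want a
fully inspectable, desk-scale implementation of the
*pair-line-graph + graph-transformer* approach.

Most network-based DTI predictors embed drugs and proteins separately
and score pairs afterwards. `dtiline` instead makes the candidate
**drug–protein pair** the unit of classification:

1. **Feature extraction.** Every drug-related association matrix
   (drug–drug interaction, drug–disease, drug–side-effect) is projected
   to a drug–drug similarity network by the Jaccard coefficient
   `Sim(A, B) = |A ∩ B| / |A ∪ B|`; together with the chemical
   similarity matrix that gives four drug networks (three for proteins:
   protein–protein, protein–disease, sequence similarity). A restart
   random walk `S^{t+1} = (1 − p_r) S^t B + p_r I` (restart `p_r = 0.5`,
   20 iterations) turns each network into per-entity diffusion states;
   concatenation gives features of width `4·n_drugs` and `3·n_proteins`
   (2832 and 4536 at the reference scale of 708 drugs / 1512 proteins).
2. **PCA** reduces each entity type to 125 dimensions (default).
3. **Line graph.** Known interactions plus an equal number of sampled
   negatives become nodes; an edge joins two pairs sharing a drug or a
   protein; node features concatenate the pair's reduced features.
4. **Graph transformer.** Per-arc multi-head attention
   `α_{c,ij} = softmax_{j∈N(i)}(q_{c,i}ᵀ k_{c,j} / √d)` with gated
   residual connections between layers, head-averaged final layer, and a
   fully connected two-logit head; trained transductively with Adam on
   cross-entropy (80/10/10 split, best-validation selection). Forward
   *and* backward passes are implemented in the package (R + small C++
   kernels) and gradient-checked against finite differences.
5. **Evaluation** with AUROC (rank statistic) and AUPR (threshold
   sweep), both implemented from first principles and tested against
   brute-force oracles; ablation modes drop the transformer
   (`no_gtn`) or the line graph (`no_line_graph`).

A seeded synthetic heterogeneous-network simulator with planted
latent-factor interaction structure makes the entire pipeline testable
without external data; an ingestion adapter (`ingest_real_dataset()`)
accepts real networks in the same TSV edge-list layout.

## Worked example

```r
library(dtiline)

net  <- simulate_hetnet(synth_config(seed = 1))
net
#> <synth_hetnet> 120 drugs, 180 proteins, 60 diseases, 40 side effects
#>   drug-protein interactions: 818 (density 0.0379)

prep <- prepare_dti_data(net, pca_dim = 64, seed = 1)
prep$graph
#> <pair_line_graph> 1636 pair nodes (818 positive), 29921 edges, 128 features

fit <- train_gtn(prep$graph, gtn_config(),
                 train_config(n_iterations = 150, eval_every = 25, seed = 1))
evaluate(fit, split = "test")
#> <dti_metrics> split = test, n = 164 (82 positive)
#>   AUROC = 0.9542   AUPR = 0.9549

logistic_baseline(prep$graph, split = "test")
#> <dti_metrics> split = test, n = 164 (82 positive)
#>   AUROC = 0.9438   AUPR = 0.9414
```

The simulator planted ~800 true interactions among 120 × 180 candidate
pairs with 5% label noise; the graph transformer recovers the held-out
test pairs at AUROC 0.954, slightly ahead of a logistic regression on
the identical features — the planted signal is linear-ish in the
diffusion features, so the margin is modest by design. `glance(fit)`,
`tidy(fit)` and `autoplot()` expose the training history and ROC/PR
curves; `run_ablation(prep, "no_gtn")` and
`run_ablation(prep, "no_line_graph")` rerun the two reduced variants.

`run_pipeline(pipeline_config(out_dir = "run1", seed = 1))` executes
simulate → featurize → reduce → build-linegraph → train → evaluate with
content-digest stage skipping and a JSON run manifest;
`inst/cli/dtiline` wraps the same functions for shell use.

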