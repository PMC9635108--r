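#' Prepare line-graph training data from a heterogeneous network
#'
#' Runs the feature pipeline end to end in memory: diffusion features for
#' drugs and proteins, separate principal-component reductions, 1:1 (or
#' `neg_ratio`:1) negative sampling, the train/val/test split, and the
#' pair line graph with concatenated reduced features.
#'
#' @param net A `synth_hetnet` (simulated or ingested).
#' @param pca_dim Components per entity type. `NULL` (default) uses 125
#'   capped at what the entity count allows (`min(125, n_entities - 1)`).
#' @param neg_ratio Negatives per positive; default 1.
#' @param restart,n_iter,tol Random-walk-with-restart settings.
#' @param fractions Train/val/test fractions; default `c(0.8, 0.1, 0.1)`.
#' @param seed Seed for negative sampling and the split.
#' @return List with `graph` (split `pair_line_graph`), `drug_red`,
#'   `protein_red` (reduced feature matrices), `projections`, and `net`.
#' @export
prepare_dti_data <- function(net, pca_dim = NULL, neg_ratio = 1,
                             restart = 0.5, n_iter = 20, tol = 1e-10,
                             fractions = c(0.8, 0.1, 0.1), seed = 1) {
  feats <- diffusion_features(net, restart = restart, n_iter = n_iter, tol = tol)
  dim_d <- if (is.null(pca_dim)) min(125L, nrow(feats$drug) - 1L) else pca_dim
  dim_p <- if (is.null(pca_dim)) min(125L, nrow(feats$protein) - 1L) else pca_dim
  proj_d <- fit_projection(feats$drug, dim_d)
  proj_p <- fit_projection(feats$protein, dim_p)
  drug_red <- project_features(proj_d, feats$drug)
  protein_red <- project_features(proj_p, feats$protein)
  pairs <- candidate_pairs(net, neg_ratio = neg_ratio, seed = seed)
  pairs <- split_candidates(pairs, fractions = fractions, seed = seed + 1L)
  g <- build_line_graph(pairs, drug_red, protein_red)
  g$nodes$split <- pairs$split
  list(graph = g, drug_red = drug_red, protein_red = protein_red,
       projections = list(drug = proj_d, protein = proj_p), net = net)
}

#' Simulate, train and evaluate one full experiment
#'
#' Convenience wrapper: simulate a synthetic heterogeneous network,
#' prepare the pair line graph, train the graph-transformer, and report
#' test metrics next to the logistic baseline on the same features.
#'
#' @param synth_cfg A [synth_config()].
#' @param gtn_cfg,tr_cfg Model and training configurations.
#' @inheritParams prepare_dti_data
#' @return List with `prep`, `fit`, `report` (test `dti_metrics`) and
#'   `baseline` (test `dti_metrics` of the logistic baseline).
#' @export
run_dti_experiment <- function(synth_cfg = synth_config(),
                               gtn_cfg = gtn_config(),
                               tr_cfg = train_config(),
                               pca_dim = NULL, neg_ratio = 1) {
  net <- simulate_hetnet(synth_cfg)
  prep <- prepare_dti_data(net, pca_dim = pca_dim, neg_ratio = neg_ratio,
                           seed = synth_cfg$seed)
  fit <- train_gtn(prep$graph, gtn_cfg, tr_cfg)
  list(prep = prep, fit = fit,
       report = evaluate(fit, split = "test"),
       baseline = logistic_baseline(prep$graph, split = "test"))
}
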