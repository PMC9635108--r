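# "no line graph" ablation: the same graph-transformer stack applied to
# the bipartite drug/protein interaction graph (training-split
# interactions as edges), with pair scores from concatenated endpoint
# embeddings.

bipartite_setup <- function(prep, add_self_loops = TRUE) {
  dr <- prep$drug_red; pr <- prep$protein_red
  if (ncol(dr) != ncol(pr)) {
    abort("no_line_graph mode needs equal drug and protein feature widths")
  }
  nd <- nrow(dr)
  nodes <- prep$graph$nodes
  di <- match(nodes$drug_id, rownames(dr))
  pj <- nd + match(nodes$protein_id, rownames(pr))
  if (anyNA(di) || anyNA(pj)) abort("candidate pairs reference unknown entities")
  train_pos <- which(nodes$label == 1L & nodes$split == "train")
  if (length(train_pos) == 0) abort("no training-split positive pairs to build the bipartite graph")
  arcs <- rbind(cbind(src = di[train_pos], dst = pj[train_pos]),
                cbind(src = pj[train_pos], dst = di[train_pos]))
  n_ent <- nd + nrow(pr)
  if (add_self_loops) {
    arcs <- rbind(arcs, cbind(src = seq_len(n_ent), dst = seq_len(n_ent)))
  }
  arcs <- arcs[order(arcs[, 2], arcs[, 1]), , drop = FALSE]
  list(F_ent = rbind(dr, pr), arcs = arcs, di = di, pj = pj, n_ent = n_ent,
       drug_ids = rownames(dr), protein_ids = rownames(pr), nd = nd)
}

bipartite_pair_logits <- function(emb_H, di, pj, head) {
  cat_f <- cbind(emb_H[di, , drop = FALSE], emb_H[pj, , drop = FALSE])
  list(cat = cat_f,
       logits = cat_f %*% head$W_out + rep(head$b_out, each = nrow(cat_f)))
}

train_bipartite_gtn <- function(prep, gtn_cfg = gtn_config(),
                                tr_cfg = train_config()) {
  bp <- bipartite_setup(prep, add_self_loops = gtn_cfg$add_self_loops)
  idx <- split_indices(prep$graph$nodes)
  y <- prep$graph$labels
  scaler <- standardize_features(bp$F_ent, seq_len(bp$n_ent))
  X <- scaler$apply(bp$F_ent)
  out <- layer_out_dim(gtn_cfg, gtn_cfg$n_layers)
  with_local_seed(tr_cfg$seed, {
    params <- gtn_init_params(ncol(X), gtn_cfg,
                              seed = sample.int(.Machine$integer.max, 1))
    params$head <- list(W_out = unif_init(2L * out, 2L, 2L * out),
                        b_out = numeric(2))
    st <- adam_state(params)
    best <- list(params = params, val = -Inf, iter = 0L)
    hist <- list()
    for (it in seq_len(tr_cfg$n_iterations)) {
      masks <- make_dropout_masks(gtn_cfg, bp$n_ent)
      emb <- gtn_embed(X, bp$arcs, params, gtn_cfg, masks, keep_cache = TRUE)
      pl <- bipartite_pair_logits(emb$H, bp$di, bp$pj, params$head)
      sc <- softmax_ce(pl$logits, y, idx$train)
      if (!is.finite(sc$loss)) {
        abort(sprintf("training diverged (non-finite loss) at iteration %d", it))
      }
      dW_out <- crossprod(pl$cat, sc$dlogits)
      db_out <- colSums(sc$dlogits)
      dcat <- sc$dlogits %*% t(params$head$W_out)
      dEmb <- index_add(bp$n_ent, bp$di, dcat[, seq_len(out), drop = FALSE]) +
        index_add(bp$n_ent, bp$pj, dcat[, out + seq_len(out), drop = FALSE])
      back <- gtn_layers_backward(emb$cache, bp$arcs, params, gtn_cfg, dEmb)
      grads <- list(layers = back$layers,
                    head = list(W_out = dW_out, b_out = db_out))
      upd <- adam_update(params, grads, st, lr = tr_cfg$learning_rate)
      params <- upd$params; st <- upd$state
      if (it %% tr_cfg$eval_every == 0 || it == tr_cfg$n_iterations) {
        emb_eval <- gtn_embed(X, bp$arcs, params, gtn_cfg)
        scores <- predict_scores(
          bipartite_pair_logits(emb_eval$H, bp$di, bp$pj, params$head)$logits)
        val_auc <- auroc(y[idx$val], scores[idx$val])
        hist[[length(hist) + 1L]] <- tibble::tibble(
          iteration = it, loss = sc$loss, val_auroc = val_auc)
        if (val_auc >= best$val) best <- list(params = params, val = val_auc, iter = it)
      }
    }
    new_gtn_fit("bipartite", best$params, gtn_cfg, tr_cfg,
                dplyr::bind_rows(hist), best$iter, best$val, scaler,
                prep$graph,
                extra = list(bipartite = bp))
  })
}

bipartite_scores <- function(fit, g) {
  bp <- fit$bipartite
  X <- fit$scaler$apply(bp$F_ent)
  emb <- gtn_embed(X, bp$arcs, fit$params, fit$gtn_config)
  di <- match(g$nodes$drug_id, bp$drug_ids)
  pj <- bp$nd + match(g$nodes$protein_id, bp$protein_ids)
  if (anyNA(di) || anyNA(pj)) abort("pairs reference entities unknown to the fitted bipartite model")
  predict_scores(bipartite_pair_logits(emb$H, di, pj, fit$params$head)$logits)
}
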