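#' Training configuration
#'
#' @param learning_rate Adam initial learning rate; default 0.001.
#' @param n_iterations Full-graph optimisation iterations; default 2000.
#'   The model is transductive, so one iteration is one gradient step on
#'   the whole graph's training-node cross-entropy.
#' @param eval_every Validation-AUROC evaluation interval; default 50.
#' @param seed Seed driving initialisation and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, n_iterations = 2000,
                         eval_every = 50, seed = 1) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    abort("`learning_rate` must be > 0")
  }
  structure(list(
    learning_rate = learning_rate,
    n_iterations = assert_count(n_iterations, "n_iterations"),
    eval_every = assert_count(eval_every, "eval_every"),
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "train_config")
}

#' Split candidate pairs into train / validation / test
#'
#' Positives and negatives are partitioned independently at the given
#' fractions (largest-remainder apportionment, so 10 positives at
#' (0.8, 0.1, 0.1) give exactly 8/1/1), permuted under `seed`. Errors if
#' any split would miss a class.
#'
#' @param pairs Candidate-pair data frame with a `label` column.
#' @param fractions Length-3 positive vector summing to 1; default
#'   `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed.
#' @return `pairs` with an added `split` factor
#'   (`"train"`, `"val"`, `"test"`).
#' @export
split_candidates <- function(pairs, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot("label" %in% names(pairs))
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three positive numbers summing to 1")
  }
  split_names <- c("train", "val", "test")
  apportion <- function(n) {
    raw <- n * fractions
    k <- floor(raw)
    rem <- n - sum(k)
    if (rem > 0) {
      extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
      k[extra] <- k[extra] + 1
    }
    k
  }
  out <- rep(NA_character_, nrow(pairs))
  with_local_seed(seed, {
    for (lab in c(1L, 0L)) {
      idx <- which(pairs$label == lab)
      sizes <- apportion(length(idx))
      if (any(sizes == 0)) {
        abort(sprintf(
          "too few samples of class %d (%d) to populate train/val/test",
          lab, length(idx)))
      }
      idx <- sample(idx)
      out[idx] <- rep(split_names, sizes)
    }
  })
  pairs$split <- factor(out, levels = split_names)
  pairs
}

standardize_features <- function(X, idx_fit) {
  mu <- colMeans(X[idx_fit, , drop = FALSE])
  sd <- apply(X[idx_fit, , drop = FALSE], 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(apply = function(M) sweep(sweep(M, 2, mu), 2, sd, "/"),
       mean = mu, sd = sd)
}

split_indices <- function(nodes) {
  list(train = which(nodes$split == "train"),
       val = which(nodes$split == "val"),
       test = which(nodes$split == "test"))
}

new_gtn_fit <- function(type, params, gtn_cfg, tr_cfg, history, best_iter,
                        best_val, scaler, graph, extra = list()) {
  structure(c(list(
    type = type, params = params, gtn_config = gtn_cfg,
    train_config = tr_cfg, history = history,
    best_iteration = best_iter, best_val_auroc = best_val,
    scaler = scaler, graph = graph,
    n_parameters = count_parameters(params)
  ), extra), class = "gtn_fit")
}

#' Train the graph-transformer classifier on a split pair line graph
#'
#' Full-graph Adam steps on the training nodes' cross-entropy; validation
#' labels never enter the loss (transductive node classification: all
#' candidate nodes participate in message passing). The validation AUROC
#' is tracked every `eval_every` iterations and the best-validation
#' parameters are returned. Features are column-standardised on
#' training-node statistics before entering the network.
#'
#' @param g A [build_line_graph()] result whose `nodes` carry a `split`
#'   column (see [split_candidates()]).
#' @param gtn_cfg A [gtn_config()].
#' @param tr_cfg A [train_config()].
#' @return Object of class `gtn_fit` with the best parameters, the
#'   training `history` tibble (iteration, loss, val_auroc) and metadata.
#' @export
train_gtn <- function(g, gtn_cfg = gtn_config(), tr_cfg = train_config()) {
  stopifnot(inherits(g, "pair_line_graph"), "split" %in% names(g$nodes))
  if (any(!is.finite(g$features))) abort("graph features must be finite")
  idx <- split_indices(g$nodes)
  arcs <- to_directed_arcs(g, add_self_loops = gtn_cfg$add_self_loops)
  scaler <- standardize_features(g$features, idx$train)
  X <- scaler$apply(g$features)
  y <- g$labels
  with_local_seed(tr_cfg$seed, {
    params <- gtn_init_params(ncol(X), gtn_cfg,
                              seed = sample.int(.Machine$integer.max, 1))
    st <- adam_state(params)
    best <- list(params = params, val = -Inf, iter = 0L)
    hist <- list()
    for (it in seq_len(tr_cfg$n_iterations)) {
      masks <- make_dropout_masks(gtn_cfg, nrow(X))
      lg <- gtn_loss_grad(X, arcs, params, gtn_cfg, y, idx$train, masks)
      if (!is.finite(lg$loss)) {
        abort(sprintf("training diverged (non-finite loss) at iteration %d", it))
      }
      upd <- adam_update(params, lg$grads, st, lr = tr_cfg$learning_rate)
      params <- upd$params
      st <- upd$state
      if (it %% tr_cfg$eval_every == 0 || it == tr_cfg$n_iterations) {
        scores <- predict_scores(gtn_forward(X, arcs, params, gtn_cfg))
        val_auc <- auroc(y[idx$val], scores[idx$val])
        hist[[length(hist) + 1L]] <- tibble::tibble(
          iteration = it, loss = lg$loss, val_auroc = val_auc)
        if (val_auc >= best$val) {
          best <- list(params = params, val = val_auc, iter = it)
        }
      }
    }
    new_gtn_fit("full", best$params, gtn_cfg, tr_cfg,
                dplyr::bind_rows(hist), best$iter, best$val, scaler, g)
  })
}

fit_scores <- function(fit, g) {
  X <- fit$scaler$apply(g$features)
  if (fit$type == "full") {
    arcs <- to_directed_arcs(g, add_self_loops = fit$gtn_config$add_self_loops)
    predict_scores(gtn_forward(X, arcs, fit$params, fit$gtn_config))
  } else if (fit$type == "linear") {
    predict_scores(X %*% fit$params$W + rep(fit$params$b, each = nrow(X)))
  } else {
    bipartite_scores(fit, g)
  }
}

#' @export
predict.gtn_fit <- function(object, g = NULL, ...) {
  fit_scores(object, if (is.null(g)) object$graph else g)
}

#' Evaluate a trained model on one split
#'
#' @param fit A `gtn_fit`.
#' @param g Optionally a different split `pair_line_graph`; defaults to
#'   the graph the model was trained on.
#' @param split Which split to score (`"test"`, `"val"` or `"train"`).
#' @return A [metrics_report()] (`dti_metrics`).
#' @export
evaluate <- function(fit, g = NULL, split = "test") {
  stopifnot(inherits(fit, "gtn_fit"))
  if (is.null(g)) g <- fit$graph
  split <- match.arg(split, c("test", "val", "train"))
  idx <- which(g$nodes$split == split)
  if (length(idx) == 0) abort(sprintf("split '%s' is empty", split))
  scores <- fit_scores(fit, g)
  metrics_report(g$labels[idx], scores[idx], split = split)
}

#' @export
print.gtn_fit <- function(x, ...) {
  cat(sprintf("<gtn_fit> type = %s, %d parameters\n", x$type, x$n_parameters))
  cat(sprintf("  best validation AUROC %.4f at iteration %d\n",
              x$best_val_auroc, x$best_iteration))
  invisible(x)
}

#' @export
tidy.gtn_fit <- function(x, ...) x$history

#' @export
glance.gtn_fit <- function(x, ...) {
  tibble::tibble(
    type = x$type, n_parameters = x$n_parameters,
    best_iteration = x$best_iteration,
    best_val_auroc = x$best_val_auroc,
    final_loss = x$history$loss[nrow(x$history)]
  )
}

#' @export
autoplot.gtn_fit <- function(object, ...) {
  df <- tidyr_longer(object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}

tidyr_longer <- function(history) {
  dplyr::bind_rows(
    tibble::tibble(iteration = history$iteration, metric = "training loss",
                   value = history$loss),
    tibble::tibble(iteration = history$iteration, metric = "validation AUROC",
                   value = history$val_auroc)
  )
}

# ---- no-GTN ablation: linear softmax head on raw pair features ----

train_linear_head <- function(g, tr_cfg) {
  idx <- split_indices(g$nodes)
  scaler <- standardize_features(g$features, idx$train)
  X <- scaler$apply(g$features)
  y <- g$labels
  with_local_seed(tr_cfg$seed, {
    params <- list(W = unif_init(ncol(X), 2L, ncol(X)), b = numeric(2))
    st <- adam_state(params)
    best <- list(params = params, val = -Inf, iter = 0L)
    hist <- list()
    for (it in seq_len(tr_cfg$n_iterations)) {
      logits <- X %*% params$W + rep(params$b, each = nrow(X))
      sc <- softmax_ce(logits, y, idx$train)
      if (!is.finite(sc$loss)) {
        abort(sprintf("training diverged (non-finite loss) at iteration %d", it))
      }
      grads <- list(W = crossprod(X, sc$dlogits), b = colSums(sc$dlogits))
      upd <- adam_update(params, grads, st, lr = tr_cfg$learning_rate)
      params <- upd$params; st <- upd$state
      if (it %% tr_cfg$eval_every == 0 || it == tr_cfg$n_iterations) {
        scores <- predict_scores(X %*% params$W + rep(params$b, each = nrow(X)))
        val_auc <- auroc(y[idx$val], scores[idx$val])
        hist[[length(hist) + 1L]] <- tibble::tibble(
          iteration = it, loss = sc$loss, val_auroc = val_auc)
        if (val_auc >= best$val) best <- list(params = params, val = val_auc, iter = it)
      }
    }
    new_gtn_fit("linear", best$params, NULL, tr_cfg,
                dplyr::bind_rows(hist), best$iter, best$val, scaler, g)
  })
}

#' Logistic-regression baseline on the concatenated pair features
#'
#' Plain maximum-likelihood logistic regression (no graph) on the same
#' standardised pair features the graph models see; used as the reference
#' the planted-signal recovery is compared against.
#'
#' @param g A split `pair_line_graph`.
#' @param split Split to report metrics on.
#' @return A `dti_metrics` report with the fitted coefficients attached as
#'   attribute `"coefficients"`.
#' @export
logistic_baseline <- function(g, split = "test") {
  idx <- split_indices(g$nodes)
  scaler <- standardize_features(g$features, idx$train)
  X <- cbind(1, scaler$apply(g$features))
  fit <- suppressWarnings(
    stats::glm.fit(X[idx$train, , drop = FALSE], g$labels[idx$train],
                   family = stats::binomial())
  )
  scores <- as.numeric(plogis(X %*% fit$coefficients))
  eval_idx <- which(g$nodes$split == split)
  rep <- metrics_report(g$labels[eval_idx], scores[eval_idx], split = split)
  attr(rep, "coefficients") <- fit$coefficients
  rep
}

#' Run one pipeline variant for the ablation comparison
#'
#' `"full"` is the standard pair-line-graph transformer; `"no_gtn"` drops
#' message passing and trains the fully connected head directly on the
#' pair features; `"no_line_graph"` applies the same graph-transformer to
#' the bipartite drug/protein graph (training-split interactions as
#' edges) and scores pairs from concatenated endpoint embeddings.
#'
#' @param prep A [prepare_dti_data()] result.
#' @param mode One of `"full"`, `"no_gtn"`, `"no_line_graph"`.
#' @param gtn_cfg,tr_cfg Model and training configurations.
#' @param split Split to report metrics on.
#' @return List with elements `fit` (`gtn_fit`) and `report`
#'   (`dti_metrics`).
#' @export
run_ablation <- function(prep, mode = c("full", "no_gtn", "no_line_graph"),
                         gtn_cfg = gtn_config(), tr_cfg = train_config(),
                         split = "test") {
  mode <- match.arg(mode)
  fit <- switch(mode,
    full = train_gtn(prep$graph, gtn_cfg, tr_cfg),
    no_gtn = train_linear_head(prep$graph, tr_cfg),
    no_line_graph = train_bipartite_gtn(prep, gtn_cfg, tr_cfg)
  )
  list(fit = fit, report = evaluate(fit, split = split))
}
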