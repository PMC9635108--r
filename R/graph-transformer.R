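#' Graph-transformer configuration
#'
#' Architecture of the pair classifier: stacked graph-transformer layers
#' with per-edge multi-head softmax attention, gated residual connections
#' between layers, and a final layer whose heads are averaged with no
#' non-linearity, followed by a fully connected two-logit head.
#'
#' @param n_layers Number of graph-transformer layers (>= 1); default 2.
#' @param n_heads Attention heads `C` per layer; default 4.
#' @param head_dim Hidden size `d` of each head; default 32. Hidden layers
#'   concatenate heads (width `C * d`); the final layer averages them
#'   (width `d`).
#' @param dropout Dropout probability applied to hidden-layer activations
#'   during training; default 0.1.
#' @param use_gated_residual Use the learned per-node convex gate between
#'   the aggregated message and a linear projection of the layer input;
#'   default `TRUE`.
#' @param add_self_loops Append a self-arc per node so every attention
#'   neighborhood is non-empty; default `TRUE`.
#' @param activation Hidden-layer activation, `"relu"` or `"none"`.
#' @return An object of class `gtn_config`.
#' @export
gtn_config <- function(n_layers = 2, n_heads = 4, head_dim = 32,
                       dropout = 0.1, use_gated_residual = TRUE,
                       add_self_loops = TRUE,
                       activation = c("relu", "none")) {
  structure(list(
    n_layers = assert_count(n_layers, "n_layers"),
    n_heads = assert_count(n_heads, "n_heads"),
    head_dim = assert_count(head_dim, "head_dim"),
    dropout = assert_prob(dropout, "dropout", hi = 1, hi_open = TRUE),
    use_gated_residual = isTRUE(use_gated_residual),
    add_self_loops = isTRUE(add_self_loops),
    activation = match.arg(activation)
  ), class = "gtn_config")
}

layer_out_dim <- function(config, layer) {
  if (layer == config$n_layers) config$head_dim
  else config$n_heads * config$head_dim
}

unif_init <- function(nr, nc, fan_in) {
  matrix(runif(nr * nc, -1 / sqrt(fan_in), 1 / sqrt(fan_in)), nr, nc)
}

#' Initialise graph-transformer parameters
#'
#' Uniform fan-in-scaled initialisation from a seeded generator, so a seed
#' fully determines the starting point. Weight matrices are stored as a
#' named key-to-array list: per layer the query/key/value projections
#' (`W_q`, `W_k`, `W_v`, stacked across heads as `d_in x (C*d)`), their
#' biases, the residual projection `W_r` and gate parameters `w_g`, `b_g`;
#' plus the classification head `W_out`, `b_out`.
#'
#' @param input_dim Width of the node features entering layer 1.
#' @param config A [gtn_config()].
#' @param n_classes Number of output logits; default 2.
#' @param seed Integer seed.
#' @return List with elements `layers` (list of per-layer parameter lists)
#'   and `head` (`W_out`, `b_out`).
#' @export
gtn_init_params <- function(input_dim, config, n_classes = 2, seed = 1) {
  stopifnot(inherits(config, "gtn_config"))
  C <- config$n_heads; d <- config$head_dim
  with_local_seed(seed, {
    d_in <- input_dim
    layers <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      out <- layer_out_dim(config, l)
      layers[[l]] <- list(
        W_q = unif_init(d_in, C * d, d_in), b_q = numeric(C * d),
        W_k = unif_init(d_in, C * d, d_in), b_k = numeric(C * d),
        W_v = unif_init(d_in, C * d, d_in), b_v = numeric(C * d),
        W_r = unif_init(d_in, out, d_in),
        w_g = as.numeric(unif_init(3L * out, 1L, 3L * out)),
        b_g = 0
      )
      d_in <- out
    }
    head <- list(W_out = unif_init(d_in, n_classes, d_in),
                 b_out = numeric(n_classes))
    list(layers = layers, head = head)
  })
}

check_arcs <- function(arcs, n) {
  stopifnot(is.matrix(arcs), ncol(arcs) == 2)
  if (nrow(arcs) == 0 || any(arcs < 1) || any(arcs > n)) {
    abort("arcs must be a non-empty matrix of node indices in 1..n")
  }
  missing <- setdiff(seq_len(n), unique(arcs[, 2]))
  if (length(missing) > 0) {
    abort(sprintf(paste0(
      "node %d has an empty neighborhood; attention is undefined — ",
      "enable add_self_loops or connect the node"), missing[1]))
  }
  invisible(arcs)
}

#' Multi-head attention weights on a directed arc set
#'
#' For each arc (j to i) and head c computes the scaled dot-product score
#' \eqn{\exp(q_{c,i}^\top k_{c,j} / \sqrt{d})} with
#' \eqn{q = W_q h + b_q}, \eqn{k = W_k h + b_k}, normalised over each
#' destination's neighborhood (line-graph edges carry no attributes, so
#' the edge terms are zero).
#'
#' @param H Node feature matrix (`n` x `d_in`).
#' @param arcs Two-column matrix of (src, dst) node indices; every node
#'   must appear as a destination.
#' @param layer_params Parameter list for the layer (see
#'   [gtn_init_params()]).
#' @param n_heads,head_dim Head count `C` and per-head width `d`.
#' @return `nrow(arcs)` x `n_heads` matrix of attention weights; each
#'   destination's arcs sum to 1 per head.
#' @export
attention_scores <- function(H, arcs, layer_params, n_heads, head_dim) {
  n <- nrow(H)
  check_arcs(arcs, n)
  Ht <- t(H)
  Qt <- crossprod(layer_params$W_q, Ht) + layer_params$b_q
  Kt <- crossprod(layer_params$W_k, Ht) + layer_params$b_k
  src <- as.integer(arcs[, 1]); dst <- as.integer(arcs[, 2])
  S <- .arc_attention_scores_t(Qt, Kt, src, dst, n_heads, head_dim)
  .group_softmax(S, dst, n)
}

#' Aggregate value messages with attention weights
#'
#' Per head, messages \eqn{m_{c,i} = \sum_{j \in N(i)} \alpha_{c,ij}
#' (W_v h_j + b_v)} are formed from the neighbor (source) features; heads
#' are concatenated on hidden layers and averaged on the final layer.
#'
#' @inheritParams attention_scores
#' @param alpha Attention weights from [attention_scores()].
#' @param combine `"concat"` (width `C*d`) or `"mean"` (width `d`).
#' @return Aggregated message matrix (one row per node).
#' @export
aggregate_messages <- function(H, arcs, alpha, layer_params, n_heads,
                               head_dim, combine = c("concat", "mean")) {
  combine <- match.arg(combine)
  n <- nrow(H)
  Vt <- crossprod(layer_params$W_v, t(H)) + layer_params$b_v
  M <- t(.attn_aggregate_t(alpha, Vt, as.integer(arcs[, 1]),
                           as.integer(arcs[, 2]), n, n_heads, head_dim))
  if (combine == "concat") M
  else M %*% (kronecker(matrix(1, n_heads, 1), diag(head_dim)) / n_heads)
}

#' Gated residual combination of message and input projection
#'
#' Computes `r = h_prev %*% W_r`, a scalar per-node gate
#' `beta = sigmoid([m, r, m - r] %*% w_g + b_g)`, and the convex
#' combination `beta * r + (1 - beta) * m`, which keeps each coordinate of
#' the output between the message and the residual and counteracts
#' over-smoothing in deep stacks.
#'
#' @param h_prev Layer input (`n` x `d_in`).
#' @param m Aggregated message (`n` x `out`).
#' @param W_r Residual projection (`d_in` x `out`).
#' @param w_g Gate vector (length `3 * out`).
#' @param b_g Scalar gate bias.
#' @return List with `h` (combined output) and `beta` (per-node gate).
#' @export
gated_residual <- function(h_prev, m, W_r, w_g, b_g = 0) {
  r <- h_prev %*% W_r
  stopifnot(ncol(r) == ncol(m), length(w_g) == 3L * ncol(m))
  z <- cbind(m, r, m - r) %*% w_g + b_g
  beta <- plogis(as.numeric(z))
  list(h = beta * r + (1 - beta) * m, beta = beta, r = r, z = as.numeric(z))
}

#' Forward pass of the graph-transformer classifier
#'
#' Hidden layers: attention, head-concatenated aggregation, gated
#' residual, activation (and dropout when `masks` are supplied). Final
#' graph-transformer layer: heads averaged, no activation. A fully
#' connected head then maps node embeddings to one logit per class.
#'
#' @param features Node feature matrix.
#' @param arcs Directed arc matrix (see [to_directed_arcs()]).
#' @param params Parameters from [gtn_init_params()].
#' @param config A [gtn_config()].
#' @param masks Optional list of dropout masks (one per hidden layer),
#'   used during training; `NULL` disables dropout.
#' @param keep_cache Keep intermediate quantities for the backward pass.
#' @return Logit matrix (`n` x `n_classes`); with `keep_cache = TRUE` the
#'   per-layer cache is attached as attribute `"cache"`.
#' @export
gtn_forward <- function(features, arcs, params, config, masks = NULL,
                        keep_cache = FALSE) {
  emb <- gtn_embed(features, arcs, params, config, masks = masks,
                   keep_cache = keep_cache)
  n <- nrow(features)
  logits <- emb$H %*% params$head$W_out + rep(params$head$b_out, each = n)
  if (any(!is.finite(logits))) {
    abort("non-finite values produced in the classification head")
  }
  if (keep_cache) {
    attr(logits, "cache") <- list(layers = emb$cache, H_final = emb$H)
  }
  logits
}

# Embedding stack only (all graph-transformer layers, no classifier head).
gtn_embed <- function(features, arcs, params, config, masks = NULL,
                      keep_cache = FALSE) {
  stopifnot(inherits(config, "gtn_config"))
  C <- config$n_heads; d <- config$head_dim
  H <- features
  n <- nrow(H)
  src <- as.integer(arcs[, 1]); dst <- as.integer(arcs[, 2])
  check_arcs(arcs, n)
  cache <- if (keep_cache) vector("list", config$n_layers) else NULL
  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    final <- l == config$n_layers
    Ht <- t(H)
    Qt <- crossprod(lp$W_q, Ht) + lp$b_q
    Kt <- crossprod(lp$W_k, Ht) + lp$b_k
    Vt <- crossprod(lp$W_v, Ht) + lp$b_v
    alpha <- .group_softmax(.arc_attention_scores_t(Qt, Kt, src, dst, C, d),
                            dst, n)
    Mt <- .attn_aggregate_t(alpha, Vt, src, dst, n, C, d)
    M <- if (final) {
      t(Mt) %*% (kronecker(matrix(1, C, 1), diag(d)) / C)
    } else {
      t(Mt)
    }
    if (config$use_gated_residual) {
      gr <- gated_residual(H, M, lp$W_r, lp$w_g, lp$b_g)
      A <- gr$h
    } else {
      gr <- NULL
      A <- M
    }
    H_out <- if (!final && config$activation == "relu") relu(A) else A
    mask <- if (!final && !is.null(masks)) masks[[l]] else NULL
    if (!is.null(mask)) H_out <- H_out * mask
    if (any(!is.finite(H_out))) {
      abort(sprintf("non-finite values produced in graph-transformer layer %d", l))
    }
    if (keep_cache) {
      cache[[l]] <- list(H_in = H, alpha = alpha, M = M, gr = gr, A = A,
                         mask = mask, final = final,
                         Qt = Qt, Kt = Kt, Vt = Vt)
    }
    H <- H_out
  }
  list(H = H, cache = cache)
}

#' Interaction probabilities from two-class logits
#'
#' Softmax over the two logits; returns the positive-class column,
#' strictly increasing in the logit difference.
#'
#' @param logits Matrix with one row per node and 2 columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_scores <- function(logits) {
  stopifnot(is.matrix(logits), ncol(logits) == 2)
  if (any(!is.finite(logits))) abort("logits must be finite")
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  as.numeric(e[, 2] / rowSums(e))
}
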