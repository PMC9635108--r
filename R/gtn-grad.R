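# Hand-derived reverse-mode gradients for the graph-transformer stack and
# the Adam optimizer. Verified against central finite differences in the
# test suite (test-graph-transformer.R).

# Softmax cross-entropy on a subset of rows. labels in {0, 1}.
softmax_ce <- function(logits, labels, idx) {
  z <- logits[idx, , drop = FALSE]
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  y1 <- labels[idx] + 1L
  n <- length(idx)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y1)], 1e-300)))
  dz <- p
  dz[cbind(seq_len(n), y1)] <- dz[cbind(seq_len(n), y1)] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[idx, ] <- dz / n
  list(loss = loss, dlogits = dlogits)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

# Backward through all graph-transformer layers given the gradient of the
# final embeddings. Returns per-layer parameter gradients plus the
# gradient w.r.t. the input features.
gtn_layers_backward <- function(cache, arcs, params, config, dH) {
  C <- config$n_heads; d <- config$head_dim
  src <- as.integer(arcs[, 1]); dst <- as.integer(arcs[, 2])
  grads <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    cc <- cache[[l]]
    lp <- params$layers[[l]]
    H_in <- cc$H_in
    n <- nrow(H_in)
    out <- ncol(cc$M)
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    if (!cc$final && config$activation == "relu") dH <- dH * (cc$A > 0)
    g <- list(W_q = NULL, b_q = NULL, W_k = NULL, b_k = NULL,
              W_v = NULL, b_v = NULL,
              W_r = matrix(0, nrow(lp$W_r), ncol(lp$W_r)),
              w_g = numeric(length(lp$w_g)), b_g = 0)
    dH_in <- matrix(0, n, ncol(H_in))
    if (config$use_gated_residual) {
      gr <- cc$gr
      beta <- gr$beta
      dbeta <- rowSums(dH * (gr$r - cc$M))
      dz <- dbeta * beta * (1 - beta)
      w_m <- lp$w_g[seq_len(out)]
      w_r <- lp$w_g[out + seq_len(out)]
      w_d <- lp$w_g[2L * out + seq_len(out)]
      dM <- dH * (1 - beta) + outer(dz, w_m + w_d)
      dr <- dH * beta + outer(dz, w_r - w_d)
      g$w_g <- as.numeric(crossprod(cbind(cc$M, gr$r, cc$M - gr$r), dz))
      g$b_g <- sum(dz)
      g$W_r <- crossprod(H_in, dr)
      dH_in <- dH_in + dr %*% t(lp$W_r)
    } else {
      dM <- dH
    }
    # expand the message gradient to per-head column blocks (mean combine
    # spreads dM/C to every head; concat keeps the blocks as-is)
    dMall <- if (cc$final) {
      dM[, rep(seq_len(d), C), drop = FALSE] / C
    } else {
      dM
    }
    bk <- .attn_backward_t(cc$alpha, cc$Qt, cc$Kt, cc$Vt, t(dMall),
                           src, dst, C, d)
    g$W_q <- t(bk$dQt %*% H_in); g$b_q <- rowSums(bk$dQt)
    g$W_k <- t(bk$dKt %*% H_in); g$b_k <- rowSums(bk$dKt)
    g$W_v <- t(bk$dVt %*% H_in); g$b_v <- rowSums(bk$dVt)
    dH_in <- dH_in +
      t(lp$W_q %*% bk$dQt + lp$W_k %*% bk$dKt + lp$W_v %*% bk$dVt)
    grads[[l]] <- g
    dH <- dH_in
  }
  list(layers = grads, dFeatures = dH)
}

# Loss and full parameter gradient for the node-classification model.
gtn_loss_grad <- function(features, arcs, params, config, labels, idx,
                          masks = NULL) {
  logits <- gtn_forward(features, arcs, params, config, masks = masks,
                        keep_cache = TRUE)
  cache <- attr(logits, "cache")
  sc <- softmax_ce(logits, labels, idx)
  dW_out <- crossprod(cache$H_final, sc$dlogits)
  db_out <- colSums(sc$dlogits)
  dH <- sc$dlogits %*% t(params$head$W_out)
  back <- gtn_layers_backward(cache$layers, arcs, params, config, dH)
  list(loss = sc$loss,
       grads = list(layers = back$layers,
                    head = list(W_out = dW_out, b_out = db_out)),
       logits = logits)
}

# ---- Adam ----

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(step, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- step(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

count_parameters <- function(params) {
  if (is.list(params)) sum(vapply(params, count_parameters, numeric(1)))
  else length(params)
}

make_dropout_masks <- function(config, n) {
  if (config$dropout == 0 || config$n_layers < 2) return(NULL)
  lapply(seq_len(config$n_layers - 1L), function(l) {
    out <- layer_out_dim(config, l)
    matrix(rbinom(n * out, 1, 1 - config$dropout), n, out) / (1 - config$dropout)
  })
}
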