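tiny_setup <- function(n = 6, d_in = 4, C = 2, d = 3, seed = 1,
                       p_edge = 0.5, self_loops = TRUE) {
  withr::with_seed(seed, {
    H <- matrix(rnorm(n * d_in), n, d_in)
    adj <- matrix(rbinom(n * n, 1, p_edge), n, n)
    adj[lower.tri(adj, diag = TRUE)] <- 0
    e <- which(adj == 1, arr.ind = TRUE)
    arcs <- rbind(cbind(e[, 1], e[, 2]), cbind(e[, 2], e[, 1]))
    if (self_loops) arcs <- rbind(arcs, cbind(1:n, 1:n))
    colnames(arcs) <- c("src", "dst")
    cfg <- gtn_config(n_layers = 1, n_heads = C, head_dim = d, dropout = 0)
    params <- gtn_init_params(d_in, cfg, seed = seed + 100)
    list(H = H, arcs = arcs, cfg = cfg, params = params, lp = params$layers[[1]])
  })
}

test_that("attention weights normalise to one per node and head", {
  s <- tiny_setup(n = 8, seed = 3)
  al <- attention_scores(s$H, s$arcs, s$lp, 2, 3)
  expect_true(all(al >= 0))
  sums <- rowsum(al, s$arcs[, 2])
  expect_equal(unname(sums), matrix(1, 8, 2), tolerance = 1e-6)
})

test_that("a single-neighbor node gets attention weight one", {
  s <- tiny_setup(n = 5, p_edge = 0, self_loops = TRUE)  # self-arcs only
  al <- attention_scores(s$H, s$arcs, s$lp, 2, 3)
  expect_equal(unname(al), matrix(1, 5, 2), tolerance = 1e-12)
})

test_that("identical neighbor features give uniform attention", {
  s <- tiny_setup(n = 6, p_edge = 1)
  H <- matrix(rep(s$H[1, ], each = 6), 6)  # all nodes identical
  al <- attention_scores(H, s$arcs, s$lp, 2, 3)
  deg <- table(s$arcs[, 2])
  expect_equal(al[, 1], as.numeric(1 / deg[as.character(s$arcs[, 2])]),
               tolerance = 1e-12)
})

test_that("attention equals the dense masked-softmax oracle", {
  for (seed in 1:3) {
    s <- tiny_setup(n = 7, seed = seed)
    al <- attention_scores(s$H, s$arcs, s$lp, 2, 3)
    expect_equal(al, dense_attention_oracle(s$H, s$arcs, s$lp, 2, 3),
                 tolerance = 1e-6)
  }
})

test_that("empty neighborhoods are rejected when self-loops are off", {
  s <- tiny_setup(n = 5, p_edge = 0, self_loops = TRUE)
  expect_error(attention_scores(s$H, s$arcs[-2, , drop = FALSE], s$lp, 2, 3),
               "empty neighborhood")
})

test_that("aggregation reduces to identity on isolated self-loops", {
  n <- 4
  H <- withr::with_seed(2, matrix(rnorm(n * 3), n, 3))
  arcs <- cbind(src = 1:n, dst = 1:n)
  lp <- list(W_v = diag(3), b_v = numeric(3))
  al <- matrix(1, n, 1)
  m <- aggregate_messages(H, arcs, al, lp, 1, 3)
  expect_equal(m, H, tolerance = 1e-12)
})

test_that("uniform attention over identical values returns that value", {
  s <- tiny_setup(n = 6, p_edge = 1)
  H <- matrix(rep(s$H[1, ], each = 6), 6)
  al <- attention_scores(H, s$arcs, s$lp, 2, 3)
  m <- aggregate_messages(H, s$arcs, al, s$lp, 2, 3)
  v1 <- (H %*% s$lp$W_v + matrix(s$lp$b_v, 6, 6, byrow = TRUE))[1, ]
  expect_equal(unname(m[1, ]), unname(v1), tolerance = 1e-10)
})

test_that("aggregation matches the per-node loop oracle", {
  for (seed in 4:6) {
    s <- tiny_setup(n = 7, seed = seed)
    al <- attention_scores(s$H, s$arcs, s$lp, 2, 3)
    for (combine in c("concat", "mean")) {
      expect_equal(
        aggregate_messages(s$H, s$arcs, al, s$lp, 2, 3, combine),
        loop_aggregate_oracle(s$H, s$arcs, al, s$lp, 2, 3, combine),
        tolerance = 1e-6)
    }
  }
})

test_that("the gate interpolates between residual and message", {
  withr::with_seed(9, {
    n <- 10; d_in <- 4; out <- 3
    h <- matrix(rnorm(n * d_in), n)
    m <- matrix(rnorm(n * out), n)
    W_r <- matrix(rnorm(d_in * out), d_in)
    w_g <- rnorm(3 * out)
    r <- h %*% W_r
    # saturated gates hit the endpoints
    expect_equal(gated_residual(h, m, W_r, w_g * 0, 1e4)$h, r)
    expect_equal(gated_residual(h, m, W_r, w_g * 0, -1e4)$h, m)
    # in between, every coordinate stays inside the segment [m, r]
    gr <- gated_residual(h, m, W_r, w_g, 0.3)
    expect_true(all(gr$h >= pmin(m, r) - 1e-12))
    expect_true(all(gr$h <= pmax(m, r) + 1e-12))
    expect_true(all(gr$beta > 0 & gr$beta < 1))
  })
})

test_that("an all-zero network outputs the classifier bias everywhere", {
  s <- tiny_setup(n = 6, C = 1, d = 3)
  params <- rapply(s$params, function(x) x * 0, how = "replace")
  params$head$b_out <- c(0.3, -0.2)
  cfg <- gtn_config(n_layers = 1, n_heads = 1, head_dim = 3, dropout = 0)
  logits <- gtn_forward(s$H, s$arcs, params, cfg)
  expect_equal(unname(logits), matrix(c(0.3, -0.2), 6, 2, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("forward is equivariant under node permutation", {
  s <- tiny_setup(n = 8, seed = 11)
  cfg <- gtn_config(n_layers = 2, n_heads = 2, head_dim = 3, dropout = 0)
  params <- gtn_init_params(4, cfg, seed = 2)
  logits <- gtn_forward(s$H, s$arcs, params, cfg)
  perm <- withr::with_seed(1, sample(8))
  inv <- order(perm)
  arcs_p <- cbind(inv[s$arcs[, 1]], inv[s$arcs[, 2]])
  logits_p <- gtn_forward(s$H[perm, ], arcs_p, params, cfg)
  expect_equal(logits_p, logits[perm, ], tolerance = 1e-10)
})

test_that("an isolated node's logits depend only on its own features", {
  s <- tiny_setup(n = 6, seed = 13)
  arcs <- rbind(s$arcs[s$arcs[, 1] != 1 & s$arcs[, 2] != 1, , drop = FALSE],
                c(1, 1))
  cfg <- gtn_config(n_layers = 2, n_heads = 2, head_dim = 3, dropout = 0)
  params <- gtn_init_params(4, cfg, seed = 5)
  l1 <- gtn_forward(s$H, arcs, params, cfg)
  H2 <- s$H
  H2[-1, ] <- H2[-1, ] + 1.5   # perturb everyone else
  l2 <- gtn_forward(H2, arcs, params, cfg)
  expect_equal(l1[1, ], l2[1, ], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(l1[2, ], l2[2, ])))
})

test_that("forward is deterministic without dropout", {
  s <- tiny_setup(n = 8, seed = 17)
  expect_identical(gtn_forward(s$H, s$arcs, s$params, s$cfg),
                   gtn_forward(s$H, s$arcs, s$params, s$cfg))
})

test_that("softmax scores follow the two-logit formula", {
  expect_equal(predict_scores(matrix(c(0, 0), 1)), 0.5)
  expect_gt(predict_scores(matrix(c(-10, 10), 1)), 0.999)
  z <- withr::with_seed(3, matrix(rnorm(40), 20, 2))
  expect_equal(predict_scores(z),
               exp(z[, 2]) / (exp(z[, 1]) + exp(z[, 2])),
               tolerance = 1e-12)
  expect_error(predict_scores(matrix(c(Inf, 0), 1)), "finite")
})

test_that("analytic gradients match central finite differences", {
  g <- with_toy_split(toy_line_graph(n_pairs = 18, seed = 21))
  idx <- which(g$nodes$split == "train")
  arcs <- to_directed_arcs(g)
  configs <- list(
    gtn_config(n_layers = 2, n_heads = 2, head_dim = 3, dropout = 0),
    gtn_config(n_layers = 1, n_heads = 3, head_dim = 2, dropout = 0),
    gtn_config(n_layers = 2, n_heads = 2, head_dim = 3, dropout = 0,
               use_gated_residual = FALSE)
  )
  for (cfg in configs) {
    params <- gtn_init_params(ncol(g$features), cfg, seed = 31)
    lg <- dtiline:::gtn_loss_grad(g$features, arcs, params, cfg,
                                  g$labels, idx)
    loss_at <- function(p) {
      dtiline:::gtn_loss_grad(g$features, arcs, p, cfg, g$labels, idx)$loss
    }
    for (l in seq_len(cfg$n_layers)) {
      for (key in c("W_q", "W_k", "W_v", "W_r", "w_g", "b_q", "b_v")) {
        if (!cfg$use_gated_residual && key %in% c("W_r", "w_g")) next
        i <- 2L
        eps <- 1e-5
        up <- params; up$layers[[l]][[key]][i] <- up$layers[[l]][[key]][i] + eps
        dn <- params; dn$layers[[l]][[key]][i] <- dn$layers[[l]][[key]][i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        ana <- lg$grads$layers[[l]][[key]][i]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = sprintf("layer %d %s", l, key))
      }
    }
    up <- params; up$head$W_out[1] <- up$head$W_out[1] + 1e-5
    dn <- params; dn$head$W_out[1] <- dn$head$W_out[1] - 1e-5
    expect_equal(lg$grads$head$W_out[1],
                 (loss_at(up) - loss_at(dn)) / 2e-5, tolerance = 1e-4)
  }
})

test_that("a gate-free single layer is exactly attention plus aggregation", {
  s <- tiny_setup(n = 7, seed = 23)
  cfg <- gtn_config(n_layers = 1, n_heads = 2, head_dim = 3, dropout = 0,
                    use_gated_residual = FALSE)
  params <- gtn_init_params(4, cfg, seed = 8)
  lp <- params$layers[[1]]
  logits <- gtn_forward(s$H, s$arcs, params, cfg)
  al <- attention_scores(s$H, s$arcs, lp, 2, 3)
  M <- aggregate_messages(s$H, s$arcs, al, lp, 2, 3, combine = "mean")
  manual <- M %*% params$head$W_out +
    matrix(params$head$b_out, 7, 2, byrow = TRUE)
  expect_equal(logits, manual, tolerance = 1e-10)
})

test_that("non-finite activations name the offending layer", {
  s <- tiny_setup(n = 5, seed = 25)
  params <- s$params
  params$layers[[1]]$W_v[1, 1] <- Inf
  expect_error(gtn_forward(s$H, s$arcs, params, s$cfg), "layer 1")
})
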