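# Independent reference implementations used to check the package's
# vectorised/compiled code paths. Deliberately naive: sets, loops and
# dense linear algebra only.

# Jaccard of binary rows via explicit set operations.
jaccard_set_oracle <- function(A) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- which(A[i, ] == 1)
      b <- which(A[j, ] == 1)
      u <- length(union(a, b))
      S[i, j] <- if (i == j) 1 else if (u == 0) 0 else length(intersect(a, b)) / u
    }
  }
  S
}

# Closed-form restart random walk: S = p (I - (1-p) B)^{-1}.
rwr_closed_form <- function(B, p) {
  n <- nrow(B)
  p * solve(diag(n) - (1 - p) * B)
}

# AUROC as the average pairwise comparison of positive vs negative scores.
auroc_pairwise_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# AUPR by exhaustive enumeration of score thresholds.
aupr_threshold_oracle <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  area <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    r <- tp / sum(labels == 1)
    p <- tp / (tp + fp)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# O(n^2) scan for line-graph edges: pairs share a drug or a protein.
edge_scan_oracle <- function(pairs) {
  n <- nrow(pairs)
  out <- list()
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (pairs$drug_id[u] == pairs$drug_id[v] ||
          pairs$protein_id[u] == pairs$protein_id[v]) {
        out[[length(out) + 1]] <- c(u, v)
      }
    }
  }
  if (length(out) == 0) matrix(integer(), 0, 2) else do.call(rbind, out)
}

# Dense masked-softmax attention: full n x n score matrix per head,
# exponentiated, masked to the neighborhood, row-normalised.
dense_attention_oracle <- function(H, arcs, lp, C, d) {
  n <- nrow(H)
  Q <- H %*% lp$W_q + matrix(lp$b_q, n, C * d, byrow = TRUE)
  K <- H %*% lp$W_k + matrix(lp$b_k, n, C * d, byrow = TRUE)
  alpha <- matrix(0, nrow(arcs), C)
  for (c in seq_len(C)) {
    cols <- ((c - 1) * d + 1):(c * d)
    S <- exp(tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(d))
    mask <- matrix(FALSE, n, n)
    mask[arcs[, c(2, 1), drop = FALSE]] <- TRUE   # [dst, src]
    S[!mask] <- 0
    W <- S / rowSums(S)
    alpha[, c] <- W[arcs[, c(2, 1), drop = FALSE]]
  }
  alpha
}

# Per-node loop aggregation of value messages.
loop_aggregate_oracle <- function(H, arcs, alpha, lp, C, d,
                                  combine = "concat") {
  n <- nrow(H)
  V <- H %*% lp$W_v + matrix(lp$b_v, n, C * d, byrow = TRUE)
  M <- matrix(0, n, C * d)
  for (a in seq_len(nrow(arcs))) {
    j <- arcs[a, 1]; i <- arcs[a, 2]
    for (c in seq_len(C)) {
      cols <- ((c - 1) * d + 1):(c * d)
      M[i, cols] <- M[i, cols] + alpha[a, c] * V[j, cols]
    }
  }
  if (combine == "concat") return(M)
  out <- matrix(0, n, d)
  for (c in seq_len(C)) out <- out + M[, ((c - 1) * d + 1):(c * d)]
  out / C
}

# Small random line graph with separable or noisy features, for model and
# training tests.
toy_line_graph <- function(n_drugs = 6, n_proteins = 8, n_pairs = 30,
                           d_feat = 5, separable = FALSE, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(drug_id = paste0("d:", seq_len(n_drugs)),
                        protein_id = paste0("p:", seq_len(n_proteins)),
                        stringsAsFactors = FALSE)
    pick <- sample(nrow(grid), n_pairs)
    pairs <- tibble::tibble(drug_id = grid$drug_id[pick],
                            protein_id = grid$protein_id[pick],
                            label = rbinom(n_pairs, 1, 0.5))
    if (sum(pairs$label) < 2) pairs$label[1:2] <- 1L
    if (sum(1 - pairs$label) < 2) pairs$label[3:4] <- 0L
    dfe <- matrix(rnorm(n_drugs * d_feat), n_drugs,
                  dimnames = list(paste0("d:", seq_len(n_drugs)), NULL))
    pfe <- matrix(rnorm(n_proteins * d_feat), n_proteins,
                  dimnames = list(paste0("p:", seq_len(n_proteins)), NULL))
    g <- build_line_graph(pairs, dfe, pfe)
    if (separable) {
      g$features[, 1] <- g$labels + 0.05 * rnorm(nrow(g$features))
    }
    g
  })
}

# Attach a split column to a toy graph ensuring each class in each split.
with_toy_split <- function(g, seed = 1) {
  pairs <- g$nodes
  pairs <- split_candidates(pairs, c(0.6, 0.2, 0.2), seed = seed)
  g$nodes$split <- pairs$split
  g
}

# Central finite-difference derivative of f at one parameter entry.
numeric_grad_entry <- function(f, params, path, i, eps = 1e-5) {
  pp <- params
  pp[[path]][i] <- pp[[path]][i] + eps
  up <- f(pp)
  pp[[path]][i] <- pp[[path]][i] - 2 * eps
  dn <- f(pp)
  (up - dn) / (2 * eps)
}
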