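#' Jaccard similarity projection of a binary association matrix
#'
#' Treats each row as the set of attribute indices it is associated with
#' and returns the pairwise Jaccard coefficient
#' \eqn{Sim(A, B) = |A \cap B| / |A \cup B|}. Two empty profiles get
#' similarity 0 off the diagonal; the diagonal is 1 by convention.
#'
#' @param assoc Binary matrix (entities in rows, attributes in columns),
#'   ideally with row names.
#' @return Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @examples
#' a <- rbind(x = c(1, 1, 0), y = c(1, 0, 1))
#' jaccard_similarity(a)  # off-diagonal 1/3
#' @export
jaccard_similarity <- function(assoc) {
  assert_binary_matrix(assoc, "assoc")
  inter <- tcrossprod(assoc)
  sizes <- rowSums(assoc)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  diag(sim) <- 1
  if (!is.null(rownames(assoc))) dimnames(sim) <- list(rownames(assoc), rownames(assoc))
  sim
}

#' Row-normalised transition matrix of a similarity network
#'
#' `B[i, j] = A[i, j] / sum_j A[i, j]`. An all-zero row (an entity with no
#' similarity mass) becomes a self-transition row, keeping the matrix
#' row-stochastic without redistributing mass to other entities.
#'
#' @param sim Non-negative square matrix.
#' @return Row-stochastic matrix of the same shape.
#' @export
transition_matrix <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) {
    abort("`sim` must be a square matrix")
  }
  if (any(sim < 0)) {
    bad <- which(sim < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("`sim` has a negative entry at row %d, col %d", bad[1], bad[2]))
  }
  rs <- rowSums(sim)
  B <- sim / ifelse(rs > 0, rs, 1)
  zero <- which(rs == 0)
  if (length(zero) > 0) B[cbind(zero, zero)] <- 1
  B
}

#' Random walk with restart diffusion states
#'
#' Iterates all start distributions jointly:
#' \deqn{S^{t+1} = (1 - p_r) S^t B + p_r E}
#' with `E = I` (row *i* restarts to entity *i*) and `S^0 = I`, stopping
#' after `n_iter` iterations or when the maximum absolute change drops
#' below `tol`. Row *i* of the result is the visiting distribution of a
#' restarting walk started at entity *i*.
#'
#' @param B Row-stochastic transition matrix.
#' @param restart Restart probability \eqn{p_r \in (0, 1]}; default 0.5.
#' @param n_iter Maximum number of iterations; default 20.
#' @param tol Early-stopping tolerance on the max-abs update; default 1e-10.
#' @return Row-stochastic diffusion-state matrix.
#' @export
rwr_diffusion <- function(B, restart = 0.5, n_iter = 20, tol = 1e-10) {
  if (!is.matrix(B) || nrow(B) != ncol(B)) abort("`B` must be square")
  if (!is.numeric(restart) || length(restart) != 1 || restart <= 0 || restart > 1) {
    abort("`restart` must lie in (0, 1]; a walk without restart has no stationary start-specific state")
  }
  n_iter <- assert_count(n_iter, "n_iter")
  if (tol < 0) abort("`tol` must be >= 0")
  if (max(abs(rowSums(B) - 1)) > 1e-6) abort("`B` must be row-stochastic")
  n <- nrow(B)
  E <- diag(n)
  S <- E
  for (t in seq_len(n_iter)) {
    S_new <- (1 - restart) * (S %*% B) + restart * E
    delta <- max(abs(S_new - S))
    S <- S_new
    if (delta < tol) break
  }
  dimnames(S) <- dimnames(B)
  S
}

#' Concatenate diffusion states into one entity feature matrix
#'
#' Stitches the diffusion-state matrices of several networks over the same
#' entities into one wide feature matrix (width `n_entities * n_networks`),
#' preserving network order in named column blocks.
#'
#' @param states Named list of square diffusion-state matrices sharing the
#'   same row-id ordering.
#' @return Matrix with a `"blocks"` attribute (tibble of `network`,
#'   `start`, `end` column offsets).
#' @export
assemble_entity_features <- function(states) {
  stopifnot(is.list(states), length(states) >= 1)
  if (is.null(names(states)) || any(names(states) == "")) {
    names(states) <- paste0("network", seq_along(states))
  }
  ids <- rownames(states[[1]])
  for (nm in names(states)) {
    s <- states[[nm]]
    if (!is.matrix(s) || nrow(s) != nrow(states[[1]])) {
      abort(sprintf("diffusion state '%s' has mismatched dimensions", nm))
    }
    if (!identical(rownames(s), ids)) {
      abort(sprintf("diffusion state '%s' has a different entity id ordering", nm))
    }
  }
  X <- do.call(cbind, states)
  rownames(X) <- ids
  widths <- vapply(states, ncol, integer(1))
  ends <- cumsum(widths)
  attr(X, "blocks") <- tibble::tibble(
    network = names(states),
    start = ends - widths + 1L,
    end = ends
  )
  X
}

#' The homogeneous similarity networks of a heterogeneous network
#'
#' Drug side: Jaccard projections of the drug-drug interaction,
#' drug-disease and drug-side-effect matrices plus the chemical similarity
#' matrix used directly as weighted adjacency (four networks). Protein
#' side: Jaccard projections of protein-protein interaction and
#' protein-disease matrices plus the sequence similarity matrix (three
#' networks).
#'
#' @param net A `synth_hetnet` (simulated or read from disk).
#' @return List with named elements `drug` (4 matrices) and `protein`
#'   (3 matrices).
#' @export
hetnet_similarity_networks <- function(net) {
  stopifnot(inherits(net, "synth_hetnet"))
  list(
    drug = list(
      drug_interaction = jaccard_similarity(net$edges$drug_drug),
      drug_disease = jaccard_similarity(net$edges$drug_disease),
      drug_side_effect = jaccard_similarity(net$edges$drug_se),
      drug_chemical = net$sim$drug_chemical
    ),
    protein = list(
      protein_interaction = jaccard_similarity(net$edges$protein_protein),
      protein_disease = jaccard_similarity(net$edges$protein_disease),
      protein_sequence = net$sim$protein_sequence
    )
  )
}

#' Diffusion feature matrices for drugs and proteins
#'
#' Runs restart random walks on every homogeneous drug and protein network
#' of `net` and assembles the per-entity diffusion states into the two
#' wide feature matrices (width `4 * n_drugs` and `3 * n_proteins`).
#'
#' @inheritParams rwr_diffusion
#' @param net A `synth_hetnet`.
#' @return List with elements `drug` and `protein`, each as returned by
#'   [assemble_entity_features()].
#' @export
diffusion_features <- function(net, restart = 0.5, n_iter = 20, tol = 1e-10) {
  nets <- hetnet_similarity_networks(net)
  diffuse_all <- function(sims) {
    lapply(sims, function(s) {
      rwr_diffusion(transition_matrix(s), restart = restart,
                    n_iter = n_iter, tol = tol)
    })
  }
  list(
    drug = assemble_entity_features(diffuse_all(nets$drug)),
    protein = assemble_entity_features(diffuse_all(nets$protein))
  )
}
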