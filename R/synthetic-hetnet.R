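#' Configuration for the synthetic heterogeneous network simulator
#'
#' The simulator plants a low-dimensional latent interaction structure:
#' drugs and proteins carry non-negative latent factor vectors, a
#' drug-protein interaction is drawn from a logistic model on the latent
#' dot product, and disease / side-effect association profiles are drawn
#' from the same latent space so that similar entities share associations
#' (which is what makes Jaccard projections informative downstream).
#'
#' @param n_drugs,n_proteins,n_diseases,n_side_effects Entity counts (>= 1).
#' @param latent_dim Dimension of the planted latent factors.
#' @param positive_rate Expected density of the drug-protein interaction
#'   matrix; the logistic intercept is calibrated by bisection so the
#'   expected positive count is `positive_rate * n_drugs * n_proteins`.
#' @param assoc_density Expected density of each association edge type
#'   (drug-drug, drug-disease, drug-side-effect, protein-disease,
#'   protein-protein).
#' @param noise Label noise in `[0, 0.5)`. Applied as class-balanced flips:
#'   a true interaction is dropped with probability `noise` and a
#'   non-interaction is spuriously added with probability
#'   `noise * rate / (1 - rate)`, preserving the expected density while
#'   mislabelling about `noise` of each class. The same `noise` perturbs
#'   the weighted similarity matrices.
#' @param signal Logistic scale on the latent dot products; controls how
#'   separable planted positives are from negatives. The default of 20
#'   gives a latent-oracle AUROC around 0.95 at the default sizes.
#' @param seed Integer seed; equal seeds and configs give byte-identical
#'   networks.
#'
#' @return An object of class `synth_config` (a named list).
#' @seealso [simulate_hetnet()]
#' @export
synth_config <- function(n_drugs = 120, n_proteins = 180, n_diseases = 60,
                         n_side_effects = 40, latent_dim = 8,
                         positive_rate = 800 / (120 * 180),
                         assoc_density = 0.15, noise = 0.05,
                         signal = 20, seed = 1) {
  cfg <- list(
    n_drugs = assert_count(n_drugs, "n_drugs"),
    n_proteins = assert_count(n_proteins, "n_proteins"),
    n_diseases = assert_count(n_diseases, "n_diseases"),
    n_side_effects = assert_count(n_side_effects, "n_side_effects"),
    latent_dim = assert_count(latent_dim, "latent_dim"),
    positive_rate = assert_prob(positive_rate, "positive_rate"),
    assoc_density = assert_prob(assoc_density, "assoc_density"),
    noise = assert_prob(noise, "noise", lo = 0, hi = 0.5, hi_open = TRUE),
    signal = assert_prob(signal, "signal", lo = 0, hi = Inf, lo_open = TRUE),
    seed = assert_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "synth_config")
}

entity_ids <- function(prefix, n) paste0(prefix, seq_len(n))

half_normal_factors <- function(n, k) {
  matrix(abs(rnorm(n * k)), n, k) / sqrt(k)
}

cosine_similarity <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(U / nrm)
  S[S > 1] <- 1
  S[S < -1] <- -1
  S
}

# Symmetric binary adjacency with expected off-diagonal density `density`,
# edge probability increasing in latent cosine similarity.
draw_latent_adjacency <- function(U, density, signal, ids) {
  n <- nrow(U)
  S <- cosine_similarity(U)
  eta <- signal * S[upper.tri(S)]
  b <- calibrate_intercept(eta, density)
  p <- plogis(eta + b)
  e <- rbinom(length(p), 1, p)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  A[upper.tri(A)] <- e
  A + t(A)
}

# Bipartite binary association with expected density `density`, drawn from a
# logistic model on affinities between entity factors and attribute anchors.
draw_latent_association <- function(U, n_attr, density, signal,
                                    row_ids, col_prefix) {
  W <- half_normal_factors(n_attr, ncol(U))
  eta <- signal * tcrossprod(U, W)
  b <- calibrate_intercept(as.vector(eta), density)
  A <- matrix(rbinom(length(eta), 1, plogis(eta + b)), nrow(U), n_attr,
              dimnames = list(row_ids, entity_ids(col_prefix, n_attr)))
  A
}

# Noisy monotone transform of latent cosine similarity: symmetric, [0,1],
# unit diagonal.
noisy_similarity <- function(U, noise, ids) {
  S <- cosine_similarity(U)
  n <- nrow(S)
  eps <- matrix(runif(n * n, -noise, noise), n, n)
  eps <- (eps + t(eps)) / 2
  S <- S + eps
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

#' Simulate a heterogeneous drug/protein/disease/side-effect network
#'
#' Generates the six binary edge sets (drug-protein, drug-drug,
#' drug-disease, drug-side-effect, protein-disease, protein-protein), the
#' two weighted similarity matrices (drug chemical, protein sequence) and
#' the ground-truth interaction propensity matrix, all driven by planted
#' latent factors. Node identifiers carry type prefixes (`d:`, `p:`,
#' `dis:`, `se:`).
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_hetnet`: a list with elements
#'   `drug_ids`, `protein_ids`, `disease_ids`, `se_ids`, `edges` (named
#'   list of six binary matrices), `sim` (named list `drug_chemical`,
#'   `protein_sequence`), `propensity` (latent dot products), `latent`
#'   (the planted factors) and `config`.
#' @examples
#' net <- simulate_hetnet(synth_config(n_drugs = 20, n_proteins = 30, seed = 7))
#' sum(net$edges$drug_protein)
#' @export
simulate_hetnet <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nd <- config$n_drugs; np <- config$n_proteins
  expected_pos <- config$positive_rate * nd * np
  if (expected_pos < 1) {
    abort(sprintf(paste0(
      "expected positive count %.3f < 1: positive_rate = %g is too small ",
      "for n_drugs = %d, n_proteins = %d"),
      expected_pos, config$positive_rate, nd, np))
  }
  with_local_seed(config$seed, {
    d_ids <- entity_ids("d:", nd)
    p_ids <- entity_ids("p:", np)
    U <- half_normal_factors(nd, config$latent_dim)
    V <- half_normal_factors(np, config$latent_dim)
    rownames(U) <- d_ids; rownames(V) <- p_ids

    propensity <- tcrossprod(U, V)
    dimnames(propensity) <- list(d_ids, p_ids)
    eta <- config$signal * propensity
    b <- calibrate_intercept(as.vector(eta), config$positive_rate)
    P <- plogis(eta + b)
    Y <- matrix(rbinom(length(P), 1, P), nd, np, dimnames = dimnames(P))
    if (config$noise > 0) {
      rho <- mean(P)
      drop_mask <- matrix(rbinom(length(P), 1, config$noise), nd, np)
      add_mask <- matrix(rbinom(length(P), 1, config$noise * rho / (1 - rho)), nd, np)
      Y <- ifelse(Y == 1, 1L - drop_mask, add_mask)
      dimnames(Y) <- dimnames(P)
    }
    if (sum(Y) == 0) {
      abort(sprintf(paste0(
        "simulated drug-protein edge set is empty (positive_rate = %g, ",
        "n_drugs = %d, n_proteins = %d); increase positive_rate or sizes"),
        config$positive_rate, nd, np))
    }

    edges <- list(
      drug_protein = Y,
      drug_drug = draw_latent_adjacency(U, config$assoc_density, config$signal, d_ids),
      drug_disease = draw_latent_association(U, config$n_diseases,
                                             config$assoc_density, config$signal,
                                             d_ids, "dis:"),
      drug_se = draw_latent_association(U, config$n_side_effects,
                                        config$assoc_density, config$signal,
                                        d_ids, "se:"),
      protein_disease = draw_latent_association(V, config$n_diseases,
                                                config$assoc_density, config$signal,
                                                p_ids, "dis:"),
      protein_protein = draw_latent_adjacency(V, config$assoc_density,
                                              config$signal, p_ids)
    )
    sim <- list(
      drug_chemical = noisy_similarity(U, config$noise, d_ids),
      protein_sequence = noisy_similarity(V, config$noise, p_ids)
    )

    structure(list(
      drug_ids = d_ids, protein_ids = p_ids,
      disease_ids = entity_ids("dis:", config$n_diseases),
      se_ids = entity_ids("se:", config$n_side_effects),
      edges = edges, sim = sim,
      propensity = propensity,
      latent = list(drug = U, protein = V),
      config = config
    ), class = "synth_hetnet")
  })
}

#' @export
print.synth_hetnet <- function(x, ...) {
  cat(sprintf(
    "<synth_hetnet> %d drugs, %d proteins, %d diseases, %d side effects\n",
    length(x$drug_ids), length(x$protein_ids),
    length(x$disease_ids), length(x$se_ids)))
  cat(sprintf("  drug-protein interactions: %d (density %.4f)\n",
              sum(x$edges$drug_protein), mean(x$edges$drug_protein)))
  invisible(x)
}

#' Ground-truth interaction labels for candidate pairs
#'
#' @param net A `synth_hetnet`.
#' @param pairs A data frame with columns `drug_id` and `protein_id`.
#' @return Integer vector: 1 if the pair is in the drug-protein edge set,
#'   0 otherwise.
#' @export
ground_truth_labels <- function(net, pairs) {
  stopifnot(inherits(net, "synth_hetnet"),
            all(c("drug_id", "protein_id") %in% names(pairs)))
  di <- match(pairs$drug_id, net$drug_ids)
  pi_ <- match(pairs$protein_id, net$protein_ids)
  if (anyNA(di)) {
    abort(sprintf("unknown drug id: %s", pairs$drug_id[which(is.na(di))[1]]))
  }
  if (anyNA(pi_)) {
    abort(sprintf("unknown protein id: %s", pairs$protein_id[which(is.na(pi_))[1]]))
  }
  as.integer(net$edges$drug_protein[cbind(di, pi_)])
}

#' All known interactions of a network as a candidate-pair tibble
#'
#' @param net A `synth_hetnet`.
#' @return A tibble with columns `drug_id`, `protein_id`, `label` (all 1).
#' @export
positive_pairs <- function(net) {
  stopifnot(inherits(net, "synth_hetnet"))
  idx <- which(net$edges$drug_protein == 1, arr.ind = TRUE)
  tibble::tibble(
    drug_id = net$drug_ids[idx[, 1]],
    protein_id = net$protein_ids[idx[, 2]],
    label = 1L
  )
}
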