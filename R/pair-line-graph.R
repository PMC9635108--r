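#' Sample non-interacting drug-protein pairs as negatives
#'
#' Draws `n` (drug, protein) combinations uniformly without replacement
#' from the complement of the positive set, matching the 1:1
#' negative-sampling protocol used for training when
#' `n = nrow(positives)`.
#'
#' @param positives Data frame with columns `drug_id`, `protein_id`.
#' @param drug_ids,protein_ids The full id universes.
#' @param n Number of negatives to draw.
#' @param seed Integer seed; sampling is reproducible.
#' @return Tibble with columns `drug_id`, `protein_id`, `label` (all 0).
#' @export
sample_negatives <- function(positives, drug_ids, protein_ids, n, seed = 1) {
  n <- assert_count(n, "n", min = 0L)
  nd <- length(drug_ids); np <- length(protein_ids)
  di <- match(positives$drug_id, drug_ids)
  pi_ <- match(positives$protein_id, protein_ids)
  if (anyNA(di) || anyNA(pi_)) abort("positives reference unknown drug or protein ids")
  pos_lin <- (pi_ - 1) * nd + di
  if (anyDuplicated(pos_lin)) abort("positive pairs must be unique")
  n_free <- nd * np - length(pos_lin)
  if (n > n_free) {
    abort(sprintf("cannot sample %d negatives: only %d non-positive pairs exist", n, n_free))
  }
  if (n == 0) {
    return(tibble::tibble(drug_id = character(), protein_id = character(),
                          label = integer()))
  }
  with_local_seed(seed, {
    free <- setdiff(seq_len(nd * np), pos_lin)
    lin <- free[sample.int(length(free), n)]
    tibble::tibble(
      drug_id = drug_ids[(lin - 1) %% nd + 1],
      protein_id = protein_ids[(lin - 1) %/% nd + 1],
      label = 0L
    )
  })
}

#' Assemble candidate pairs: known positives plus sampled negatives
#'
#' @param net A `synth_hetnet`.
#' @param neg_ratio Negatives per positive (default 1, the standard
#'   balanced protocol).
#' @param seed Seed for negative sampling.
#' @return Tibble of candidate pairs with `drug_id`, `protein_id`, `label`.
#' @export
candidate_pairs <- function(net, neg_ratio = 1, seed = 1) {
  pos <- positive_pairs(net)
  neg <- sample_negatives(pos, net$drug_ids, net$protein_ids,
                          n = round(neg_ratio * nrow(pos)), seed = seed)
  dplyr::bind_rows(pos, neg)
}

#' Build the drug-protein pair line graph
#'
#' Candidate pairs become nodes; an undirected edge joins two pairs iff
#' they share a drug or share a protein (two distinct pairs can never
#' share both). Node features are the concatenation of the pair's drug
#' feature row and protein feature row.
#'
#' @param pairs Data frame of candidate pairs (`drug_id`, `protein_id`,
#'   `label`), unique.
#' @param drug_feats,protein_feats Feature matrices with row names
#'   covering every referenced id.
#' @return An object of class `pair_line_graph`: list with `nodes`
#'   (tibble: `node`, `drug_id`, `protein_id`, `label`), `edges`
#'   (two-column integer matrix `u`, `v` with `u < v`), `features`
#'   (`n_nodes` x `(d_drug + d_protein)`) and `labels`.
#' @examples
#' feats <- diag(2); rownames(feats) <- c("d:1", "d:2")
#' pfeats <- diag(2); rownames(pfeats) <- c("p:1", "p:2")
#' pairs <- tibble::tibble(drug_id = c("d:1", "d:1"),
#'                         protein_id = c("p:1", "p:2"), label = c(1L, 0L))
#' build_line_graph(pairs, feats, pfeats)$edges  # one edge: shared drug
#' @export
build_line_graph <- function(pairs, drug_feats, protein_feats) {
  stopifnot(all(c("drug_id", "protein_id", "label") %in% names(pairs)))
  n <- nrow(pairs)
  if (anyDuplicated(pairs[, c("drug_id", "protein_id")])) {
    abort("candidate pairs must be unique")
  }
  miss_d <- setdiff(unique(pairs$drug_id), rownames(drug_feats))
  if (length(miss_d) > 0) {
    abort(sprintf("no drug feature row for id: %s", miss_d[1]))
  }
  miss_p <- setdiff(unique(pairs$protein_id), rownames(protein_feats))
  if (length(miss_p) > 0) {
    abort(sprintf("no protein feature row for id: %s", miss_p[1]))
  }
  # all-pairs within each shared-entity group
  group_edges <- function(key) {
    idx <- split(seq_len(n), key)
    idx <- idx[lengths(idx) >= 2]
    if (length(idx) == 0) return(matrix(integer(), 0, 2))
    do.call(rbind, lapply(idx, function(ii) t(utils::combn(sort(ii), 2))))
  }
  edges <- rbind(group_edges(pairs$drug_id), group_edges(pairs$protein_id))
  if (nrow(edges) > 0) {
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("u", "v")
  rownames(edges) <- NULL
  features <- cbind(
    drug_feats[pairs$drug_id, , drop = FALSE],
    protein_feats[pairs$protein_id, , drop = FALSE]
  )
  rownames(features) <- paste(pairs$drug_id, pairs$protein_id, sep = "|")
  structure(list(
    nodes = tibble::tibble(node = seq_len(n),
                           drug_id = pairs$drug_id,
                           protein_id = pairs$protein_id,
                           label = as.integer(pairs$label)),
    edges = edges,
    features = features,
    labels = as.integer(pairs$label),
    d_drug = ncol(drug_feats),
    d_protein = ncol(protein_feats)
  ), class = "pair_line_graph")
}

#' @export
print.pair_line_graph <- function(x, ...) {
  cat(sprintf("<pair_line_graph> %d pair nodes (%d positive), %d edges, %d features\n",
              nrow(x$nodes), sum(x$labels), nrow(x$edges), ncol(x$features)))
  invisible(x)
}

#' Expand an undirected line graph into directed arcs
#'
#' Each undirected edge becomes two arcs (j to i and i to j); with
#' `add_self_loops` one self-arc per node is appended so every node has a
#' non-empty attention neighborhood.
#'
#' @param g A `pair_line_graph`.
#' @param add_self_loops Append one self-arc per node (default `TRUE`).
#' @return Two-column integer matrix with columns `src`, `dst`.
#' @export
to_directed_arcs <- function(g, add_self_loops = TRUE) {
  stopifnot(inherits(g, "pair_line_graph"))
  n <- nrow(g$nodes)
  e <- g$edges
  arcs <- rbind(
    cbind(src = e[, 1], dst = e[, 2]),
    cbind(src = e[, 2], dst = e[, 1])
  )
  if (add_self_loops) {
    arcs <- rbind(arcs, cbind(src = seq_len(n), dst = seq_len(n)))
  }
  arcs <- arcs[order(arcs[, 2], arcs[, 1]), , drop = FALSE]
  rownames(arcs) <- NULL
  arcs
}

#' Serialize / restore a pair line graph as TSV
#'
#' Writes `linegraph_nodes.tsv` (`pair_id`, `drug_id`, `protein_id`,
#' `label`, and `split` if present) and `linegraph_edges.tsv` (`u`, `v`)
#' plus the node feature matrix.
#'
#' @param g A `pair_line_graph`.
#' @param dir Output directory.
#' @export
write_line_graph <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- as.data.frame(g$nodes)
  nodes$pair_id <- rownames(g$features)
  cols <- c("pair_id", "drug_id", "protein_id", "label",
            intersect("split", names(nodes)))
  write.table(nodes[, cols], file.path(dir, "linegraph_nodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(g$edges), file.path(dir, "linegraph_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  feats <- g$features
  colnames(feats) <- c(paste0("drug_f", seq_len(g$d_drug)),
                       paste0("protein_f", seq_len(g$d_protein)))
  write_matrix_tsv(feats, file.path(dir, "linegraph_features.tsv"))
  invisible(dir)
}

#' @rdname write_line_graph
#' @export
read_line_graph <- function(dir) {
  nodes <- read.delim(file.path(dir, "linegraph_nodes.tsv"),
                      stringsAsFactors = FALSE)
  edges <- as.matrix(read.delim(file.path(dir, "linegraph_edges.tsv")))
  storage.mode(edges) <- "integer"
  feats <- read_matrix_tsv(file.path(dir, "linegraph_features.tsv"))
  d_drug <- sum(startsWith(colnames(feats), "drug_f"))
  nd <- tibble::tibble(node = seq_len(nrow(nodes)),
                       drug_id = nodes$drug_id,
                       protein_id = nodes$protein_id,
                       label = as.integer(nodes$label))
  if ("split" %in% names(nodes)) nd$split <- nodes$split
  rownames(feats) <- nodes$pair_id
  structure(list(
    nodes = nd, edges = edges, features = feats,
    labels = as.integer(nodes$label),
    d_drug = d_drug, d_protein = ncol(feats) - d_drug
  ), class = "pair_line_graph")
}
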