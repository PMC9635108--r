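test_that("negative sampling respects size, disjointness and determinism", {
  d_ids <- paste0("d:", 1:6); p_ids <- paste0("p:", 1:8)
  pos <- tibble::tibble(drug_id = c("d:1", "d:2", "d:3"),
                        protein_id = c("p:1", "p:2", "p:3"), label = 1L)
  expect_identical(nrow(sample_negatives(pos, d_ids, p_ids, 0)), 0L)
  neg <- sample_negatives(pos, d_ids, p_ids, n = nrow(pos), seed = 5)
  expect_identical(nrow(neg), 3L)
  expect_identical(nrow(dplyr::inner_join(
    neg, pos, by = c("drug_id", "protein_id"))), 0L)
  expect_identical(neg, sample_negatives(pos, d_ids, p_ids, 3, seed = 5))
  expect_error(sample_negatives(pos, d_ids, p_ids, 46), "only 45")
})

test_that("with one free combination the sampled negative is forced", {
  d_ids <- c("d:1", "d:2"); p_ids <- c("p:1", "p:2")
  pos <- tibble::tibble(drug_id = c("d:1", "d:1", "d:2"),
                        protein_id = c("p:1", "p:2", "p:1"), label = 1L)
  neg <- sample_negatives(pos, d_ids, p_ids, 1, seed = 42)
  expect_identical(neg$drug_id, "d:2")
  expect_identical(neg$protein_id, "p:2")
})

feat <- function(ids, d = 3, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(length(ids) * d), length(ids),
                                dimnames = list(ids, NULL)))
}

test_that("line-graph edges join exactly the pairs sharing an endpoint", {
  dfe <- feat(paste0("d:", 1:3)); pfe <- feat(paste0("p:", 1:3), seed = 2)
  shared <- tibble::tibble(drug_id = c("d:1", "d:1"),
                           protein_id = c("p:1", "p:2"), label = c(1L, 0L))
  g <- build_line_graph(shared, dfe, pfe)
  expect_identical(unname(g$edges), matrix(c(1L, 2L), 1))
  disjoint <- tibble::tibble(drug_id = c("d:1", "d:2"),
                             protein_id = c("p:1", "p:2"), label = c(1L, 0L))
  expect_identical(nrow(build_line_graph(disjoint, dfe, pfe)$edges), 0L)
})

test_that("line-graph features concatenate the endpoint feature rows", {
  dfe <- feat(paste0("d:", 1:3)); pfe <- feat(paste0("p:", 1:3), seed = 2)
  pairs <- tibble::tibble(drug_id = c("d:2", "d:3"),
                          protein_id = c("p:1", "p:1"), label = c(1L, 0L))
  g <- build_line_graph(pairs, dfe, pfe)
  expect_identical(ncol(g$features), 6L)
  expect_equal(unname(g$features[1, ]), unname(c(dfe["d:2", ], pfe["p:1", ])))
  expect_error(
    build_line_graph(tibble::tibble(drug_id = "d:9", protein_id = "p:1",
                                    label = 1L), dfe, pfe),
    "d:9")
})

test_that("the edge set matches an O(n^2) scan on random candidate sets", {
  d_ids <- paste0("d:", 1:12); p_ids <- paste0("p:", 1:15)
  dfe <- feat(d_ids); pfe <- feat(p_ids, seed = 3)
  pairs <- withr::with_seed(7, {
    grid <- expand.grid(drug_id = d_ids, protein_id = p_ids,
                        stringsAsFactors = FALSE)
    pick <- sample(nrow(grid), 60)
    tibble::tibble(drug_id = grid$drug_id[pick],
                   protein_id = grid$protein_id[pick],
                   label = rbinom(60, 1, 0.5))
  })
  g <- build_line_graph(pairs, dfe, pfe)
  oracle <- edge_scan_oracle(pairs)
  expect_identical(unname(g$edges),
                   oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE])
})

test_that("a one-drug star yields the complete graph on its pairs", {
  for (k in c(2, 5, 9)) {
    p_ids <- paste0("p:", seq_len(k))
    pairs <- tibble::tibble(drug_id = "d:1", protein_id = p_ids, label = 1L)
    g <- build_line_graph(pairs, feat("d:1"), feat(p_ids, seed = 4))
    expect_identical(nrow(g$edges), as.integer(k * (k - 1) / 2))
  }
})

test_that("permuting the input pairs yields an isomorphic line graph", {
  d_ids <- paste0("d:", 1:5); p_ids <- paste0("p:", 1:6)
  dfe <- feat(d_ids); pfe <- feat(p_ids, seed = 5)
  pairs <- tibble::tibble(
    drug_id = c("d:1", "d:1", "d:2", "d:3", "d:4", "d:4"),
    protein_id = c("p:1", "p:2", "p:2", "p:3", "p:3", "p:6"),
    label = c(1L, 0L, 1L, 1L, 0L, 1L))
  perm <- c(4, 1, 6, 2, 5, 3)
  g1 <- build_line_graph(pairs, dfe, pfe)
  g2 <- build_line_graph(pairs[perm, ], dfe, pfe)
  key <- function(g) {
    ids <- paste(g$nodes$drug_id, g$nodes$protein_id)
    e <- cbind(ids[g$edges[, 1]], ids[g$edges[, 2]])
    e <- t(apply(e, 1, sort))
    sort(paste(e[, 1], e[, 2], sep = "~"))
  }
  expect_identical(key(g1), key(g2))
})

test_that("arc expansion doubles edges and appends self-loops", {
  dfe <- feat(paste0("d:", 1:3)); pfe <- feat(paste0("p:", 1:4), seed = 6)
  one <- build_line_graph(
    tibble::tibble(drug_id = c("d:1", "d:1"), protein_id = c("p:1", "p:2"),
                   label = c(1L, 0L)), dfe, pfe)
  expect_identical(nrow(to_directed_arcs(one, add_self_loops = FALSE)), 2L)
  none <- build_line_graph(
    tibble::tibble(drug_id = c("d:1", "d:2"), protein_id = c("p:1", "p:2"),
                   label = c(1L, 0L)), dfe, pfe)
  arcs <- to_directed_arcs(none, add_self_loops = TRUE)
  expect_identical(nrow(arcs), 2L)
  expect_true(all(arcs[, 1] == arcs[, 2]))
  g <- toy_line_graph(n_pairs = 25, seed = 3)
  expect_identical(nrow(to_directed_arcs(g, TRUE)),
                   2L * nrow(g$edges) + nrow(g$nodes))
})

test_that("a split line graph round-trips through TSV", {
  g <- with_toy_split(toy_line_graph(n_pairs = 20, seed = 9))
  dir <- withr::local_tempdir()
  write_line_graph(g, dir)
  back <- read_line_graph(dir)
  expect_identical(unname(back$edges), unname(g$edges))
  expect_identical(back$labels, g$labels)
  expect_identical(back$nodes$split, as.character(g$nodes$split))
  expect_equal(unname(back$features), unname(g$features))
  expect_identical(back$d_drug, g$d_drug)
})
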