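# On-disk formats: 3-column TSV edge lists (source_id, target_id, weight)
# for binary edge sets, delimited matrices with an id header row and id
# first column for weighted/feature matrices. Doubles are written with 17
# significant digits so write -> read round-trips exactly.

fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%d", as.integer(x)),
         formatC(x, digits = 17, format = "g"))
}

#' Write / read a numeric matrix as delimited text with id headers
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path (tab-separated text).
#' @return `read_matrix_tsv` returns the matrix with dimnames restored.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(id = rownames(x),
                   matrix(fmt_num(x), nrow(x), ncol(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write / read a binary adjacency as a 3-column TSV edge list
#'
#' Emits one row per non-zero entry with columns `source_id`, `target_id`,
#' `weight` (1 for binary edges). Reading requires the full id vectors so
#' that isolated entities keep their all-zero rows.
#'
#' @param x Binary matrix with dimnames.
#' @param path Output path.
#' @param row_ids,col_ids Full id vectors for reconstruction.
#' @export
write_edges_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  idx <- which(x != 0, arr.ind = TRUE)
  df <- data.frame(source_id = rownames(x)[idx[, 1]],
                   target_id = colnames(x)[idx[, 2]],
                   weight = 1L)
  df <- df[order(df$source_id, df$target_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path, row_ids, col_ids) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  m <- matrix(0L, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(df) > 0) {
    ri <- match(df$source_id, row_ids)
    ci <- match(df$target_id, col_ids)
    if (anyNA(ri)) abort(sprintf("%s: unknown source id %s", path,
                                 df$source_id[which(is.na(ri))[1]]))
    if (anyNA(ci)) abort(sprintf("%s: unknown target id %s", path,
                                 df$target_id[which(is.na(ci))[1]]))
    bad <- which(!(df$weight %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("%s: non-binary weight %g at file row %d (%s -> %s)",
                    path, df$weight[bad[1]], bad[1],
                    df$source_id[bad[1]], df$target_id[bad[1]]))
    }
    m[cbind(ri, ci)] <- 1L
  }
  m
}

hetnet_files <- function() {
  list(edges = c(drug_protein = "edges_drug_protein.tsv",
                 drug_drug = "edges_drug_drug.tsv",
                 drug_disease = "edges_drug_disease.tsv",
                 drug_se = "edges_drug_side_effect.tsv",
                 protein_disease = "edges_protein_disease.tsv",
                 protein_protein = "edges_protein_protein.tsv"),
       sim = c(drug_chemical = "sim_drug_chemical.tsv",
               protein_sequence = "sim_protein_sequence.tsv"),
       nodes = "nodes.tsv")
}

#' Write / read a heterogeneous network directory
#'
#' The directory layout is one TSV edge list per binary edge type, one
#' delimited matrix per weighted similarity network, and a `nodes.tsv`
#' declaring every node id and its type so isolated nodes survive the
#' round trip.
#'
#' @param net A `synth_hetnet` (or the list returned by [read_hetnet()]).
#' @param dir Directory path (created if missing).
#' @return `read_hetnet` returns a `synth_hetnet`-shaped list (without the
#'   simulator-only `latent` / `propensity` elements).
#' @export
write_hetnet <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ff <- hetnet_files()
  nodes <- data.frame(
    node_id = c(net$drug_ids, net$protein_ids, net$disease_ids, net$se_ids),
    type = rep(c("drug", "protein", "disease", "side_effect"),
               c(length(net$drug_ids), length(net$protein_ids),
                 length(net$disease_ids), length(net$se_ids))))
  write.table(nodes, file.path(dir, ff$nodes), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(ff$edges)) {
    write_edges_tsv(net$edges[[nm]], file.path(dir, ff$edges[[nm]]))
  }
  for (nm in names(ff$sim)) {
    write_matrix_tsv(net$sim[[nm]], file.path(dir, ff$sim[[nm]]))
  }
  invisible(dir)
}

#' @rdname write_hetnet
#' @export
read_hetnet <- function(dir) {
  ff <- hetnet_files()
  expected <- c(ff$nodes, unname(ff$edges), unname(ff$sim))
  missing <- expected[!file.exists(file.path(dir, expected))]
  if (length(missing) > 0) {
    abort(sprintf("missing heterogeneous-network files in %s: %s",
                  dir, paste(missing, collapse = ", ")))
  }
  nodes <- read.delim(file.path(dir, ff$nodes), stringsAsFactors = FALSE)
  ids <- split(nodes$node_id, factor(nodes$type,
               levels = c("drug", "protein", "disease", "side_effect")))
  dims <- list(
    drug_protein = list(ids$drug, ids$protein),
    drug_drug = list(ids$drug, ids$drug),
    drug_disease = list(ids$drug, ids$disease),
    drug_se = list(ids$drug, ids$side_effect),
    protein_disease = list(ids$protein, ids$disease),
    protein_protein = list(ids$protein, ids$protein)
  )
  edges <- lapply(names(ff$edges), function(nm) {
    read_edges_tsv(file.path(dir, ff$edges[[nm]]), dims[[nm]][[1]], dims[[nm]][[2]])
  })
  names(edges) <- names(ff$edges)
  sim <- lapply(names(ff$sim), function(nm) {
    m <- read_matrix_tsv(file.path(dir, ff$sim[[nm]]))
    if (any(m < 0 | m > 1)) {
      abort(sprintf("%s: similarity entries outside [0, 1]", ff$sim[[nm]]))
    }
    m
  })
  names(sim) <- names(ff$sim)
  structure(list(
    drug_ids = ids$drug, protein_ids = ids$protein,
    disease_ids = ids$disease, se_ids = ids$side_effect,
    edges = edges, sim = sim,
    propensity = NULL, latent = NULL, config = NULL
  ), class = "synth_hetnet")
}
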