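#' Pipeline configuration
#'
#' One structured configuration (and one global seed) drives the whole
#' simulate / featurize / reduce / build-linegraph / train / evaluate
#' chain with stable on-disk artifacts under `out_dir`.
#'
#' @param out_dir Output directory for every stage artifact.
#' @param synth A [synth_config()] (the simulate stage).
#' @param restart,n_iter,tol Random-walk-with-restart settings.
#' @param pca_dim Components per entity type (`NULL` = 125 capped at
#'   entity count - 1).
#' @param neg_ratio Negatives per positive.
#' @param fractions Train/val/test fractions.
#' @param gtn A [gtn_config()].
#' @param train A [train_config()].
#' @param seed Global seed; propagated to simulation, sampling, split and
#'   training.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synth = synth_config(),
                            restart = 0.5, n_iter = 20, tol = 1e-10,
                            pca_dim = NULL, neg_ratio = 1,
                            fractions = c(0.8, 0.1, 0.1),
                            gtn = gtn_config(), train = train_config(),
                            seed = 1) {
  seed <- assert_count(seed, "seed", min = 0L)
  synth$seed <- seed
  train$seed <- seed
  structure(list(out_dir = out_dir, synth = synth, restart = restart,
                 n_iter = n_iter, tol = tol, pca_dim = pca_dim,
                 neg_ratio = neg_ratio, fractions = fractions,
                 gtn = gtn, train = train, seed = seed),
            class = "pipeline_config")
}

file_digests <- function(paths) {
  paths <- sort(paths)
  d <- tools::md5sum(paths)
  names(d) <- basename(names(d))
  as.list(d)
}

config_digest <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

read_manifests <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::read_json(path)
}

#' Run the full pipeline with digest-based stage skipping
#'
#' Executes simulate, featurize, reduce, linegraph, train and evaluate in
#' order, each stage reading its inputs from the files the previous stage
#' wrote. A stage is skipped when its recorded manifest entry matches the
#' current configuration digest, input digests and output digests
#' (content-addressed: corrupting an artifact forces its producing stage,
#' and anything whose inputs then change, to recompute). A failing stage
#' aborts with the stage named; partial outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @param log Emit per-stage progress to `stderr` (default `TRUE`).
#' @return Invisibly, the list of stage manifests (also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config, log = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  old <- read_manifests(manifest_path)
  old <- stats::setNames(old, vapply(old, `[[`, "", "stage"))
  say <- function(...) if (log) message("[dtiline] ", sprintf(...))

  hd <- file.path(out, "hetnet")
  ff <- hetnet_files()
  hetnet_paths <- file.path(hd, c(ff$nodes, unname(ff$edges), unname(ff$sim)))
  paths <- list(
    simulate = hetnet_paths,
    featurize = file.path(out, c("features_drug.tsv", "features_protein.tsv")),
    reduce = file.path(out, c("reduced_drug.tsv", "reduced_protein.tsv")),
    linegraph = file.path(out, "linegraph",
                          c("linegraph_nodes.tsv", "linegraph_edges.tsv",
                            "linegraph_features.tsv")),
    train = file.path(out, c("checkpoint.rds", "history.tsv")),
    evaluate = file.path(out, "metrics",
                         c("metrics.json", "roc_points.tsv", "pr_points.tsv"))
  )
  inputs <- list(
    simulate = character(),
    featurize = paths$simulate,
    reduce = paths$featurize,
    linegraph = c(paths$reduce, file.path(hd, ff$edges[["drug_protein"]]),
                  file.path(hd, ff$nodes)),
    train = paths$linegraph,
    evaluate = c(paths$train[1], paths$linegraph)
  )
  cfgs <- list(
    simulate = config$synth,
    featurize = list(restart = config$restart, n_iter = config$n_iter,
                     tol = config$tol),
    reduce = list(pca_dim = config$pca_dim),
    linegraph = list(neg_ratio = config$neg_ratio,
                     fractions = config$fractions, seed = config$seed),
    train = list(gtn = config$gtn, train = config$train),
    evaluate = list(split = "test")
  )
  runners <- list(
    simulate = function() write_hetnet(simulate_hetnet(config$synth), hd),
    featurize = function() {
      net <- read_hetnet(hd)
      feats <- diffusion_features(net, restart = config$restart,
                                  n_iter = config$n_iter, tol = config$tol)
      colnames(feats$drug) <- paste0("c", seq_len(ncol(feats$drug)))
      colnames(feats$protein) <- paste0("c", seq_len(ncol(feats$protein)))
      write_matrix_tsv(feats$drug, paths$featurize[1])
      write_matrix_tsv(feats$protein, paths$featurize[2])
    },
    reduce = function() {
      for (i in 1:2) {
        X <- read_matrix_tsv(paths$featurize[i])
        k <- if (is.null(config$pca_dim)) min(125L, nrow(X) - 1L) else config$pca_dim
        proj <- fit_projection(X, k)
        red <- project_features(proj, X)
        colnames(red) <- paste0("PC", seq_len(ncol(red)))
        write_matrix_tsv(red, paths$reduce[i])
        write_projection(proj, file.path(out, c("projection_drug",
                                                "projection_protein")[i]))
      }
    },
    linegraph = function() {
      net <- read_hetnet(hd)
      dr <- read_matrix_tsv(paths$reduce[1])
      pr <- read_matrix_tsv(paths$reduce[2])
      pairs <- candidate_pairs(net, neg_ratio = config$neg_ratio,
                               seed = config$seed)
      pairs <- split_candidates(pairs, fractions = config$fractions,
                                seed = config$seed + 1L)
      g <- build_line_graph(pairs, dr, pr)
      g$nodes$split <- pairs$split
      write_line_graph(g, file.path(out, "linegraph"))
    },
    train = function() {
      g <- read_line_graph(file.path(out, "linegraph"))
      g$nodes$split <- factor(g$nodes$split, levels = c("train", "val", "test"))
      fit <- train_gtn(g, config$gtn, config$train)
      saveRDS(fit, paths$train[1])
      write.table(as.data.frame(fit$history), paths$train[2],
                  sep = "\t", quote = FALSE, row.names = FALSE)
    },
    evaluate = function() {
      fit <- readRDS(paths$train[1])
      g <- read_line_graph(file.path(out, "linegraph"))
      g$nodes$split <- factor(g$nodes$split, levels = c("train", "val", "test"))
      write_metrics(evaluate(fit, g, split = "test"), file.path(out, "metrics"))
    }
  )

  manifests <- list()
  for (stage in names(runners)) {
    cfg_d <- config_digest(cfgs[[stage]])
    in_d <- if (length(inputs[[stage]]) > 0) file_digests(inputs[[stage]]) else list()
    prev <- old[[stage]]
    fresh <- !is.null(prev) &&
      identical(as.character(prev$config_digest), as.character(cfg_d)) &&
      identical(lapply(prev$inputs, as.character), lapply(in_d, as.character)) &&
      all(file.exists(paths[[stage]])) &&
      identical(lapply(prev$outputs, as.character),
                lapply(file_digests(paths[[stage]]), as.character))
    if (fresh) {
      say("stage %-9s skipped (digests match)", stage)
      entry <- prev
      entry$skipped <- TRUE
    } else {
      say("stage %-9s running", stage)
      ok <- tryCatch({ runners[[stage]](); TRUE },
                     error = function(e) e)
      if (!isTRUE(ok)) {
        abort(sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(ok)))
      }
      entry <- list(stage = stage, seed = config$seed,
                    config_digest = cfg_d, inputs = in_d,
                    outputs = file_digests(paths[[stage]]),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    skipped = FALSE)
    }
    manifests[[stage]] <- entry
    jsonlite::write_json(unname(manifests), manifest_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifests)
}

#' Ingest an on-disk heterogeneous network directory
#'
#' Parses a directory in the package's edge-list / matrix layout (the same
#' format the simulator writes) into the in-memory network structure,
#' validating that association edge lists are binary and similarity
#' entries lie in `[0, 1]`. Errors name the offending file (and, for
#' non-binary entries, the file row and node pair).
#'
#' @param dir Directory with the network files (see [write_hetnet()]).
#' @return A `synth_hetnet`-shaped network (without simulator-only
#'   ground-truth elements).
#' @export
ingest_real_dataset <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("directory not found: %s", dir))
  read_hetnet(dir)
}
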