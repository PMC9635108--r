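balanced_pairs <- function(n_pos, n_neg, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    drug_id = paste0("d:", seq_len(n_pos + n_neg)),
    protein_id = paste0("p:", seq_len(n_pos + n_neg)),
    label = c(rep(1L, n_pos), rep(0L, n_neg))
  ))
}

test_that("splits use exact per-class fractions and partition the input", {
  pairs <- split_candidates(balanced_pairs(10, 10), c(0.8, 0.1, 0.1), seed = 3)
  tab <- table(pairs$split, pairs$label)
  expect_identical(as.vector(tab), c(8L, 1L, 1L, 8L, 1L, 1L))
  again <- split_candidates(balanced_pairs(10, 10), c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(pairs$split, again$split)
  big <- split_candidates(balanced_pairs(430, 570), seed = 5)
  expect_false(anyNA(big$split))
  expect_identical(nrow(big), 1000L)
  expect_true(all(table(big$split, big$label) >= 1))
})

test_that("too few samples to populate every split is an error", {
  expect_error(split_candidates(balanced_pairs(2, 10)), "class 1")
  expect_error(split_candidates(balanced_pairs(10, 10), c(0.5, 0.5, 0)),
               "fractions")
})

test_that("AUROC handles perfect, inverted and random rankings", {
  y <- c(1, 1, 0, 0, 1, 0)
  expect_equal(auroc(y, y), 1)
  expect_equal(auroc(y, 1 - y), 0)
  withr::with_seed(8, {
    for (i in 1:3) {
      yy <- rbinom(50, 1, 0.4)
      if (length(unique(yy)) < 2) next
      ss <- sample(20, 50, replace = TRUE)  # heavy ties
      expect_equal(auroc(yy, ss), auroc_pairwise_oracle(yy, ss),
                   tolerance = 1e-10)
    }
  })
  expect_error(auroc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUROC is invariant to strictly monotone score transforms", {
  withr::with_seed(4, {
    y <- rbinom(40, 1, 0.5)
    s <- rnorm(40)
    a <- auroc(y, s)
    expect_equal(auroc(y, exp(s)), a, tolerance = 1e-12)
    expect_equal(auroc(y, 3 * s - 10), a, tolerance = 1e-12)
    expect_equal(auroc(y, plogis(s)), a, tolerance = 1e-12)
  })
})

test_that("AUROC and AUPR agree with pROC on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    y <- rbinom(80, 1, 0.5)
    s <- rnorm(80) + y
    expect_equal(auroc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-10)
  })
})

test_that("AUPR matches exhaustive threshold enumeration", {
  y <- c(1, 0, 1, 1, 0)
  expect_equal(aupr(y, c(0.9, 0.1, 0.8, 0.7, 0.2)), 1)
  expect_equal(aupr(y, rep(0.5, 5)), 0.6)  # constant scores: prevalence
  withr::with_seed(9, {
    for (i in 1:3) {
      yy <- rbinom(50, 1, 0.3)
      if (length(unique(yy)) < 2) next
      ss <- round(rnorm(50), 1)
      expect_equal(aupr(yy, ss), aupr_threshold_oracle(yy, ss),
                   tolerance = 1e-10)
    }
  })
})

test_that("the ROC curve runs from (0,0) to (1,1)", {
  withr::with_seed(2, {
    y <- rbinom(30, 1, 0.5)
    pts <- roc_points(y, rnorm(30))
    expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
    expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  })
})

test_that("training configuration validates its inputs", {
  expect_error(train_config(n_iterations = 0), "n_iterations")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("training reduces the loss on a separable toy graph", {
  g <- with_toy_split(toy_line_graph(n_pairs = 40, n_drugs = 8,
                                     n_proteins = 10, separable = TRUE,
                                     seed = 6))
  fit <- train_gtn(g, gtn_config(n_heads = 2, head_dim = 4, dropout = 0),
                   train_config(n_iterations = 200, eval_every = 25, seed = 2))
  h <- fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_gt(evaluate(fit, split = "train")$auroc, 0.95)
})

test_that("training is deterministic given a seed", {
  g <- with_toy_split(toy_line_graph(n_pairs = 30, seed = 7))
  cfg <- gtn_config(n_heads = 2, head_dim = 3)  # dropout active
  tcfg <- train_config(n_iterations = 30, eval_every = 10, seed = 5)
  f1 <- train_gtn(g, cfg, tcfg)
  f2 <- train_gtn(g, cfg, tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  r1 <- evaluate(f1, split = "test")
  r2 <- evaluate(f1, split = "test")
  expect_identical(glance(r1), glance(r2))
})

test_that("evaluation reports stay within [0, 1] and carry both curves", {
  g <- with_toy_split(toy_line_graph(n_pairs = 30, seed = 8))
  fit <- train_gtn(g, gtn_config(n_heads = 2, head_dim = 3, dropout = 0),
                   train_config(n_iterations = 20, eval_every = 10, seed = 1))
  rep <- evaluate(fit, split = "test")
  expect_true(rep$auroc >= 0 && rep$auroc <= 1)
  expect_true(rep$aupr >= 0 && rep$aupr <= 1)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_identical(glance(rep)$n, rep$n)
})

test_that("ablation variants run and the no-GTN head is strictly smaller", {
  net <- simulate_hetnet(synth_config(n_drugs = 30, n_proteins = 40,
                                      n_diseases = 12, n_side_effects = 8,
                                      positive_rate = 0.12, seed = 3))
  prep <- prepare_dti_data(net, pca_dim = 16, seed = 3)
  tcfg <- train_config(n_iterations = 40, eval_every = 20, seed = 3)
  gcfg <- gtn_config(n_heads = 2, head_dim = 8, dropout = 0)
  full <- run_ablation(prep, "full", gcfg, tcfg)
  no_gtn <- run_ablation(prep, "no_gtn", gcfg, tcfg)
  no_lg <- run_ablation(prep, "no_line_graph", gcfg, tcfg)
  expect_lt(no_gtn$fit$n_parameters, full$fit$n_parameters)
  expect_s3_class(no_lg$report, "dti_metrics")
  # full-mode report is the plain evaluation of its fitted model
  expect_identical(glance(full$report),
                   glance(evaluate(full$fit, split = "test")))
  expect_error(run_ablation(prep, "nonsense"), "arg")
})

test_that("the logistic baseline separates the separable toy", {
  g <- with_toy_split(toy_line_graph(n_pairs = 40, separable = TRUE, seed = 10))
  rep <- logistic_baseline(g, split = "train")
  expect_gt(rep$auroc, 0.95)
})
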