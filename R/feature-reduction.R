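#' Fit a principal-component projection of entity features
#'
#' Column-centers `X` (no unit-variance scaling: diffusion features share a
#' probability scale) and keeps the leading eigenvectors of the covariance.
#' A deterministic sign convention is applied — each component's
#' largest-magnitude loading is positive — so repeated fits are
#' bit-comparable.
#'
#' @param X Numeric matrix (entities in rows).
#' @param n_components Number of components to keep; must be at most
#'   `min(nrow(X), ncol(X))`. Default 125.
#' @return An object of class `projection_model` with elements `mean`,
#'   `components` (orthonormal columns), `explained_variance`
#'   (non-increasing) and `n_components`.
#' @export
fit_projection <- function(X, n_components = 125) {
  stopifnot(is.matrix(X), is.numeric(X))
  n_components <- assert_count(n_components, "n_components")
  if (n_components > min(dim(X))) {
    abort(sprintf("n_components = %d exceeds min(nrow, ncol) = %d",
                  n_components, min(dim(X))))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  comp <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude entry of each component positive
  flip <- vapply(seq_len(ncol(comp)), function(j) {
    v <- comp[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  comp <- sweep(comp, 2, flip, "*")
  dimnames(comp) <- NULL
  structure(list(
    mean = pc$center,
    components = comp,
    explained_variance = pc$sdev[seq_len(n_components)]^2,
    n_components = n_components
  ), class = "projection_model")
}

#' Project features onto a fitted principal-component basis
#'
#' Computes `(X - mean) %*% components`; the output has exactly
#' `n_components` columns and row names carried over from `X`.
#'
#' @param model A [fit_projection()] result.
#' @param X Matrix whose column count matches the fitted mean length.
#' @return Reduced matrix (`nrow(X)` by `n_components`).
#' @export
project_features <- function(model, X) {
  stopifnot(inherits(model, "projection_model"), is.matrix(X))
  if (ncol(X) != length(model$mean)) {
    abort(sprintf("X has %d columns but the model was fitted on %d",
                  ncol(X), length(model$mean)))
  }
  Y <- sweep(X, 2, model$mean) %*% model$components
  rownames(Y) <- rownames(X)
  Y
}

#' @export
predict.projection_model <- function(object, newdata, ...) {
  project_features(object, newdata)
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %d components over %d input columns\n",
              x$n_components, length(x$mean)))
  cat(sprintf("  leading explained variance: %s\n",
              paste(signif(utils::head(x$explained_variance, 3), 4),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.projection_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    explained_variance = x$explained_variance,
    proportion = x$explained_variance / sum(x$explained_variance)
  )
}

#' @export
glance.projection_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    input_dim = length(x$mean),
    total_variance = sum(x$explained_variance)
  )
}

#' Serialize / restore a projection model as delimited text
#'
#' @param model A `projection_model`.
#' @param dir Directory to hold `projection_mean.tsv`,
#'   `projection_components.tsv` and `projection_variance.tsv`.
#' @export
write_projection <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  in_names <- names(model$mean)
  if (is.null(in_names)) in_names <- paste0("x", seq_along(model$mean))
  mean_m <- matrix(model$mean, nrow = 1, dimnames = list("mean", in_names))
  write_matrix_tsv(mean_m, file.path(dir, "projection_mean.tsv"))
  comp <- model$components
  dimnames(comp) <- list(in_names, paste0("PC", seq_len(ncol(comp))))
  write_matrix_tsv(comp, file.path(dir, "projection_components.tsv"))
  var_m <- matrix(model$explained_variance, nrow = 1,
                  dimnames = list("variance", paste0("PC", seq_len(model$n_components))))
  write_matrix_tsv(var_m, file.path(dir, "projection_variance.tsv"))
  invisible(dir)
}

#' @rdname write_projection
#' @export
read_projection <- function(dir) {
  mean_m <- read_matrix_tsv(file.path(dir, "projection_mean.tsv"))
  comp <- read_matrix_tsv(file.path(dir, "projection_components.tsv"))
  var_m <- read_matrix_tsv(file.path(dir, "projection_variance.tsv"))
  structure(list(
    mean = setNames(as.numeric(mean_m[1, ]), colnames(mean_m)),
    components = comp,
    explained_variance = as.numeric(var_m[1, ]),
    n_components = ncol(comp)
  ), class = "projection_model")
}
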