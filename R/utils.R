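# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that a seed fully determines the output.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, deparse(x)))
  }
  as.integer(x)
}

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a probability in %s%g, %g%s, got %s", name,
                  if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", deparse(x)))
  }
  as.numeric(x)
}

assert_binary_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", name))
  }
  bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("`%s` must be binary; non-binary entry %g at row %d, col %d",
                  name, x[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  }
  invisible(x)
}

# rowsum() that always returns one row per group 1..n, zero-filled.
# Fast path: when every group is present the sorted-unique groups are
# exactly 1..n and no padding pass is needed.
index_add <- function(n, idx, x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
  s <- rowsum(x, group = idx, reorder = TRUE)
  if (nrow(s) == n) {
    dimnames(s) <- NULL
    return(s)
  }
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(s)), ] <- s
  out
}



relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Monotone calibration of a logistic intercept by bisection so that
# mean(plogis(eta + b)) == target.
calibrate_intercept <- function(eta, target, lo = -80, hi = 80, iters = 60L) {
  f <- function(b) mean(plogis(eta + b)) - target
  if (f(lo) > 0 || f(hi) < 0) abort("intercept calibration failed: target density unreachable")
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
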