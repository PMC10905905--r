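#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# one-hot encode a value against a fixed category vector, last slot = overflow
one_hot <- function(value, categories, other = TRUE) {
  v <- numeric(length(categories) + as.integer(other))
  i <- match(value, categories)
  if (is.na(i)) {
    if (!other) abort(sprintf("value '%s' not in categories", value))
    v[length(v)] <- 1
  } else {
    v[i] <- 1
  }
  v
}

# affine map helper: X %*% W + b for row-major batches (column-major add)
affine <- function(X, W, b) {
  X %*% W + rep(b, each = nrow(X))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

prelu <- function(x, slope) {
  ifelse(x > 0, x, slope * x)
}

# scatter-add rows of `m` into an n-row accumulator by integer group `idx`
rowsum_into <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  if (nrow(m) > 0L) {
    rs <- rowsum(m, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
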