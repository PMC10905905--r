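# Minimal dense-layer toolkit used by the GIN encoder and prediction heads:
# uniform fan-in initialization, inverted dropout, and Adam with L2 weight
# decay.  All parameters live in flat named lists of matrices/vectors so the
# optimizer, gradient checks and checkpoints can treat them uniformly.

init_matrix <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_bias <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  stats::runif(fan_out, -lim, lim)
}

dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(n * m) >= rate) / (1 - rate), n, m)
}

adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0),
       v = lapply(w, function(x) x * 0),
       t = 0L)
}

adam_step <- function(w, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(w)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * w[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    w[[nm]] <- w[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(w = w, state = state)
}

# elementwise sum of two same-shape gradient lists
grad_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
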