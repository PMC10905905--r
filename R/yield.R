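#' Fine-tuning configuration for the yield model
#'
#' Defaults follow the reference recipe: 500 epochs of Adam (batch 128,
#' weight decay 1e-5), learning rate 5e-4 decayed to 5e-5 and 5e-6 at
#' epochs 400 and 450, Monte-Carlo-dropout inference with 30 passes.
#' Schedule stages beyond the configured epoch count are dropped, so
#' shortened runs keep a valid (possibly empty) schedule.
#'
#' @param alpha Mixing weight in \[0, 1\] between the homoscedastic squared
#'   error (`alpha = 0`) and the heteroscedastic negative-log-likelihood
#'   term (`alpha = 1`).
#' @param epochs,batch_size,learning_rate,weight_decay Optimizer settings.
#' @param lr_schedule List with `epochs` (strictly increasing) and `rates`.
#' @param mc_passes Number of stochastic forward passes at inference.
#' @param dropout_rate Dropout probability.
#' @param yield_scaling `"standardize"` (zero mean / unit SD on the training
#'   yields, inverted for reporting) or `"raw"` (percent scale).
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A named list.
#' @export
finetune_config <- function(alpha = 0.1, epochs = 500L, batch_size = 128L,
                            learning_rate = 5e-4,
                            lr_schedule = list(epochs = c(400L, 450L),
                                               rates = c(5e-5, 5e-6)),
                            weight_decay = 1e-5, mc_passes = 30L,
                            dropout_rate = 0.1,
                            yield_scaling = c("standardize", "raw"),
                            seed = 1L) {
  yield_scaling <- match.arg(yield_scaling)
  if (alpha < 0 || alpha > 1)
    abort("`alpha` must be in [0, 1]", class = "ginyield_config_error")
  if (length(lr_schedule$epochs) != length(lr_schedule$rates) ||
      is.unsorted(lr_schedule$epochs, strictly = TRUE))
    abort("lr_schedule epochs must be strictly increasing and match rates",
          class = "ginyield_config_error")
  keep <- lr_schedule$epochs <= epochs
  lr_schedule$epochs <- as.integer(lr_schedule$epochs[keep])
  lr_schedule$rates <- lr_schedule$rates[keep]
  list(alpha = alpha, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size),
       learning_rate = learning_rate, lr_schedule = lr_schedule,
       weight_decay = weight_decay, mc_passes = as.integer(mc_passes),
       dropout_rate = dropout_rate, yield_scaling = yield_scaling,
       seed = as.integer(seed))
}

#' Mixed homoscedastic/heteroscedastic fine-tuning loss
#'
#' `(1 - alpha) * (y - mu)^2 + alpha * ((y - mu)^2 / sigma2 + log(sigma2))`.
#' At `alpha = 0` this is plain squared error; at `alpha = 1` it is the
#' Gaussian negative log-likelihood (up to constants) in which the model
#' predicts its own per-reaction variance.
#'
#' @param y Observed yield(s).
#' @param mu_hat Predicted mean(s).
#' @param sigma2_hat Predicted variance(s); must be positive.
#' @param alpha Mixing weight in \[0, 1\].
#' @return Loss value(s), same length as `y`.
#' @export
#' @examples
#' finetune_loss(1, 0, 1, 0.5)  # 0.5 * 1 + 0.5 * (1 + 0) = 1
finetune_loss <- function(y, mu_hat, sigma2_hat, alpha) {
  if (any(sigma2_hat <= 0))
    abort("`sigma2_hat` must be positive", class = "ginyield_domain_error")
  if (alpha < 0 || alpha > 1)
    abort("`alpha` must be in [0, 1]", class = "ginyield_domain_error")
  sq <- (y - mu_hat)^2
  (1 - alpha) * sq + alpha * (sq / sigma2_hat + log(sigma2_hat))
}

# reaction-level prediction head: sum-pooled reactant representations
# concatenated with the product representation -> hidden PReLU layer with
# dropout -> (mu, log sigma^2)
yield_head_init <- function(rep_dim, hidden = 1024L, seed = 1L) {
  set.seed(seed)
  list(W1 = init_matrix(2L * rep_dim, hidden),
       b1 = init_bias(2L * rep_dim, hidden),
       W2 = init_matrix(hidden, 2L),
       b2 = init_bias(hidden, 2L),
       prelu_h = 0.25,
       hidden = as.integer(hidden))
}

#' Initialize a yield model from a pre-trained encoder (or from scratch)
#'
#' The GIN component is copied bit-for-bit from the pre-trained checkpoint;
#' the auxiliary pre-training head is deliberately not loaded (it exists
#' only for the pre-text task).  The reaction-level prediction head is
#' always freshly initialized from `head_init_seed`.  With
#' `pretrained = NULL` all parameters are random: the from-scratch
#' baseline.
#'
#' @param pretrained A `pretrain_fit`, a checkpoint path, or `NULL`.
#' @param gin_template A `gin_parameters` defining the architecture when
#'   `pretrained` is `NULL` (required in that case); when both are given
#'   the checkpoint must be architecture-compatible with the template.
#' @param head_hidden Hidden width of the prediction head.
#' @param head_init_seed Seed for the freshly initialized head (and the
#'   from-scratch encoder).
#' @return A list with `gin` and `head`, ready for [run_finetuning()].
#' @export
init_yield_model <- function(pretrained = NULL, gin_template = NULL,
                             head_hidden = 1024L, head_init_seed = 1L) {
  if (is.null(pretrained)) {
    if (is.null(gin_template))
      abort("from-scratch initialization needs `gin_template`")
    cfg <- gin_template$config
    gin <- gin_init(cfg$node_dim, cfg$edge_dim, L = cfg$L,
                    hidden = cfg$hidden, rep_dim = cfg$rep_dim,
                    message_mode = cfg$message_mode, seed = head_init_seed)
  } else {
    if (is.character(pretrained))
      pretrained <- load_checkpoint(pretrained,
                                    expect_config = gin_template$config)
    stopifnot(inherits(pretrained$gin, "gin_parameters"))
    if (!is.null(gin_template)) {
      fields <- c("node_dim", "edge_dim", "L", "hidden", "rep_dim",
                  "message_mode")
      bad <- fields[vapply(fields, function(f)
        !identical(pretrained$gin$config[[f]], gin_template$config[[f]]),
        logical(1))]
      if (length(bad) > 0)
        abort(sprintf("pre-trained encoder incompatible: %s",
                      paste(bad, collapse = ", ")),
              class = "ginyield_manifest_error")
    }
    gin <- pretrained$gin
  }
  head <- yield_head_init(gin$config$rep_dim, hidden = head_hidden,
                          seed = head_init_seed)
  list(gin = gin, head = head)
}

# Batched forward over a list of featurized reactions
# (each list(reactants = list of graphs, product = graph)).
yield_forward_batch <- function(gin, head, reactions, dropout_rate = 0,
                                stochastic = FALSE, keep_cache = FALSE) {
  n_rxn <- length(reactions)
  ms <- vapply(reactions, function(r) length(r$reactants), integer(1))
  if (any(ms < 1))
    abort("every reaction needs at least one reactant",
          class = "ginyield_input_error")
  graphs <- c(unlist(lapply(reactions, `[[`, "reactants"),
              recursive = FALSE),
              lapply(reactions, `[[`, "product"))
  react_rxn <- rep(seq_len(n_rxn), ms)
  n_react <- sum(ms)
  prod_rows <- n_react + seq_len(n_rxn)

  fwd <- gin_forward_batch(gin, batch_graphs(graphs),
                           dropout_rate = dropout_rate,
                           stochastic = stochastic, keep_cache = keep_cache)
  REP <- fwd$rep
  Rsum <- rowsum_into(REP[seq_len(n_react), , drop = FALSE], react_rxn,
                      n_rxn)
  C <- cbind(Rsum, REP[prod_rows, , drop = FALSE])
  Z1 <- affine(C, head$W1, head$b1)
  A1 <- prelu(Z1, head$prelu_h)
  maskH <- if (stochastic && dropout_rate > 0)
    dropout_mask(nrow(A1), ncol(A1), dropout_rate) else NULL
  A1d <- if (!is.null(maskH)) A1 * maskH else A1
  OUT <- affine(A1d, head$W2, head$b2)
  res <- list(mu = OUT[, 1], log_sigma2 = OUT[, 2],
              sigma2 = exp(OUT[, 2]))
  if (keep_cache)
    res$cache <- list(fwd = fwd, C = C, Z1 = Z1, A1d = A1d, maskH = maskH,
                      react_rxn = react_rxn, n_react = n_react,
                      prod_rows = prod_rows, n_rxn = n_rxn)
  res
}

# gradients of mean batch loss w.r.t. all gin + head parameters
yield_backward_batch <- function(gin, head, res, d_mu, d_s) {
  cache <- res$cache
  dOUT <- cbind(d_mu, d_s)
  g <- list()
  g$W2 <- t(cache$A1d) %*% dOUT
  g$b2 <- colSums(dOUT)
  dA1d <- dOUT %*% t(head$W2)
  dA1 <- if (!is.null(cache$maskH)) dA1d * cache$maskH else dA1d
  pos <- cache$Z1 > 0
  dZ1 <- dA1 * ifelse(pos, 1, head$prelu_h)
  g$prelu_h <- sum(dA1 * cache$Z1 * !pos)
  g$W1 <- t(cache$C) %*% dZ1
  g$b1 <- colSums(dZ1)
  dC <- dZ1 %*% t(head$W1)

  rep_dim <- gin$config$rep_dim
  dRsum <- dC[, seq_len(rep_dim), drop = FALSE]
  dProd <- dC[, rep_dim + seq_len(rep_dim), drop = FALSE]
  dREP <- rbind(dRsum[cache$react_rxn, , drop = FALSE], dProd)
  gin_grads <- gin_backward_batch(gin, cache$fwd, dREP)
  list(gin = gin_grads, head = g)
}

#' Forward pass of the yield model on one reaction
#'
#' Encodes each reactant and the product with the same GIN, sum-pools the
#' reactant representations (order-invariant), concatenates with the
#' product representation, and applies the prediction head to obtain the
#' predictive mean and variance.  The variance is parameterized as
#' `exp(log sigma2)` and is therefore always positive.
#'
#' @param reaction A list with `reactants` (list of `molecular_graph`) and
#'   `product` (a `molecular_graph`), e.g. from [featurize_reaction()].
#' @param gin A `gin_parameters`.
#' @param head A head from [yield_head_init()] / [init_yield_model()].
#' @param dropout_rate,stochastic Dropout control; deterministic when
#'   `stochastic = FALSE`.
#' @return A list of class `yield_prediction` with `mu`, `sigma2`.
#' @export
yield_forward <- function(reaction, gin, head, dropout_rate = 0,
                          stochastic = FALSE) {
  res <- yield_forward_batch(gin, head, list(reaction),
                             dropout_rate = dropout_rate,
                             stochastic = stochastic)
  structure(list(mu = unname(res$mu), sigma2 = unname(res$sigma2)),
            class = "yield_prediction")
}

#' @export
print.yield_prediction <- function(x, ...) {
  cat(sprintf("<yield_prediction> mu = %.3f, sigma2 = %.4f\n",
              x$mu, x$sigma2))
  invisible(x)
}

#' Fine-tune the yield model on a set of reactions
#'
#' Trains the GIN encoder and reaction head jointly with the mixed loss
#' ([finetune_loss()]) under the staged learning-rate schedule.  Yields are
#' standardized on the training set by default (stabilizes the log-variance
#' term); predictions are reported back on the percent scale.
#'
#' @param data A tibble with a `rxn` list-column of featurized reactions
#'   (see [load_reaction_csv()]) and a `yield` column (percent scale).
#' @param init A list with `gin` and `head` from [init_yield_model()].
#' @param config See [finetune_config()].
#' @param verbose Emit line-oriented JSON per-epoch log records.
#' @return An object of class `yield_model` with the trained components,
#'   yield-scaling statistics, per-epoch loss `history` and `config`.
#' @export
run_finetuning <- function(data, init, config = finetune_config(),
                           verbose = FALSE) {
  stopifnot(is.data.frame(data), "rxn" %in% names(data),
            "yield" %in% names(data), nrow(data) > 0)
  gin <- init$gin
  head <- init$head
  y_raw <- as.numeric(data$yield)
  if (config$yield_scaling == "standardize") {
    y_center <- mean(y_raw)
    y_scale <- stats::sd(y_raw)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  } else {
    y_center <- 0; y_scale <- 1
  }
  y <- (y_raw - y_center) / y_scale
  N <- nrow(data)
  reactions <- data$rxn

  head_names <- c("W1", "b1", "W2", "b2", "prelu_h")
  all_w <- c(gin$w, stats::setNames(head[head_names],
                                    paste0("head_", head_names)))
  opt <- adam_init(all_w)
  set.seed(config$seed)
  history <- tibble(epoch = integer(0), loss = numeric(0),
                    learning_rate = numeric(0))

  lr_at <- function(epoch) {
    lr <- config$learning_rate
    sch <- config$lr_schedule
    for (i in seq_along(sch$epochs))
      if (epoch >= sch$epochs[i]) lr <- sch$rates[i]
    lr
  }

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(epoch)
    order <- sample.int(N)
    starts <- seq(1, N, by = config$batch_size)
    losses <- numeric(0)
    for (s in starts) {
      idx <- order[s:min(s + config$batch_size - 1, N)]
      B <- length(idx)
      gin$w <- all_w[names(gin$w)]
      for (nm in head_names) head[[nm]] <- all_w[[paste0("head_", nm)]]
      res <- yield_forward_batch(gin, head, reactions[idx],
                                 dropout_rate = config$dropout_rate,
                                 stochastic = TRUE, keep_cache = TRUE)
      e <- y[idx] - res$mu
      loss <- mean(finetune_loss(y[idx], res$mu, res$sigma2, config$alpha))
      if (!is.finite(loss))
        abort(sprintf(
          "non-finite loss at epoch %d, batch starting at %d (ids: %s)",
          epoch, s, paste(utils::head(idx), collapse = ",")),
          class = "ginyield_numeric_error")
      losses <- c(losses, loss)
      d_mu <- (-2 * e * (1 - config$alpha) -
                 2 * config$alpha * e / res$sigma2) / B
      d_s <- config$alpha * (1 - e^2 / res$sigma2) / B
      bk <- yield_backward_batch(gin, head, res, d_mu, d_s)
      grads <- c(bk$gin, stats::setNames(bk$head[head_names],
                                         paste0("head_", head_names)))
      step <- adam_step(all_w, grads, opt, lr = lr,
                        weight_decay = config$weight_decay)
      all_w <- step$w
      opt <- step$state
    }
    history <- dplyr::bind_rows(history,
                                tibble(epoch = epoch, loss = mean(losses),
                                       learning_rate = lr))
    if (verbose)
      message(jsonlite::toJSON(list(phase = "finetune", epoch = epoch,
                                    loss = mean(losses), lr = lr),
                               auto_unbox = TRUE))
  }

  gin$w <- all_w[names(gin$w)]
  for (nm in head_names) head[[nm]] <- all_w[[paste0("head_", nm)]]
  structure(
    list(gin = gin, head = head, config = config,
         y_center = y_center, y_scale = y_scale,
         history = history),
    class = "yield_model")
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf("<yield_model> alpha = %.2f, %d epochs trained\n",
              x$config$alpha, nrow(x$history)))
  invisible(x)
}

#' @method tidy yield_model
#' @export
tidy.yield_model <- function(x, ...) x$history

#' @method glance yield_model
#' @export
glance.yield_model <- function(x, ...) {
  tibble(alpha = x$config$alpha, epochs = nrow(x$history),
         final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)]
         else NA_real_,
         yield_scaling = x$config$yield_scaling)
}

#' Fine-tuning loss curve
#'
#' @param object A `yield_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot yield_model
#' @export
autoplot.yield_model <- function(object, ...) {
  ggplot(object$history, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "training loss") +
    theme_minimal()
}

#' Predict reaction yields with Monte-Carlo dropout
#'
#' Runs `passes` stochastic forward passes (dropout active) for every
#' reaction and averages the per-pass predictive means; the result is
#' reported on the percent yield scale.  With `dropout_rate = 0` every pass
#' is identical to the deterministic forward pass.  The per-pass means are
#' retained in the `"mc_samples"` attribute; the across-pass mean of the
#' predicted variances is reported as `.pred_var` (an extension beyond the
#' mean-averaging rule, clearly separated from `.pred`).
#'
#' @param model A `yield_model`.
#' @param data Tibble with a `rxn` list-column (or a list of featurized
#'   reactions).
#' @param passes Number of stochastic passes (T).
#' @param seed Seed making the stochastic passes reproducible.
#' @return `data` with `.pred` (MC-averaged mean yield), `.pred_var`
#'   (mean predicted variance, percent^2), and `.pred_sd`.
#' @export
predict_mc_dropout <- function(model, data, passes = model$config$mc_passes,
                               seed = 1L) {
  stopifnot(inherits(model, "yield_model"), passes >= 1)
  reactions <- if (is.data.frame(data)) data$rxn else data
  set.seed(seed)
  mu_mat <- matrix(NA_real_, length(reactions), passes)
  var_mat <- matrix(NA_real_, length(reactions), passes)
  for (t in seq_len(passes)) {
    res <- yield_forward_batch(model$gin, model$head, reactions,
                               dropout_rate = model$config$dropout_rate,
                               stochastic = TRUE)
    mu_mat[, t] <- res$mu * model$y_scale + model$y_center
    var_mat[, t] <- res$sigma2 * model$y_scale^2
  }
  out <- if (is.data.frame(data)) as_tibble(data) else
    tibble(rxn = reactions)
  out$.pred <- rowMeans(mu_mat)
  out$.pred_var <- rowMeans(var_mat)
  out$.pred_sd <- sqrt(out$.pred_var)
  attr(out, "mc_samples") <- mu_mat
  out
}

#' Deterministic (dropout-off) yield predictions
#'
#' @param object A `yield_model`.
#' @param data Tibble with a `rxn` list-column.
#' @param ... Unused.
#' @return `data` with `.pred` and `.pred_var` columns (percent scale).
#' @export
predict.yield_model <- function(object, data, ...) {
  reactions <- if (is.data.frame(data)) data$rxn else data
  res <- yield_forward_batch(object$gin, object$head, reactions)
  out <- if (is.data.frame(data)) as_tibble(data) else
    tibble(rxn = reactions)
  out$.pred <- unname(res$mu * object$y_scale + object$y_center)
  out$.pred_var <- unname(res$sigma2 * object$y_scale^2)
  out
}

#' Regression metrics for yield predictions
#'
#' Root mean squared error, mean absolute error and the coefficient of
#' determination (`R^2 = 1 - SSE/SST`, SST about the mean of the truths).
#' With constant truths `R^2` is undefined and reported as `NA`.
#'
#' @param data Optional tibble holding truth and estimate columns.
#' @param truth,estimate Column names (when `data` given) or numeric
#'   vectors.
#' @return A one-row tibble with `rmse`, `mae`, `r2`.
#' @export
#' @examples
#' evaluate_predictions(truth = c(0, 10), estimate = c(0, 0))
evaluate_predictions <- function(data = NULL, truth = "yield",
                                 estimate = ".pred") {
  if (!is.null(data)) {
    y <- as.numeric(data[[truth]])
    p <- as.numeric(data[[estimate]])
  } else {
    y <- as.numeric(truth)
    p <- as.numeric(estimate)
  }
  if (length(y) != length(p) || length(y) < 2)
    abort("need equal-length truth/estimate vectors of length >= 2")
  sse <- sum((y - p)^2)
  sst <- sum((y - mean(y))^2)
  tibble(
    rmse = sqrt(mean((y - p)^2)),
    mae = mean(abs(y - p)),
    r2 = if (sst == 0) NA_real_ else 1 - sse / sst)
}

#' Observed-versus-predicted plot
#'
#' @param data Output of [predict_mc_dropout()] or [predict.yield_model()]
#'   containing `yield` and `.pred`.
#' @return A ggplot.
#' @export
plot_predictions <- function(data) {
  stopifnot(all(c("yield", ".pred") %in% names(data)))
  ggplot(data, aes(x = .data$yield, y = .data$.pred)) +
    geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "observed yield (%)", y = "predicted yield (%)") +
    theme_minimal()
}
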