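#' Eigenvalue-weighted pre-training loss
#'
#' The pre-text-task loss for one molecule: the squared error of each
#' pseudo-label dimension weighted by the corresponding PCA eigenvalue,
#' averaged over the `q` dimensions:
#' `(1/q) * sum_j lambda_j * (z_j - zhat_j)^2`.  Dimensions that carry more
#' descriptor variance therefore dominate the pre-training signal.
#'
#' @param z True pseudo-label vector (length q).
#' @param z_hat Predicted pseudo-label vector (length q).
#' @param eigenvalues Nonnegative eigenvalue weights (length q).
#' @return A single nonnegative number.
#' @export
#' @examples
#' pretrain_loss(c(1, 1), c(0, 0), c(3, 1))  # (3 + 1) / 2 = 2
pretrain_loss <- function(z, z_hat, eigenvalues) {
  if (length(z) != length(z_hat) || length(z) != length(eigenvalues))
    abort("z, z_hat and eigenvalues must have equal length")
  if (any(eigenvalues < 0))
    abort("eigenvalues must be nonnegative")
  mean(eigenvalues * (z - z_hat)^2)
}

# matrix version: rows = molecules; returns per-molecule losses
pretrain_loss_rows <- function(Z, Zhat, eigenvalues) {
  rowMeans(sweep((Z - Zhat)^2, 2, eigenvalues, `*`))
}

#' Pre-training configuration
#'
#' Defaults follow the reference training recipe: 10 epochs of Adam with
#' batch size 128, learning rate 5e-4 and weight decay 1e-5.
#'
#' @param epochs,batch_size,learning_rate,weight_decay Optimizer settings.
#' @param dropout_rate Dropout applied during training forward passes.
#' @param normalize_eigenvalues Divide the eigenvalue weights by their sum
#'   (off by default; the raw eigenvalues enter the loss).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return A named list.
#' @export
pretrain_config <- function(epochs = 10L, batch_size = 128L,
                            learning_rate = 5e-4, weight_decay = 1e-5,
                            dropout_rate = 0.1,
                            normalize_eigenvalues = FALSE, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, weight_decay = weight_decay,
              dropout_rate = dropout_rate,
              normalize_eigenvalues = isTRUE(normalize_eigenvalues),
              seed = as.integer(seed))
  if (cfg$epochs < 0 || cfg$batch_size < 1 || cfg$learning_rate < 0 ||
      cfg$weight_decay < 0 || cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    abort("invalid pre-training configuration",
          class = "ginyield_config_error")
  cfg
}

#' Pre-train the GIN on descriptor pseudo-labels
#'
#' Jointly trains the GIN encoder and a one-layer auxiliary prediction head
#' (`rep_dim -> q`) to predict each molecule's pseudo-label vector under the
#' eigenvalue-weighted loss ([pretrain_loss()]).  Minibatches are reshuffled
#' every epoch with the run seed.
#'
#' @param data A tibble with a `graph` list-column of `molecular_graph`
#'   objects (e.g. from [featurize_smiles()], joined with pseudo-labels)
#'   and pseudo-label columns `pl1 ... plq`.
#' @param eigenvalues Eigenvalue weights, length q; defaults to the
#'   `"eigenvalues"` attribute carried by [make_pseudo_labels()] output.
#' @param gin Optional `gin_parameters` to start from; default builds a
#'   fresh encoder matching the graphs' feature dimensions.
#' @param config See [pretrain_config()].
#' @param verbose Emit a line-oriented JSON log record per epoch.
#' @return An object of class `pretrain_fit`: the trained `gin`, the
#'   auxiliary `head`, the per-epoch loss `history` (epoch 0 is the
#'   deterministic loss before any update), `config` and `eigenvalues`.
#' @export
run_pretraining <- function(data, eigenvalues = attr(data, "eigenvalues"),
                            gin = NULL, config = pretrain_config(),
                            verbose = FALSE) {
  stopifnot(is.data.frame(data), "graph" %in% names(data))
  pl_cols <- grep("^pl[0-9]+$", names(data), value = TRUE)
  if (length(pl_cols) == 0) abort("no pseudo-label columns (pl1, pl2, ...)")
  pl_cols <- paste0("pl", seq_along(pl_cols))
  Z <- as.matrix(data[, pl_cols, drop = FALSE])
  q <- ncol(Z)
  if (is.null(eigenvalues))
    abort("eigenvalues must be supplied (or attached to `data`)")
  if (length(eigenvalues) != q)
    abort(sprintf("head/label dimension mismatch: %d eigenvalues for q = %d",
                  length(eigenvalues), q),
          class = "ginyield_config_error")
  lam <- as.numeric(eigenvalues)
  if (config$normalize_eigenvalues) lam <- lam / sum(lam)

  graphs <- data$graph
  M <- length(graphs)
  set.seed(config$seed)
  if (is.null(gin)) {
    g1 <- graphs[[1]]
    gin <- gin_init(ncol(g1$node_features), ncol(g1$edge_features),
                    seed = config$seed)
  }
  rep_dim <- gin$config$rep_dim
  head <- list(W = init_matrix(rep_dim, q), b = init_bias(rep_dim, q))

  all_w <- c(gin$w, list(head_W = head$W, head_b = head$b))
  opt <- adam_init(all_w)

  eval_loss <- function(w) {
    gin_eval <- gin
    gin_eval$w <- w[names(gin$w)]
    fwd <- gin_forward_batch(gin_eval, batch_graphs(graphs))
    Zhat <- affine(fwd$rep, w$head_W, w$head_b)
    mean(pretrain_loss_rows(Z, Zhat, lam))
  }

  history <- tibble(epoch = 0L, loss = eval_loss(all_w))
  if (verbose)
    message(jsonlite::toJSON(list(phase = "pretrain", epoch = 0,
                                  loss = history$loss[1]), auto_unbox = TRUE))

  for (epoch in seq_len(config$epochs)) {
    order <- sample.int(M)
    starts <- seq(1, M, by = config$batch_size)
    epoch_losses <- numeric(0)
    for (s in starts) {
      idx <- order[s:min(s + config$batch_size - 1, M)]
      B <- length(idx)
      gin$w <- all_w[names(gin$w)]
      fwd <- gin_forward_batch(gin, batch_graphs(graphs[idx]),
                               dropout_rate = config$dropout_rate,
                               stochastic = TRUE, keep_cache = TRUE)
      Zhat <- affine(fwd$rep, all_w$head_W, all_w$head_b)
      diff <- Zhat - Z[idx, , drop = FALSE]
      epoch_losses <- c(epoch_losses,
                        mean(pretrain_loss_rows(Z[idx, , drop = FALSE],
                                                Zhat, lam)))
      dZhat <- sweep(2 * diff, 2, lam, `*`) / (q * B)
      grads <- gin_backward_batch(gin, fwd, dZhat %*% t(all_w$head_W))
      grads$head_W <- t(fwd$rep) %*% dZhat
      grads$head_b <- colSums(dZhat)
      step <- adam_step(all_w, grads, opt, lr = config$learning_rate,
                        weight_decay = config$weight_decay)
      all_w <- step$w
      opt <- step$state
    }
    history <- dplyr::bind_rows(history,
                                tibble(epoch = epoch,
                                       loss = mean(epoch_losses)))
    if (verbose)
      message(jsonlite::toJSON(list(phase = "pretrain", epoch = epoch,
                                    loss = mean(epoch_losses)),
                               auto_unbox = TRUE))
  }

  gin$w <- all_w[names(gin$w)]
  structure(
    list(gin = gin,
         head = list(W = all_w$head_W, b = all_w$head_b),
         history = history,
         config = config,
         eigenvalues = as.numeric(eigenvalues),
         q = q),
    class = "pretrain_fit")
}

#' @export
print.pretrain_fit <- function(x, ...) {
  cat(sprintf(
    "<pretrain_fit> q = %d, %d epochs; loss %.4f -> %.4f\n",
    x$q, max(x$history$epoch), x$history$loss[1],
    x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @method tidy pretrain_fit
#' @export
tidy.pretrain_fit <- function(x, ...) x$history

#' @method glance pretrain_fit
#' @export
glance.pretrain_fit <- function(x, ...) {
  tibble(q = x$q, epochs = max(x$history$epoch),
         initial_loss = x$history$loss[1],
         final_loss = x$history$loss[nrow(x$history)])
}

#' Training-loss curve of a pre-training run
#'
#' @param object A `pretrain_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pretrain_fit
#' @export
autoplot.pretrain_fit <- function(object, ...) {
  ggplot(object$history, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "epoch", y = "eigenvalue-weighted training loss") +
    theme_minimal()
}
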