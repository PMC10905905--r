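#' Initialize GIN encoder parameters
#'
#' Builds the learnable weights of the graph isomorphism network encoder:
#' a one-layer affine node embedder with ReLU (`node_dim -> hidden`), a
#' one-layer linear edge embedder (`edge_dim -> hidden`), `L` two-layer
#' node-update networks (`hidden -> hidden -> hidden`, ReLU hidden layer;
#' ReLU output except a linear output at the last layer), and a one-layer
#' projection to the molecular representation (`hidden -> rep_dim`) with a
#' learnable PReLU activation.
#'
#' The message-passing update at layer `l` gives node `j` the sum, over its
#' incident edges, of `ReLU(neighbour embedding + edge embedding)`, added to
#' the node's own previous embedding before the update network.  The
#' alternative reading in which the message uses the center node's own
#' embedding (which makes messages independent of the neighbours) is
#' available as `message_mode = "literal"`.
#'
#' @param node_dim,edge_dim Feature dimensions (see [schema_dims()]).
#' @param L Number of message-passing layers.
#' @param hidden Embedding width.
#' @param rep_dim Width of the molecular representation.
#' @param message_mode `"neighbor"` (default) or `"literal"`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `gin_parameters`.
#' @export
gin_init <- function(node_dim, edge_dim, L = 3L, hidden = 300L,
                     rep_dim = 1024L,
                     message_mode = c("neighbor", "literal"), seed = 1L) {
  message_mode <- match.arg(message_mode)
  stopifnot(L >= 0, hidden >= 1, rep_dim >= 1)
  set.seed(seed)
  w <- list(
    Wn = init_matrix(node_dim, hidden), bn = init_bias(node_dim, hidden),
    We = init_matrix(edge_dim, hidden), be = init_bias(edge_dim, hidden))
  for (l in seq_len(L)) {
    w[[sprintf("psi%d_W1", l)]] <- init_matrix(hidden, hidden)
    w[[sprintf("psi%d_b1", l)]] <- init_bias(hidden, hidden)
    w[[sprintf("psi%d_W2", l)]] <- init_matrix(hidden, hidden)
    w[[sprintf("psi%d_b2", l)]] <- init_bias(hidden, hidden)
  }
  w$Wr <- init_matrix(hidden, rep_dim)
  w$br <- init_bias(hidden, rep_dim)
  w$prelu <- 0.25
  structure(
    list(config = list(node_dim = node_dim, edge_dim = edge_dim,
                       L = as.integer(L), hidden = as.integer(hidden),
                       rep_dim = as.integer(rep_dim),
                       message_mode = message_mode),
         w = w),
    class = "gin_parameters")
}

#' @export
print.gin_parameters <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<gin_parameters> L = %d, hidden = %d, rep_dim = %d, mode = %s (%s params)\n",
    cfg$L, cfg$hidden, cfg$rep_dim, cfg$message_mode,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total scalar parameter count of a GIN encoder
#'
#' @param params A `gin_parameters` object.
#' @return Integer count of all scalar weights.
#' @export
count_parameters <- function(params) {
  stopifnot(inherits(params, "gin_parameters"))
  sum(vapply(params$w, length, integer(1)))
}

# stack a list of molecular_graph into one node/edge batch
batch_graphs <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offsets <- c(0L, cumsum(n_nodes))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  E <- do.call(rbind, lapply(graphs, `[[`, "edge_features"))
  src <- integer(0); dst <- integer(0)
  for (i in seq_along(graphs)) {
    ei <- graphs[[i]]$edge_index
    if (nrow(ei) > 0) {
      src <- c(src, ei[, "src"] + offsets[i])
      dst <- c(dst, ei[, "dst"] + offsets[i])
    }
  }
  list(X = X, E = E, src = src, dst = dst,
       graph_id = rep(seq_along(graphs), n_nodes),
       n_nodes = n_nodes, n_graphs = length(graphs))
}

# Batched forward pass.  Returns the representation matrix (n_graphs x
# rep_dim) and, when keep_cache, every intermediate needed for backprop.
gin_forward_batch <- function(params, batch, dropout_rate = 0,
                              stochastic = FALSE, keep_cache = FALSE) {
  cfg <- params$config
  w <- params$w
  if (ncol(batch$X) != cfg$node_dim || ncol(batch$E) != cfg$edge_dim)
    abort(sprintf(
      "feature dimensions (%d, %d) do not match encoder schema (%d, %d)",
      ncol(batch$X), ncol(batch$E), cfg$node_dim, cfg$edge_dim),
      class = "ginyield_schema_error")
  n <- nrow(batch$X)
  use_drop <- stochastic && dropout_rate > 0

  pre_n <- affine(batch$X, w$Wn, w$bn)
  H <- relu(pre_n)
  HE <- if (nrow(batch$E) > 0) affine(batch$E, w$We, w$be) else
    matrix(0, 0, cfg$hidden)

  layers <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    Hprev <- H
    if (length(batch$src) > 0) {
      msrc <- if (cfg$message_mode == "neighbor")
        Hprev[batch$src, , drop = FALSE]
      else Hprev[batch$dst, , drop = FALSE]
      Mpre <- msrc + HE
      S <- rowsum_into(relu(Mpre), batch$dst, n)
    } else {
      Mpre <- matrix(0, 0, cfg$hidden)
      S <- matrix(0, n, cfg$hidden)
    }
    AGG <- Hprev + S
    Z1 <- affine(AGG, w[[sprintf("psi%d_W1", l)]], w[[sprintf("psi%d_b1", l)]])
    A1 <- relu(Z1)
    mask1 <- if (use_drop) dropout_mask(nrow(A1), ncol(A1), dropout_rate)
    A1d <- if (!is.null(mask1)) A1 * mask1 else A1
    Z2 <- affine(A1d, w[[sprintf("psi%d_W2", l)]], w[[sprintf("psi%d_b2", l)]])
    H <- if (l < cfg$L) relu(Z2) else Z2
    if (keep_cache)
      layers[[l]] <- list(Hprev = Hprev, Mpre = Mpre, Z1 = Z1, A1d = A1d,
                          mask1 = mask1, Z2 = Z2)
  }

  HG <- rowsum(H, batch$graph_id) / batch$n_nodes
  ZR <- affine(HG, w$Wr, w$br)
  REP0 <- prelu(ZR, w$prelu)
  maskR <- if (use_drop) dropout_mask(nrow(REP0), ncol(REP0), dropout_rate)
  REP <- if (!is.null(maskR)) REP0 * maskR else REP0

  out <- list(rep = REP, pooled = HG, node_final = H, edge_emb = HE)
  if (keep_cache)
    out$cache <- list(batch = batch, pre_n = pre_n, HE = HE, layers = layers,
                      HG = HG, ZR = ZR, maskR = maskR)
  out
}

# Reverse-mode gradients of a scalar loss through the batched forward pass.
# d_rep: gradient w.r.t. the (post-dropout) representation matrix.
gin_backward_batch <- function(params, fwd, d_rep) {
  cfg <- params$config
  w <- params$w
  cache <- fwd$cache
  batch <- cache$batch
  n <- nrow(batch$X)
  g <- list()

  dREP0 <- if (!is.null(cache$maskR)) d_rep * cache$maskR else d_rep
  pos <- cache$ZR > 0
  dZR <- dREP0 * ifelse(pos, 1, w$prelu)
  g$prelu <- sum(dREP0 * cache$ZR * !pos)
  g$Wr <- t(cache$HG) %*% dZR
  g$br <- colSums(dZR)
  dHG <- dZR %*% t(w$Wr)

  dH <- (dHG / batch$n_nodes)[batch$graph_id, , drop = FALSE]
  dHE_total <- matrix(0, nrow(cache$HE), cfg$hidden)

  for (l in rev(seq_len(cfg$L))) {
    ly <- cache$layers[[l]]
    dZ2 <- if (l < cfg$L) dH * (ly$Z2 > 0) else dH
    g[[sprintf("psi%d_W2", l)]] <- t(ly$A1d) %*% dZ2
    g[[sprintf("psi%d_b2", l)]] <- colSums(dZ2)
    dA1d <- dZ2 %*% t(w[[sprintf("psi%d_W2", l)]])
    dZ1 <- dA1d * (ly$Z1 > 0)
    if (!is.null(ly$mask1)) dZ1 <- dZ1 * ly$mask1
    g[[sprintf("psi%d_W1", l)]] <- t(ly$Hprev + rowsum_into(
      relu(ly$Mpre), batch$dst, n)) %*% dZ1
    g[[sprintf("psi%d_b1", l)]] <- colSums(dZ1)
    dAGG <- dZ1 %*% t(w[[sprintf("psi%d_W1", l)]])
    dHprev <- dAGG
    if (length(batch$src) > 0) {
      dM <- dAGG[batch$dst, , drop = FALSE]
      dMpre <- dM * (ly$Mpre > 0)
      if (cfg$message_mode == "neighbor") {
        dHprev <- dHprev + rowsum_into(dMpre, batch$src, n)
      } else {
        dHprev <- dHprev + rowsum_into(dMpre, batch$dst, n)
      }
      dHE_total <- dHE_total + dMpre
    }
    dH <- dHprev
  }

  dpre_n <- dH * (cache$pre_n > 0)
  g$Wn <- t(batch$X) %*% dpre_n
  g$bn <- colSums(dpre_n)
  if (nrow(batch$E) > 0) {
    g$We <- t(batch$E) %*% dHE_total
    g$be <- colSums(dHE_total)
  } else {
    g$We <- w$We * 0
    g$be <- w$be * 0
  }
  g
}

#' Run the GIN encoder on a single molecular graph
#'
#' Embeds nodes and edges, applies the message-passing layers, average-pools
#' the final node embeddings into a graph embedding, and projects it to the
#' molecular representation.  With `stochastic = FALSE` the output is
#' deterministic; with `stochastic = TRUE` dropout is applied to each
#' node-update hidden layer and to the representation.
#'
#' @param graph A `molecular_graph`.
#' @param params A `gin_parameters` object.
#' @param dropout_rate Dropout probability used when `stochastic`.
#' @param stochastic Apply dropout?
#' @return A list of class `graph_embedding` with `node_embeddings` (final
#'   layer), `edge_embeddings`, `pooled` (graph embedding, mean of final
#'   node embeddings) and `representation`.
#' @export
gin_forward <- function(graph, params, dropout_rate = 0,
                        stochastic = FALSE) {
  stopifnot(inherits(graph, "molecular_graph"),
            inherits(params, "gin_parameters"))
  fwd <- gin_forward_batch(params, batch_graphs(list(graph)),
                           dropout_rate = dropout_rate,
                           stochastic = stochastic)
  structure(
    list(node_embeddings = fwd$node_final,
         edge_embeddings = fwd$edge_emb,
         pooled = drop(fwd$pooled),
         representation = drop(fwd$rep)),
    class = "graph_embedding")
}

#' @export
print.graph_embedding <- function(x, ...) {
  cat(sprintf("<graph_embedding> %d nodes -> representation[%d]\n",
              nrow(x$node_embeddings), length(x$representation)))
  invisible(x)
}

# --- checkpoints ----------------------------------------------------------

checkpoint_manifest <- function(params, extra = list()) {
  c(list(format = "ginyield-checkpoint", version = 1L,
         config = params$config), extra)
}

#' Save / load encoder checkpoints
#'
#' A checkpoint stores the named weight tensors together with a manifest
#' (schema dimensions, layer count, widths, message mode) so that
#' fine-tuning can verify architectural compatibility before loading.
#'
#' @param object A list with at least `gin` (a `gin_parameters`); typically
#'   a `pretrain_fit` or `yield_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the stored list.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object$gin, "gin_parameters"))
  object$manifest <- checkpoint_manifest(object$gin,
                                         object$manifest %||% list())
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_config Optional config list to validate against (e.g.
#'   `gin_init(...)$config`); mismatching fields are reported and loading
#'   is refused.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  object <- readRDS(path)
  mf <- object$manifest
  if (is.null(mf) || !identical(mf$format, "ginyield-checkpoint"))
    abort("not a ginyield checkpoint", class = "ginyield_manifest_error")
  if (!is.null(expect_config)) {
    fields <- c("node_dim", "edge_dim", "L", "hidden", "rep_dim",
                "message_mode")
    bad <- fields[vapply(fields, function(f)
      !identical(mf$config[[f]], expect_config[[f]]), logical(1))]
    if (length(bad) > 0)
      abort(sprintf(
        "checkpoint incompatible with target architecture; mismatched: %s",
        paste(sprintf("%s (checkpoint %s, target %s)", bad,
                      vapply(mf$config[bad], format, character(1)),
                      vapply(expect_config[bad], format, character(1))),
              collapse = "; ")),
        class = "ginyield_manifest_error")
  }
  object
}
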