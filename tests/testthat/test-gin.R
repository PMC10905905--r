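test_that("parameter count follows the closed-form sum of affine layer sizes", {
  nd <- 70; ed <- 13; H <- 12; R <- 9
  g <- gin_init(nd, ed, L = 3, hidden = H, rep_dim = R, seed = 1)
  closed_form <- (nd * H + H) + (ed * H + H) +
    3 * 2 * (H * H + H) +
    (H * R + R) + 1            # projection + PReLU slope
  expect_equal(count_parameters(g), closed_form)

  # doubling L adds exactly the parameters of the extra update networks
  g6 <- gin_init(nd, ed, L = 6, hidden = H, rep_dim = R, seed = 1)
  expect_equal(count_parameters(g6) - count_parameters(g),
               3 * 2 * (H * H + H))

  # L = 0 degenerate: only embedders and projection remain
  g0 <- gin_init(nd, ed, L = 0, hidden = H, rep_dim = R, seed = 1)
  expect_equal(count_parameters(g0),
               (nd * H + H) + (ed * H + H) + (H * R + R) + 1)
})

test_that("a single-node graph reduces to chained update networks with trivial pooling", {
  gin <- tiny_gin()
  g <- featurize_molecule("C")
  emb <- gin_forward(g, gin)
  # pooled graph embedding equals the single final node embedding
  expect_equal(emb$pooled, emb$node_embeddings[1, ], tolerance = 1e-12)

  # the neighbour sum is empty, so the forward pass is psi_L(...psi_1(h0))
  w <- gin$w
  h <- pmax(g$node_features %*% w$Wn + w$bn, 0)
  for (l in seq_len(gin$config$L)) {
    z1 <- h %*% w[[sprintf("psi%d_W1", l)]] + w[[sprintf("psi%d_b1", l)]]
    h <- pmax(z1, 0) %*% w[[sprintf("psi%d_W2", l)]] +
      w[[sprintf("psi%d_b2", l)]]
    if (l < gin$config$L) h <- pmax(h, 0)
  }
  expect_equal(emb$pooled, h[1, ], tolerance = 1e-10)
})

test_that("the representation is invariant to node relabelling", {
  gin <- tiny_gin()
  smiles <- c("CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1", "CC(C)CC(N)C(=O)O",
              "FC(F)(F)c1ccc(Br)cc1", "C1CCOC1")
  set.seed(55)
  worst <- 0
  for (smi in smiles) {
    g <- featurize_molecule(smi)
    ref <- gin_forward(g, gin)$representation
    for (k in 1:10) {
      perm <- sample(nrow(g$node_features))
      gp <- permute_graph(g, perm)
      d <- max(abs(gin_forward(gp, gin)$representation - ref))
      worst <- max(worst, d)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("a two-node forward pass matches a hand-executed scalar oracle", {
  # minimal dimensions with hand-set weights
  gin <- gin_init(node_dim = 2, edge_dim = 1, L = 1, hidden = 2,
                  rep_dim = 2, seed = 1)
  gin$w$Wn <- diag(2); gin$w$bn <- c(0, 0)
  gin$w$We <- matrix(c(1, -1), 1, 2); gin$w$be <- c(0.5, 0)
  gin$w$psi1_W1 <- matrix(c(1, 0.5, -0.5, 1), 2, 2); gin$w$psi1_b1 <- c(0, 0.1)
  gin$w$psi1_W2 <- diag(2); gin$w$psi1_b2 <- c(-0.2, 0)
  gin$w$Wr <- matrix(c(1, 0, 1, 1), 2, 2); gin$w$br <- c(0, -10)
  gin$w$prelu <- 0.25

  graph <- structure(list(
    node_features = rbind(c(1, 2), c(3, -1)),
    edge_index = cbind(src = c(1L, 2L), dst = c(2L, 1L)),
    edge_features = rbind(2, 2),
    smiles = "toy", elements = c("C", "C")), class = "molecular_graph")

  # scalar oracle, written out step by step
  relu0 <- function(x) pmax(x, 0)
  h1 <- relu0(c(1, 2))                    # node 1 embedding (Wn = I)
  h2 <- relu0(c(3, -1))
  he <- c(2 * 1 + 0.5, 2 * -1 + 0)        # edge embedding, both directions
  m_into_1 <- relu0(h2 + he)              # neighbour message k=2 -> j=1
  m_into_2 <- relu0(h1 + he)
  a1 <- h1 + m_into_1
  a2 <- h2 + m_into_2
  psi <- function(a) {
    z1 <- c(a[1] * 1 + a[2] * 0.5, a[1] * -0.5 + a[2] * 1 + 0.1)
    relu0(z1) %*% diag(2) + c(-0.2, 0)    # linear output (last layer)
  }
  hg <- (psi(a1) + psi(a2)) / 2
  zr <- c(hg[1], hg[1] + hg[2] - 10)
  expected <- ifelse(zr > 0, zr, 0.25 * zr)

  emb <- gin_forward(graph, gin)
  expect_equal(emb$representation, expected, tolerance = 1e-12)
})

test_that("deterministic mode is bit-reproducible; dropout mode is not a no-op", {
  gin <- tiny_gin()
  g <- featurize_molecule("CCOc1ccccc1")
  a <- gin_forward(g, gin)$representation
  b <- gin_forward(g, gin)$representation
  expect_identical(a, b)
  set.seed(1)
  s1 <- gin_forward(g, gin, dropout_rate = 0.3, stochastic = TRUE)$representation
  s2 <- gin_forward(g, gin, dropout_rate = 0.3, stochastic = TRUE)$representation
  expect_false(identical(s1, s2))
})

test_that("node embeddings only see the L-hop neighbourhood", {
  gin <- tiny_gin(L = 2)
  g <- featurize_molecule("CCCCCCCC")   # 8-carbon path
  base <- gin_forward(g, gin)$node_embeddings
  g2 <- g
  g2$node_features[8, ] <- 1 - g2$node_features[8, ]  # perturb far-end node
  pert <- gin_forward(g2, gin)$node_embeddings
  # node 1 is 7 hops from node 8 > L = 2: unchanged
  expect_equal(pert[1, ], base[1, ], tolerance = 1e-12)
  # a node within L hops of the perturbation changes
  expect_false(isTRUE(all.equal(pert[7, ], base[7, ])))
})

test_that("analytic gradients match finite differences", {
  sch <- default_feature_schema()
  gin <- tiny_gin(L = 2, hidden = 7, rep_dim = 5, seed = 3)
  batch <- batch_graphs_for_test(c("CCO", "c1ccccc1", "C"))
  fwd <- ginyield:::gin_forward_batch(gin, batch, keep_cache = TRUE)
  set.seed(9)
  Wf <- matrix(rnorm(3 * 5), 3, 5)
  loss_fn <- function(w) {
    gg <- gin; gg$w <- w
    sum(ginyield:::gin_forward_batch(gg, batch)$rep * Wf)
  }
  grads <- ginyield:::gin_backward_batch(gin, fwd, Wf)
  set.seed(10)
  for (nm in names(gin$w)) {
    x <- gin$w[[nm]]
    idxs <- if (length(x) > 3) sample(length(x), 3) else seq_along(x)
    for (i in idxs) {
      h <- 1e-5
      wp <- gin$w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- gin$w; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (loss_fn(wp) - loss_fn(wm)) / (2 * h)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-5,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip bit-identically and refuse mismatched architectures", {
  gin <- tiny_gin()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(list(gin = gin), path)
  back <- load_checkpoint(path, expect_config = gin$config)
  expect_identical(back$gin$w, gin$w)

  other <- tiny_gin(hidden = 8L)
  expect_error(load_checkpoint(path, expect_config = other$config),
               "hidden", class = "ginyield_manifest_error")
})
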