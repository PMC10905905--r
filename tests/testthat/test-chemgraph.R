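# block boundaries of the one-hot node feature layout, derived from the
# schema definition independently of the featurizer's internals
node_onehot_blocks <- function(schema) {
  widths <- c(element = length(schema$elements) + 1L,
              charge = length(schema$charges) + 1L,
              degree = length(schema$degrees) + 1L,
              hybrid = length(schema$hybridization) + 1L,
              hcount = length(schema$h_counts) + 1L,
              valence = length(schema$valences) + 1L,
              chirality = length(schema$chirality) + 1L)
  ends <- cumsum(widths)
  mapply(function(s, e) s:e, ends - widths + 1L, ends, SIMPLIFY = FALSE)
}

test_that("single-heavy-atom, aromatic-ring and two-atom molecules featurize as expected", {
  sch <- default_feature_schema()
  blocks <- node_onehot_blocks(sch)

  methane <- featurize_molecule("C", sch)
  expect_equal(nrow(methane$node_features), 1)
  expect_equal(nrow(methane$edge_index), 0)
  # adjacent-hydrogen block encodes the value 4 (categories 0:6 + overflow)
  hblock <- methane$node_features[1, blocks$hcount]
  expect_equal(which(hblock == 1), 5L)

  benzene <- featurize_molecule("c1ccccc1", sch)
  expect_equal(nrow(benzene$node_features), 6)
  expect_equal(nrow(benzene$edge_index), 12)
  nf <- benzene$node_features
  n_onehot <- max(blocks$chirality)
  ring_flags <- nf[, n_onehot + seq_along(sch$ring_sizes), drop = FALSE]
  expect_true(all(ring_flags[, which(sch$ring_sizes == 6)] == 1))
  aromatic_col <- ncol(nf) - 1L
  in_ring_col <- ncol(nf)
  expect_true(all(nf[, aromatic_col] == 1))
  expect_true(all(nf[, in_ring_col] == 1))
  # every edge row has aromatic bond type (4th slot of the bond-type block)
  expect_true(all(benzene$edge_features[, 4] == 1))

  ethane <- featurize_molecule("CC", sch)
  expect_equal(nrow(ethane$node_features), 2)
  expect_equal(nrow(ethane$edge_index), 2)
  ef <- ethane$edge_features
  expect_true(all(ef[, 1] == 1))              # single bond
  expect_equal(sum(ef[, ncol(ef)]), 0)        # not conjugated
  expect_equal(sum(ef[, ncol(ef) - 1L]), 0)   # not in ring
})

test_that("every one-hot block sums to exactly one per node row", {
  sch <- default_feature_schema()
  blocks <- node_onehot_blocks(sch)
  for (smi in c("CCO", "c1ccccc1", "[Na+].[O-]C(=O)C", "F[Pd]Cl",
                "N[C@@H](C)C(=O)O", "C#N", "O=S(=O)(O)O")) {
    g <- featurize_molecule(smi, sch)
    for (b in blocks)
      expect_equal(unname(rowSums(g$node_features[, b, drop = FALSE])),
                   rep(1, nrow(g$node_features)), info = smi)
    # edge one-hot blocks: bond type (5), stereo (6)
    if (nrow(g$edge_index) > 0) {
      expect_equal(unname(rowSums(g$edge_features[, 1:5, drop = FALSE])),
                   rep(1, nrow(g$edge_features)), info = smi)
      expect_equal(unname(rowSums(g$edge_features[, 6:11, drop = FALSE])),
                   rep(1, nrow(g$edge_features)), info = smi)
    }
  }
})

test_that("featurization is deterministic and invariant to input atom order", {
  a <- featurize_molecule("CCO")
  b <- featurize_molecule("CCO")
  expect_identical(a$node_features, b$node_features)
  expect_identical(a$edge_features, b$edge_features)

  # alternative writings canonicalize to the same graph
  for (pair in list(c("OCC", "CCO"),
                    c("C1=CC=CC=C1", "c1ccccc1"),
                    c("C(C)O", "CCO"))) {
    g1 <- featurize_molecule(pair[1])
    g2 <- featurize_molecule(pair[2])
    expect_identical(g1$smiles, g2$smiles)
    expect_identical(g1$node_features, g2$node_features)
    expect_identical(g1$edge_index, g2$edge_index)
  }
})

test_that("each bond is stored in both directions with identical features", {
  for (smi in c("CCO", "c1ccncc1", "CC(=O)O")) {
    g <- featurize_molecule(smi)
    key <- paste(g$edge_index[, "src"], g$edge_index[, "dst"])
    rev_key <- paste(g$edge_index[, "dst"], g$edge_index[, "src"])
    expect_setequal(key, rev_key)
    for (i in seq_along(key)) {
      j <- match(rev_key[i], key)
      expect_equal(g$edge_features[i, ], g$edge_features[j, ], info = smi)
    }
    expect_false(any(g$edge_index[, "src"] == g$edge_index[, "dst"]))
  }
})

test_that("unparsable or hypervalent SMILES are rejected with the offending string", {
  expect_error(featurize_molecule("C1CC"), "C1CC",
               class = "ginyield_sanitize_error")
  expect_error(featurize_molecule("not-a-smiles"),
               class = "ginyield_sanitize_error")
  expect_error(featurize_molecule("C(C)(C)(C)(C)C"), "valence",
               class = "ginyield_sanitize_error")
})

test_that("directional bonds map to E and Z stereo categories", {
  stereo_block <- function(g) g$edge_features[, 6:11, drop = FALSE]
  # categories: none, Z, E, cis, trans, any
  trans <- featurize_molecule("F/C=C/F")
  cis <- featurize_molecule("F/C=C\\F")
  expect_true(any(stereo_block(trans)[, 3] == 1))  # E
  expect_false(any(stereo_block(trans)[, 2] == 1))
  expect_true(any(stereo_block(cis)[, 2] == 1))    # Z
  expect_false(any(stereo_block(cis)[, 3] == 1))
  plain <- featurize_molecule("C=C")
  expect_true(all(stereo_block(plain)[, 1] == 1))  # none
})

test_that("reaction SMILES splits into m reactant graphs and one product", {
  rx <- featurize_reaction("CC.O>>CCO")
  expect_length(rx$reactants, 2)
  expect_s3_class(rx$product, "molecular_graph")

  ident <- featurize_reaction("C>>C")
  expect_identical(ident$reactants[[1]]$node_features,
                   ident$product$node_features)

  expect_error(featurize_reaction("CC.O"), class = "ginyield_format_error")
  expect_error(featurize_reaction("CC>>CCO.O"),
               class = "ginyield_format_error")
  expect_error(featurize_reaction("CC>>"), class = "ginyield_format_error")
  # a failing component is named in the error
  expect_error(featurize_reaction("C1CC.O>>CCO"), "reactant 1",
               class = "ginyield_sanitize_error")
  expect_error(featurize_reaction("CC.O>>C1CC"), "product",
               class = "ginyield_sanitize_error")
})

test_that("featurize_smiles keeps valid rows and reports rejections", {
  dat <- tibble::tibble(smiles = c("CCO", "C1CC", "c1ccccc1"))
  out <- featurize_smiles(dat)
  expect_equal(nrow(out), 2)
  expect_equal(out$n_atoms, c(3, 6))
  rej <- attr(out, "rejections")
  expect_equal(rej$smiles, "C1CC")
})

test_that("feature schema survives a JSON round trip", {
  sch <- default_feature_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_schema(sch, path)
  sch2 <- read_feature_schema(path)
  expect_identical(schema_dims(sch), schema_dims(sch2))
  g1 <- featurize_molecule("CC(=O)O", sch)
  g2 <- featurize_molecule("CC(=O)O", sch2)
  expect_identical(g1$node_features, g2$node_features)
})
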