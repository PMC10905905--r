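# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small synthetic corpus shared across module tests
fixture_corpus <- function() {
  memo("corpus", generate_synthetic_corpus(
    synthetic_spec(num_molecules = 80, num_reactions = 60,
                   noise_sd = 5, seed = 101)))
}

fixture_molecules <- function() {
  memo("molecules", featurize_smiles(fixture_corpus()$molecules, "smiles"))
}

fixture_reactions <- function() {
  memo("reactions", featurize_reactions(fixture_corpus()$reactions))
}

# descriptors -> filter -> labels for the fixture corpus
fixture_labels <- function() {
  memo("labels", {
    desc <- compute_descriptors(fixture_corpus()$molecules, "smiles")
    fs <- filter_and_standardize(desc)
    labeler <- fit_pseudo_labeler(fs$data)
    labels <- make_pseudo_labels(labeler, fs$data)
    list(desc = desc, fs = fs, labeler = labeler, labels = labels)
  })
}

# pre-training input: graphs joined with pseudo-labels
fixture_pretrain_data <- function() {
  memo("pretrain_data", {
    fl <- fixture_labels()
    mols <- fixture_molecules()
    dat <- dplyr::inner_join(mols, fl$labels,
                             by = c("smiles" = "molecule"))
    attr(dat, "eigenvalues") <- attr(fl$labels, "eigenvalues")
    dat
  })
}

# a small encoder (reduced widths) for fast property tests
tiny_gin <- function(L = 2L, hidden = 16L, rep_dim = 12L, seed = 7L,
                     schema = default_feature_schema(), ...) {
  d <- schema_dims(schema)
  gin_init(d$node_dim, d$edge_dim, L = L, hidden = hidden,
           rep_dim = rep_dim, seed = seed, ...)
}

# permute the nodes of a molecular_graph (relabelling edges accordingly)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  out <- g
  out$node_features <- g$node_features[perm, , drop = FALSE]
  if (nrow(g$edge_index) > 0) {
    out$edge_index <- cbind(src = inv[g$edge_index[, "src"]],
                            dst = inv[g$edge_index[, "dst"]])
  }
  out$elements <- g$elements[perm]
  out
}

batch_graphs_for_test <- function(smiles) {
  ginyield:::batch_graphs(lapply(smiles, featurize_molecule))
}
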