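# Synthetic molecule and reaction generator.
#
# A small fragment grammar (substituted aromatic/aliphatic cores with
# halide, amine, ether, nitrile, boronic-acid-like substituents) produces
# valid, sanitizable SMILES; reactions sample m reactants plus a product
# from the molecule pool and receive a yield that is a fixed smooth
# (logistic) function of graph-level covariates -- quantities the 2D
# descriptor set captures directly, so descriptor-guided pre-training is
# provably informative for the synthetic task.  The generator emulates the
# structure-property link of HTE yield data, not reaction chemistry: the
# product is not a chemical transformation of the reactants.

#' Specification for the synthetic corpus generator
#'
#' @param num_molecules Number of distinct molecules in the pool.
#' @param num_reactions Number of reactions to assemble.
#' @param max_heavy_atoms Upper bound on heavy atoms per molecule.
#' @param m_range Integer range (min, max) of reactants per reaction.
#' @param yield_fun Identifier of the yield function (one implemented:
#'   `"graph_logistic"`).
#' @param noise_sd Yield noise SD in percent points.
#' @param heteroscedastic If `TRUE`, the noise SD grows with the total
#'   heavy-atom count of the participants.
#' @param seed RNG seed; the corpus is a pure function of the spec.
#' @return A named list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(num_molecules = 500L, num_reactions = 300L,
                           max_heavy_atoms = 12L, m_range = c(2L, 4L),
                           yield_fun = "graph_logistic", noise_sd = 5,
                           heteroscedastic = FALSE, seed = 1L) {
  if (m_range[1] > m_range[2] || m_range[1] < 1)
    abort("invalid reactant arity range", class = "ginyield_parameter_error")
  if (noise_sd < 0)
    abort("`noise_sd` must be nonnegative", class = "ginyield_parameter_error")
  if (!identical(yield_fun, "graph_logistic"))
    abort("unknown yield function", class = "ginyield_parameter_error")
  structure(
    list(num_molecules = as.integer(num_molecules),
         num_reactions = as.integer(num_reactions),
         max_heavy_atoms = as.integer(max_heavy_atoms),
         m_range = as.integer(m_range), yield_fun = yield_fun,
         noise_sd = noise_sd, heteroscedastic = isTRUE(heteroscedastic),
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

synthetic_grammar <- function() {
  list(
    cores = list(
      list(template = "c1ccc(%s)cc1", slots = 1L),
      list(template = "c1ccc(%s)c(%s)c1", slots = 2L),
      list(template = "c1cc(%s)cc(%s)c1", slots = 2L),
      list(template = "c1ccnc(%s)c1", slots = 1L),
      list(template = "c1cnc(%s)c(%s)c1", slots = 2L),
      list(template = "c1cc(%s)co1", slots = 1L),
      list(template = "c1cc(%s)cs1", slots = 1L),
      list(template = "C1CCC(%s)CC1", slots = 1L),
      list(template = "C1CC(%s)C(%s)C1", slots = 2L),
      list(template = "C1CC(%s)CO1", slots = 1L),
      list(template = "C1CCN(%s)C1", slots = 1L),
      list(template = "CC(%s)C", slots = 1L),
      list(template = "CC(%s)C%s", slots = 2L),
      list(template = "CCC%s", slots = 1L),
      list(template = "CCOC%s", slots = 1L),
      list(template = "CCNC(=O)%s", slots = 1L)
    ),
    substituents = c("", "C", "CC", "O", "N", "F", "Cl", "Br", "OC",
                     "C#N", "C(F)(F)F", "B(O)O", "S", "C=C", "CN", "C(=O)O")
  )
}

# graph-level covariates entering the yield function
synthetic_covariates <- function(profile) {
  n <- profile$n
  comp <- if (nrow(profile$bonds) == 0) n else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(profile$bonds[, c("a1", "a2"), drop = FALSE]))
    igraph::count_components(g)
  }
  c(heavy = n,
    rings = nrow(profile$bonds) - n + comp,
    f_het = mean(profile$elements != "C"),
    f_arom = mean(profile$aromatic))
}

# fixed smooth yield surface on [0, 100]
synthetic_yield_fun <- function(reactant_cov, product_cov) {
  x_size <- mean(vapply(reactant_cov, `[[`, numeric(1), "heavy"))
  x_ring <- product_cov[["rings"]]
  x_het <- mean(c(vapply(reactant_cov, `[[`, numeric(1), "f_het"),
                  product_cov[["f_het"]]))
  x_arom <- product_cov[["f_arom"]]
  eta <- 0.35 * (x_size - 7) + 0.8 * (x_ring - 1) +
    4.0 * (x_het - 0.2) - 1.5 * (x_arom - 0.3)
  100 * stats::plogis(eta)
}

#' Generate a synthetic molecule/reaction corpus
#'
#' Molecules are assembled from the fragment grammar until
#' `num_molecules` distinct SMILES pass the same sanitization gate as real
#' inputs; reactions draw `m` distinct reactants and one product from the
#' pool.  The noiseless yield is a fixed logistic function of graph-level
#' covariates (mean reactant size, product ring count, heteroatom fraction,
#' product aromaticity); Gaussian noise is added (optionally with SD
#' growing in the participants' total heavy-atom count) and the result is
#' clamped to \[0, 100\].
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `molecules` (tibble: `smiles`, covariates) and
#'   `reactions` (tibble: `id`, `reaction_smiles`, `yield`, `m`,
#'   `yield_true`, `noise_sd_true`, `size_covariate`).
#' @export
generate_synthetic_corpus <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  gr <- synthetic_grammar()

  smiles <- character(0)
  profiles <- list()
  attempts <- 0L
  max_attempts <- 200L * spec$num_molecules
  while (length(smiles) < spec$num_molecules && attempts < max_attempts) {
    attempts <- attempts + 1L
    core <- gr$cores[[sample.int(length(gr$cores), 1)]]
    subs <- sample(gr$substituents, core$slots, replace = TRUE)
    cand <- do.call(sprintf, c(list(core$template), as.list(subs)))
    cand <- gsub("()", "", cand, fixed = TRUE)  # empty substituent slots
    prof <- tryCatch(mol_profile(cand), error = function(e) NULL)
    if (is.null(prof)) next
    if (prof$n > spec$max_heavy_atoms) next
    if (prof$smiles %in% smiles) next
    smiles <- c(smiles, prof$smiles)
    profiles[[length(profiles) + 1L]] <- prof
  }
  if (length(smiles) < spec$num_molecules)
    abort("fragment grammar exhausted before reaching num_molecules",
          class = "ginyield_parameter_error")

  covs <- lapply(profiles, synthetic_covariates)
  molecules <- dplyr::bind_cols(
    tibble(smiles = smiles),
    as_tibble(do.call(rbind, covs)))

  n_pool <- length(smiles)
  ms <- sample(seq(spec$m_range[1], spec$m_range[2]),
               spec$num_reactions, replace = TRUE)
  reactant_idx <- lapply(ms, function(m) sample.int(n_pool, m))
  product_idx <- sample.int(n_pool, spec$num_reactions, replace = TRUE)

  y_true <- numeric(spec$num_reactions)
  size_cov <- numeric(spec$num_reactions)
  for (i in seq_len(spec$num_reactions)) {
    rc <- covs[reactant_idx[[i]]]
    y_true[i] <- synthetic_yield_fun(rc, covs[[product_idx[i]]])
    size_cov[i] <- sum(vapply(rc, `[[`, numeric(1), "heavy")) +
      covs[[product_idx[i]]][["heavy"]]
  }
  sd_i <- if (spec$heteroscedastic) {
    rng <- range(size_cov)
    u <- if (diff(rng) > 0) (size_cov - rng[1]) / diff(rng) else rep(0.5,
      length(size_cov))
    spec$noise_sd * (0.3 + 1.4 * u)
  } else rep(spec$noise_sd, spec$num_reactions)
  y <- pmin(pmax(y_true + stats::rnorm(spec$num_reactions, 0, sd_i), 0), 100)

  reactions <- tibble(
    id = as.character(seq_len(spec$num_reactions)),
    reaction_smiles = vapply(seq_len(spec$num_reactions), function(i)
      paste0(paste(smiles[reactant_idx[[i]]], collapse = "."), ">>",
             smiles[product_idx[i]]), character(1)),
    yield = y,
    m = ms,
    yield_true = y_true,
    noise_sd_true = sd_i,
    size_covariate = size_cov)

  list(molecules = molecules, reactions = reactions)
}

#' Featurize the reactions of a synthetic corpus
#'
#' Convenience wrapper attaching a `rxn` list-column of featurized
#' reactions (memoizing per-molecule featurization across reactions).
#'
#' @param reactions The `reactions` tibble of a synthetic corpus.
#' @param schema A feature schema.
#' @return The tibble with a `rxn` list-column appended.
#' @export
featurize_reactions <- function(reactions,
                                schema = default_feature_schema()) {
  cache <- new.env(parent = emptyenv())
  feat1 <- function(s) {
    g <- cache[[s]]
    if (is.null(g)) {
      g <- featurize_molecule(s, schema)
      cache[[s]] <- g
    }
    g
  }
  reactions$rxn <- lapply(reactions$reaction_smiles, function(rs) {
    parts <- strsplit(rs, ">>", fixed = TRUE)[[1]]
    list(reactants = lapply(strsplit(parts[1], ".", fixed = TRUE)[[1]],
                            feat1),
         product = feat1(parts[2]))
  })
  reactions
}
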