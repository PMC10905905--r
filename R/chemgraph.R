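#' Featurize a molecule into a node/edge-attributed graph
#'
#' Converts a SMILES string into the molecular-graph representation used by
#' the GIN encoder: one node per heavy atom (hydrogens are folded into the
#' adjacent-hydrogen-count node feature), one pair of directed edges per
#' chemical bond (each bond is stored in both directions with identical
#' features, so incoming-message sums can index edges directly).
#'
#' Node feature blocks: element, formal charge, heavy-atom degree,
#' hybridization, attached hydrogens, total valence, chirality tag,
#' ring-size flags (3-8), hydrogen-bond donor/acceptor flags, aromaticity,
#' in-ring flag.  Edge feature blocks: bond type, stereochemistry (E/Z from
#' directional SMILES bonds), in-ring flag, conjugation flag.
#'
#' The string is first sanitized and canonicalized with Open Babel; strings
#' that fail to parse, or whose atoms exceed standard valences, are rejected
#' with an error naming the offending SMILES.
#'
#' @param smiles A single SMILES string.
#' @param schema A [default_feature_schema()] object.
#' @return An object of class `molecular_graph` with fields `node_features`
#'   (num_nodes x node_dim matrix), `edge_index` (num_directed_edges x 2
#'   integer matrix of (src, dst) pairs), `edge_features`, `smiles`
#'   (canonical form), and `elements`.
#' @export
#' @examples
#' g <- featurize_molecule("c1ccccc1")
#' g$smiles
#' nrow(g$node_features)
featurize_molecule <- function(smiles, schema = default_feature_schema()) {
  stopifnot(is.character(smiles), length(smiles) == 1L,
            inherits(schema, "feature_schema"))
  p <- mol_profile(smiles)
  n <- p$n
  bonds <- p$bonds
  rings <- p$rings
  valence <- as.integer(p$order_sum + p$hs)

  is_no <- p$elements %in% c("N", "O")
  donor <- is_no & p$hs >= 1L
  acceptor <- is_no & p$charges <= 0L &
    !(p$elements == "N" & (p$order_sum + p$hs) >= 4)

  node_rows <- lapply(seq_len(n), function(j) {
    c(one_hot(p$elements[j], schema$elements),
      one_hot(p$charges[j], schema$charges),
      one_hot(p$degree[j], schema$degrees),
      one_hot(p$hyb[j], schema$hybridization),
      one_hot(p$hs[j], schema$h_counts),
      one_hot(valence[j], schema$valences),
      one_hot(p$chirality[j], schema$chirality),
      as.numeric(rings$sizes[j, schema$ring_sizes]),
      as.numeric(donor[j]), as.numeric(acceptor[j]),
      as.numeric(p$aromatic[j]), as.numeric(rings$atom[j]))
  })
  node_features <- do.call(rbind, node_rows)

  pi_capable <- function(j, b_excl) {
    inc <- which((bonds[, "a1"] == j | bonds[, "a2"] == j) &
                   seq_len(nrow(bonds)) != b_excl)
    has_multiple <- any(bonds[inc, "order"] > 1) ||
      any(p$aromatic[setdiff(c(bonds[inc, "a1"], bonds[inc, "a2"]), j)] &
            p$aromatic[j])
    lone_pair <- p$elements[j] %in% c("N", "O", "S") && p$charges[j] <= 0 &&
      !(p$elements[j] == "N" & (p$order_sum[j] + p$hs[j]) >= 4)
    has_multiple || lone_pair
  }

  dims <- schema_dims(schema)
  if (nrow(bonds) > 0) {
    edge_rows <- lapply(seq_len(nrow(bonds)), function(b) {
      a1 <- bonds[b, "a1"]; a2 <- bonds[b, "a2"]
      arom_bond <- rings$bond[b] && p$aromatic[a1] && p$aromatic[a2]
      btype <- if (arom_bond) "aromatic" else
        c("single", "double", "triple")[min(bonds[b, "order"], 3L)]
      stereo <- p$stereo[[paste(min(a1, a2), max(a1, a2), sep = "-")]] %||% "none"
      conj <- arom_bond || (pi_capable(a1, b) && pi_capable(a2, b) &&
                              (p$hyb[a1] %in% c("sp", "sp2")) &&
                              (p$hyb[a2] %in% c("sp", "sp2")))
      c(one_hot(btype, schema$bond_types),
        one_hot(stereo, schema$bond_stereo, other = FALSE),
        as.numeric(rings$bond[b]), as.numeric(conj))
    })
    ef1 <- do.call(rbind, edge_rows)
    edge_index <- rbind(cbind(bonds[, "a1"], bonds[, "a2"]),
                        cbind(bonds[, "a2"], bonds[, "a1"]))
    edge_features <- rbind(ef1, ef1)
  } else {
    edge_index <- matrix(integer(0), 0, 2)
    edge_features <- matrix(numeric(0), 0, dims$edge_dim)
  }
  colnames(edge_index) <- c("src", "dst")

  structure(
    list(node_features = node_features,
         edge_index = edge_index,
         edge_features = edge_features,
         smiles = p$smiles,
         elements = p$elements),
    class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d nodes, %d directed edges\n",
              x$smiles, nrow(x$node_features), nrow(x$edge_index)))
  invisible(x)
}

#' Featurize a reaction SMILES into reactant and product graphs
#'
#' A reaction SMILES has the form `"r1.r2.<...>.rm>>product"`: `m >= 1`
#' dot-separated reactants on the left of the `>>` separator and exactly one
#' product on the right.  Every component is featurized with
#' [featurize_molecule()]; a component that fails sanitization is reported
#' by name.
#'
#' @param reaction_smiles A single reaction SMILES string.
#' @param schema A feature schema.
#' @return A list with elements `reactants` (list of `molecular_graph`,
#'   length m) and `product` (a single `molecular_graph`).
#' @export
#' @examples
#' rx <- featurize_reaction("CC.O>>CCO")
#' length(rx$reactants)
featurize_reaction <- function(reaction_smiles,
                               schema = default_feature_schema()) {
  stopifnot(is.character(reaction_smiles), length(reaction_smiles) == 1L)
  parts <- strsplit(reaction_smiles, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !grepl(">>", reaction_smiles, fixed = TRUE))
    abort(sprintf("reaction SMILES must contain one '>>': '%s'",
                  reaction_smiles), class = "ginyield_format_error")
  lhs <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
  rhs <- strsplit(parts[2], ".", fixed = TRUE)[[1]]
  if (length(rhs) != 1L || !nzchar(parts[2]))
    abort(sprintf("expected exactly one product, got %d: '%s'",
                  length(rhs), reaction_smiles),
          class = "ginyield_format_error")
  if (length(lhs) < 1L || any(!nzchar(lhs)))
    abort(sprintf("expected at least one reactant: '%s'", reaction_smiles),
          class = "ginyield_format_error")
  reactants <- lapply(seq_along(lhs), function(i) {
    tryCatch(featurize_molecule(lhs[i], schema), error = function(e)
      abort(sprintf("reactant %d ('%s') rejected: %s", i, lhs[i],
                    conditionMessage(e)),
            class = "ginyield_sanitize_error"))
  })
  product <- tryCatch(featurize_molecule(rhs, schema), error = function(e)
    abort(sprintf("product ('%s') rejected: %s", rhs, conditionMessage(e)),
          class = "ginyield_sanitize_error"))
  list(reactants = reactants, product = product)
}

#' Featurize a column of SMILES strings
#'
#' Data-frame-first wrapper over [featurize_molecule()]: takes a data frame
#' with a SMILES column and returns it as a tibble with a `graph`
#' list-column plus node/edge counts.  Rows that fail sanitization are
#' dropped and reported via the `"rejections"` attribute (a tibble of
#' SMILES + reason), mirroring the exclusion of molecules that fail the
#' sanity check.
#'
#' @param data A data frame.
#' @param smiles_col Name of the SMILES column.
#' @param schema A feature schema.
#' @return A tibble with columns of `data` plus `graph`, `n_atoms`,
#'   `n_bonds`; attribute `rejections` holds the rejected rows.
#' @export
featurize_smiles <- function(data, smiles_col = "smiles",
                             schema = default_feature_schema()) {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  res <- purrr::map(data[[smiles_col]], function(s)
    tryCatch(featurize_molecule(s, schema), error = function(e) e))
  bad <- vapply(res, inherits, logical(1), "error")
  rej <- tibble(
    smiles = as.character(data[[smiles_col]][bad]),
    reason = vapply(res[bad], conditionMessage, character(1)))
  out <- as_tibble(data[!bad, , drop = FALSE])
  out$graph <- res[!bad]
  out$n_atoms <- vapply(out$graph, function(g) nrow(g$node_features), numeric(1))
  out$n_bonds <- vapply(out$graph, function(g) nrow(g$edge_index) / 2, numeric(1))
  attr(out, "rejections") <- rej
  out
}
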