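#' Feature schema for molecular-graph featurization
#'
#' A feature schema fixes, once and for all, the vocabularies used to one-hot
#' encode atom and bond properties.  Encoding any molecule under a given
#' schema is deterministic, and the encoding dimensions never change after
#' construction, so graphs produced under the same schema are always
#' dimensionally compatible with a trained encoder.
#'
#' Node features (one block per property, in order): element symbol, formal
#' charge, heavy-atom degree, hybridization, number of attached hydrogens,
#' total valence, chirality tag, ring-size membership flags (sizes 3-8),
#' hydrogen-bond donor flag, acceptor flag, aromaticity flag, in-ring flag.
#' Edge features: bond type, bond stereochemistry, in-ring flag, conjugation
#' flag.
#'
#' The default element vocabulary covers common organic elements plus the
#' metals that occur in Pd-catalysed cross-coupling chemistry; anything else
#' falls into a trailing "other" bucket so unseen elements never hard-fail.
#'
#' @param elements Character vector of element symbols (an "other" bucket is
#'   always appended).
#' @param charges Integer vector of formal-charge categories.
#' @param max_count Largest degree / H-count / valence encoded exactly;
#'   larger values fall into an overflow bucket.
#' @param ring_sizes Integer vector of ring sizes with a membership flag each.
#' @return An object of class `feature_schema`.
#' @export
#' @examples
#' sch <- default_feature_schema()
#' schema_dims(sch)
default_feature_schema <- function(
    elements = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si",
                 "Pd", "Fe", "Sn", "K", "Na", "Cs", "Li", "Mg", "Cu", "Zn"),
    charges = -2:2,
    max_count = 6L,
    ring_sizes = 3:8) {
  structure(
    list(
      elements      = as.character(elements),
      charges       = as.integer(charges),
      degrees       = 0:max_count,
      hybridization = c("sp", "sp2", "sp3"),
      h_counts      = 0:max_count,
      valences      = 0:max_count,
      chirality     = c("none", "CW", "CCW"),
      ring_sizes    = as.integer(ring_sizes),
      bond_types    = c("single", "double", "triple", "aromatic"),
      bond_stereo   = c("none", "Z", "E", "cis", "trans", "any")
    ),
    class = "feature_schema"
  )
}

#' Encoding dimensions of a feature schema
#'
#' @param schema A `feature_schema`.
#' @return Named list with `node_dim` and `edge_dim`.
#' @export
schema_dims <- function(schema) {
  stopifnot(inherits(schema, "feature_schema"))
  node_dim <-
    (length(schema$elements) + 1L) +       # element + other
    (length(schema$charges) + 1L) +        # formal charge + other
    (length(schema$degrees) + 1L) +        # degree + overflow
    (length(schema$hybridization) + 1L) +  # hybridization + other
    (length(schema$h_counts) + 1L) +       # adjacent H + overflow
    (length(schema$valences) + 1L) +       # valence + overflow
    (length(schema$chirality) + 1L) +      # chirality + other
    length(schema$ring_sizes) +            # ring-size flags
    4L                                     # donor, acceptor, aromatic, in-ring
  edge_dim <-
    (length(schema$bond_types) + 1L) +     # bond type + other
    length(schema$bond_stereo) +           # stereo categories (incl. none)
    2L                                     # in-ring, conjugated
  list(node_dim = node_dim, edge_dim = edge_dim)
}

#' @export
print.feature_schema <- function(x, ...) {
  d <- schema_dims(x)
  cat("<feature_schema>\n")
  cat("  elements:", paste(x$elements, collapse = " "), "+ other\n")
  cat("  node_dim:", d$node_dim, " edge_dim:", d$edge_dim, "\n")
  invisible(x)
}

#' Write / read a feature schema as JSON
#'
#' Serializing the schema makes featurization reproducible across sessions
#' and machines: a checkpoint stores the schema dimensions it was built for
#' and refuses inputs featurized under an incompatible schema.
#'
#' @param schema A `feature_schema`.
#' @param path File path.
#' @return `read_feature_schema` returns a `feature_schema`.
#' @export
write_feature_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_schema
#' @export
read_feature_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- default_feature_schema()
  for (nm in names(sch)) {
    if (!nm %in% names(raw)) abort(sprintf("schema file misses field '%s'", nm))
    sch[[nm]] <- if (is.numeric(sch[[nm]])) as.integer(raw[[nm]]) else as.character(raw[[nm]])
  }
  sch
}
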