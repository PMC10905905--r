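# Native 2D molecular descriptor engine.
#
# Computes a fixed, deterministic registry of 2D descriptors from the
# molecular graph alone (no conformers): constitutional counts, ring
# descriptors, connectivity indices (Zagreb, Randic chi, Kier kappa/alpha),
# distance-matrix topological indices (Wiener, Balaban J, eccentric
# connectivity), information-content indices, Moreau-Broto autocorrelations
# over five atomic weighting schemes, Burden-eigenvalue (BCUT-like) bounds,
# and Gasteiger partial-charge summaries.  Descriptors that are undefined
# for a molecule (e.g. distance-based indices of a disconnected graph)
# evaluate to NA -- missing, never silently zero.

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Fe = 26, Cu = 29, Zn = 30, Br = 35,
  Sn = 50, I = 53, Li = 3, Cs = 55, Pd = 46)

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.453, K = 39.098, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Br = 79.904, Sn = 118.71, I = 126.904, Li = 6.941, Cs = 132.905,
  Pd = 106.42)

PAULING_EN <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98, Na = 0.93,
  Mg = 1.31, Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, K = 0.82,
  Fe = 1.83, Cu = 1.90, Zn = 1.65, Br = 2.96, Sn = 1.96, I = 2.66,
  Li = 0.98, Cs = 0.79, Pd = 2.20)

VALENCE_ELECTRONS <- c(
  H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Na = 1, Mg = 2, Si = 4,
  P = 5, S = 6, Cl = 7, K = 1, Fe = 8, Cu = 11, Zn = 12, Br = 7,
  Sn = 4, I = 7, Li = 1, Cs = 1, Pd = 10)

atom_weight <- function(elements, kind) {
  tab <- switch(kind,
                Z = ATOMIC_NUMBER, m = ATOMIC_MASS, en = PAULING_EN,
                v = VALENCE_ELECTRONS)
  w <- unname(tab[elements])
  w  # NA for unknown elements -> descriptor NA, by design
}

# heavy-atom distance matrix (igraph); Inf across fragments
profile_distances <- function(p) {
  if (p$n == 1L) return(matrix(0, 1, 1))
  g <- igraph::make_empty_graph(p$n, directed = FALSE)
  if (nrow(p$bonds) > 0)
    g <- igraph::add_edges(g, t(p$bonds[, c("a1", "a2"), drop = FALSE]))
  igraph::distances(g)
}

shannon <- function(counts) {
  counts <- counts[counts > 0]
  pr <- counts / sum(counts)
  -sum(pr * log2(pr))
}

# Kier-Hall valence delta: (Zv - h) / (Z - Zv - 1), plain delta for C
kh_delta_v <- function(p) {
  zv <- atom_weight(p$elements, "v")
  z <- atom_weight(p$elements, "Z")
  num <- zv - p$hs
  den <- z - zv - 1
  dv <- ifelse(den > 0, num / den, num)
  dv
}

paths_of_length <- function(p, len) {
  # number of simple paths with `len` edges (len in 2:3), each counted once
  if (nrow(p$bonds) == 0) return(0)
  adj <- vector("list", p$n)
  for (b in seq_len(nrow(p$bonds))) {
    a1 <- p$bonds[b, "a1"]; a2 <- p$bonds[b, "a2"]
    adj[[a1]] <- c(adj[[a1]], a2); adj[[a2]] <- c(adj[[a2]], a1)
  }
  count <- 0L
  walk <- function(u, depth, path) {
    if (depth == len) { count <<- count + 1L; return(invisible()) }
    for (w in adj[[u]]) if (!w %in% path) walk(w, depth + 1L, c(path, w))
  }
  for (v in seq_len(p$n)) walk(v, 0L, v)
  count / 2
}

descriptor_env <- function(p) {
  e <- new.env(parent = emptyenv())
  e$p <- p
  e$D <- NULL
  e$dist <- function() {
    if (is.null(e$D)) e$D <- profile_distances(e$p)
    e$D
  }
  e
}

# --- registry -------------------------------------------------------------

build_descriptor_registry <- function() {
  reg <- list()
  add <- function(name, family, fn) {
    reg[[name]] <<- list(name = name, family = family, fn = fn)
  }

  halogens <- c("F", "Cl", "Br", "I")
  metals <- c("Na", "Mg", "K", "Fe", "Cu", "Zn", "Sn", "Li", "Cs", "Pd")

  ## constitutional
  add("nAtom", "constitutional", function(e) e$p$n)
  add("nBond", "constitutional", function(e) nrow(e$p$bonds))
  add("nH", "constitutional", function(e) sum(e$p$hs))
  add("MW", "constitutional", function(e) {
    m <- atom_weight(e$p$elements, "m")
    sum(m) + ATOMIC_MASS[["H"]] * sum(e$p$hs)
  })
  for (el in c("C", "N", "O", "S", "P", "B", halogens)) {
    local({
      el0 <- el
      add(paste0("n", el0), "constitutional",
          function(e) sum(e$p$elements == el0))
    })
  }
  add("nX", "constitutional", function(e) sum(e$p$elements %in% halogens))
  add("nMetal", "constitutional", function(e) sum(e$p$elements %in% metals))
  add("nHet", "constitutional", function(e) sum(e$p$elements != "C"))
  add("fHet", "constitutional", function(e) sum(e$p$elements != "C") / e$p$n)
  add("nAromAtom", "constitutional", function(e) sum(e$p$aromatic))
  add("fAromAtom", "constitutional", function(e) sum(e$p$aromatic) / e$p$n)
  add("totFormalCharge", "constitutional", function(e) sum(e$p$charges))
  add("totAbsCharge", "constitutional", function(e) sum(abs(e$p$charges)))
  add("nHBDon", "constitutional", function(e)
    sum(e$p$elements %in% c("N", "O") & e$p$hs >= 1))
  add("nHBAcc", "constitutional", function(e)
    sum(e$p$elements %in% c("N", "O") & e$p$charges <= 0 &
          !(e$p$elements == "N" & (e$p$order_sum + e$p$hs) >= 4)))
  add("fCsp3", "constitutional", function(e) {
    nc <- sum(e$p$elements == "C")
    if (nc == 0) return(NA_real_)
    sum(e$p$elements == "C" & e$p$hyb == "sp3") / nc
  })
  for (o in 1:3) {
    local({
      o0 <- o
      add(c("nBondsS", "nBondsD", "nBondsT")[o0], "constitutional",
          function(e) sum(e$p$bonds[, "order"] == o0 & !(e$p$rings$bond &
            e$p$aromatic[e$p$bonds[, "a1"]] & e$p$aromatic[e$p$bonds[, "a2"]])))
    })
  }
  add("nBondsA", "constitutional", function(e)
    sum(e$p$rings$bond & e$p$aromatic[e$p$bonds[, "a1"]] &
          e$p$aromatic[e$p$bonds[, "a2"]]))
  add("nRot", "constitutional", function(e) {
    if (nrow(e$p$bonds) == 0) return(0)
    deg <- e$p$degree
    sum(e$p$bonds[, "order"] == 1 & !e$p$rings$bond &
          deg[e$p$bonds[, "a1"]] > 1 & deg[e$p$bonds[, "a2"]] > 1)
  })
  for (d in 1:4) {
    local({
      d0 <- d
      add(paste0("nDeg", d0), "constitutional",
          function(e) sum(e$p$degree == d0))
    })
  }

  ## ring
  add("nRing", "ring", function(e) {
    comp <- if (e$p$n == 1L) 1L else {
      g <- igraph::make_empty_graph(e$p$n, directed = FALSE)
      if (nrow(e$p$bonds) > 0)
        g <- igraph::add_edges(g, t(e$p$bonds[, c("a1", "a2"), drop = FALSE]))
      igraph::count_components(g)
    }
    nrow(e$p$bonds) - e$p$n + comp
  })
  add("nRingAtom", "ring", function(e) sum(e$p$rings$atom))
  add("nRingBond", "ring", function(e) sum(e$p$rings$bond))
  for (s in 3:8) {
    local({
      s0 <- s
      add(paste0("nRingAtom", s0), "ring",
          function(e) sum(e$p$rings$sizes[, s0]))
    })
  }

  ## connectivity
  add("Zagreb1", "connectivity", function(e) sum(e$p$degree^2))
  add("Zagreb2", "connectivity", function(e) {
    if (nrow(e$p$bonds) == 0) return(0)
    sum(e$p$degree[e$p$bonds[, "a1"]] * e$p$degree[e$p$bonds[, "a2"]])
  })
  add("Chi0", "connectivity", function(e) {
    d <- e$p$degree[e$p$degree > 0]
    if (length(d) == 0) return(NA_real_)
    sum(1 / sqrt(d))
  })
  add("Chi1", "connectivity", function(e) {
    if (nrow(e$p$bonds) == 0) return(NA_real_)
    sum(1 / sqrt(e$p$degree[e$p$bonds[, "a1"]] *
                   e$p$degree[e$p$bonds[, "a2"]]))
  })
  add("Chi0v", "connectivity", function(e) {
    dv <- kh_delta_v(e$p)
    dv <- dv[dv > 0]
    if (length(dv) == 0) return(NA_real_)
    sum(1 / sqrt(dv))
  })
  add("Chi1v", "connectivity", function(e) {
    if (nrow(e$p$bonds) == 0) return(NA_real_)
    dv <- kh_delta_v(e$p)
    pr <- dv[e$p$bonds[, "a1"]] * dv[e$p$bonds[, "a2"]]
    if (any(is.na(pr)) || any(pr <= 0)) return(NA_real_)
    sum(1 / sqrt(pr))
  })
  add("Kappa1", "connectivity", function(e) {
    A <- e$p$n; P1 <- nrow(e$p$bonds)
    if (P1 == 0) return(NA_real_)
    A * (A - 1)^2 / P1^2
  })
  add("Kappa2", "connectivity", function(e) {
    A <- e$p$n; P2 <- paths_of_length(e$p, 2L)
    if (P2 == 0) return(NA_real_)
    (A - 1) * (A - 2)^2 / P2^2
  })
  add("Kappa3", "connectivity", function(e) {
    A <- e$p$n; P3 <- paths_of_length(e$p, 3L)
    if (P3 == 0) return(NA_real_)
    if (A %% 2 == 0) (A - 3) * (A - 2)^2 / P3^2
    else (A - 1) * (A - 3)^2 / P3^2
  })

  ## topological (distance-matrix) -- NA on disconnected graphs
  topo_guard <- function(e) {
    D <- e$dist()
    if (any(!is.finite(D))) NULL else D
  }
  add("Wiener", "topological", function(e) {
    D <- topo_guard(e); if (is.null(D)) return(NA_real_)
    sum(D[upper.tri(D)])
  })
  add("MeanDist", "topological", function(e) {
    D <- topo_guard(e); if (is.null(D)) return(NA_real_)
    if (e$p$n == 1) return(0)
    mean(D[upper.tri(D)])
  })
  add("Diameter", "topological", function(e) {
    D <- topo_guard(e); if (is.null(D)) return(NA_real_)
    max(D)
  })
  add("Radius", "topological", function(e) {
    D <- topo_guard(e); if (is.null(D)) return(NA_real_)
    if (e$p$n == 1) return(0)
    min(apply(D, 1, max))
  })
  add("EccConn", "topological", function(e) {
    D <- topo_guard(e); if (is.null(D)) return(NA_real_)
    sum(e$p$degree * apply(D, 1, max))
  })
  add("BalabanJ", "topological", function(e) {
    D <- topo_guard(e); if (is.null(D)) return(NA_real_)
    B <- nrow(e$p$bonds)
    if (B == 0) return(NA_real_)
    mu <- B - e$p$n + 1
    s <- rowSums(D)
    B / (mu + 1) * sum(1 / sqrt(s[e$p$bonds[, "a1"]] * s[e$p$bonds[, "a2"]]))
  })

  ## information content
  add("IC_element", "information", function(e)
    shannon(table(e$p$elements)))
  add("TIC_element", "information", function(e)
    e$p$n * shannon(table(e$p$elements)))
  add("IC_degree", "information", function(e)
    shannon(table(e$p$degree)))
  add("IC_hyb", "information", function(e)
    shannon(table(e$p$hyb)))

  ## Moreau-Broto autocorrelation, raw and centered, lags 0-5
  for (kind in c("Z", "m", "en", "v", "deg")) {
    for (lag in 0:5) {
      local({
        kind0 <- kind; lag0 <- lag
        add(sprintf("ATS%d_%s", lag0, kind0), "autocorrelation", function(e) {
          w <- if (kind0 == "deg") as.numeric(e$p$degree)
               else atom_weight(e$p$elements, kind0)
          if (any(is.na(w))) return(NA_real_)
          if (lag0 == 0) return(sum(w^2))
          D <- e$dist()
          idx <- which(D == lag0, arr.ind = TRUE)
          if (nrow(idx) == 0) return(0)
          sum(w[idx[, 1]] * w[idx[, 2]]) / 2
        })
        add(sprintf("ATSC%d_%s", lag0, kind0), "autocorrelation",
            function(e) {
          w <- if (kind0 == "deg") as.numeric(e$p$degree)
               else atom_weight(e$p$elements, kind0)
          if (any(is.na(w))) return(NA_real_)
          w <- w - mean(w)
          if (lag0 == 0) return(sum(w^2))
          D <- e$dist()
          idx <- which(D == lag0, arr.ind = TRUE)
          if (nrow(idx) == 0) return(0)
          sum(w[idx[, 1]] * w[idx[, 2]]) / 2
        })
      })
    }
  }

  ## Burden-eigenvalue bounds
  for (kind in c("Z", "en")) {
    local({
      kind0 <- kind
      burden_eigs <- function(e) {
        w <- atom_weight(e$p$elements, kind0)
        if (any(is.na(w))) return(NULL)
        B <- matrix(0.001, e$p$n, e$p$n)
        diag(B) <- w
        for (b in seq_len(nrow(e$p$bonds))) {
          a1 <- e$p$bonds[b, "a1"]; a2 <- e$p$bonds[b, "a2"]
          v <- 0.1 * e$p$bonds[b, "order"]
          B[a1, a2] <- v; B[a2, a1] <- v
        }
        eigen(B, symmetric = TRUE, only.values = TRUE)$values
      }
      add(paste0("BCUThi_", kind0), "burden", function(e) {
        ev <- burden_eigs(e); if (is.null(ev)) NA_real_ else max(ev)
      })
      add(paste0("BCUTlo_", kind0), "burden", function(e) {
        ev <- burden_eigs(e); if (is.null(ev)) NA_real_ else min(ev)
      })
    })
  }
  add("SpecRadAdj", "burden", function(e) {
    if (nrow(e$p$bonds) == 0) return(0)
    A <- matrix(0, e$p$n, e$p$n)
    for (b in seq_len(nrow(e$p$bonds))) {
      A[e$p$bonds[b, "a1"], e$p$bonds[b, "a2"]] <- 1
      A[e$p$bonds[b, "a2"], e$p$bonds[b, "a1"]] <- 1
    }
    max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  })

  ## Gasteiger partial-charge summaries (NA when Open Babel yields none)
  pc_guard <- function(e) {
    pc <- e$p$partial_charges
    if (length(pc) == 0 || any(is.na(pc)) || any(!is.finite(pc))) NULL else pc
  }
  add("GCmax", "charge", function(e) {
    pc <- pc_guard(e); if (is.null(pc)) NA_real_ else max(pc)
  })
  add("GCmin", "charge", function(e) {
    pc <- pc_guard(e); if (is.null(pc)) NA_real_ else min(pc)
  })
  add("GCmeanAbs", "charge", function(e) {
    pc <- pc_guard(e); if (is.null(pc)) NA_real_ else mean(abs(pc))
  })
  add("GCsumAbs", "charge", function(e) {
    pc <- pc_guard(e); if (is.null(pc)) NA_real_ else sum(abs(pc))
  })

  reg
}

.registry_cache <- new.env(parent = emptyenv())

descriptor_registry <- function() {
  if (is.null(.registry_cache$reg))
    .registry_cache$reg <- build_descriptor_registry()
  .registry_cache$reg
}

#' Names of the 2D descriptor set
#'
#' Enumerates the native 2D descriptor registry in its fixed order.  The
#' registry is constructed once and is deterministic: the same names, in the
#' same order, in every session.
#'
#' @return Character vector of descriptor names.
#' @export
#' @examples
#' length(descriptor_names())
descriptor_names <- function() {
  names(descriptor_registry())
}

#' Compute 2D molecular descriptors for a set of molecules
#'
#' Computes the full native 2D descriptor set for every molecule.  Input can
#' be a character vector of SMILES or a data frame with a SMILES column.
#' Descriptors that are undefined for a molecule are returned as `NA`; a
#' molecule on which the engine fails entirely yields a row of `NA`s and a
#' warning (it is not silently dropped).  Identical SMILES always produce
#' identical rows.
#'
#' @param data Character vector of SMILES, or a data frame.
#' @param smiles_col Column holding SMILES when `data` is a data frame.
#' @return A tibble with a `molecule` identifier column (the input SMILES)
#'   followed by one numeric column per descriptor.
#' @export
#' @examples
#' compute_descriptors(c("CCO", "c1ccccc1"))[, 1:5]
compute_descriptors <- function(data, smiles_col = "smiles") {
  smiles <- if (is.data.frame(data)) {
    stopifnot(smiles_col %in% names(data))
    as.character(data[[smiles_col]])
  } else as.character(data)
  reg <- descriptor_registry()
  rows <- lapply(smiles, function(s) {
    prof <- tryCatch(mol_profile(s), error = function(err) err)
    if (inherits(prof, "error")) {
      warn(sprintf("descriptor engine failed on '%s': %s", s,
                   conditionMessage(prof)))
      return(rep(NA_real_, length(reg)))
    }
    e <- descriptor_env(prof)
    vapply(reg, function(d) {
      v <- tryCatch(as.numeric(d$fn(e)), error = function(err) NA_real_)
      if (length(v) != 1L || !is.finite(v)) NA_real_ else v
    }, numeric(1))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- names(reg)
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(molecule = smiles), out)
  out
}

#' Filter and standardize a descriptor matrix
#'
#' Applies, in this fixed order: (1) drop descriptors with more than
#' `missing_threshold` missing values; (2) drop descriptors whose non-missing
#' values are all identical (zero variance); (3) drop molecules that still
#' have any missing value in a retained descriptor; (4) standardize each
#' retained descriptor to mean zero, standard deviation one (population SD,
#' i.e. divide by n).  The returned report stores everything needed to
#' replay the selection and scaling exactly on new molecules.
#'
#' @param data A descriptor tibble from [compute_descriptors()] (first
#'   column `molecule`, descriptor columns after).
#' @param missing_threshold Maximum tolerated number of missing values per
#'   descriptor, as an absolute count of rows.
#' @return A list with `data` (standardized tibble) and `report` (an object
#'   of class `descriptor_filter`).
#' @export
filter_and_standardize <- function(data, missing_threshold = 10) {
  stopifnot(is.data.frame(data), nrow(data) > 0, names(data)[1] == "molecule")
  desc <- as.matrix(data[, -1, drop = FALSE])
  miss <- colSums(is.na(desc))
  dropped_missing <- colnames(desc)[miss > missing_threshold]
  keep1 <- setdiff(colnames(desc), dropped_missing)
  constant <- vapply(keep1, function(cn) {
    v <- desc[, cn]; v <- v[!is.na(v)]
    length(v) == 0 || all(v == v[1])
  }, logical(1))
  dropped_constant <- keep1[constant]
  keep2 <- keep1[!constant]
  if (length(keep2) == 0)
    abort("all descriptor columns were dropped by filtering",
          class = "ginyield_config_error")
  sub <- desc[, keep2, drop = FALSE]
  bad_row <- rowSums(is.na(sub)) > 0
  dropped_molecules <- as.character(data$molecule[bad_row])
  sub <- sub[!bad_row, , drop = FALSE]
  if (nrow(sub) == 0)
    abort("all molecules excluded by missing-descriptor rule",
          class = "ginyield_config_error")
  means <- colMeans(sub)
  sds <- sqrt(colMeans(sweep(sub, 2, means)^2))  # population SD
  zero_sd <- sds == 0
  if (any(zero_sd)) {
    dropped_constant <- c(dropped_constant, keep2[zero_sd])
    keep2 <- keep2[!zero_sd]
    sub <- sub[, keep2, drop = FALSE]
    means <- means[keep2]; sds <- sds[keep2]
    if (length(keep2) == 0)
      abort("all descriptor columns were dropped by filtering",
            class = "ginyield_config_error")
  }
  std <- sweep(sweep(sub, 2, means), 2, sds, `/`)
  out <- dplyr::bind_cols(
    tibble(molecule = as.character(data$molecule[!bad_row])),
    as_tibble(std))
  report <- structure(
    list(retained = keep2,
         dropped_missing = dropped_missing,
         dropped_constant = dropped_constant,
         dropped_molecules = dropped_molecules,
         means = means, sds = sds,
         missing_threshold = missing_threshold),
    class = "descriptor_filter")
  list(data = out, report = report)
}

#' @export
print.descriptor_filter <- function(x, ...) {
  cat(sprintf(
    "<descriptor_filter> %d retained | dropped: %d missing-excess, %d constant | %d molecules excluded\n",
    length(x$retained), length(x$dropped_missing),
    length(x$dropped_constant), length(x$dropped_molecules)))
  invisible(x)
}

#' Apply a fitted descriptor filter/standardization to new molecules
#'
#' Selects the retained descriptor columns and applies the stored means and
#' SDs; never refits.  Molecules with a missing value in a retained
#' descriptor are excluded (reported in the `"excluded"` attribute),
#' mirroring the fitting-time molecule-exclusion rule.
#'
#' @param data A descriptor tibble with the original descriptor columns.
#' @param report A `descriptor_filter` from [filter_and_standardize()].
#' @return Standardized tibble over the retained descriptors.
#' @export
apply_standardization <- function(data, report) {
  stopifnot(inherits(report, "descriptor_filter"),
            names(data)[1] == "molecule")
  missing_cols <- setdiff(report$retained, names(data))
  if (length(missing_cols) > 0)
    abort(sprintf("descriptor columns absent from input: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ginyield_schema_error")
  sub <- as.matrix(data[, report$retained, drop = FALSE])
  bad_row <- rowSums(is.na(sub)) > 0
  std <- sweep(sweep(sub[!bad_row, , drop = FALSE], 2, report$means),
               2, report$sds, `/`)
  out <- dplyr::bind_cols(
    tibble(molecule = as.character(data$molecule[!bad_row])),
    as_tibble(std))
  attr(out, "excluded") <- as.character(data$molecule[bad_row])
  out
}

#' Invert a standardization (for round-trip checks)
#'
#' @param data Standardized tibble over the retained descriptors.
#' @param report The `descriptor_filter` used to standardize.
#' @return Tibble on the original descriptor scale.
#' @export
destandardize <- function(data, report) {
  stopifnot(inherits(report, "descriptor_filter"))
  m <- as.matrix(data[, report$retained, drop = FALSE])
  raw <- sweep(sweep(m, 2, report$sds, `*`), 2, report$means, `+`)
  dplyr::bind_cols(tibble(molecule = data$molecule), as_tibble(raw))
}
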