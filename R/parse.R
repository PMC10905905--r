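# Internal chemistry layer.
#
# Open Babel (through ChemmineOB) is the parsing and sanitization authority:
# it canonicalizes SMILES, kekulizes, and emits V2000 SDF (bond orders,
# formal charges) and MOL2 (hybridization-typed atoms).  Open Babel preserves
# SMILES atom order in both output formats, so per-atom annotations that the
# file formats do not carry (aromatic flags, chirality tags, directional
# double-bond markers) are read off the canonical SMILES string itself by a
# light tokenizer and aligned by atom index.  The tokenizer's connectivity is
# cross-checked against the SDF bond table on every molecule.

ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) "")
  if (is.null(out)) out <- ""
  out
}

# canonical SMILES or NA if Open Babel rejects the string
ob_canonical <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  out <- sub("[ \t\r\n].*$", "", out)
  if (!nzchar(out)) return(NA_character_)
  out
}

# --- V2000 SDF ------------------------------------------------------------

parse_sdf_v2000 <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) abort("empty SDF", class = "ginyield_parse_error")
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  bonds <- NULL
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- cbind(
      a1    = as.integer(substr(bond_lines, 1, 3)),
      a2    = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- matrix(integer(0), 0, 3,
                    dimnames = list(NULL, c("a1", "a2", "order")))
  }
  charges <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    k <- toks[1]
    for (i in seq_len(k)) {
      charges[toks[2 * i]] <- toks[2 * i + 1]
    }
  }
  list(n_atoms = n_atoms, elements = elements, bonds = bonds,
       charges = charges)
}

# --- MOL2 atom types ------------------------------------------------------

parse_mol2_atoms <- function(mol2_text) {
  lines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1]]
  a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
  if (length(a0) == 0)
    return(list(types = character(0), partial_charges = numeric(0)))
  rest <- lines[(a0[1] + 1):length(lines)]
  stop_at <- grep("^@<TRIPOS>", rest)
  if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1)]
  rest <- rest[nzchar(trimws(rest))]
  fields <- strsplit(trimws(rest), "[ \t]+")
  list(
    types = vapply(fields, function(f) f[6], character(1)),
    partial_charges = vapply(fields, function(f)
      suppressWarnings(as.numeric(f[9])), numeric(1))
  )
}

mol2_hybridization <- function(atom_type, element) {
  suffix <- sub("^[^.]*\\.?", "", atom_type)
  if (suffix %in% c("1")) return("sp")
  if (suffix %in% c("2", "ar", "am", "pl3", "co2", "cat")) return("sp2")
  if (suffix %in% c("3", "4", "o", "o2", "O", "O2", "t", "th")) return("sp3")
  if (element %in% c("F", "Cl", "Br", "I")) return("sp3")
  "other"
}

# --- canonical-SMILES tokenizer ------------------------------------------

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

tokenize_smiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()   # from, to, sym (written order)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- ""
  ring_open <- list()  # label -> list(atom, sym)
  i <- 1L

  add_atom <- function(element, aromatic, chirality, hcount, charge,
                       bracket) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, chirality = chirality,
      hcount = hcount, charge = charge, bracket = bracket)
    id <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(from = prev, to = id,
                                           sym = pending)
    }
    pending <<- ""
    prev <<- id
    invisible(id)
  }

  close_ring <- function(label) {
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      sym <- if (nzchar(op$sym)) op$sym else pending
      bonds[[length(bonds) + 1L]] <<- list(from = op$atom, to = prev,
                                           sym = sym)
      ring_open[[label]] <<- NULL
    } else {
      ring_open[[label]] <<- list(atom = prev, sym = pending)
    }
    pending <<- ""
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9+-]*)?$", body))[[1]]
      if (length(m) == 0)
        abort(sprintf("cannot parse bracket atom '[%s]'", body),
              class = "ginyield_parse_error")
      sym <- m[3]
      aromatic <- sym == tolower(sym) && substr(sym, 1, 1) %in% letters
      element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      chir <- if (m[4] == "@@") "CW" else if (m[4] == "@") "CCW" else "none"
      hcount <- if (nzchar(m[5])) {
        if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
      } else 0L
      charge <- 0L
      if (nzchar(m[6])) {
        cs <- m[6]
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(cs)
        } else {
          charge <- sum(strsplit(cs, "")[[1]] == "+") -
            sum(strsplit(cs, "")[[1]] == "-")
        }
      }
      add_atom(element, aromatic, chir, hcount, charge, bracket = TRUE)
      i <- j + 1L
    } else {
      # organic-subset atom, two-letter halogens first
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, "none", NA_integer_, 0L, bracket = FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, "none", NA_integer_, 0L, bracket = FALSE)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, "none", NA_integer_, 0L, bracket = FALSE)
        i <- i + 1L
      } else {
        abort(sprintf("unexpected character '%s' in SMILES '%s'", ch, smiles),
              class = "ginyield_parse_error")
      }
    }
  }
  if (length(ring_open) > 0 && any(!vapply(ring_open, is.null, logical(1))))
    abort(sprintf("unmatched ring bond in '%s'", smiles),
          class = "ginyield_parse_error")
  list(atoms = atoms, bonds = bonds)
}

# --- ring perception ------------------------------------------------------

# ring bonds = edges not cut by bridge removal; ring-size membership flags
# found by bounded simple-cycle search over the ring subgraph
ring_info <- function(n_atoms, bonds, max_size = 8L) {
  in_ring_bond <- logical(nrow(bonds))
  in_ring_atom <- logical(n_atoms)
  sizes <- matrix(FALSE, n_atoms, max_size)
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(bonds[, c("a1", "a2"), drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < n_atoms)
      g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    ring_bonds <- bonds[in_ring_bond, , drop = FALSE]
    in_ring_atom[c(ring_bonds[, "a1"], ring_bonds[, "a2"])] <- TRUE
    adj <- vector("list", n_atoms)
    for (b in seq_len(nrow(ring_bonds))) {
      a1 <- ring_bonds[b, "a1"]; a2 <- ring_bonds[b, "a2"]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
    }
    for (v in which(in_ring_atom)) {
      visited <- logical(n_atoms)
      found <- logical(max_size)
      dfs <- function(u, depth) {
        for (w in adj[[u]]) {
          if (w == v && depth >= 3L) {
            found[depth] <<- TRUE
          } else if (!visited[w] && w != v && depth < max_size) {
            visited[w] <<- TRUE
            dfs(w, depth + 1L)
            visited[w] <<- FALSE
          }
        }
      }
      dfs(v, 1L)
      sizes[v, ] <- found
    }
  }
  list(bond = in_ring_bond, atom = in_ring_atom, sizes = sizes)
}

# --- implicit hydrogens / valence ----------------------------------------

STANDARD_VALENCES <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

implicit_h <- function(element, bracket, hcount, order_sum) {
  if (bracket) return(if (is.na(hcount)) 0L else hcount)
  vals <- STANDARD_VALENCES[[element]]
  if (is.null(vals)) return(0L)
  fit <- vals[vals >= order_sum]
  if (length(fit) == 0) return(NA_integer_)  # hypervalent: fails sanitization
  fit[1] - order_sum
}

# --- E/Z assignment from directional bonds -------------------------------

assign_double_bond_stereo <- function(tok) {
  dir_val <- function(sym) if (sym == "/") 1 else if (sym == "\\") -1 else 0
  res <- list()
  for (b in tok$bonds) {
    if (b$sym != "=") next
    j <- b$from; k <- b$to
    d1 <- NA_real_; d2 <- NA_real_
    for (fb in tok$bonds) {
      if (!fb$sym %in% c("/", "\\")) next
      dv <- dir_val(fb$sym)
      if (fb$to == j && fb$from != k && is.na(d1)) d1 <- dv        # x -> j
      if (fb$from == j && fb$to != k && is.na(d1)) d1 <- -dv       # j -> x
      if (fb$from == k && fb$to != j && is.na(d2)) d2 <- dv        # k -> y
      if (fb$to == k && fb$from != j && is.na(d2)) d2 <- -dv       # y -> k
    }
    stereo <- if (is.na(d1) && is.na(d2)) {
      "none"
    } else if (is.na(d1) || is.na(d2)) {
      "any"
    } else if (d1 == d2) "E" else "Z"
    res[[paste(min(j, k), max(j, k), sep = "-")]] <- stereo
  }
  res
}

# --- consolidated molecular profile ---------------------------------------

# Parse a SMILES once into everything both the graph featurizer and the
# descriptor engine need.  Errors carry the offending input string.
mol_profile <- function(smiles) {
  can <- ob_canonical(smiles)
  if (is.na(can))
    abort(sprintf("SMILES failed sanitization: '%s'", smiles),
          class = "ginyield_sanitize_error")
  sdf <- parse_sdf_v2000(ob_convert("SMI", "SDF", can))
  m2 <- parse_mol2_atoms(ob_convert("SMI", "MOL2", can))
  tok <- tokenize_smiles(can)

  n <- sdf$n_atoms
  if (length(tok$atoms) != n || length(m2$types) != n)
    abort(sprintf("internal atom-count mismatch for '%s'", can),
          class = "ginyield_parse_error")
  tok_elems <- vapply(tok$atoms, `[[`, character(1), "element")
  if (!all(toupper(tok_elems) == toupper(sdf$elements)))
    abort(sprintf("internal atom-order mismatch for '%s'", can),
          class = "ginyield_parse_error")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tok_from <- vapply(tok$bonds, `[[`, integer(1), "from")
  tok_to <- vapply(tok$bonds, `[[`, integer(1), "to")
  if (!setequal(key(tok_from, tok_to),
                key(sdf$bonds[, "a1"], sdf$bonds[, "a2"])))
    abort(sprintf("internal bond mismatch for '%s'", can),
          class = "ginyield_parse_error")

  bonds <- sdf$bonds
  order_sum <- numeric(n); degree <- integer(n)
  for (b in seq_len(nrow(bonds))) {
    a1 <- bonds[b, "a1"]; a2 <- bonds[b, "a2"]; o <- bonds[b, "order"]
    order_sum[a1] <- order_sum[a1] + o; order_sum[a2] <- order_sum[a2] + o
    degree[a1] <- degree[a1] + 1L; degree[a2] <- degree[a2] + 1L
  }
  hs <- integer(n)
  for (j in seq_len(n)) {
    at <- tok$atoms[[j]]
    h <- implicit_h(at$element, at$bracket, at$hcount, order_sum[j])
    if (is.na(h))
      abort(sprintf(
        "SMILES failed sanitization (valence of %s exceeded): '%s'",
        at$element, smiles), class = "ginyield_sanitize_error")
    hs[j] <- h
    vals <- STANDARD_VALENCES[[at$element]]
    if (!is.null(vals) &&
        order_sum[j] + h > max(vals) + max(0L, sdf$charges[j]))
      abort(sprintf(
        "SMILES failed sanitization (valence of %s exceeded): '%s'",
        at$element, smiles), class = "ginyield_sanitize_error")
  }
  rings <- ring_info(n, bonds)
  list(
    smiles = can, n = n, elements = sdf$elements, bonds = bonds,
    charges = sdf$charges, hs = hs, degree = degree, order_sum = order_sum,
    aromatic = vapply(tok$atoms, `[[`, logical(1), "aromatic"),
    chirality = vapply(tok$atoms, `[[`, character(1), "chirality"),
    hyb = vapply(seq_len(n), function(j)
      mol2_hybridization(m2$types[j], sdf$elements[j]), character(1)),
    partial_charges = m2$partial_charges,
    rings = rings,
    stereo = assign_double_bond_stereo(tok)
  )
}
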