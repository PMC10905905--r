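#' Load a reaction-yield CSV
#'
#' Reads a CSV holding reaction SMILES (`"r1.r2.<...>>>product"`) and a
#' numeric yield column, featurizes every reaction, and returns one record
#' per valid row.  Rows that fail (missing yield, unparsable reaction,
#' component failing sanitization) are collected into a rejection report
#' attached as the `"rejections"` attribute -- never silently dropped.
#' Column names are configurable so the loader adapts to the benchmark
#' repositories' CSV dialects.
#'
#' @param path CSV file path.
#' @param smiles_col,yield_col,id_col Column names; `id_col = NULL`
#'   numbers the rows.
#' @param schema Feature schema for featurization.
#' @return A tibble with `id`, `reaction_smiles`, `yield`, `m` (number of
#'   reactants) and a `rxn` list-column of featurized reactions.
#' @export
load_reaction_csv <- function(path, smiles_col = "reaction_smiles",
                              yield_col = "yield", id_col = NULL,
                              schema = default_feature_schema()) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in c(smiles_col, yield_col))
    if (!cn %in% names(df))
      abort(sprintf("column '%s' not present in %s", cn, path))
  ids <- if (!is.null(id_col)) as.character(df[[id_col]]) else
    as.character(seq_len(nrow(df)))
  yields <- suppressWarnings(as.numeric(df[[yield_col]]))

  records <- vector("list", nrow(df))
  reasons <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(yields[i])) {
      reasons[i] <- "missing yield"
      next
    }
    rec <- tryCatch(featurize_reaction(df[[smiles_col]][i], schema),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      reasons[i] <- conditionMessage(rec)
      next
    }
    records[[i]] <- rec
  }
  ok <- !nzchar(reasons)
  out <- tibble(
    id = ids[ok],
    reaction_smiles = as.character(df[[smiles_col]][ok]),
    yield = yields[ok],
    m = vapply(records[ok], function(r) length(r$reactants), integer(1)),
    rxn = records[ok])
  attr(out, "rejections") <- tibble(id = ids[!ok], reason = reasons[!ok])
  out
}

#' Write reactions back to CSV (round-trip partner of the loader)
#'
#' @param data Tibble with `reaction_smiles` and `yield`.
#' @param path Output path.
#' @param smiles_col,yield_col Column names to write.
#' @return `path`, invisibly.
#' @export
write_reaction_csv <- function(data, path, smiles_col = "reaction_smiles",
                               yield_col = "yield") {
  df <- data.frame(a = data$reaction_smiles, b = data$yield)
  names(df) <- c(smiles_col, yield_col)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Train/test splits for reaction datasets
#'
#' Two protocols: `"random_ratio"` draws a seeded random permutation and
#' assigns the first `floor(train_fraction * N)` records to training (a
#' published shuffle order, supplied via `shuffle`, is used verbatim
#' instead when present); `"out_of_sample"` puts every record of one held
#' -out group (e.g. a substance combination absent from training) into the
#' test set.
#'
#' @param data Tibble of reaction records.
#' @param kind `"random_ratio"` or `"out_of_sample"`.
#' @param train_fraction Training fraction for random splits.
#' @param seed Seed for the internal permutation.
#' @param shuffle Optional integer permutation of `1:nrow(data)` (e.g. a
#'   published shuffle file read with [read_split_file()]); overrides the
#'   internal permutation.
#' @param group_col,test_group Grouping column and held-out level for
#'   out-of-sample splits.
#' @return A list with integer row indices `train` and `test` (disjoint,
#'   exhaustive).
#' @export
make_split <- function(data, kind = c("random_ratio", "out_of_sample"),
                       train_fraction = 0.7, seed = 1L, shuffle = NULL,
                       group_col = NULL, test_group = NULL) {
  kind <- match.arg(kind)
  N <- nrow(data)
  if (kind == "random_ratio") {
    if (train_fraction <= 0 || train_fraction >= 1)
      abort("`train_fraction` must be in (0, 1)")
    perm <- if (!is.null(shuffle)) {
      if (!setequal(shuffle, seq_len(N)))
        abort("`shuffle` must be a permutation of 1:nrow(data)")
      as.integer(shuffle)
    } else {
      set.seed(seed)
      sample.int(N)
    }
    n_train <- floor(train_fraction * N)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[-seq_len(n_train)]))
  } else {
    if (is.null(group_col) || !group_col %in% names(data))
      abort("out-of-sample splits need a valid `group_col`")
    groups <- as.character(data[[group_col]])
    if (is.null(test_group) || !test_group %in% groups)
      abort(sprintf("unknown test group '%s'; available: %s",
                    test_group %||% "<NULL>",
                    paste(sort(unique(groups)), collapse = ", ")))
    test <- which(groups == test_group)
    list(train = setdiff(seq_len(N), test), test = test)
  }
}

#' Read a plain-text split index file (one integer per line)
#'
#' @param path File path.
#' @return Integer vector.
#' @export
read_split_file <- function(path) {
  as.integer(readLines(path))
}
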