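#' Fit a PCA pseudo-labeler on a standardized descriptor matrix
#'
#' Performs PCA on the standardized descriptor matrix (eigendecomposition of
#' the sample covariance, computed via SVD) and keeps the smallest number of
#' leading components `q` whose cumulative explained variance reaches
#' `explained_variance_target` (default 70%), unless `q_override` fixes `q`
#' directly.  Component signs follow a deterministic convention: each
#' component is flipped so that its largest-magnitude loading is positive.
#'
#' The fitted object also stores per-component score statistics used later
#' by [make_pseudo_labels()]: the empirical SD of the fitting scores (the
#' clipping scale) and the post-clipping mean/SD (the re-standardization).
#'
#' @param data Standardized descriptor tibble (first column `molecule`),
#'   e.g. `filter_and_standardize(...)$data`.
#' @param explained_variance_target Fraction in (0, 1].
#' @param q_override Optional integer fixing the number of components.
#' @param clip_multiplier Scores are clipped at plus/minus this multiple of
#'   their fitting-set SD before re-standardization.
#' @return An object of class `pseudo_labeler`.
#' @export
fit_pseudo_labeler <- function(data, explained_variance_target = 0.70,
                               q_override = NULL, clip_multiplier = 10) {
  stopifnot(is.data.frame(data), names(data)[1] == "molecule")
  stopifnot_scalar_number(explained_variance_target,
                          "explained_variance_target")
  if (explained_variance_target <= 0 || explained_variance_target > 1)
    abort("`explained_variance_target` must be in (0, 1]",
          class = "ginyield_parameter_error")
  if (clip_multiplier <= 0)
    abort("`clip_multiplier` must be positive",
          class = "ginyield_parameter_error")
  X <- as.matrix(data[, -1, drop = FALSE])
  if (anyNA(X)) abort("matrix contains missing values; filter first")
  p <- ncol(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  eigenvalues_all <- pc$sdev^2
  total_var <- sum(eigenvalues_all)
  cumvar <- cumsum(eigenvalues_all) / total_var
  q <- if (!is.null(q_override)) {
    q_override <- as.integer(q_override)
    if (q_override < 1 || q_override > length(eigenvalues_all))
      abort("`q_override` out of range", class = "ginyield_parameter_error")
    q_override
  } else {
    which(cumvar >= explained_variance_target)[1]
  }
  if (nrow(X) <= q)
    abort("need more molecules than components",
          class = "ginyield_parameter_error")

  U <- pc$rotation[, seq_len(q), drop = FALSE]
  # deterministic sign: largest-|loading| positive
  for (j in seq_len(q)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  center <- pc$center
  scores <- sweep(X, 2, center) %*% U
  score_sd <- apply(scores, 2, stats::sd)
  lim <- clip_multiplier * score_sd
  clipped <- pmin(pmax(scores, rep(-lim, each = nrow(scores))),
                  rep(lim, each = nrow(scores)))
  post_means <- colMeans(clipped)
  post_sds <- sqrt(colMeans(sweep(clipped, 2, post_means)^2))  # population

  structure(
    list(components = U,
         eigenvalues = eigenvalues_all[seq_len(q)],
         eigenvalues_all = eigenvalues_all,
         total_variance = total_var,
         center = center,
         q = q,
         explained_variance_target = explained_variance_target,
         explained_variance = cumvar[q],
         clip_multiplier = clip_multiplier,
         score_sd = score_sd,
         post_clip_means = post_means,
         post_clip_sds = post_sds,
         descriptor_names = colnames(X)),
    class = "pseudo_labeler")
}

#' @export
print.pseudo_labeler <- function(x, ...) {
  cat(sprintf(
    "<pseudo_labeler> q = %d of p = %d descriptors (%.1f%% variance explained)\n",
    x$q, length(x$descriptor_names), 100 * x$explained_variance))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pseudo_labeler
#' @export
tidy.pseudo_labeler <- function(x, ...) {
  ev <- x$eigenvalues_all
  tibble(component = seq_along(ev),
         eigenvalue = ev,
         explained_variance = ev / x$total_variance,
         cumulative_variance = cumsum(ev) / x$total_variance,
         retained = seq_along(ev) <= x$q)
}

#' @method glance pseudo_labeler
#' @export
glance.pseudo_labeler <- function(x, ...) {
  tibble(q = x$q, p = length(x$descriptor_names),
         explained_variance = x$explained_variance,
         clip_multiplier = x$clip_multiplier)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

#' Scree plot of a fitted pseudo-labeler
#'
#' @param object A `pseudo_labeler`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pseudo_labeler
#' @export
autoplot.pseudo_labeler <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$component, y = .data$cumulative_variance)) +
    geom_line() +
    geom_point(aes(colour = .data$retained), size = 1) +
    geom_hline(yintercept = object$explained_variance_target,
               linetype = "dashed") +
    labs(x = "principal component", y = "cumulative explained variance",
         colour = "retained") +
    theme_minimal()
}

#' Project molecules to clipped, re-standardized pseudo-labels
#'
#' Computes principal-component scores for each molecule, clips each
#' dimension at plus/minus `clip_multiplier` times that dimension's
#' fitting-set SD, and re-standardizes with the stored post-clipping
#' statistics so every dimension has mean 0 / SD 1 on the fitting set.
#' Replaying on any data uses only the statistics stored in the labeler, so
#' results are bit-identical across calls.
#'
#' @param labeler A fitted [fit_pseudo_labeler()] object.
#' @param data Standardized descriptor tibble over the same descriptor
#'   columns the labeler was fitted on.
#' @return A tibble: `molecule` plus `pl1 ... plq` pseudo-label columns;
#'   the eigenvalues used for loss weighting are in the `"eigenvalues"`
#'   attribute.
#' @export
make_pseudo_labels <- function(labeler, data) {
  stopifnot(inherits(labeler, "pseudo_labeler"),
            names(data)[1] == "molecule")
  missing_cols <- setdiff(labeler$descriptor_names, names(data))
  if (length(missing_cols) > 0)
    abort(sprintf("descriptor columns absent from input: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ginyield_schema_error")
  X <- as.matrix(data[, labeler$descriptor_names, drop = FALSE])
  if (anyNA(X)) abort("matrix contains missing values; filter first")
  scores <- sweep(X, 2, labeler$center) %*% labeler$components
  lim <- labeler$clip_multiplier * labeler$score_sd
  clipped <- pmin(pmax(scores, rep(-lim, each = nrow(scores))),
                  rep(lim, each = nrow(scores)))
  z <- sweep(sweep(clipped, 2, labeler$post_clip_means), 2,
             labeler$post_clip_sds, `/`)
  colnames(z) <- paste0("pl", seq_len(labeler$q))
  out <- dplyr::bind_cols(tibble(molecule = as.character(data$molecule)),
                          as_tibble(z))
  attr(out, "eigenvalues") <- labeler$eigenvalues
  out
}

#' Persist / restore a pseudo-labeler as JSON
#'
#' @param labeler A `pseudo_labeler`.
#' @param path File path.
#' @return `read_pseudo_labeler` returns the restored `pseudo_labeler`.
#' @export
write_pseudo_labeler <- function(labeler, path) {
  stopifnot(inherits(labeler, "pseudo_labeler"))
  obj <- unclass(labeler)
  obj$components <- list(dim = dim(labeler$components),
                         values = as.numeric(labeler$components))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pseudo_labeler
#' @export
read_pseudo_labeler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- matrix(obj$components$values, obj$components$dim[1],
                 obj$components$dim[2])
  rownames(comp) <- obj$descriptor_names
  obj$components <- comp
  obj$center <- stats::setNames(as.numeric(obj$center), obj$descriptor_names)
  for (nm in c("score_sd", "post_clip_means", "post_clip_sds",
               "eigenvalues", "eigenvalues_all"))
    obj[[nm]] <- as.numeric(obj[[nm]])
  obj$q <- as.integer(obj$q)
  structure(obj, class = "pseudo_labeler")
}
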