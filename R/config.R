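#' Default pipeline configuration
#'
#' Every tunable of the pipeline has a named key whose default equals the
#' reference recipe: descriptor missing-value threshold 10; PCA explained
#' -variance target 0.70 with clip multiplier 10; GIN with L = 3 layers of
#' width 300, representation width 1024, dropout 0.1; pre-training 10
#' epochs / batch 128 / LR 5e-4 / weight decay 1e-5; fine-tuning 500 epochs
#' with LR decays at epochs 400 and 450; 30 Monte-Carlo-dropout passes.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    descriptors = list(missing_threshold = 10),
    pca = list(explained_variance = 0.70, q = NULL, clip_multiplier = 10),
    gin = list(L = 3L, hidden = 300L, rep_dim = 1024L, dropout_rate = 0.1,
               message_mode = "neighbor"),
    pretrain = list(epochs = 10L, batch_size = 128L, learning_rate = 5e-4,
                    weight_decay = 1e-5, normalize_eigenvalues = FALSE),
    finetune = list(alpha = 0.1, epochs = 500L, batch_size = 128L,
                    learning_rate = 5e-4,
                    lr_schedule = list(epochs = c(400L, 450L),
                                       rates = c(5e-5, 5e-6)),
                    weight_decay = 1e-5, mc_passes = 30L,
                    yield_scaling = "standardize"),
    seed = 1L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML configuration file over the defaults
#'
#' Keys present in the file override [default_config()]; everything else
#' keeps its default, so a config file only needs to state deviations.
#' Basic validation (positivity, ranges) is applied to the merged result.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ev <- cfg$pca$explained_variance
  if (!is.numeric(ev) || ev <= 0 || ev > 1)
    abort("pca$explained_variance must be in (0, 1]",
          class = "ginyield_config_error")
  for (key in c("missing_threshold")) {
    if (cfg$descriptors[[key]] < 0)
      abort("descriptors$missing_threshold must be nonnegative",
            class = "ginyield_config_error")
  }
  if (!cfg$gin$message_mode %in% c("neighbor", "literal"))
    abort("gin$message_mode must be 'neighbor' or 'literal'",
          class = "ginyield_config_error")
  pretrain_config(epochs = cfg$pretrain$epochs,
                  batch_size = cfg$pretrain$batch_size,
                  learning_rate = cfg$pretrain$learning_rate,
                  weight_decay = cfg$pretrain$weight_decay,
                  dropout_rate = cfg$gin$dropout_rate)
  finetune_config(alpha = cfg$finetune$alpha, epochs = cfg$finetune$epochs,
                  batch_size = cfg$finetune$batch_size,
                  learning_rate = cfg$finetune$learning_rate,
                  lr_schedule = cfg$finetune$lr_schedule,
                  weight_decay = cfg$finetune$weight_decay,
                  mc_passes = cfg$finetune$mc_passes,
                  dropout_rate = cfg$gin$dropout_rate,
                  yield_scaling = cfg$finetune$yield_scaling)
  invisible(cfg)
}

#' Build a run manifest for an artifact
#'
#' Records the subcommand, the fully resolved configuration (all defaults
#' materialized), MD5 digests of the input files, the seed, package version
#' and a timestamp, so any artifact can be traced to the exact run that
#' produced it and reruns reproduce it (within stochastic tolerance).
#'
#' @param subcommand Character label of the pipeline phase.
#' @param config Resolved configuration list.
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed of the run.
#' @return Named list of class `run_manifest`.
#' @export
run_manifest <- function(subcommand, config, inputs = character(0),
                         seed = config$seed %||% 1L) {
  digests <- if (length(inputs) > 0) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.character(d), names(d))
  } else character(0)
  structure(
    list(subcommand = subcommand,
         config = config,
         input_digests = as.list(digests),
         seed = as.integer(seed),
         artifact_version = as.character(utils::packageVersion("ginyield")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a manifest as a JSON sidecar file
#'
#' @param manifest A `run_manifest`.
#' @param path Destination (conventionally `<artifact>.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
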