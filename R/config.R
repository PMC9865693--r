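# YAML run configuration: documented defaults, unknown-key rejection,
# dotted-path overrides.

default_run_config <- function() {
  list(
    seed = 42L,
    data = list(size = 512L, seq_len = 8L, scan_axis = 1L, keep_empty = FALSE),
    phantom = list(n_slices = 24L, height = 64L, width = 64L,
                   fg_max_fraction = 0.08, contrast = 0.15,
                   n_distractors = 3L, noise_sd = 0.03, jitter_sd = 0.6),
    network = list(input_channels = 1L, num_classes = 2L, reduce = 1L,
                   seq_len = 8L, msa_on_skips = "auto", gru_kernel = 3L,
                   threshold = 0.5),
    loss = list(focal_alpha = 0.25, focal_gamma = 2, smooth = 1e-6),
    train = list(
      momentum = 0.9, schedule_kind = "step", cosine_lr_min = 1e-4,
      stage1 = list(iterations = 120L, batch_size = 16L, lr = 0.01,
                    decay_every = 10L, decay_factor = 0.5),
      stage2 = list(lr = 0.01, max_epochs = 40L, patience = 10L),
      stage3 = list(lr = 0.001, max_epochs = 40L, patience = 10L)
    )
  )
}

merge_config <- function(base, new, path = "") {
  for (key in names(new)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base)) {
      stop(sprintf("unknown configuration key '%s'", full))
    }
    if (is.list(base[[key]]) && is.list(new[[key]])) {
      base[[key]] <- merge_config(base[[key]], new[[key]], full)
    } else {
      base[[key]] <- new[[key]]
    }
  }
  base
}

apply_override <- function(cfg, assignment) {
  kv <- strsplit(assignment, "=", fixed = TRUE)[[1]]
  if (length(kv) != 2) stop(sprintf("override '%s' is not key=value", assignment))
  keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
  val <- utils::type.convert(kv[2], as.is = TRUE)
  # rebuild nested list for the dotted path
  nested <- val
  for (k in rev(keys)) nested <- stats::setNames(list(nested), k)
  merge_config(cfg, nested)
}

#' Parse a run configuration
#'
#' Reads an optional YAML file, applies `key.path=value` overrides, fills
#' every documented default and rejects unknown keys.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides character vector of dotted-path overrides, e.g.
#'   `"data.seq_len=4"`.
#' @return a validated `run_config` list.
#' @export
parse_config <- function(path = NULL, overrides = character()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
    y <- yaml::read_yaml(path)
    if (!is.null(y)) cfg <- merge_config(cfg, y)
  }
  for (o in overrides) cfg <- apply_override(cfg, o)
  # run component validations
  do.call(loss_config, cfg$loss)
  do.call(phantom_config, c(cfg$phantom, list(seed = cfg$seed)))
  do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  do.call(network_config, c(cfg$network, list(seed = cfg$seed)))
  if (cfg$network$threshold <= 0 || cfg$network$threshold >= 1) {
    stop("threshold must be inside (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Write the fully resolved configuration next to a run's outputs
#' @param cfg a `run_config`.
#' @param dir output directory.
#' @export
echo_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config_resolved.yaml"))
  invisible(file.path(dir, "config_resolved.yaml"))
}
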