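#' Save and load network checkpoints
#'
#' A checkpoint is a single JSON document holding the network configuration,
#' the schedule, both weight matrices (as nested arrays), the class names
#' and the training-log header, so a fitted model can be archived and
#' reloaded portably.
#'
#' @param object a fitted [cbsnn()] model.
#' @param path file path for the JSON checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `"cbsnn"` object (without the per-sample novelty
#'   table, which is not part of the checkpoint).
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "cbsnn"))
  payload <- list(
    format = "cbsnn-checkpoint-1",
    config = unclass(object$config),
    schedule = unclass(object$schedule),
    mode = object$mode,
    classes = object$classes,
    n_samples = object$n_samples,
    n_classes = object$n_classes,
    W1 = object$W1, W2 = object$W2,
    log_header = names(object$log),
    log = object$log)
  payload$config$params_hidden <- unclass(payload$config$params_hidden)
  payload$config$params_output <- unclass(payload$config$params_output)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "cbsnn-checkpoint-1")
    stop("not a recognized checkpoint file")
  cfg <- p$config
  cfg$params_hidden <- do.call(neuron_params, as.list(cfg$params_hidden))
  cfg$params_output <- do.call(neuron_params, as.list(cfg$params_output))
  cfg$layer_sizes <- as.integer(cfg$layer_sizes)
  class(cfg) <- "network_config"
  sch <- p$schedule; class(sch) <- "schedule_config"
  log <- as.data.frame(p$log)
  attr(log, "n_samples") <- p$n_samples
  structure(list(W1 = matrix(unlist(p$W1), nrow = cfg$layer_sizes[1]),
                 W2 = matrix(unlist(p$W2), nrow = cfg$layer_sizes[2]),
                 config = cfg, schedule = sch, mode = p$mode,
                 log = log, novelty = NULL,
                 n_samples = p$n_samples, n_classes = p$n_classes,
                 classes = p$classes, call = NULL),
            class = "cbsnn")
}

#' Read a YAML experiment configuration
#'
#' Reads a configuration file with optional blocks `network:`, `encoding:`,
#' `schedule:`, `data:` and `experiment:` and merges them over the package
#' defaults.  Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return A named list with elements `network`, `encoding`, `schedule`,
#'   `data`, `experiment`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  blocks <- c("network", "encoding", "schedule", "data", "experiment")
  bad <- setdiff(names(raw), blocks)
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  defaults <- list(
    network = list(hidden = 30, T = 100, dt = 1, eta_i = 0.1, eta_c = 0.02,
                   stdp_rate = 8, es_threshold_mode = "single",
                   vprime_mode = "window_total", seed = 1),
    encoding = list(mode = "current", max_rate = 0.5),
    schedule = list(n_epochs = 20, T_start = 1, NE_th = 0.05, I_re = 5,
                    batch_size = 32),
    data = list(kind = "synthetic", n_classes = 3, n_per_class = 200,
                dims = 4, separation = 6, overlap_fraction = 0.2,
                test_fraction = 0.25, path = NULL, images = NULL,
                labels = NULL, label_column = NULL),
    experiment = list(mode = "cbsnn", subset_fraction = 0.5, seeds = 1))
  for (b in blocks) {
    if (!is.null(raw[[b]])) {
      extra <- setdiff(names(raw[[b]]), names(defaults[[b]]))
      if (length(extra))
        stop(sprintf("unknown key(s) in '%s': %s", b,
                     paste(extra, collapse = ", ")))
      defaults[[b]][names(raw[[b]])] <- raw[[b]]
    }
  }
  defaults
}
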