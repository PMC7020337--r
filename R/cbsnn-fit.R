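#' Fit a curiosity-trained spiking neural network classifier
#'
#' Trains a three-layer conductance-based LIF network on labelled feature
#' vectors.  Per presentation, feed-forward spiking dynamics are blended with
#' an equilibrium-state membrane correction over the simulation window, the
#' output layer is clamped toward a one-hot teacher signal, and weights
#' receive a bilinear STDP update (presynaptic potential times postsynaptic
#' potential derivative), averaged per batch.
#'
#' Under `mode = "cbsnn"` the curiosity scheduler runs: after `T_start` full
#' epochs, each epoch retrains only samples whose novelty — the cosine
#' distance between their output potentials and their teacher signal —
#' reaches `NE_th`, with a full review every `I_re` epochs.  `"baseline"`
#' trains every sample every epoch; `"random_subset"` trains a uniform
#' random fraction each epoch.
#'
#' @param x numeric feature matrix (samples x features, values in `[0, 1]`)
#'   or a [labeled_dataset()].
#' @param y integer vector of 0-based class labels (ignored when `x` is a
#'   `labeled_dataset`).
#' @param mode training strategy; see Details.
#' @param hidden hidden-layer width.
#' @param config a [network_config()]; by default one is built from the data
#'   dimensions, `hidden` and `seed`.
#' @param schedule a [schedule_config()].
#' @param subset_fraction fraction trained per epoch in `"random_subset"`
#'   mode, in `(0, 1]`.
#' @param fixed_subset in `"random_subset"` mode, keep one fixed subset for
#'   all epochs instead of resampling each epoch.
#' @param seed master seed (used when `config` is not supplied).
#' @param verbose print one line per epoch.
#' @param ... unused.
#'
#' @return An object of class `"cbsnn"`: a list with the fitted weights
#'   (`W1`, `W2`), `config`, `schedule`, `mode`, the per-epoch training
#'   `log`, the final novelty table `novelty`, `classes`, and `call`.
#' @seealso [predict.cbsnn()], [computation_ratio()], [run_experiment()]
#' @export
#' @examples
#' ds <- synth_clusters(3, 30, dims = 4, separation = 8, seed = 1)
#' fit <- cbsnn(ds, schedule = schedule_config(n_epochs = 3), hidden = 10)
#' fit
cbsnn <- function(x, ...) UseMethod("cbsnn")

#' @rdname cbsnn
#' @export
cbsnn.labeled_dataset <- function(x, ...) {
  fit <- cbsnn.default(x$features, x$labels, ...,
                       n_classes = x$n_classes, class_names = x$class_names)
  fit$call <- match.call()
  fit
}

#' @rdname cbsnn
#' @param n_classes number of classes; defaults to `max(y) + 1`.
#' @param class_names optional class names in code order.
#' @export
cbsnn.default <- function(x, y, mode = c("cbsnn", "baseline", "random_subset"),
                          hidden = 30, config = NULL, schedule = NULL,
                          subset_fraction = 0.5, fixed_subset = FALSE,
                          seed = 1, verbose = FALSE,
                          n_classes = NULL, class_names = NULL, ...) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) == 0) stop("dataset is empty")
  if (is.null(n_classes)) n_classes <- max(y) + 1L
  if (any(y < 0L | y >= n_classes)) stop("labels outside [0, n_classes)")
  if (is.null(config))
    config <- network_config(c(ncol(x), hidden, n_classes), seed = seed)
  if (config$layer_sizes[1] != ncol(x))
    stop("config input width does not match the data")
  if (config$layer_sizes[3] < n_classes)
    stop("config output width smaller than the number of classes")
  if (is.null(schedule)) schedule <- schedule_config()
  if (mode == "random_subset" &&
      (subset_fraction <= 0 || subset_fraction > 1))
    stop("random_subset requires 0 < subset_fraction <= 1")

  selection <- switch(mode, cbsnn = "curiosity", baseline = "full",
                      random_subset = "random")
  res <- fit_snn(x, y, config, schedule, selection = selection,
                 subset_fraction = subset_fraction,
                 fixed_subset = fixed_subset, verbose = verbose)
  structure(list(W1 = res$network$W1, W2 = res$network$W2,
                 config = config, schedule = schedule, mode = mode,
                 log = res$log, novelty = res$novelty,
                 n_samples = nrow(x), n_classes = n_classes,
                 classes = class_names %||% as.character(seq_len(n_classes) - 1L),
                 call = match.call()),
            class = "cbsnn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict classes or output potentials for new samples
#'
#' Presents each sample to the fitted network without a teacher signal and
#' reads out the mean output potentials over the final quarter of the
#' window; classes are decoded as the argmax (ties to the lowest index).
#'
#' @param object a fitted [cbsnn()] model.
#' @param newdata feature matrix in `[0, 1]` or a [labeled_dataset()].
#' @param type `"class"` for 0-based class codes, `"potential"` for the raw
#'   output potential matrix.
#' @param seed seed for the stochastic rate encoder (prediction is
#'   deterministic given it); defaults to a fixed offset of the training
#'   seed.
#' @param ... unused.
#' @return Integer class vector or potential matrix.
#' @export
predict.cbsnn <- function(object, newdata, type = c("class", "potential"),
                          seed = NULL, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "labeled_dataset")) newdata$features
       else as.matrix(newdata)
  cfg <- object$config
  if (ncol(x) != cfg$layer_sizes[1])
    stop("newdata width does not match the input layer")
  if (is.null(seed)) seed <- cfg$seed + 100003L
  cfg$seed <- as.integer(seed)
  net <- structure(list(config = cfg, W1 = object$W1, W2 = object$W2),
                   class = "snn_network")
  n <- nrow(x)
  bs <- 64L
  Vk <- matrix(0, n, cfg$layer_sizes[3])
  for (batch in split(seq_len(n), ceiling(seq_len(n) / bs))) {
    inp <- encode_batch(x, batch, cfg, e = 0L)
    Vk[batch, ] <- run_window(net, inp, teacher = NULL)$V_k
  }
  if (type == "potential") return(Vk)
  max.col(Vk, "first") - 1L
}

#' Classification accuracy of a fitted model on a dataset
#'
#' @param object a fitted [cbsnn()] model.
#' @param ds a [labeled_dataset()].
#' @param ... passed to [predict.cbsnn()].
#' @return Fraction of correctly classified samples.
#' @export
evaluate_accuracy <- function(object, ds, ...) {
  mean(predict(object, ds, ...) == ds$labels)
}

#' @export
print.cbsnn <- function(x, ...) {
  sz <- x$config$layer_sizes
  cat(sprintf("Curiosity-trained spiking network (%s mode)\n", x$mode))
  cat(sprintf("  layers %d-%d-%d, window %d steps, batch %d\n",
              sz[1], sz[2], sz[3], x$config$T, x$schedule$batch_size))
  cat(sprintf("  schedule: T_start=%d, NE_th=%.3g, I_re=%d, %d epochs run\n",
              x$schedule$T_start, x$schedule$NE_th, x$schedule$I_re,
              nrow(x$log)))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final epoch: loss %.4f, train accuracy %.3f\n",
              last$loss, last$accuracy))
  cat(sprintf("  presentations: %d (%.1f%% of full-data training)\n",
              last$cumulative,
              100 * last$cumulative / (nrow(x$log) * x$n_samples)))
  invisible(x)
}

#' @export
summary.cbsnn <- function(object, ...) {
  log <- object$log
  s <- list(
    mode = object$mode,
    layer_sizes = object$config$layer_sizes,
    epochs = nrow(log),
    full_epochs = sum(log$kind == "full"),
    presentations = log$cumulative[nrow(log)],
    presentation_fraction = log$cumulative[nrow(log)] /
      (nrow(log) * object$n_samples),
    final_loss = log$loss[nrow(log)],
    final_train_accuracy = log$accuracy[nrow(log)],
    novelty_mean = mean(object$novelty$NE),
    novelty_above_threshold = mean(object$novelty$NE >= object$schedule$NE_th),
    log = log)
  class(s) <- "summary.cbsnn"
  s
}

#' @export
print.summary.cbsnn <- function(x, ...) {
  cat(sprintf("Spiking network classifier, %s mode, layers %s\n",
              x$mode, paste(x$layer_sizes, collapse = "-")))
  cat(sprintf("  %d epochs (%d full), %d sample presentations (%.1f%% of full)\n",
              x$epochs, x$full_epochs, x$presentations,
              100 * x$presentation_fraction))
  cat(sprintf("  final loss %.4f, final train accuracy %.3f\n",
              x$final_loss, x$final_train_accuracy))
  cat(sprintf("  novelty: mean %.4f, %.1f%% of samples above threshold\n",
              x$novelty_mean, 100 * x$novelty_above_threshold))
  invisible(x)
}

#' @export
coef.cbsnn <- function(object, ...) {
  list(input_hidden = object$W1, hidden_output = object$W2)
}

#' Plot training progress of a fitted spiking network
#'
#' Two base-graphics panels: mean loss and selected-sample count per epoch,
#' with full-review epochs marked.
#'
#' @param x a fitted [cbsnn()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cbsnn <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  full <- log$epoch[log$kind == "full"]
  graphics::plot(log$epoch, log$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean loss",
                 main = sprintf("%s training", x$mode), ...)
  graphics::abline(v = full, col = "grey70", lty = 3)
  graphics::plot(log$epoch, log$selected, type = "h", lwd = 3,
                 xlab = "epoch", ylab = "samples trained")
  graphics::abline(h = x$n_samples, col = "grey50", lty = 2)
  invisible(x)
}
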