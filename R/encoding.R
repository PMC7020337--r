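#' Bernoulli rate coding of a feature vector
#'
#' Converts a feature vector with entries in `[0, 1]` into a spike raster:
#' input neuron `i` fires independently at each step with probability
#' `features[i] * max_rate` (a discrete-time Poisson-style code).  The raster
#' is reproducible given `seed`; the seed is applied locally so the caller's
#' RNG stream is untouched.
#'
#' @param features numeric vector, entries in `[0, 1]` (min-max normalize
#'   first; see [normalize_features()]).
#' @param max_rate firing probability per step for a feature value of 1;
#'   in `(0, 1]`.
#' @param duration number of time steps (the network simulation window).
#' @param seed integer seed.
#'
#' @return An object of class `"spike_train"`: a list with `spikes` (a
#'   `duration x length(features)` 0/1 matrix), `duration`, `seed`.
#' @export
#' @examples
#' st <- rate_encode(c(0, 0.5, 1), max_rate = 0.5, duration = 20, seed = 1)
#' colMeans(st$spikes)
rate_encode <- function(features, max_rate = 0.5, duration = 100, seed = 1) {
  if (any(features < 0 | features > 1))
    stop("features must lie in [0, 1]; min-max normalize them first")
  if (max_rate <= 0 || max_rate > 1) stop("max_rate must be in (0, 1]")
  d <- length(features)
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(duration * d), duration, d)
  .Random.seed_restore(old)
  spikes <- matrix(as.integer(u < rep(features * max_rate, each = duration)),
                   duration, d)
  structure(list(spikes = spikes, duration = duration, seed = seed),
            class = "spike_train")
}

# save/restore the global RNG state so encoders are stream-neutral
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Deterministic constant-drive encoding
#'
#' The sampling-free alternative to [rate_encode()]: every step carries the
#' feature value itself (scaled by `max_rate`) as a graded drive instead of a
#' 0/1 spike.  Useful for reproducible unit tests and as a configuration
#' switch (`encode_mode = "current"`).
#'
#' @inheritParams rate_encode
#' @return A `"spike_train"` whose `spikes` matrix holds graded values in
#'   `[0, max_rate]` repeated over time.
#' @export
current_encode <- function(features, max_rate = 0.5, duration = 100, seed = 1) {
  if (any(features < 0 | features > 1))
    stop("features must lie in [0, 1]; min-max normalize them first")
  spikes <- matrix(rep(features * max_rate, each = duration),
                   duration, length(features))
  structure(list(spikes = spikes, duration = duration, seed = seed),
            class = "spike_train")
}

#' Build a teacher signal for a class label
#'
#' The teacher is a vector over output neurons with `amplitude` at the
#' labelled class and `baseline` elsewhere.  With the defaults (1, 0) it is a
#' one-hot vector, which makes the cosine-distance novelty of an output
#' reduce to one minus its normalized target component.
#'
#' @param label 0-based class index.
#' @param n_classes number of classes (output width).
#' @param amplitude teacher potential at the target neuron.
#' @param baseline teacher potential elsewhere; must differ from `amplitude`.
#'
#' @return An object of class `"teacher_signal"`: list with `V_T` (numeric
#'   vector) and `label`.
#' @export
make_teacher <- function(label, n_classes, amplitude = 1, baseline = 0) {
  if (label < 0 || label >= n_classes) stop("label out of range")
  if (amplitude == baseline) stop("amplitude must differ from baseline")
  v <- rep(baseline, n_classes)
  v[label + 1L] <- amplitude
  if (sum(v^2) == 0) stop("teacher signal must have nonzero norm")
  structure(list(V_T = v, label = as.integer(label)), class = "teacher_signal")
}

#' Decode output potentials to a class index
#'
#' Returns the 0-based index of the maximal output potential; ties go to the
#' lowest index so decoding is deterministic.
#'
#' @param V_out numeric vector of output-layer potentials.
#' @return Integer class index in `[0, length(V_out))`.
#' @export
decode_prediction <- function(V_out) {
  if (length(V_out) == 0) stop("V_out must be nonempty")
  if (any(!is.finite(V_out))) stop("non-finite output potentials")
  as.integer(which.max(V_out)) - 1L
}
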