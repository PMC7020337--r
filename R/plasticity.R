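#' Bilinear STDP weight delta for one sample
#'
#' The weight change of the synapse from presynaptic neuron `j` to
#' postsynaptic neuron `i` is proportional to the product of the presynaptic
#' potential and the postsynaptic potential derivative:
#' `dW[j, i] = rate * V_pre[j] * dV_post[i]` — an outer product.  `V_pre` is
#' the final-quarter time-averaged potential of the presynaptic layer (for
#' the input layer, its average spike rate) and `dV_post` the total potential
#' change applied to the postsynaptic neuron over the window divided by the
#' window length, so a converged neuron (`dV_post = 0`) stops learning.
#'
#' @param V_pre presynaptic potentials (length = rows of the weight matrix).
#' @param dV_post postsynaptic potential derivatives (length = columns).
#' @param rate positive proportionality constant; the sign of the update is
#'   carried by `dV_post`.
#' @param source tag, `"hidden-input"` or `"output-hidden"`.
#'
#' @return An object of class `"weight_delta"`: list with `dW` (matrix),
#'   `source`, `batch_size = 1`.
#' @export
#' @examples
#' bistdp_delta(c(1, 2), 3, rate = 0.1)$dW
bistdp_delta <- function(V_pre, dV_post, rate, source = "hidden-input") {
  dW <- rate * outer(as.numeric(V_pre), as.numeric(dV_post))
  if (any(!is.finite(dW))) stop("non-finite weight delta")
  structure(list(dW = dW, source = source, batch_size = 1L),
            class = "weight_delta")
}

# batch form: rows of V_pre/dV_post are samples; crossprod sums the
# per-sample outer products, apply_updates divides by batch_size.
bistdp_batch <- function(V_pre, dV_post, rate, source = "hidden-input") {
  dW <- rate * crossprod(V_pre, dV_post)
  if (any(!is.finite(dW))) stop("non-finite weight delta")
  structure(list(dW = dW, source = source, batch_size = nrow(V_pre)),
            class = "weight_delta")
}

#' Apply a (batch-averaged) weight delta
#'
#' Returns `clip(W + dW / batch_size, bounds)`; the input matrix is left
#' unchanged.  Deltas from the samples of one batch are summed by the caller
#' and averaged here, so weights are updated once per batch.
#'
#' @param W weight matrix.
#' @param delta a [bistdp_delta()] object (or one summed over a batch).
#' @param bounds length-2 numeric clipping bounds, or `NULL` for no clipping.
#' @return The updated weight matrix.
#' @export
apply_updates <- function(W, delta, bounds = NULL) {
  if (!all(dim(W) == dim(delta$dW))) stop("weight/delta shape mismatch")
  W2 <- W + delta$dW / delta$batch_size
  if (!is.null(bounds)) W2 <- pmin(pmax(W2, bounds[1]), bounds[2])
  W2
}
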