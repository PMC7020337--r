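#' Biophysical constants of a conductance-based LIF layer
#'
#' Bundles the per-layer constants of the leaky integrate-and-fire model with
#' an excitatory conductance channel: the membrane relaxes toward the leak
#' potential `V_L` with time constant `tau_m`, while the spike-driven
#' conductance `g_E` pulls it toward the excitatory reversal potential `V_E`
#' and itself decays with time constant `tau_E`.  A neuron fires when its
#' potential reaches `V_th`, is reset to `V_reset`, and is held there for
#' `t_ref` steps.
#'
#' All quantities are dimensionless; the defaults place the dynamics on a
#' convenient unit scale (resting potential 0, threshold 1).
#'
#' @param C_m membrane capacitance.
#' @param R_m membrane resistance.
#' @param g_L leak conductance (> 0).
#' @param V_L leak (resting) potential.
#' @param V_E excitatory reversal potential; must exceed `V_th`.
#' @param tau_E conductance time constant (> 0), in simulation steps.
#' @param tau_m membrane time constant (> 0), in simulation steps.
#' @param V_th firing threshold.
#' @param V_reset post-spike potential; must not exceed `V_L`.
#' @param t_ref refractory duration in steps (>= 0).
#' @param eta_g gain applied to the weighted presynaptic spike sum before it
#'   drives the conductance.
#'
#' @return An object of class `"neuron_params"`.
#' @export
#' @examples
#' p <- neuron_params()
#' p$tau_m
neuron_params <- function(C_m = 1, R_m = 1, g_L = 1, V_L = 0, V_E = 5,
                          tau_E = 5, tau_m = 10, V_th = 1, V_reset = 0,
                          t_ref = 2, eta_g = 1) {
  if (tau_E <= 0 || tau_m <= 0) stop("tau_E and tau_m must be positive")
  if (t_ref < 0) stop("t_ref must be >= 0")
  if (g_L <= 0) stop("g_L must be positive")
  if (!(V_reset <= V_L && V_L < V_th && V_th < V_E))
    stop("require V_reset <= V_L < V_th < V_E")
  structure(list(C_m = C_m, R_m = R_m, g_L = g_L, V_L = V_L, V_E = V_E,
                 tau_E = tau_E, tau_m = tau_m, V_th = V_th, V_reset = V_reset,
                 t_ref = as.integer(t_ref), eta_g = eta_g),
            class = "neuron_params")
}

#' Dynamic state of a LIF layer
#'
#' Holds the per-neuron dynamic variables: membrane potential `V`, excitatory
#' conductance `g_E`, the current-step spike indicator `spiked`, and the
#' remaining refractory steps `ref_remaining`.  A refractory neuron has its
#' potential frozen at the reset value and cannot spike.
#'
#' @param n layer width.
#' @param params a [neuron_params()] object supplying the resting potential.
#'
#' @return An object of class `"layer_state"` with equal-length vectors
#'   `V`, `g_E`, `spiked`, `ref_remaining`.
#' @export
layer_state <- function(n, params = neuron_params()) {
  if (n < 1) stop("layer width must be positive")
  structure(list(V = rep(params$V_L, n), g_E = rep(0, n),
                 spiked = integer(n), ref_remaining = integer(n)),
            class = "layer_state")
}

# elementwise cores shared by the vector ops and the batched engine -----------

.cond_step <- function(g_E, input, tau_E, dt) {
  pmax(g_E + dt / tau_E * (-g_E + input), 0)
}

.mem_delta <- function(V, g_E, params, dt) {
  dt / params$tau_m *
    (-(V - params$V_L) - (g_E / params$g_L) * (V - params$V_E))
}

.es_delta <- function(V, g_E, es_target, params, eta_i) {
  -eta_i * ((V - es_target) + (V - params$V_L) +
              (g_E / params$g_L) * (V - params$V_E))
}

#' Advance the excitatory conductance one Euler step
#'
#' Integrates `tau_E * dg/dt = -g_E + input`, where `input` is the weighted
#' presynaptic spike sum `eta_g * sum_j w[j,i] * spike_j`, already reduced
#' over presynaptic neurons.  The conductance is floored at zero so that a
#' transiently negative weighted input (weights may be negative) cannot leave
#' an unphysical negative conductance behind.
#'
#' @param state a [layer_state()].
#' @param weighted_spike_input numeric vector of layer width.
#' @param params a [neuron_params()].
#' @param dt Euler step size (> 0).
#'
#' @return The updated `layer_state`.
#' @export
update_conductance <- function(state, weighted_spike_input, params, dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (length(weighted_spike_input) != length(state$g_E))
    stop("weighted_spike_input length does not match layer width")
  state$g_E <- .cond_step(state$g_E, weighted_spike_input, params$tau_E, dt)
  state
}

#' Advance membrane potentials one Euler step
#'
#' Applies the conductance-based membrane equation
#' `tau_m * dV/dt = -(V - V_L) - (g_E/g_L) * (V - V_E)` to every
#' non-refractory neuron.  Refractory neurons receive a zero increment and
#' stay clamped at the reset potential.  The per-neuron increment is returned
#' alongside the state because the training rule blends this feed-forward
#' delta with an equilibrium-state delta.
#'
#' @inheritParams update_conductance
#' @return A list with elements `state` (updated) and `delta_ff` (the applied
#'   increment vector, zero for refractory neurons).
#' @export
update_membrane <- function(state, params, dt = 1) {
  if (any(!is.finite(state$V)) || any(!is.finite(state$g_E)))
    stop("non-finite values in layer state")
  delta <- .mem_delta(state$V, state$g_E, params, dt)
  delta[state$ref_remaining > 0] <- 0
  state$V <- state$V + delta
  list(state = state, delta_ff = delta)
}

#' Threshold crossing, reset and refractory bookkeeping
#'
#' Neurons at or above threshold (and not refractory) emit a spike, are reset
#' to `V_reset`, and enter refraction for `t_ref` steps.  Neurons already in
#' refraction count down by one step and cannot fire.
#'
#' @inheritParams update_conductance
#' @return A list with elements `state` (updated) and `spikes` (integer 0/1
#'   vector for the current step).
#' @export
fire_and_reset <- function(state, params) {
  active <- state$ref_remaining == 0L
  sp <- active & state$V >= params$V_th
  state$ref_remaining[!active] <- state$ref_remaining[!active] - 1L
  state$V[sp] <- params$V_reset
  state$ref_remaining[sp] <- params$t_ref
  state$spiked <- as.integer(sp)
  list(state = state, spikes = as.integer(sp))
}
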