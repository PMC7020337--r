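#' Configuration of the three-layer spiking network
#'
#' The network is a fully connected input -> hidden -> output LIF network.
#' Each sample is presented for `T` Euler steps of size `dt`.  Within the
#' window two membrane updates are blended: the feed-forward conductance
#' dynamics (weight `t/T` at step `t`) and an equilibrium-state relaxation
#' that nudges each potential toward consistency with its weighted inputs
#' (weight `1 - t/T`), so the equilibrium correction dominates early and the
#' feed-forward dynamics late.  The output layer is additionally clamped
#' toward the teacher signal at every step during training.
#'
#' @param layer_sizes integer triple `(input, hidden, output)` widths.
#' @param T simulation window in steps (>= 1).
#' @param dt Euler step size.
#' @param eta_i equilibrium tuning rate (> 0).
#' @param eta_c supervised clamp rate (> 0).  Deliberately weak by default:
#'   the clamped output then deviates from the teacher in proportion to how
#'   wrong the network's own drive still is, which is exactly the residual
#'   the cosine-distance novelty score thresholds.
#' @param stdp_rate proportionality constant of the bilinear STDP update
#'   (output projection).
#' @param stdp_rate_hidden proportionality constant for the input-to-hidden
#'   projection; defaults to `stdp_rate / 50`.  The hidden projection has no
#'   supervised error signal — its updates are purely Hebbian — so it drifts
#'   rather than converges and is kept well below the error-driven output
#'   projection's rate.
#' @param max_rate encoder peak firing probability per step.
#' @param encode_mode `"rate"` for Bernoulli rate coding, `"current"` for the
#'   deterministic constant-drive encoder.
#' @param w_bounds length-2 numeric, weight clipping bounds, or `NULL` for
#'   unbounded weights.
#' @param es_threshold_mode how the firing-threshold term enters the
#'   equilibrium target: `"count"` subtracts `V_th` once per presynaptic
#'   neuron, `"single"` subtracts one `V_th`.
#' @param vprime_mode how the postsynaptic potential derivative of the STDP
#'   rule is read out: `"window_total"` (total applied potential change over
#'   the window divided by `T`) or `"last_step"` (the final step's change).
#' @param params_hidden,params_output [neuron_params()] for each plastic
#'   layer.
#' @param teacher_amplitude,teacher_baseline teacher signal levels used
#'   during training; the defaults give a one-hot teacher.  Passing
#'   `teacher_baseline = NULL` resolves to `-amplitude/(n_classes - 1)`,
#'   a zero-mean push-pull teacher whose clamp depresses wrong-class
#'   potentials as much as it raises the target.
#' @param readout_fraction fraction of the window (from the end) over which
#'   potentials are time-averaged for the readout `V_k` and the presynaptic
#'   STDP factors, in `(0, 1]`.
#' @param seed master seed for weight initialization and encoding.
#'
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(layer_sizes, T = 100, dt = 1,
                           eta_i = 0.1, eta_c = 0.02, stdp_rate = 8,
                           stdp_rate_hidden = NULL,
                           max_rate = 0.5,
                           encode_mode = c("current", "rate"),
                           w_bounds = c(-3, 3),
                           es_threshold_mode = c("single", "count"),
                           vprime_mode = c("window_total", "last_step"),
                           params_hidden = neuron_params(),
                           params_output = neuron_params(),
                           teacher_amplitude = 1, teacher_baseline = 0,
                           readout_fraction = 0.25, seed = 1) {
  if (length(layer_sizes) != 3) stop("exactly three layers are required")
  if (any(layer_sizes < 1)) stop("layer sizes must be positive")
  if (T < 1) stop("T must be >= 1")
  if (eta_i <= 0 || eta_c <= 0 || stdp_rate <= 0) stop("rates must be positive")
  structure(list(layer_sizes = as.integer(layer_sizes), T = as.integer(T),
                 dt = dt, eta_i = eta_i, eta_c = eta_c, stdp_rate = stdp_rate,
                 stdp_rate_hidden = stdp_rate_hidden %||% (stdp_rate / 50),
                 max_rate = max_rate, encode_mode = match.arg(encode_mode),
                 w_bounds = w_bounds,
                 es_threshold_mode = match.arg(es_threshold_mode),
                 vprime_mode = match.arg(vprime_mode),
                 params_hidden = params_hidden, params_output = params_output,
                 teacher_amplitude = teacher_amplitude,
                 teacher_baseline = teacher_baseline,
                 readout_fraction = readout_fraction,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Initialize a network from its configuration
#'
#' Weights of each projection are drawn uniformly from `[-w0, w0]` with
#' `w0 = 1/sqrt(fan_in)`, reproducibly from `config$seed`; both layer states
#' start at rest (`V = V_L`, `g_E = 0`).
#'
#' @param config a [network_config()].
#' @return A list with `config`, weight matrices `W1`
#'   (input x hidden) and `W2` (hidden x output), of class `"snn_network"`.
#' @export
init_network <- function(config) {
  sz <- config$layer_sizes
  old <- .Random.seed_save()
  set.seed(config$seed)
  w0_1 <- 1 / sqrt(sz[1])
  w0_2 <- 1 / sqrt(sz[2])
  W1 <- matrix(stats::runif(sz[1] * sz[2], -w0_1, w0_1), sz[1], sz[2])
  W2 <- matrix(stats::runif(sz[2] * sz[3], -w0_2, w0_2), sz[2], sz[3])
  .Random.seed_restore(old)
  structure(list(config = config, W1 = W1, W2 = W2), class = "snn_network")
}

#' Equilibrium-state membrane correction
#'
#' Relaxes each postsynaptic potential toward consistency with its weighted
#' presynaptic potentials.  The correction is
#' `-eta_i * [ (V - (t(W) V_pre - thr)) + (V - V_L) + (g_E/g_L)(V - V_E) ]`,
#' where `thr` is the firing-threshold term: `V_th` times the presynaptic
#' count when `es_threshold_mode = "count"`, a single `V_th` when `"single"`.
#' All three bracketed terms are restorative corrections of the same sign
#' convention, so the update is a single damped relaxation.
#'
#' @param V postsynaptic potentials (vector).
#' @param W_in weight matrix, presynaptic x postsynaptic.
#' @param V_pre presynaptic potentials (vector).
#' @param g_E postsynaptic conductances (vector).
#' @param params [neuron_params()] of the postsynaptic layer.
#' @param eta_i equilibrium tuning rate.
#' @param es_threshold_mode `"single"` or `"count"`.
#' @return The correction vector `delta_es`.
#' @export
equilibrium_delta <- function(V, W_in, V_pre, g_E, params, eta_i = 0.1,
                              es_threshold_mode = "single") {
  if (any(!is.finite(V)) || any(!is.finite(V_pre)) || any(!is.finite(g_E)))
    stop("non-finite inputs to equilibrium_delta")
  thr <- if (es_threshold_mode == "count") params$V_th * nrow(W_in)
         else params$V_th
  target <- drop(V_pre %*% W_in) - thr
  .es_delta(V, g_E, target, params, eta_i)
}

#' Blend the feed-forward and equilibrium deltas
#'
#' Returns `(t/T) * delta_ff + (1 - t/T) * delta_es`: the equilibrium
#' correction carries the update early in the presentation window and the
#' feed-forward dynamics take over as `t` approaches `T`.
#'
#' @param delta_ff,delta_es numeric vectors of equal length.
#' @param t current step, `0 <= t <= T`.
#' @param T window length (> 0).
#' @return The blended delta vector.
#' @export
blended_update <- function(delta_ff, delta_es, t, T) {
  if (T == 0) stop("window length T must be positive")
  if (t < 0 || t > T) stop("t must lie in [0, T]")
  (t / T) * delta_ff + (1 - t / T) * delta_es
}

#' Supervised clamp of output potentials toward the teacher
#'
#' Returns `dV = -eta_c * (V_out - V_T)`.  Repeated application with
#' `0 < eta_c < 1` contracts the output geometrically toward the teacher.
#'
#' @param V_out output potentials.
#' @param teacher a [make_teacher()] object or a numeric vector.
#' @param eta_c clamp rate.
#' @return The clamp increment `dV`.
#' @export
supervised_clamp <- function(V_out, teacher, eta_c = 0.5) {
  V_T <- if (inherits(teacher, "teacher_signal")) teacher$V_T else teacher
  if (length(V_out) != length(V_T)) stop("output/teacher dimension mismatch")
  -eta_c * (V_out - V_T)
}

#' Sum-of-squares potential loss
#'
#' `C = sum_i (V_i - V_T_i)^2` over output neurons.
#'
#' @inheritParams supervised_clamp
#' @return Nonnegative scalar, zero iff the vectors are equal.
#' @export
potential_loss <- function(V_out, teacher) {
  V_T <- if (inherits(teacher, "teacher_signal")) teacher$V_T else teacher
  if (length(V_out) != length(V_T)) stop("output/teacher dimension mismatch")
  sum((V_out - V_T)^2)
}

# ---------------------------------------------------------------------------
# Batched presentation engine.
#
# Simulates B independent samples simultaneously: every dynamic variable is a
# B x width matrix and each Euler step is a handful of matrix operations.
# This is the single code path behind present_sample(), training and
# prediction; the exported per-neuron operations above define the same
# arithmetic on vectors and are cross-checked against this engine in the
# test suite.
#
# input: T x B x d array of encoded drive (0/1 spikes or graded current).
# teacher: optional B x k matrix of teacher potentials.
# Returns time-averaged readouts over the final ceil(T/4) steps (V_k and the
# presynaptic averages used by the STDP rule), the accumulated applied
# potential change per neuron (the discrete potential derivative), and an
# optional full single-sample trace.
run_window <- function(net, input, teacher = NULL, record = FALSE) {
  cfg <- net$config
  ph <- cfg$params_hidden; po <- cfg$params_output
  Tw <- cfg$T; dt <- cfg$dt
  d <- dim(input)[3]; B <- dim(input)[2]
  h <- cfg$layer_sizes[2]; k <- cfg$layer_sizes[3]
  thr1 <- if (cfg$es_threshold_mode == "count") ph$V_th * d else ph$V_th
  thr2 <- if (cfg$es_threshold_mode == "count") po$V_th * h else po$V_th

  Vh <- matrix(ph$V_L, B, h); gh <- matrix(0, B, h)
  refh <- matrix(0L, B, h)
  Vo <- matrix(po$V_L, B, k); go <- matrix(0, B, k)
  refo <- matrix(0L, B, k)
  # free-running copy of the output layer: same conductance drive, no
  # teacher clamp; its potentials are the readout V_k so novelty and
  # decoding reflect what the network produces on its own.
  Vf <- matrix(po$V_L, B, k); reff <- matrix(0L, B, k)
  acc_h <- matrix(0, B, h); acc_o <- matrix(0, B, k)
  acc_f <- matrix(0, B, k)
  last_h <- matrix(0, B, h); last_o <- matrix(0, B, k)
  last_f <- matrix(0, B, k)
  q <- ceiling(Tw * cfg$readout_fraction); tail_start <- Tw - q + 1
  sum_in <- matrix(0, B, d); sum_h <- matrix(0, B, h); sum_o <- matrix(0, B, k)
  trace <- if (record) vector("list", Tw) else NULL

  for (t in seq_len(Tw)) {
    s_in <- matrix(input[t, , ], B, d)

    # hidden layer -----------------------------------------------------------
    gh <- .cond_step(gh, ph$eta_g * (s_in %*% net$W1), ph$tau_E, dt)
    act_h <- refh == 0L
    dff_h <- .mem_delta(Vh, gh, ph, dt)
    des_h <- .es_delta(Vh, gh, s_in %*% net$W1 - thr1, ph, cfg$eta_i)
    dV_h <- (t / Tw) * dff_h + (1 - t / Tw) * des_h
    dV_h[!act_h] <- 0
    Vh <- Vh + dV_h; acc_h <- acc_h + dV_h; last_h <- dV_h
    if (t >= tail_start) sum_h <- sum_h + Vh   # pre-reset readout
    sp_h <- act_h & (Vh >= ph$V_th)
    refh[!act_h] <- refh[!act_h] - 1L
    # reset jumps count toward the hidden net displacement, so the
    # unsupervised potential derivative stays bounded for firing neurons
    acc_h[sp_h] <- acc_h[sp_h] + (ph$V_reset - Vh[sp_h])
    Vh[sp_h] <- ph$V_reset
    refh[sp_h] <- ph$t_ref
    sp_h_num <- matrix(as.numeric(sp_h), B, h)

    # output layer -----------------------------------------------------------
    go <- .cond_step(go, po$eta_g * (sp_h_num %*% net$W2), po$tau_E, dt)
    es_in_o <- Vh %*% net$W2 - thr2
    act_o <- refo == 0L
    dff_o <- .mem_delta(Vo, go, po, dt)
    des_o <- .es_delta(Vo, go, es_in_o, po, cfg$eta_i)
    dV_o <- (t / Tw) * dff_o + (1 - t / Tw) * des_o
    dV_o[!act_o] <- 0
    Vo <- Vo + dV_o; acc_o <- acc_o + dV_o; last_o <- dV_o
    if (!is.null(teacher)) {
      dsup <- -cfg$eta_c * (Vo - teacher)
      dsup[!act_o] <- 0
      Vo <- Vo + dsup; acc_o <- acc_o + dsup; last_o <- last_o + dsup
    }
    # readout: the presentation's own output potentials (clamped when a
    # teacher is present), sampled pre-reset
    if (t >= tail_start && !is.null(teacher)) sum_o <- sum_o + Vo
    sp_o <- act_o & (Vo >= po$V_th)
    refo[!act_o] <- refo[!act_o] - 1L
    Vo[sp_o] <- po$V_reset
    refo[sp_o] <- po$t_ref

    # free-running output (readout path)
    act_f <- reff == 0L
    dV_f <- (t / Tw) * .mem_delta(Vf, go, po, dt) +
      (1 - t / Tw) * .es_delta(Vf, go, es_in_o, po, cfg$eta_i)
    dV_f[!act_f] <- 0
    Vf <- Vf + dV_f; acc_f <- acc_f + dV_f; last_f <- dV_f
    if (t >= tail_start && is.null(teacher)) sum_o <- sum_o + Vf
    sp_f <- act_f & (Vf >= po$V_th)
    reff[!act_f] <- reff[!act_f] - 1L
    Vf[sp_f] <- po$V_reset
    reff[sp_f] <- po$t_ref

    if (t >= tail_start) sum_in <- sum_in + s_in
    if (record) {
      trace[[t]] <- list(step = t, dff_h = dff_h[1, ], des_h = des_h[1, ],
                         dff_o = dff_o[1, ], des_o = des_o[1, ],
                         V_h = Vh[1, ], V_o = Vo[1, ],
                         sp_h = as.integer(sp_h[1, ]),
                         sp_o = as.integer(sp_o[1, ]))
    }
  }

  # output potential derivative: the teacher-attributable part, i.e. the
  # clamped trajectory's accumulated change minus the free-running one's.
  # It vanishes exactly when the network already reproduces the teacher
  # (a converged neuron stops learning) and each extra teacher-induced
  # spike contributes V_th of depolarization, so it acts as a
  # rate-difference error code.  Without a teacher both paths coincide and
  # no supervised signal remains.
  vp_h <- if (cfg$vprime_mode == "last_step") last_h else acc_h / Tw
  vp_o <- if (cfg$vprime_mode == "last_step") last_o - last_f
          else (acc_o - acc_f) / Tw
  list(V_k = sum_o / q, Vbar_hidden = sum_h / q, Vbar_input = sum_in / q,
       vprime_hidden = vp_h, vprime_output = vp_o, trace = trace)
}

#' Present one encoded sample to the network
#'
#' Runs the full `T`-step window: per step, conductance and membrane updates
#' (the feed-forward delta), the equilibrium-state correction, their
#' time-blended combination, the optional supervised clamp on the output
#' layer, and threshold firing with reset for both plastic layers.  The
#' output readout `V_k` is the mean output potential over the final quarter
#' of the window, sampled after the membrane update but before threshold
#' reset, which smooths over spike-reset artifacts and keeps the readout of
#' a strongly driven (frequently firing) neuron above that of a quiet one.
#'
#' @param net an [init_network()] object.
#' @param spike_train a [rate_encode()]/[current_encode()] object whose width
#'   matches the input layer.
#' @param teacher optional [make_teacher()] target; when given, the output
#'   layer is clamped toward it at every step.
#' @param learn when `TRUE`, the bilinear STDP update is computed from this
#'   presentation and applied to the returned network's weights.
#' @param record_trace when `TRUE`, the per-step state of the first sample is
#'   kept and returned as a data frame (columns: step, layer, neuron, V,
#'   delta_ff, delta_es, spike).
#'
#' @return A list with `V_k` (output readout vector), `network` (unchanged
#'   unless `learn = TRUE`), and `trace` (`NULL` or a data frame).
#' @export
present_sample <- function(net, spike_train, teacher = NULL, learn = FALSE,
                           record_trace = FALSE) {
  cfg <- net$config
  sp <- spike_train$spikes
  if (ncol(sp) != cfg$layer_sizes[1])
    stop("spike train width does not match the input layer")
  if (spike_train$duration != cfg$T)
    stop("spike train duration does not match the simulation window")
  input <- array(sp, c(cfg$T, 1, ncol(sp)))
  tm <- if (is.null(teacher)) NULL else matrix(teacher$V_T, 1)
  out <- run_window(net, input, tm, record = record_trace)
  if (learn) {
    d1 <- bistdp_batch(out$Vbar_input, out$vprime_hidden, cfg$stdp_rate_hidden,
                       source = "hidden-input")
    d2 <- bistdp_batch(out$Vbar_hidden, out$vprime_output, cfg$stdp_rate,
                       source = "output-hidden")
    net$W1 <- apply_updates(net$W1, d1, cfg$w_bounds)
    net$W2 <- apply_updates(net$W2, d2, cfg$w_bounds)
  }
  trace <- if (record_trace) flatten_trace(out$trace) else NULL
  list(V_k = drop(out$V_k), network = net, trace = trace)
}

# long-format per-step trace (single sample) for debugging / serialization
flatten_trace <- function(steps) {
  do.call(rbind, lapply(steps, function(s) {
    rbind(
      data.frame(step = s$step, layer = "hidden",
                 neuron = seq_along(s$V_h), V = s$V_h,
                 delta_ff = s$dff_h, delta_es = s$des_h, spike = s$sp_h),
      data.frame(step = s$step, layer = "output",
                 neuron = seq_along(s$V_o), V = s$V_o,
                 delta_ff = s$dff_o, delta_es = s$des_o, spike = s$sp_o)
    )
  }))
}
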