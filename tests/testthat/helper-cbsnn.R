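# Shared fixtures and independent oracles for the test suite.

tiny_dataset <- function(seed = 5, n_per_class = 20) {
  synth_clusters(3, n_per_class, dims = 4, separation = 8,
                 overlap_fraction = 0.1, seed = seed)
}

tiny_config <- function(..., seed = 3) {
  network_config(c(4, 8, 3), T = 40, ..., seed = seed)
}

# test-only IDX writer (big-endian), used to round-trip read_idx()
write_idx_images <- function(path, images) {  # images: n x rows x cols array
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(2051L, con, size = 4, endian = "big")
  writeBin(dim(images)[1], con, size = 4, endian = "big")
  writeBin(dim(images)[2], con, size = 4, endian = "big")
  writeBin(dim(images)[3], con, size = 4, endian = "big")
  # pixel bytes in row-major order per image
  for (i in seq_len(dim(images)[1]))
    writeBin(as.integer(t(images[i, , ])), con, size = 1)
}

write_idx_labels <- function(path, labels) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(2049L, con, size = 4, endian = "big")
  writeBin(length(labels), con, size = 4, endian = "big")
  writeBin(as.integer(labels), con, size = 1)
}

# independent trace of the four-step schedule's control flow
trace_schedule_kinds <- function(T_start, I_re, n_epochs) {
  e0 <- T_start
  kinds <- character(n_epochs)
  for (e in seq_len(n_epochs)) {
    if (e <= T_start) {
      kinds[e] <- "full"
    } else if (e - e0 == I_re) {
      kinds[e] <- "full"
      e0 <- e
    } else {
      kinds[e] <- "selective"
    }
  }
  kinds
}

# op-by-op reference simulation of one sample presentation, built from the
# exported per-layer operations; mirrors the batched engine independently.
reference_present <- function(net, spike_train, teacher = NULL) {
  cfg <- net$config
  ph <- cfg$params_hidden; po <- cfg$params_output
  Tw <- cfg$T; dt <- cfg$dt
  d <- ncol(spike_train$spikes)
  h <- cfg$layer_sizes[2]; k <- cfg$layer_sizes[3]
  sh <- layer_state(h, ph); so <- layer_state(k, po)
  sf <- layer_state(k, po)                    # free-running output copy
  q <- ceiling(Tw * cfg$readout_fraction)
  sum_o <- rep(0, k)
  esm <- cfg$es_threshold_mode
  for (t in seq_len(Tw)) {
    s_in <- spike_train$spikes[t, ]
    # hidden
    sh <- update_conductance(sh, ph$eta_g * drop(s_in %*% net$W1), ph, dt)
    dff <- update_membrane(sh, ph, dt)$delta_ff   # delta only, not applied
    des <- equilibrium_delta(sh$V, net$W1, s_in, sh$g_E, ph, cfg$eta_i, esm)
    dV <- blended_update(dff, des, t, Tw)
    dV[sh$ref_remaining > 0] <- 0
    sh$V <- sh$V + dV
    fr <- fire_and_reset(sh, ph); sh <- fr$state; sp_h <- fr$spikes
    # output (clamped)
    so <- update_conductance(so, po$eta_g * drop(sp_h %*% net$W2), po, dt)
    dff_o <- update_membrane(so, po, dt)$delta_ff
    des_o <- equilibrium_delta(so$V, net$W2, sh$V, so$g_E, po, cfg$eta_i, esm)
    dV_o <- blended_update(dff_o, des_o, t, Tw)
    dV_o[so$ref_remaining > 0] <- 0
    so$V <- so$V + dV_o
    if (!is.null(teacher)) {
      dsup <- supervised_clamp(so$V, teacher, cfg$eta_c)
      dsup[so$ref_remaining > 0] <- 0
      so$V <- so$V + dsup
    }
    if (t > Tw - q && !is.null(teacher)) sum_o <- sum_o + so$V
    so <- fire_and_reset(so, po)$state
    # output (free)
    sf$g_E <- so$g_E                           # same conductance drive
    dff_f <- update_membrane(sf, po, dt)$delta_ff
    des_f <- equilibrium_delta(sf$V, net$W2, sh$V, sf$g_E, po, cfg$eta_i, esm)
    dV_f <- blended_update(dff_f, des_f, t, Tw)
    dV_f[sf$ref_remaining > 0] <- 0
    sf$V <- sf$V + dV_f
    if (t > Tw - q && is.null(teacher)) sum_o <- sum_o + sf$V
    sf <- fire_and_reset(sf, po)$state
  }
  sum_o / q
}
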