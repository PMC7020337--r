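#' Curiosity schedule configuration
#'
#' The training schedule has four phases: (1) `T_start` initial epochs train
#' the full dataset and seed the novelty table; (2) subsequent epochs train
#' only samples whose novelty estimate reaches `NE_th`; (3) every `I_re`
#' epochs the full dataset is reviewed once, guarding against overfitting of
#' novel samples and forgetting of learned ones; (4) steps 2-3 repeat until
#' `n_epochs` epochs have run (optionally stopping early when the mean loss
#' stabilizes across consecutive full epochs).
#'
#' @param n_epochs total number of epochs (>= `T_start`).
#' @param T_start number of initial full-dataset epochs (>= 1).
#' @param NE_th novelty threshold, in `[0, 2]` (the range of the cosine
#'   distance).  `0` disables selection: every epoch trains everything.
#' @param I_re retrain interval in epochs (>= 1).
#' @param batch_size samples per weight update.
#' @param refresh_all_novelty when `TRUE`, selective epochs also re-evaluate
#'   the novelty of unselected samples (at the cost of presenting them);
#'   default `FALSE`, their estimate refreshes at the next full epoch.
#' @param early_stop stop after a full epoch whose mean loss differs from
#'   the previous full epoch's by less than `tol`.
#' @param tol early-stopping tolerance on the mean loss.
#' @return An object of class `"schedule_config"`.
#' @export
schedule_config <- function(n_epochs = 20, T_start = 1, NE_th = 0.05,
                            I_re = 5, batch_size = 32,
                            refresh_all_novelty = FALSE,
                            early_stop = FALSE, tol = 1e-4) {
  if (T_start < 1) stop("T_start must be >= 1")
  if (I_re < 1) stop("I_re must be >= 1")
  if (n_epochs < T_start) stop("n_epochs must be >= T_start")
  if (NE_th < 0 || NE_th > 2) stop("NE_th must lie in [0, 2]")
  structure(list(n_epochs = as.integer(n_epochs), T_start = as.integer(T_start),
                 NE_th = NE_th, I_re = as.integer(I_re),
                 batch_size = as.integer(batch_size),
                 refresh_all_novelty = refresh_all_novelty,
                 early_stop = early_stop, tol = tol),
            class = "schedule_config")
}

#' Novelty estimate: cosine distance from the teacher signal
#'
#' `NE = 1 - (V_k . V_T) / (||V_k|| ||V_T||)`, in `[0, 2]`: 0 for outputs
#' parallel to the teacher, 1 for orthogonal, 2 for antiparallel.  A
#' zero-norm output carries no class information and is assigned the maximal
#' novelty 2 by convention.
#'
#' @param V_k output potential vector (or a matrix with samples in rows).
#' @param V_T teacher vector, or [make_teacher()] object (matrix with
#'   matching rows when `V_k` is a matrix).
#' @return Scalar (or vector) novelty in `[0, 2]`.
#' @export
#' @examples
#' novelty_estimate(c(1, 0), c(1, 1))  # 1 - 1/sqrt(2)
novelty_estimate <- function(V_k, V_T) {
  if (inherits(V_T, "teacher_signal")) V_T <- V_T$V_T
  if (is.matrix(V_k)) {
    if (!is.matrix(V_T)) V_T <- matrix(V_T, nrow(V_k), length(V_T), byrow = TRUE)
    nk <- sqrt(rowSums(V_k^2)); nt <- sqrt(rowSums(V_T^2))
    if (any(nt == 0)) stop("teacher signal must have nonzero norm")
    ne <- 1 - rowSums(V_k * V_T) / (nk * nt)
    ne[nk == 0] <- 2
    return(pmin(pmax(ne, 0), 2))
  }
  nk <- sqrt(sum(V_k^2)); nt <- sqrt(sum(V_T^2))
  if (nt == 0) stop("teacher signal must have nonzero norm")
  if (nk == 0) return(2)
  min(max(1 - sum(V_k * V_T) / (nk * nt), 0), 2)
}

#' Threshold selection of novel samples
#'
#' Returns the ids of samples whose novelty estimate reaches the threshold;
#' the boundary `NE = NE_th` is selected.
#'
#' @param table a novelty table: data frame with columns `id` and `NE` (as
#'   kept by the trainer), or a bare numeric vector of novelty values.
#' @param NE_th threshold in `[0, 2]`.
#' @return Integer vector of selected sample ids (the `id` column, or
#'   indices when `table` is a vector).
#' @export
select_samples <- function(table, NE_th) {
  if (is.data.frame(table)) table$id[table$NE >= NE_th]
  else which(table >= NE_th)
}

#' Kind of the next training epoch
#'
#' Reproduces the scheduler's control flow: epochs up to `T_start` are full;
#' afterwards an epoch is full when `e - e_0` reaches the retrain interval
#' (and `e_0`, the last full-training epoch marker, advances to `e`),
#' otherwise selective.
#'
#' @param e epoch index (1-based, >= 1).
#' @param e_0 last full-training epoch marker (initially `T_start`).
#' @param schedule a [schedule_config()].
#' @return List with `kind` (`"full"` or `"selective"`) and the updated
#'   `e_0`.
#' @export
epoch_kind <- function(e, e_0, schedule) {
  if (e <= schedule$T_start) {
    list(kind = "full", e_0 = schedule$T_start)
  } else if (e - e_0 == schedule$I_re) {
    list(kind = "full", e_0 = e)
  } else {
    list(kind = "selective", e_0 = e_0)
  }
}

#' Ratio of sample presentations between two training logs
#'
#' Computation is accounted in sample presentations (one presentation = one
#' full `T`-step simulation of one sample), a hardware-independent proxy for
#' training time.  Returns total presentations of the first log divided by
#' the second's.
#'
#' @param log_cbsnn,log_baseline training logs (data frames with a
#'   `presentations` column) or fitted [cbsnn()] objects.
#' @return Scalar ratio.
#' @export
computation_ratio <- function(log_cbsnn, log_baseline) {
  l1 <- if (inherits(log_cbsnn, "cbsnn")) log_cbsnn$log else log_cbsnn
  l2 <- if (inherits(log_baseline, "cbsnn")) log_baseline$log else log_baseline
  if (nrow(l1) != nrow(l2))
    stop("training logs cover different numbers of epochs")
  n1 <- attr(l1, "n_samples"); n2 <- attr(l2, "n_samples")
  if (!is.null(n1) && !is.null(n2) && n1 != n2)
    stop("training logs cover different dataset sizes")
  sum(l1$presentations) / sum(l2$presentations)
}

# deterministic per-epoch seed derived from the master seed; kept < 2^31
epoch_seed <- function(master, e) {
  (as.integer(master) %% 100003L) * 20011L + e * 7919L
}

# encode the given samples with per-sample seeds that depend only on
# (master seed, epoch, sample id) -> selection cannot perturb encoding
encode_batch <- function(features, ids, cfg, e) {
  Tw <- cfg$T; d <- ncol(features)
  arr <- array(0, c(Tw, length(ids), d))
  enc <- if (cfg$encode_mode == "rate") rate_encode else current_encode
  for (b in seq_along(ids)) {
    st <- enc(features[ids[b], ], cfg$max_rate, Tw,
              seed = epoch_seed(cfg$seed, e) + ids[b])
    arr[, b, ] <- st$spikes
  }
  arr
}

# ---------------------------------------------------------------------------
# Core training loop shared by all strategies.
#
# selection = "curiosity": the four-step schedule (full until T_start,
#   novelty-thresholded afterwards, full review every I_re epochs).
# selection = "full": every epoch trains the whole dataset (the plain
#   baseline; the curiosity machinery is bypassed entirely).
# selection = "random": every epoch trains a uniform random subset of size
#   floor(subset_fraction * N), resampled each epoch unless fixed_subset.
fit_snn <- function(x, y, config, schedule, selection = "curiosity",
                    subset_fraction = 1, fixed_subset = FALSE,
                    verbose = FALSE) {
  n <- nrow(x)
  k <- config$layer_sizes[3]
  tb <- config$teacher_baseline %||%
    (-config$teacher_amplitude / max(k - 1, 1))
  teacher_mat <- matrix(tb, k, k)
  diag(teacher_mat) <- config$teacher_amplitude   # row = label + 1

  net <- init_network(config)
  novelty <- data.frame(id = seq_len(n), NE = rep(2, n), last_updated = 0L)
  log_rows <- vector("list", schedule$n_epochs)
  e_0 <- schedule$T_start
  cum <- 0
  prev_full_loss <- NA_real_
  fixed_ids <- NULL
  if (selection == "random" && fixed_subset) {
    old <- .Random.seed_save()
    set.seed(epoch_seed(config$seed, 0L))
    fixed_ids <- sort(sample(n, max(1L, floor(subset_fraction * n))))
    .Random.seed_restore(old)
  }

  for (e in seq_len(schedule$n_epochs)) {
    if (selection == "curiosity") {
      ek <- epoch_kind(e, e_0, schedule)
      e_0 <- ek$e_0
      kind <- ek$kind
      ids <- if (kind == "full") seq_len(n)
             else select_samples(novelty, schedule$NE_th)
    } else if (selection == "full") {
      kind <- "full"; ids <- seq_len(n)
    } else {
      kind <- "random"
      if (fixed_subset) ids <- fixed_ids
      else {
        old <- .Random.seed_save()
        set.seed(epoch_seed(config$seed, e) + 1L)
        ids <- sort(sample(n, max(1L, floor(subset_fraction * n))))
        .Random.seed_restore(old)
      }
    }

    n_sel <- length(ids)
    losses <- numeric(0); correct <- 0L
    if (n_sel > 0) {
      old <- .Random.seed_save()
      set.seed(epoch_seed(config$seed, e))
      ids <- ids[sample.int(n_sel)]
      .Random.seed_restore(old)
      batches <- split(ids, ceiling(seq_along(ids) / schedule$batch_size))
      losses <- numeric(n_sel); pos <- 0L
      for (batch in batches) {
        inp <- encode_batch(x, batch, config, e)
        tch <- teacher_mat[y[batch] + 1L, , drop = FALSE]
        out <- run_window(net, inp, tch)
        d1 <- bistdp_batch(out$Vbar_input, out$vprime_hidden,
                           config$stdp_rate_hidden, "hidden-input")
        d2 <- bistdp_batch(out$Vbar_hidden, out$vprime_output,
                           config$stdp_rate, "output-hidden")
        net$W1 <- apply_updates(net$W1, d1, config$w_bounds)
        net$W2 <- apply_updates(net$W2, d2, config$w_bounds)
        ne_new <- novelty_estimate(out$V_k, tch)
        novelty$NE[batch] <- ne_new
        novelty$last_updated[batch] <- e
        losses[pos + seq_along(batch)] <- rowSums((out$V_k - tch)^2)
        pos <- pos + length(batch)
        correct <- correct + sum(max.col(out$V_k, "first") == y[batch] + 1L)
      }
    }
    if (selection == "curiosity" && kind == "selective" &&
        schedule$refresh_all_novelty) {
      rest <- setdiff(seq_len(n), ids)
      if (length(rest) > 0) {
        for (batch in split(rest, ceiling(seq_along(rest) / schedule$batch_size))) {
          inp <- encode_batch(x, batch, config, e)
          tch <- teacher_mat[y[batch] + 1L, , drop = FALSE]
          out <- run_window(net, inp, tch)   # evaluation only, no learning
          novelty$NE[batch] <- novelty_estimate(out$V_k, tch)
          novelty$last_updated[batch] <- e
        }
        n_sel <- n_sel + length(rest)   # these presentations are paid for
      }
    }

    cum <- cum + n_sel
    mean_loss <- if (length(losses)) mean(losses) else NA_real_
    acc <- if (length(ids)) correct / length(ids) else NA_real_
    log_rows[[e]] <- data.frame(
      epoch = e, kind = kind, selected = length(ids),
      presentations = n_sel, cumulative = cum,
      loss = mean_loss, accuracy = acc)
    if (verbose)
      message(sprintf("epoch %3d [%9s] selected %4d  loss %.4f  acc %.3f",
                      e, kind, length(ids), mean_loss, acc))

    if (schedule$early_stop && kind == "full" && !is.na(mean_loss)) {
      if (!is.na(prev_full_loss) &&
          abs(mean_loss - prev_full_loss) < schedule$tol) {
        log_rows <- log_rows[seq_len(e)]
        break
      }
      prev_full_loss <- mean_loss
    }
  }

  log <- do.call(rbind, log_rows)
  attr(log, "n_samples") <- n
  list(network = net, log = log, novelty = novelty)
}
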