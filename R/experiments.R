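#' Run one training strategy and report accuracy and computation
#'
#' Trains the requested strategy on the training split, evaluates test
#' accuracy, and reports the computation ratio against a seed-matched
#' full-data baseline (= 1 for the baseline itself).  One row per seed.
#'
#' @param mode `"baseline"`, `"random_subset"` or `"cbsnn"`.
#' @param train,test [labeled_dataset()] splits.
#' @param hidden hidden-layer width.
#' @param schedule a [schedule_config()].
#' @param seeds integer vector of master seeds.
#' @param subset_fraction fraction for `"random_subset"` mode.
#' @param fixed_subset see [cbsnn()].
#' @param baseline_fits optional list of prefitted baseline models (one per
#'   seed) to reuse for the computation ratio.
#' @param ... further arguments to [cbsnn()].
#'
#' @return A data frame with columns `mode`, `seed`, `accuracy`,
#'   `computation_ratio`, `presentations`, `epochs`; the fitted models are
#'   attached as the `"fits"` attribute.
#' @export
run_experiment <- function(mode, train, test, hidden = 30,
                           schedule = schedule_config(), seeds = 1L,
                           subset_fraction = 0.5, fixed_subset = FALSE,
                           baseline_fits = NULL, ...) {
  rows <- vector("list", length(seeds))
  fits <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    fit <- cbsnn(train, mode = mode, hidden = hidden, schedule = schedule,
                 seed = s, subset_fraction = subset_fraction,
                 fixed_subset = fixed_subset, ...)
    if (mode == "baseline") {
      ratio <- 1
    } else {
      base <- if (!is.null(baseline_fits)) baseline_fits[[i]]
              else cbsnn(train, mode = "baseline", hidden = hidden,
                         schedule = schedule, seed = s, ...)
      ratio <- computation_ratio(fit, base)
    }
    rows[[i]] <- data.frame(
      mode = mode, seed = s,
      accuracy = evaluate_accuracy(fit, test),
      computation_ratio = ratio,
      presentations = fit$log$cumulative[nrow(fit$log)],
      epochs = nrow(fit$log))
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Compare the three training strategies
#'
#' Reproduces the strategy-comparison design: a full-data baseline, a
#' random-subset control matched to the curiosity run's selected fraction,
#' and the curiosity schedule itself, all on the same splits and seeds.
#'
#' @inheritParams run_experiment
#' @param subset_fraction fraction for the random-subset control; when `NA`
#'   it is set to the curiosity run's mean presentation fraction so the two
#'   reduced strategies spend comparable computation.
#' @return A data frame with one row per strategy and seed.
#' @export
compare_strategies <- function(train, test, hidden = 30,
                               schedule = schedule_config(), seeds = 1L,
                               subset_fraction = NA, ...) {
  base <- run_experiment("baseline", train, test, hidden, schedule, seeds, ...)
  cb <- run_experiment("cbsnn", train, test, hidden, schedule, seeds,
                       baseline_fits = attr(base, "fits"), ...)
  if (is.na(subset_fraction))
    subset_fraction <- max(0.01, min(1, mean(cb$computation_ratio)))
  rs <- run_experiment("random_subset", train, test, hidden, schedule, seeds,
                       subset_fraction = subset_fraction,
                       baseline_fits = attr(base, "fits"), ...)
  out <- rbind(base, rs, cb)
  attr(out, "fits") <- c(attr(base, "fits"), attr(rs, "fits"),
                         attr(cb, "fits"))
  out
}

#' One-at-a-time hyperparameter sweep of the curiosity schedule
#'
#' Varies exactly one of `T_start`, `NE_th`, `I_re` over `values`, holding
#' the rest of the schedule fixed, and reports test accuracy and computation
#' ratio per value (averaged over seeds).
#'
#' @param param one of `"T_start"`, `"NE_th"`, `"I_re"`.
#' @param values numeric vector of settings to try.
#' @inheritParams run_experiment
#' @return A data frame with columns `param`, `value`, `accuracy`,
#'   `computation_ratio`.
#' @export
sweep_hyperparameter <- function(param = c("T_start", "NE_th", "I_re"),
                                 values, train, test, hidden = 30,
                                 schedule = schedule_config(), seeds = 1L,
                                 ...) {
  param <- match.arg(param)
  base <- run_experiment("baseline", train, test, hidden, schedule, seeds, ...)
  rows <- lapply(values, function(v) {
    sc <- schedule
    sc[[param]] <- if (param == "NE_th") v else as.integer(v)
    r <- run_experiment("cbsnn", train, test, hidden, sc, seeds,
                        baseline_fits = attr(base, "fits"), ...)
    data.frame(param = param, value = v,
               accuracy = mean(r$accuracy),
               computation_ratio = mean(r$computation_ratio))
  })
  do.call(rbind, rows)
}
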