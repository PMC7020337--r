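make_splits <- function(seed = 5) {
  train_test_split(tiny_dataset(seed = seed), 0.25, seed = seed)
}

test_that("baseline mode reports a computation ratio of one by definition", {
  sp <- make_splits()
  rep <- run_experiment("baseline", sp$train, sp$test, hidden = 8,
                        schedule = schedule_config(n_epochs = 4), seeds = 3L)
  expect_equal(rep$computation_ratio, 1)
  expect_equal(rep$presentations, 4 * nrow(sp$train$features))
})

test_that("random-subset mode presents exactly the subset size each epoch", {
  sp <- make_splits()
  n <- nrow(sp$train$features)
  sch <- schedule_config(n_epochs = 10)
  rep <- run_experiment("random_subset", sp$train, sp$test, hidden = 8,
                        schedule = sch, seeds = 3L, subset_fraction = 0.5)
  fit <- attr(rep, "fits")[[1]]
  expect_true(all(fit$log$presentations == floor(0.5 * n)))
  expect_equal(rep$presentations, 10 * floor(0.5 * n))
  expect_equal(rep$computation_ratio, floor(0.5 * n) / n)
  # fresh resampling per epoch vs a fixed subset
  fixed <- cbsnn(sp$train, mode = "random_subset", hidden = 8,
                 schedule = sch, seed = 3, subset_fraction = 0.5,
                 fixed_subset = TRUE)
  expect_error(cbsnn(sp$train, mode = "random_subset",
                     subset_fraction = 0), "subset_fraction")
  expect_equal(nrow(fixed$log), 10)
})

test_that("the curiosity strategy spends less computation than the baseline", {
  ds <- synth_clusters(3, 100, dims = 4, separation = 6,
                       overlap_fraction = 0.2, seed = 4)
  sp <- train_test_split(ds, 0.25, seed = 4)
  rep <- compare_strategies(sp$train, sp$test,
                            schedule = schedule_config(n_epochs = 20),
                            seeds = 2L)
  expect_equal(nrow(rep), 3)
  cb <- rep[rep$mode == "cbsnn", ]
  expect_lt(cb$computation_ratio, 1)
  expect_equal(rep[rep$mode == "baseline", ]$computation_ratio, 1)
})

test_that("reports are byte-identical across reruns with the same settings", {
  sp <- make_splits(seed = 8)
  sch <- schedule_config(n_epochs = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  r1 <- run_experiment("cbsnn", sp$train, sp$test, hidden = 8,
                       schedule = sch, seeds = 11L)
  r2 <- run_experiment("cbsnn", sp$train, sp$test, hidden = 8,
                       schedule = sch, seeds = 11L)
  write.csv(r1, f1, row.names = FALSE)
  write.csv(r2, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("sweeps vary exactly one schedule parameter", {
  sp <- make_splits(seed = 12)
  sch <- schedule_config(n_epochs = 6, I_re = 2)
  sw <- sweep_hyperparameter("I_re", c(1, 3), sp$train, sp$test, hidden = 8,
                             schedule = sch, seeds = 2L)
  expect_equal(sw$param, rep("I_re", 2))
  expect_equal(sw$value, c(1, 3))
  expect_true(all(is.finite(sw$computation_ratio)))
})

test_that("fitted model methods expose the usual modelling surface", {
  sp <- make_splits(seed = 4)
  fit <- cbsnn(sp$train, schedule = schedule_config(n_epochs = 4),
               hidden = 8, seed = 2)
  expect_s3_class(fit, "cbsnn")
  expect_output(print(fit), "Curiosity-trained spiking network")
  s <- summary(fit)
  expect_s3_class(s, "summary.cbsnn")
  expect_output(print(s), "presentations")
  cf <- coef(fit)
  expect_equal(dim(cf$input_hidden), c(4, 8))
  expect_equal(dim(cf$hidden_output), c(8, 3))
  pred <- predict(fit, sp$test)
  expect_length(pred, nrow(sp$test$features))
  expect_true(all(pred %in% 0:2))
  pot <- predict(fit, sp$test, type = "potential")
  expect_equal(dim(pot), c(nrow(sp$test$features), 3))
  expect_equal(max.col(pot, "first") - 1L, pred)
  acc <- evaluate_accuracy(fit, sp$test)
  expect_gte(acc, 0); expect_lte(acc, 1)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("checkpoints round-trip a fitted model through JSON", {
  sp <- make_splits(seed = 6)
  fit <- cbsnn(sp$train, schedule = schedule_config(n_epochs = 3),
               hidden = 8, seed = 5)
  f <- tempfile(fileext = ".json")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_equal(back$W1, fit$W1)
  expect_equal(back$W2, fit$W2)
  expect_identical(predict(back, sp$test), predict(fit, sp$test))
  bad <- tempfile(); jsonlite::write_json(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})

test_that("the CLI trains, evaluates, and rejects bad usage", {
  out <- tempfile(); dir.create(out)
  suppressMessages({
    code <- cbsnn_cli(c("train", "--data", "synthetic",
                        "--n-per-class", "15", "--epochs", "4",
                        "--hidden", "6", "--seed", "2", "--out", out))
  })
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "training_log.csv")))
  expect_true(file.exists(file.path(out, "novelty.csv")))
  expect_true(file.exists(file.path(out, "checkpoint.json")))
  log <- read.csv(file.path(out, "training_log.csv"))
  expect_equal(log$kind[1], "full")

  suppressMessages({
    code2 <- cbsnn_cli(c("evaluate", "--data", "synthetic",
                         "--n-per-class", "15", "--seed", "2",
                         "--checkpoint", file.path(out, "checkpoint.json")))
  })
  expect_equal(code2, 0L)

  expect_equal(suppressMessages(cbsnn_cli(c("train", "--bogus"))), 2L)
  expect_equal(suppressMessages(cbsnn_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(
    cbsnn_cli(c("evaluate", "--data", "synthetic"))), 1L)
})

test_that("YAML configuration merges over defaults and rejects typos", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("schedule:", "  NE_th: 0.1", "  I_re: 3",
               "data:", "  n_per_class: 12"), f)
  cfg <- read_config(f)
  expect_equal(cfg$schedule$NE_th, 0.1)
  expect_equal(cfg$schedule$I_re, 3)
  expect_equal(cfg$schedule$T_start, 1)        # untouched default
  expect_equal(cfg$data$n_per_class, 12)
  writeLines(c("sched:", "  NE_th: 0.1"), f)
  expect_error(read_config(f), "unknown config block")
  writeLines(c("schedule:", "  NE_thh: 0.1"), f)
  expect_error(read_config(f), "unknown key")
})
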