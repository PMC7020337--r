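test_that("novelty estimate matches the cosine-distance geometry", {
  expect_equal(novelty_estimate(c(2, 0), c(1, 0)), 0)       # parallel
  expect_equal(novelty_estimate(c(0, 1), c(1, 0)), 1)       # orthogonal
  expect_equal(novelty_estimate(c(-3, 0), c(1, 0)), 2)      # antiparallel
  expect_equal(novelty_estimate(c(1, 0), c(1, 1)), 1 - 1 / sqrt(2),
               tolerance = 1e-10)
  expect_equal(novelty_estimate(c(0, 0), c(1, 0)), 2)       # zero-norm output
  expect_error(novelty_estimate(c(1, 0), c(0, 0)), "nonzero norm")
  # matrix form agrees with the scalar form row by row
  Vk <- rbind(c(1, 0), c(0, 0), c(0.3, -0.2))
  VT <- rbind(c(1, 1), c(1, 0), c(0, 1))
  expect_equal(novelty_estimate(Vk, VT),
               sapply(1:3, function(i) novelty_estimate(Vk[i, ], VT[i, ])))
})

test_that("novelty stays in [0, 2] over many random pairs", {
  set.seed(99)
  n <- 1e5
  Vk <- matrix(rnorm(n * 5), n, 5)
  Vk[sample(n, 100), ] <- 0                   # include zero-norm outputs
  VT <- matrix(rnorm(n * 5), n, 5)
  VT[abs(rowSums(VT^2)) < 1e-12, 1] <- 1
  ne <- novelty_estimate(Vk, VT)
  expect_true(all(ne >= 0 & ne <= 2))
  expect_equal(unname(ne[rowSums(Vk^2) == 0][1]), 2)
})

test_that("threshold selection equals a brute-force scan, boundary included", {
  expect_equal(select_samples(c(0.04, 0.05, 0.30), 0.05), c(2L, 3L))
  expect_equal(select_samples(c(0.04, 0.05, 0.30), 0), 1:3)
  set.seed(31)
  for (i in 1:50) {
    ne <- round(runif(1000, 0, 2), 3)
    th <- sample(ne, 1)                        # guarantees boundary cases
    picked <- select_samples(ne, th)
    brute <- integer(0)
    for (k in seq_along(ne)) if (ne[k] >= th) brute <- c(brute, k)
    expect_identical(picked, brute)
  }
  # data-frame novelty tables return ids, not positions
  tab <- data.frame(id = c(7L, 3L, 9L), NE = c(0.1, 0.01, 0.05))
  expect_equal(select_samples(tab, 0.05), c(7L, 9L))
})

test_that("epoch kinds match an independent schedule trace", {
  sch <- schedule_config(n_epochs = 11, T_start = 1, I_re = 5)
  e0 <- sch$T_start
  kinds <- character(11)
  for (e in 1:11) {
    ek <- epoch_kind(e, e0, sch); kinds[e] <- ek$kind; e0 <- ek$e_0
  }
  expect_equal(which(kinds == "full"), c(1, 6, 11))

  # I_re = 1 makes every epoch full; T_start covers its prefix regardless
  sch1 <- schedule_config(n_epochs = 6, T_start = 1, I_re = 1)
  e0 <- 1; k1 <- sapply(1:6, function(e) {
    ek <- epoch_kind(e, e0, sch1); e0 <<- ek$e_0; ek$kind })
  expect_true(all(k1 == "full"))
  sch3 <- schedule_config(n_epochs = 5, T_start = 3, I_re = 9)
  e0 <- 3; k3 <- sapply(1:5, function(e) {
    ek <- epoch_kind(e, e0, sch3); e0 <<- ek$e_0; ek$kind })
  expect_equal(k3[1:3], rep("full", 3))

  # 200 random (T_start, I_re, n_epochs) triples against the oracle,
  # plus the closed-form full-epoch count
  set.seed(12)
  for (i in 1:200) {
    ts <- sample(1:5, 1); ire <- sample(1:7, 1); ne <- ts + sample(0:25, 1)
    sch <- schedule_config(n_epochs = ne, T_start = ts, I_re = ire)
    e0 <- ts
    kinds <- character(ne)
    for (e in seq_len(ne)) {
      ek <- epoch_kind(e, e0, sch); kinds[e] <- ek$kind; e0 <- ek$e_0
    }
    expect_equal(kinds, trace_schedule_kinds(ts, ire, ne))
    expect_equal(sum(kinds == "full"), ts + floor((ne - ts) / ire))
  }
})

test_that("schedule configuration validates its invariants", {
  expect_error(schedule_config(T_start = 0), "T_start")
  expect_error(schedule_config(I_re = 0), "I_re")
  expect_error(schedule_config(n_epochs = 2, T_start = 5), "n_epochs")
  expect_error(schedule_config(NE_th = 2.5), "NE_th")
})

test_that("computation ratio reproduces hand-computed presentation arithmetic", {
  mk_log <- function(pres, n) {
    l <- data.frame(epoch = seq_along(pres), presentations = pres)
    attr(l, "n_samples") <- n
    l
  }
  N <- 100
  # full epochs {1, 6} plus 8 selective epochs of N/2 -> 6N of 10N
  cb <- mk_log(c(N, rep(N / 2, 4), N, rep(N / 2, 4)), N)
  base <- mk_log(rep(N, 10), N)
  expect_equal(computation_ratio(cb, base), 0.6)
  expect_equal(computation_ratio(base, base), 1)
  expect_error(computation_ratio(mk_log(rep(N, 9), N), base), "epochs")
  expect_error(computation_ratio(mk_log(rep(N, 10), 50), base), "sizes")
})

test_that("on a frozen novelty table the ratio is nonincreasing in NE_th", {
  set.seed(77)
  ne <- runif(300, 0, 1.5)
  n_full <- 4; n_sel <- 16; N <- length(ne)
  ratio_at <- function(th) {
    sel <- length(select_samples(ne, th))
    (n_full * N + n_sel * sel) / ((n_full + n_sel) * N)
  }
  ths <- seq(0, 2, by = 0.05)
  ratios <- sapply(ths, ratio_at)
  expect_true(all(diff(ratios) <= 0))
  expect_equal(ratios[1], 1)                  # NE_th = 0 selects everything
})

test_that("curiosity training with NE_th = 0 is bitwise identical to the baseline", {
  ds <- tiny_dataset(seed = 5)
  sch0 <- schedule_config(n_epochs = 6, NE_th = 0)
  schb <- schedule_config(n_epochs = 6)
  f0 <- cbsnn(ds, mode = "cbsnn", schedule = sch0, seed = 7, hidden = 8)
  fb <- cbsnn(ds, mode = "baseline", schedule = schb, seed = 7, hidden = 8)
  expect_identical(f0$W1, fb$W1)
  expect_identical(f0$W2, fb$W2)
  num <- c("epoch", "selected", "presentations", "cumulative",
           "loss", "accuracy")
  expect_identical(f0$log[num], fb$log[num])
  expect_equal(computation_ratio(f0, fb), 1)
})

test_that("training logs honour the schedule and accounting invariants", {
  ds <- tiny_dataset(seed = 6)
  sch <- schedule_config(n_epochs = 8, T_start = 2, I_re = 3)
  fit <- cbsnn(ds, mode = "cbsnn", schedule = sch, seed = 2, hidden = 8)
  log <- fit$log
  expect_equal(log$kind, trace_schedule_kinds(2, 3, 8))
  n <- nrow(ds$features)
  expect_true(all(log$selected[log$kind == "full"] == n))
  expect_equal(log$cumulative, cumsum(log$presentations))
  # novelty estimates stay inside the cosine-distance range
  expect_true(all(fit$novelty$NE >= 0 & fit$novelty$NE <= 2))
  expect_true(all(fit$novelty$last_updated <= 8))
  expect_equal(sort(fit$novelty$id), seq_len(n))
})

test_that("an empty selective epoch trains nothing and is not an error", {
  ds <- tiny_dataset(seed = 7)
  # threshold just under the maximum: after the first full epoch nearly all
  # (here: all) estimates fall below it
  sch <- schedule_config(n_epochs = 4, NE_th = 1.999)
  fit <- cbsnn(ds, mode = "cbsnn", schedule = sch, seed = 3, hidden = 8)
  sel <- fit$log[fit$log$kind == "selective", ]
  expect_true(any(sel$selected == 0))
  expect_true(all(sel$presentations[sel$selected == 0] == 0))
})

test_that("novelty of trained samples shrinks as the task is learned", {
  ds <- tiny_dataset(seed = 9)
  f1 <- cbsnn(ds, mode = "baseline",
              schedule = schedule_config(n_epochs = 1), seed = 4, hidden = 10)
  f12 <- cbsnn(ds, mode = "baseline",
               schedule = schedule_config(n_epochs = 12), seed = 4, hidden = 10)
  expect_lt(mean(f12$novelty$NE), mean(f1$novelty$NE))
})
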