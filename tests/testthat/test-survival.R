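test_that("cox_fit matches brute-force partial-likelihood maximization", {
  # small hand-listed instances, untied and tied times
  cases <- list(
    list(x = c(0, 0, 0, 0, 1, 1, 1, 1),
         time = c(5, 8, 2, 10, 1, 3, 4, 9),
         event = c(1, 1, 1, 0, 1, 1, 0, 1)),
    list(x = c(0.2, -1.3, 0.5, 2.1, -0.4, 0.9, -2.0, 1.1),
         time = c(3, 7, 2, 1, 9, 4, 12, 6),
         event = c(1, 0, 1, 1, 1, 1, 0, 1)),
    list(x = c(0, 1, 0, 1, 0, 1, 0, 1),
         time = c(2, 2, 5, 5, 8, 3, 9, 4),   # tied event times
         event = c(1, 1, 1, 1, 0, 1, 1, 1)))
  for (cs in cases) {
    fit <- cox_fit(cs$x, cs$time, cs$event)
    brute <- optimize(function(b) oracle_cox_loglik(b, cs$x, cs$time, cs$event),
                      c(-5, 5), maximum = TRUE)
    expect_equal(unname(fit$coefficients), brute$maximum, tolerance = 1e-4)
    expect_equal(fit$loglik, brute$objective, tolerance = 1e-6)
  }
})

test_that("cox_fit output invariants and degenerate designs", {
  set.seed(51)
  x <- rnorm(40); out <- toy_survival(x, loghr = 0.8, seed = 51)
  fit <- cox_fit(x, out$time, out$event)
  expect_true(fit$hr > 0)
  expect_true(fit$ci95[1] < fit$hr && fit$hr < fit$ci95[2])
  expect_error(cox_fit(cbind(x, x), out$time, out$event), "singularity")
  expect_error(cox_fit(x, out$time, rep(FALSE, 40)), "no events")
  # perfect separation -> divergence error
  xs <- c(rep(0, 10), rep(1, 10))
  tm <- c(seq(1, 5.5, 0.5), seq(20, 24.5, 0.5))
  expect_error(cox_fit(xs, tm, rep(TRUE, 20)), "divergence")
})

test_that("cox null calibration: |coef| < 4 se in >= 95% of seeds", {
  ok <- logical(50)
  for (s in seq_len(50)) {
    set.seed(700 + s)
    x <- rnorm(200)
    out <- simulate_survival(x, 0, 0.05, 0.3)
    fit <- cox_fit(x, out$time, out$event)
    ok[s] <- abs(fit$coefficients) < 4 * fit$se
  }
  expect_gte(mean(ok), 0.95)
})

test_that("log-rank test matches the frozen hand computation and survdiff", {
  # 6-sample worked example (O-E and variance accumulated by hand):
  # A: 1+, 3+, 5c ; B: 2+, 4+, 6+  ->  O-E = 4/15, V = 0.9622222
  g <- c("A", "A", "A", "B", "B", "B")
  tm <- c(1, 3, 5, 2, 4, 6)
  ev <- c(1, 1, 0, 1, 1, 1)
  lr <- logrank_test(g, tm, ev)
  expect_equal(lr$statistic, (4 / 15)^2 / 0.9622222, tolerance = 1e-6)
  # agreement with the survival package on random data, plus label symmetry
  for (s in 1:5) {
    set.seed(60 + s)
    x <- rbinom(30, 1, 0.5)
    if (length(unique(x)) < 2) next
    out <- toy_survival(rnorm(30), loghr = 0, seed = 60 + s)
    mine <- logrank_test(x, out$time, out$event)
    ref <- survival::survdiff(survival::Surv(out$time, out$event) ~ x)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
    flipped <- logrank_test(1 - x, out$time, out$event)
    expect_equal(flipped$statistic, mine$statistic, tolerance = 1e-12)
  }
  # identical survival in both groups -> statistic ~ 0
  lr0 <- logrank_test(c("A", "B", "A", "B"), c(3, 3, 7, 7), c(1, 1, 1, 1))
  expect_lt(lr0$statistic, 1e-12)
  expect_error(logrank_test(rep("A", 5), 1:5, rep(1, 5)), "grouping error")
})

test_that("maxstat equals exhaustive enumeration on random toys", {
  for (s in 1:40) {
    set.seed(800 + s)
    n <- sample(10:15, 1)
    x <- rnorm(n)
    out <- toy_survival(rnorm(n), loghr = 0, seed = 800 + s, censor = 0.2)
    ms <- maxstat_cutpoint(x, out$time, out$event)
    or <- oracle_maxstat(x, out$time, out$event)
    expect_equal(ms$max_stat, or$max_stat, tolerance = 1e-9)
    expect_equal(ms$cutoff, or$cutoff)
    expect_equal(ms$candidate_grid$stat, or$grid$stat, tolerance = 1e-9)
  }
})

test_that("maxstat is invariant under strictly monotone transforms", {
  set.seed(91)
  x <- rnorm(40)
  out <- toy_survival(x, loghr = 1, seed = 91)
  m1 <- maxstat_cutpoint(x, out$time, out$event)
  m2 <- maxstat_cutpoint(exp(x), out$time, out$event)
  expect_equal(m2$max_stat, m1$max_stat, tolerance = 1e-9)
  expect_equal(m2$cutoff, exp(m1$cutoff), tolerance = 1e-9)
  expect_equal(m2$p_adj, m1$p_adj, tolerance = 1e-9)
})

test_that("maxstat degenerate inputs raise cutpoint errors", {
  out <- toy_survival(rnorm(12), seed = 1)
  expect_error(maxstat_cutpoint(rep(1, 12), out$time, out$event),
               "cutpoint error")
  expect_error(maxstat_cutpoint(rnorm(5), out$time[1:5], out$event[1:5]),
               "cutpoint error|>= 10")
})

test_that("maxstat permutation p agrees with the analytic approximation", {
  set.seed(95)
  x <- rnorm(20)
  out <- toy_survival(x, loghr = 1.2, seed = 95)
  ms_l <- maxstat_cutpoint(x, out$time, out$event)
  set.seed(1)
  ms_p <- maxstat_cutpoint(x, out$time, out$event, pmethod = "permutation",
                           n_perm = 500)
  expect_equal(ms_p$cutoff, ms_l$cutoff)
  # both should point the same way at alpha = 0.1
  expect_equal(ms_p$p_adj < 0.1, ms_l$p_adj < 0.1)
})

test_that("planted threshold effects are localized by maxstat", {
  hits <- 0; n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    set.seed(900 + s)
    n <- 300
    x <- rnorm(n)
    thr <- quantile(x, 0.6)
    out <- simulate_survival(as.numeric(x > thr), log(2), 0.05, 0.25)
    ms <- maxstat_cutpoint(x, out$time, out$event)
    if (abs(mean(x <= ms$cutoff) - 0.6) <= 0.10) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("dichotomize_and_compare partitions exactly at the cutoff", {
  set.seed(97)
  x <- rnorm(20)
  out <- toy_survival(x, loghr = 1, seed = 97)
  dc <- dichotomize_and_compare(x, out$time, out$event)
  expect_identical(as.character(dc$groups),
                   ifelse(x <= dc$maxstat$cutoff, "low", "high"))
  expect_true(dc$logrank_p <= 1 && dc$logrank_p >= 0)
  # planted adverse high-expression effect has positive direction
  set.seed(98)
  x2 <- rnorm(100)
  out2 <- simulate_survival(x2, 1.2, 0.05, 0.2)
  dc2 <- dichotomize_and_compare(x2, out2$time, out2$event)
  expect_equal(dc2$direction, 1)
})
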