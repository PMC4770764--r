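test_that("two-group fits equal hand-computed mean differences", {
  v <- rbind(p1 = c(10, 10, 8, 8), p2 = c(9, 11, 9, 11), p3 = c(5, 6, 7, 8))
  colnames(v) <- paste0("S", 1:4)
  x <- expression_matrix(v, scale = "log2")
  g <- c("MM", "MM", "BMPC", "BMPC")
  fit <- fit_probe_models(x, g, contrast = c("MM", "BMPC"))
  expect_equal(unname(fit$coefficients),
               c(mean(v[1, 1:2]) - mean(v[1, 3:4]),
                 mean(v[2, 1:2]) - mean(v[2, 3:4]),
                 mean(v[3, 1:2]) - mean(v[3, 3:4])))
  # identical groups: logFC 0, s2 = pooled within-group variance
  expect_equal(unname(fit$coefficients[2]), 0)
  expect_equal(unname(fit$sigma2[2]), (2 + 2) / 2)
  expect_equal(unname(fit$ave_expr), unname(rowMeans(v)))
  expect_error(fit_probe_models(x, c("MM", "MM", "MM", "BMPC"),
                                c("MM", "BMPC")), "design error")
})

test_that("zero prior df reduces the moderated t to the ordinary t", {
  x <- toy_expr(30, 10, seed = 21)
  g <- rep(c("A", "B"), each = 5)
  fit <- ebayes_moderate(fit_probe_models(x, g, c("A", "B")), prior_df = 0)
  tt <- apply(x$values, 1, function(v)
    t.test(v[1:5], v[6:10], var.equal = TRUE)$statistic)
  expect_equal(unname(fit$t_mod), unname(tt), tolerance = 1e-10)
  expect_equal(unname(fit$df_total), rep(8, 30))
})

test_that("posterior variances are convex combinations of prior and sample", {
  x <- toy_expr(50, 8, seed = 22)
  fit <- ebayes_moderate(fit_probe_models(x, rep(c("A", "B"), each = 4),
                                          c("A", "B")))
  lo <- pmin(fit$s0_2, fit$sigma2); hi <- pmax(fit$s0_2, fit$sigma2)
  expect_true(all(fit$s2_post >= lo - 1e-12 & fit$s2_post <= hi + 1e-12))
  expect_gt(fit$d0, 0)
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(23)
  n_probes <- 200
  sigma2 <- 4 / rchisq(n_probes, 4)  # true inv-chi-square dispersion
  v <- matrix(rnorm(n_probes * 12, 9, sqrt(sigma2)), n_probes,
              dimnames = list(sprintf("p%03d", 1:n_probes),
                              sprintf("S%02d", 1:12)))
  g <- rep(c("A", "B"), each = 6)
  x <- expression_matrix(v, scale = "log2")
  fit <- ebayes_moderate(fit_probe_models(x, g, c("A", "B")))
  expect_true(is.finite(fit$d0))
  design <- cbind(1, g == "A")
  lf <- limma::eBayes(limma::lmFit(x$values, design))
  expect_equal(unname(fit$coefficients), unname(lf$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_2, lf$s2.prior, tolerance = 1e-6)
  expect_equal(unname(fit$t_mod), unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit$p_raw), unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("hyperparameters are recovered from their generative model", {
  # probes with variances drawn from scaled inv-chi-square(d0 = 4, s02 = 1)
  d0_hat <- s0_hat <- numeric(5)
  for (s in 1:5) {
    set.seed(100 + s)
    n_probes <- 559; n <- 12
    sigma2 <- 4 * 1 / rchisq(n_probes, 4)
    v <- matrix(rnorm(n_probes * n, 9, sqrt(sigma2)), n_probes)
    dimnames(v) <- list(sprintf("p%03d", 1:n_probes), sprintf("S%02d", 1:n))
    x <- expression_matrix(v, scale = "log2")
    fit <- ebayes_moderate(fit_probe_models(x, rep(c("A", "B"), each = 6),
                                            c("A", "B")))
    d0_hat[s] <- fit$d0; s0_hat[s] <- fit$s0_2
  }
  expect_true(all(d0_hat > 2 & d0_hat < 8))
  expect_true(all(s0_hat > 0.7 & s0_hat < 1.4))
})

test_that("BH step-up matches hand application and is order-equivariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(31)
  p <- runif(100)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 0)), "domain error")
  expect_error(bh_adjust(c(0.5, 1.2)), "domain error")
})

test_that("signed fold change is odd, monotone, and matches closed forms", {
  expect_equal(signed_fold_change(0), 1)
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-1), -2)
  x <- seq(0.1, 3, by = 0.1)
  expect_equal(signed_fold_change(-x), -signed_fold_change(x))
  expect_true(all(diff(abs(signed_fold_change(x))) > 0))
  expect_true(all(abs(signed_fold_change(rnorm(50))) >= 1))
})

test_that("differential table counts and summary lines are correct", {
  set.seed(41)
  n_probes <- 100
  v <- matrix(rnorm(n_probes * 20, 9), n_probes,
              dimnames = list(sprintf("p%03d", 1:n_probes),
                              sprintf("S%02d", 1:20)))
  # plant strong effects: 4 up, 3 down in the first group
  v[1:4, 1:10] <- v[1:4, 1:10] + 3
  v[5:7, 1:10] <- v[5:7, 1:10] - 3
  x <- expression_matrix(v, scale = "log2")
  fit <- ebayes_moderate(fit_probe_models(x, rep(c("G1", "G2"), each = 10),
                                          c("G1", "G2")))
  tab <- differential_table(fit)
  s <- attr(tab, "summary")
  expect_equal(s$n_up, 4)
  expect_equal(s$n_down, 3)
  expect_equal(unname(s$lines["total"]), "7/100 (7.0%)")
  expect_true(all(tab$p_adj >= tab$p_raw))
  expect_equal(tab$fc_signed,
               ifelse(tab$logFC >= 0, 2^tab$logFC, -2^(-tab$logFC)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_differential_table(tab, path)
  reread <- read.delim(path)
  expect_equal(nrow(reread), n_probes)
})

test_that("planted differential probes are recovered with high sensitivity", {
  # balanced groups large enough to detect the weakest planted effect
  cfg <- sim_config(n_mm = 60, n_bmpc = 60, n_mgus = 2, n_hmcl = 2,
                    n_survival = 10, n_validation = 10, n_mrna_probes = 10,
                    seed = 77)
  sim <- generate_cohort(cfg)
  fit <- ebayes_moderate(fit_probe_models(sim$mirna, sim$annotation$group,
                                          c("MM", "BMPC")))
  tab <- differential_table(fit)
  hit <- tab$probe_id[tab$p_adj <= 0.05]
  planted <- sim$truth$de$MM_vs_BMPC$probe_id
  expect_gte(mean(planted %in% hit), 0.8)
  # recovered effect sizes track the planted log2 fold changes
  m <- match(planted, tab$probe_id)
  expect_lt(median(abs(tab$logFC[m] - sim$truth$de$MM_vs_BMPC$log2fc)), 0.2)
})
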