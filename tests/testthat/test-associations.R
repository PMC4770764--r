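test_that("variance filter keeps ceil(fraction * n) most variable probes", {
  set.seed(101)
  v <- matrix(rnorm(559 * 8, 9), 559,
              dimnames = list(sprintf("p%03d", 1:559), sprintf("S%d", 1:8)))
  x <- expression_matrix(v, scale = "log2")
  f <- variance_filter(x, 0.2)
  expect_equal(nrow(f$values), 112)       # ceil(0.2 * 559)
  expect_true(all(probe_ids(f) %in% probe_ids(x)))
  # constant probes are always dropped before varying ones
  v2 <- v; v2[1:50, ] <- 5
  x2 <- expression_matrix(v2, scale = "log2")
  f2 <- variance_filter(x2, 0.5)
  expect_false(any(sprintf("p%03d", 1:50) %in% probe_ids(f2)))
  # identity at fraction 1
  expect_identical(variance_filter(x, 1)$values, x$values)
  # retained set has the highest variances
  vars <- apply(v, 1, var)
  expect_setequal(probe_ids(f), names(sort(vars, decreasing = TRUE))[1:112])
})

test_that("consensus filter honors the >= min_tools rule and is monotone", {
  calls <- rbind(g5 = c(1, 1, 1, 1, 1, 0, 0),
                 g6 = c(1, 1, 1, 1, 1, 1, 0),
                 g7 = c(1, 1, 1, 1, 1, 1, 1))
  colnames(calls) <- paste0("tool", 1:7)
  pt <- prediction_table(calls == 1)
  cs <- consensus_targets(pt, "miR-x", min_tools = 6)
  expect_setequal(cs$gene_ids, c("g6", "g7"))
  expect_setequal(consensus_targets(pt, "miR-x", min_tools = 0)$gene_ids,
                  rownames(calls))
  # raising min_tools never adds genes
  sets <- lapply(0:7, function(k)
    consensus_targets(pt, "miR-x", min_tools = k)$gene_ids)
  for (k in 2:8) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  expect_error(consensus_targets(pt, "miR-x", min_tools = 8), "exceeds")
})

test_that("correlation screen finds planted links and flags self-correlation", {
  set.seed(111)
  n <- 56
  a <- matrix(rnorm(5 * n, 9), 5,
              dimnames = list(paste0("mir", 1:5), paste0("S", 1:n)))
  b <- matrix(rnorm(8 * n, 8), 8,
              dimnames = list(paste0("g", 1:8), paste0("S", 1:n)))
  r <- 0.75
  b[1, ] <- 8 + r * scale(a[1, ])[, 1] + sqrt(1 - r^2) * rnorm(n)
  b[2, ] <- 8 - r * scale(a[2, ])[, 1] + sqrt(1 - r^2) * rnorm(n)
  hits <- correlation_screen(expression_matrix(a, scale = "log2"),
                             expression_matrix(b, scale = "log2"))
  key <- paste(hits$mirna_id, hits$mrna_probeset)
  expect_true(all(c("mir1 g1", "mir2 g2") %in% key))
  expect_lt(hits$r[key == "mir2 g2"], 0)
  expect_true(all(abs(hits$r) >= 0.6 & hits$p_adj <= 0.05))
  # x correlated with itself: r = 1, retained, not influence-flagged
  b2 <- rbind(b, self = a[1, ])
  hits2 <- correlation_screen(expression_matrix(a, scale = "log2"),
                              expression_matrix(b2, scale = "log2"))
  self_hit <- hits2[hits2$mrna_probeset == "self" & hits2$mirna_id == "mir1", ]
  expect_equal(self_hit$r, 1)
  expect_false(self_hit$influence_flag)
})

test_that("single-sample-driven correlations carry the influence flag", {
  set.seed(112)
  n <- 20
  a <- matrix(rnorm(n, 9), 1, dimnames = list("mir1", paste0("S", 1:n)))
  b <- matrix(rnorm(n, 8), 1, dimnames = list("g1", paste0("S", 1:n)))
  # one extreme co-outlier manufactures the correlation
  a[1, 1] <- 25; b[1, 1] <- 25
  hits <- correlation_screen(expression_matrix(a, scale = "log2"),
                             expression_matrix(b, scale = "log2"),
                             r_threshold = 0.6, alpha = 0.5)
  expect_equal(nrow(hits), 1)
  expect_true(hits$influence_flag)
})

test_that("zero-variance probes are excluded from the screen with a warning", {
  set.seed(113)
  a <- matrix(rnorm(3 * 12, 9), 3,
              dimnames = list(paste0("mir", 1:3), paste0("S", 1:12)))
  a[2, ] <- 4
  b <- matrix(rnorm(2 * 12, 8), 2,
              dimnames = list(paste0("g", 1:2), paste0("S", 1:12)))
  expect_warning(
    hits <- correlation_screen(expression_matrix(a, scale = "log2"),
                               expression_matrix(b, scale = "log2")),
    "zero-variance")
  expect_false("mir2" %in% hits$mirna_id)
})

test_that("global association detects linear signal and respects the null", {
  set.seed(121)
  x <- toy_expr(10, 40, seed = 121)
  # power: outcome is a linear combination of features plus small noise
  y <- colSums(x$values[1:3, ]) + rnorm(40, 0, 0.3)
  res <- global_association(x, y, n_perm = 500)
  expect_lt(res$p, 0.01)
  # survival outcome route
  out <- toy_survival(scale(y)[, 1], loghr = 1, seed = 121)
  res_s <- global_association(x, data.frame(time = out$time, event = out$event),
                              n_perm = 300)
  expect_lt(res_s$p, 0.05)
  expect_identical(res_s$outcome_type, "survival")
  # null calibration (reduced scale): uniform-ish p
  ps <- vapply(1:30, function(s) {
    set.seed(1200 + s)
    xx <- expression_matrix(matrix(rnorm(5 * 30, 9), 5,
                                   dimnames = list(paste0("p", 1:5),
                                                   paste0("S", 1:30))),
                            scale = "log2")
    global_association(xx, rnorm(30), n_perm = 200)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.80)
  expect_error(global_association(x, rep(1, 40)), "constant outcome")
})

test_that("group tests: Wilcoxon calibration and exact Fisher enumeration", {
  set.seed(131)
  null_p <- vapply(1:40, function(s) {
    set.seed(1300 + s)
    group_tests(rnorm(30), rep(c("a", "b"), 15))$p
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.93 - 0.1)  # binomial slack at 40 seeds
  tab <- matrix(c(3, 1, 1, 3), 2)
  res <- group_tests(factor(c("x", "x", "x", "y", "x", "y", "y", "y")),
                     rep(c("g1", "g2"), each = 4))
  expect_equal(res$method, "fisher")
  expect_equal(res$p, oracle_fisher_p(tab), tolerance = 1e-9)
  expect_error(group_tests(rnorm(4), rep("a", 4)), "grouping error")
  f <- factor(c("x", "x", "x", "x"), levels = c("x", "y"))
  expect_error(group_tests(f, c("g1", "g1", "g2", "g2")), "empty margin")
})
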