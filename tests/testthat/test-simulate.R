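test_that("default cohort has the study's shape and is deterministic", {
  cfg <- sim_config(seed = 42, n_mrna_probes = 50, n_validation = 20)
  sim <- generate_cohort(cfg)
  expect_equal(dim(sim$mirna), c(559, 92))   # 62 + 7 + 3 + 20
  expect_equal(nrow(sim$annotation), 92)
  expect_equal(table(sim$annotation$group)[["MM"]], 62)
  expect_equal(sum(!is.na(sim$annotation$efs_time)), 53)
  # survival only on myeloma samples
  expect_true(all(sim$annotation$group[!is.na(sim$annotation$efs_time)] == "MM"))
  sim2 <- generate_cohort(cfg)
  expect_identical(sim$mirna$values, sim2$mirna$values)
  expect_identical(sim$mrna$values, sim2$mrna$values)
  sim3 <- generate_cohort(sim_config(seed = 43, n_mrna_probes = 50,
                                     n_validation = 20))
  expect_false(identical(sim$mirna$values, sim3$mirna$values))
})

test_that("null cohorts show no systematic group differences", {
  cfg <- sim_config(n_de_probes = 0, n_mm = 20, n_bmpc = 20, n_mgus = 2,
                    n_hmcl = 2, n_survival = 10, n_validation = 10,
                    n_mirna_probes = 200, n_mrna_probes = 10, seed = 19)
  sim <- generate_cohort(cfg)
  g <- sim$annotation$group
  mm <- sim$mirna$values[, g == "MM"]; bm <- sim$mirna$values[, g == "BMPC"]
  diff <- rowMeans(mm) - rowMeans(bm)
  se <- sqrt(apply(mm, 1, var) / ncol(mm) + apply(bm, 1, var) / ncol(bm))
  expect_gte(mean(abs(diff) < 4 * se), 0.99)
  expect_equal(nrow(sim$truth$de$MM_vs_BMPC), 0)
})

test_that("simulate_survival calibration: null, effect recovery, censoring", {
  # null: Cox coefficient within 4 SE of zero
  set.seed(201)
  s <- rnorm(200)
  out <- simulate_survival(s, 0, 0.05, 0.3)
  fit <- cox_fit(s, out$time, out$event)
  expect_lt(abs(fit$coefficients), 4 * fit$se)
  # effect recovery over seeds
  est <- vapply(1:20, function(k) {
    set.seed(210 + k)
    sc <- rnorm(500)
    o <- simulate_survival(sc, 0.7, 0.05, 0.3)
    unname(cox_fit(sc, o$time, o$event)$coefficients)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.15)
  expect_true(all(abs(est - 0.7) < 0.3))
  # censoring fraction near target
  set.seed(231)
  o <- simulate_survival(rnorm(1000), 0.5, 0.05, 0.3)
  expect_lt(abs(mean(!o$event) - 0.3), 0.05)
  expect_true(all(o$time > 0))
  expect_error(simulate_survival(rnorm(5), 0, 0.05, 1.2), "config error")
})

test_that("planted prognostic probes rank at the top of a Cox screen", {
  recovered <- numeric(10)
  for (k in 1:10) {
    cfg <- sim_config(seed = 300 + k, n_mrna_probes = 10, n_validation = 10,
                      n_mirna_probes = 150)
    sim <- generate_cohort(cfg)
    efs <- get_outcome(sim$annotation, "efs")
    sx <- sim$mirna[, efs$sample_id]
    p <- vapply(seq_len(nrow(sx$values)), function(i) {
      f <- tryCatch(cox_fit(scale(sx$values[i, ]), efs$time, efs$event),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$p
    }, numeric(1))
    top <- probe_ids(sx)[order(p)][seq_len(cfg$n_prognostic)]
    recovered[k] <- mean(sim$truth$prognostic$probe_id %in% top)
  }
  expect_gte(mean(recovered), 0.9)
})

test_that("prediction-table generation respects the configured hit laws", {
  pt <- generate_prediction_table(paste0("t", 1:40), paste0("d", 1:200),
                                  hit_tools_true = c(0, 0, 0, 0, 0, 0, 0, 1),
                                  hit_tools_decoy = c(1, 0, 0, 0, 0, 0, 0, 0),
                                  seed = 7)
  cs <- consensus_targets(pt, "miR-x", min_tools = 6)
  expect_setequal(cs$gene_ids, paste0("t", 1:40))
  # default laws: most true targets pass, most decoys fail
  pt2 <- generate_prediction_table(paste0("t", 1:200), paste0("d", 1:500),
                                   seed = 8)
  cs2 <- consensus_targets(pt2, "miR-x", min_tools = 6)
  expect_gte(mean(paste0("t", 1:200) %in% cs2$gene_ids), 0.85)
  expect_lte(mean(paste0("d", 1:500) %in% cs2$gene_ids), 0.05)
})

test_that("fixture sets are byte-identical across runs and loadable", {
  cfg <- sim_config(n_mirna_probes = 60, n_mrna_probes = 30, n_mm = 14,
                    n_mgus = 2, n_bmpc = 3, n_hmcl = 3, n_survival = 12,
                    n_validation = 8, n_de_probes = 6, n_target_links = 4,
                    seed = 33)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_set(d1, cfg)
  write_fixture_set(d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  x <- read_expression(file.path(d1, "mirna.tsv"))
  expect_equal(dim(x), c(60, 22))
  expect_identical(x$scale, "log2")
  ann <- read_annotation(file.path(d1, "annotation.tsv"))
  expect_equal(nrow(ann), 22)
  pt <- read_prediction_table(file.path(d1, "predictions.tsv"))
  expect_s3_class(pt, "PredictionTable")
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$de$MM_vs_BMPC), 6)
})

test_that("planted miRNA-mRNA links carry the configured correlation", {
  cfg <- sim_config(seed = 55, n_mrna_probes = 200, n_validation = 10,
                    n_target_links = 10)
  sim <- generate_cohort(cfg)
  links <- sim$truth$links
  r_obs <- vapply(seq_len(nrow(links)), function(l)
    cor(sim$mirna$values[links$mirna_id[l], ],
        sim$mrna$values[links$mrna_id[l], ]), numeric(1))
  expect_true(all(sign(r_obs) == sign(links$r)))
  expect_lt(max(abs(abs(r_obs) - 0.7)), 0.2)
})

test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(n_de_probes = 600), "n_de_probes")
  expect_error(sim_config(n_survival = 100), "n_survival")
  expect_error(sim_config(link_r = 1), "link_r")
  expect_error(sim_config(censor_rate = 0), "censor_rate")
})
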