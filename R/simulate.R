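#' Simulation configuration
#'
#' Defines the stated world of the synthetic cohorts: array and cohort
#' sizes mirroring a miChip-scale miRNA study (559 probes; 62 myeloma, 7
#' MGUS, 3 pooled normal plasma-cell and 20 cell-line samples; 53 myeloma
#' samples with survival; an independent 345-sample validation cohort),
#' planted group differences within the observed fold-change magnitudes
#' (|log2FC| 0.44-2.2, i.e. |FC| about 1.4-4.6), planted miRNA-to-mRNA
#' links at |r| >= 0.6, and exponential proportional-hazards survival
#' driven by planted prognostic probes.
#'
#' Expression noise is Gaussian on the log2 scale with probe-specific
#' variances drawn from a scaled inverse-chi-square (`var_prior_df`,
#' scale `noise_sd^2`), so the empirical-Bayes machinery has a true
#' hyperparameter pair to recover. The validation cohort receives a global
#' affine distortion (`val_shift`, `val_slope`) so that frozen-parameter
#' transfer is exercised nontrivially. Aberration prevalences are
#' plausible myeloma frequencies, used only as defaults.
#'
#' @param n_mirna_probes,n_mrna_probes array sizes.
#' @param n_mm,n_mgus,n_bmpc,n_hmcl cohort composition.
#' @param n_survival myeloma samples with survival follow-up.
#' @param n_validation independent validation cohort size.
#' @param n_de_probes planted differential probes (myeloma vs normal).
#' @param de_log2fc_range absolute log2 fold-change interval for planted
#'   effects.
#' @param n_prognostic planted prognostic probes.
#' @param prognostic_loghr per-probe log hazard ratio (per SD of
#'   expression).
#' @param n_target_links planted miRNA-to-mRNA correlation links.
#' @param link_r planted correlation magnitude (|r| < 1).
#' @param noise_sd scale of the probe-variance prior (log2 units).
#' @param var_prior_df df of the probe-variance prior.
#' @param baseline_log2 mean log2 expression level.
#' @param censor_rate target censoring fraction, in (0, 1).
#' @param baseline_hazard exponential baseline hazard (per month).
#' @param aberration_prev named prevalence vector for the iFISH flags.
#' @param val_shift,val_slope affine distortion of the validation cohort.
#' @param seed master seed; every stage derives a named substream from it.
#' @return a validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_mirna_probes = 559, n_mrna_probes = 5000,
                       n_mm = 62, n_mgus = 7, n_bmpc = 3, n_hmcl = 20,
                       n_survival = 53, n_validation = 345,
                       n_de_probes = 67, de_log2fc_range = c(0.44, 2.2),
                       n_prognostic = 5, prognostic_loghr = 0.7,
                       n_target_links = 24, link_r = 0.7,
                       noise_sd = 1.0, var_prior_df = 4,
                       baseline_log2 = 9.0, censor_rate = 0.35,
                       baseline_hazard = 0.02,
                       aberration_prev = c(t4_14 = 0.15, t11_14 = 0.20,
                                           del17p = 0.10, gain1q21 = 0.35,
                                           del13q = 0.45, hyperdiploid = 0.50),
                       val_shift = 1.5, val_slope = 0.9, seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_mirna_probes", "n_mrna_probes", "n_mm", "n_mgus", "n_bmpc",
              "n_hmcl", "n_survival", "n_validation", "n_prognostic",
              "n_target_links")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("config error: ", nm, " must be positive",
                            call. = FALSE)
  if (cfg$n_de_probes < 0 || cfg$n_de_probes > cfg$n_mirna_probes)
    stop("config error: n_de_probes must lie in [0, n_mirna_probes]",
         call. = FALSE)
  if (cfg$n_survival > cfg$n_mm)
    stop("config error: n_survival cannot exceed n_mm", call. = FALSE)
  if (abs(cfg$link_r) >= 1) stop("config error: |link_r| must be < 1",
                                 call. = FALSE)
  if (cfg$censor_rate <= 0 || cfg$censor_rate >= 1)
    stop("config error: censor_rate must lie in (0, 1)", call. = FALSE)
  stopifnot(length(cfg$de_log2fc_range) == 2L,
            cfg$de_log2fc_range[1] > 0,
            cfg$de_log2fc_range[1] <= cfg$de_log2fc_range[2])
  if (!all(names(cfg$aberration_prev) %in% .aberration_flags))
    stop("config error: unknown aberration flag in prevalences", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate survival outcomes under exponential proportional hazards
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(loghr * score)`. Censoring is independent
#' uniform on (0, c_max), with c_max calibrated by root-finding so the
#' expected censored fraction over the realized event times equals
#' `censor_rate`.
#'
#' @param scores finite per-sample linear predictor.
#' @param loghr log hazard ratio per unit of score.
#' @param baseline_hazard positive baseline hazard.
#' @param censor_rate target censoring fraction in (0, 1).
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return data frame with `time` (positive) and `event` (logical).
#' @export
simulate_survival <- function(scores, loghr, baseline_hazard, censor_rate,
                              seed = NULL) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (censor_rate <= 0 || censor_rate >= 1)
    stop("config error: censor_rate must lie in (0, 1)", call. = FALSE)
  stopifnot(baseline_hazard > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(loghr * scores))
  # E[censored fraction] given C ~ U(0, cmax) is mean(pmin(T, cmax)) / cmax;
  # decreasing in cmax, so a root exists for any rate in (0, 1)
  frac <- function(cmax) mean(pmin(t_event, cmax)) / cmax - censor_rate
  upper <- max(t_event) * 2
  while (frac(upper) > 0) upper <- upper * 2
  cmax <- stats::uniroot(frac, c(min(t_event) * 1e-6, upper))$root
  t_cens <- stats::runif(n, 0, cmax)
  data.frame(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

# internal: scaled inverse-chi-square draws (probe-level true variances)
rinvchisq_scaled <- function(n, df, scale2) df * scale2 / stats::rchisq(n, df)

#' Generate a synthetic miRNA/mRNA cohort with planted ground truth
#'
#' Produces log2-scale miRNA and mRNA expression matrices, a clinical
#' annotation table, a shifted independent validation cohort, and the
#' planted truth needed for recovery tests. See [sim_config()] for the
#' generative model. Deterministic given the config (all randomness flows
#' from `config$seed` through named substreams).
#'
#' Planted structure:
#' * `n_de_probes` miRNAs shifted in myeloma (and, attenuated, in MGUS)
#'   relative to normal plasma cells, with random sign and magnitude
#'   within `de_log2fc_range`; cell lines additionally receive large
#'   global shifts so they segregate in clustering.
#' * `n_prognostic` miRNAs (disjoint from the differential set) whose
#'   standardized expression drives an exponential-hazards linear
#'   predictor for EFS and OS of the myeloma survival subset and the
#'   validation cohort; the prognostic probes share a latent per-sample
#'   factor carrying half their variance (survival-relevant miRNAs track
#'   a common biological axis).
#' * `n_target_links` mRNAs correlated at `link_r` (alternating sign)
#'   with high-variance null miRNAs.
#' * GPI/UAMS/IFM-type risk indices generated as linear combinations of
#'   designated probes plus noise; iFISH flags drawn at the configured
#'   prevalences.
#'
#' @param config a `SimulationConfig`.
#' @return list of class `SimulatedCohort` with elements `mirna`, `mrna`,
#'   `annotation`, `validation_mirna`, `validation_annotation`, `truth`,
#'   `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  pid <- sprintf("miR-sim-%03d", seq_len(cfg$n_mirna_probes))
  gid <- sprintf("gene-%04d", seq_len(cfg$n_mrna_probes))
  sid <- c(sprintf("MM-%02d", seq_len(cfg$n_mm)),
           sprintf("MGUS-%02d", seq_len(cfg$n_mgus)),
           sprintf("BMPC-%02d", seq_len(cfg$n_bmpc)),
           sprintf("HMCL-%02d", seq_len(cfg$n_hmcl)))
  group <- rep(c("MM", "MGUS", "BMPC", "HMCL"),
               c(cfg$n_mm, cfg$n_mgus, cfg$n_bmpc, cfg$n_hmcl))
  n_samp <- length(sid)

  ## --- miRNA expression -------------------------------------------------
  set.seed(substream_seed(cfg$seed, "mirna"))
  probe_mu <- stats::rnorm(cfg$n_mirna_probes, cfg$baseline_log2, 1.2)
  probe_var <- rinvchisq_scaled(cfg$n_mirna_probes, cfg$var_prior_df,
                                cfg$noise_sd^2)
  M <- probe_mu + sqrt(probe_var) *
    matrix(stats::rnorm(cfg$n_mirna_probes * n_samp), cfg$n_mirna_probes)
  dimnames(M) <- list(pid, sid)

  # planted differential probes (myeloma vs normal; MGUS attenuated)
  de_idx <- integer(0); de_fc <- numeric(0)
  if (cfg$n_de_probes > 0) {
    de_idx <- sample(cfg$n_mirna_probes, cfg$n_de_probes)
    de_fc <- stats::runif(cfg$n_de_probes, cfg$de_log2fc_range[1],
                          cfg$de_log2fc_range[2]) *
      sample(c(-1, 1), cfg$n_de_probes, replace = TRUE)
    M[de_idx, group == "MM"] <- M[de_idx, group == "MM"] + de_fc
    mgus_sub <- sample(seq_along(de_idx), ceiling(0.3 * length(de_idx)))
    M[de_idx[mgus_sub], group == "MGUS"] <-
      M[de_idx[mgus_sub], group == "MGUS"] + 0.6 * de_fc[mgus_sub]
  }

  # cell lines: large global shifts (proliferating lines differ strongly
  # from primary samples and should form their own cluster branch)
  hmcl_idx <- sample(cfg$n_mirna_probes, round(0.4 * cfg$n_mirna_probes))
  hmcl_shift <- stats::runif(length(hmcl_idx), 1, 3) *
    sample(c(-1, 1), length(hmcl_idx), replace = TRUE)
  M[hmcl_idx, group == "HMCL"] <- M[hmcl_idx, group == "HMCL"] + hmcl_shift

  # prognostic probes, disjoint from the differential set; they share a
  # latent per-sample factor (half their variance) emulating a common
  # biological axis, which is what makes a principal-component summary of
  # survival-relevant miRNAs meaningful
  free <- setdiff(seq_len(cfg$n_mirna_probes), de_idx)
  prog_idx <- sample(free, cfg$n_prognostic)
  prog_loghr <- rep(cfg$prognostic_loghr, cfg$n_prognostic)
  a_factor <- stats::rnorm(n_samp)
  M[prog_idx, ] <- probe_mu[prog_idx] + sqrt(probe_var[prog_idx]) *
    (sqrt(0.5) * matrix(stats::rnorm(cfg$n_prognostic * n_samp),
                        cfg$n_prognostic) +
       sqrt(0.5) * matrix(a_factor, cfg$n_prognostic, n_samp, byrow = TRUE))

  ## --- survival ---------------------------------------------------------
  mm_cols <- which(group == "MM")
  set.seed(substream_seed(cfg$seed, "survival"))
  surv_cols <- sort(sample(mm_cols, cfg$n_survival))
  zscore <- function(X, cols, idx) {
    xs <- X[idx, cols, drop = FALSE]
    t(scale(t(xs)))
  }
  lp <- drop(prog_loghr %*% zscore(M, surv_cols, prog_idx))
  efs <- simulate_survival(lp, 1, cfg$baseline_hazard, cfg$censor_rate)
  os <- simulate_survival(lp, 1, cfg$baseline_hazard / 2, cfg$censor_rate)

  ## --- clinical annotation ---------------------------------------------
  set.seed(substream_seed(cfg$seed, "clinical"))
  ann <- data.frame(sample_id = sid, group = group, stringsAsFactors = FALSE)
  for (fl in .aberration_flags) {
    v <- rep("", n_samp)
    prev <- cfg$aberration_prev[fl]
    if (!is.na(prev))
      v[group == "MM"] <- as.character(stats::rbinom(cfg$n_mm, 1, prev))
    ann[[fl]] <- v
  }
  ann$iss <- ifelse(group == "MM",
                    sample(c("I", "II", "III"), n_samp, replace = TRUE,
                           prob = c(0.35, 0.35, 0.30)), "")
  ann$b2m <- ifelse(group == "MM",
                    sprintf("%.15g", stats::rlnorm(n_samp, log(3.5), 0.5)), "")
  # risk indices: weighted sums of designated probes plus noise, myeloma only
  idx_pool <- setdiff(free, prog_idx)
  index_probes <- list(gpi = sample(idx_pool, 3), uams = sample(idx_pool, 3),
                       ifm = sample(idx_pool, 3))
  for (nm in names(index_probes)) {
    z <- colMeans(zscore(M, mm_cols, index_probes[[nm]]))
    val <- 100 + 25 * z + stats::rnorm(cfg$n_mm, 0, 0.5 * 25)
    col <- rep("", n_samp)
    col[mm_cols] <- sprintf("%.15g", val)
    ann[[nm]] <- col
  }
  for (f in c("efs_time", "efs_event", "os_time", "os_event"))
    ann[[f]] <- rep("", n_samp)
  ann$efs_time[surv_cols] <- sprintf("%.15g", efs$time)
  ann$efs_event[surv_cols] <- as.character(as.integer(efs$event))
  ann$os_time[surv_cols] <- sprintf("%.15g", os$time)
  ann$os_event[surv_cols] <- as.character(as.integer(os$event))
  annotation <- clinical_annotation(ann)

  ## --- mRNA expression with planted links -------------------------------
  set.seed(substream_seed(cfg$seed, "mrna"))
  gene_mu <- stats::rnorm(cfg$n_mrna_probes, 8, 1.3)
  gene_var <- rinvchisq_scaled(cfg$n_mrna_probes, cfg$var_prior_df, 1)
  G <- gene_mu + sqrt(gene_var) *
    matrix(stats::rnorm(cfg$n_mrna_probes * n_samp), cfg$n_mrna_probes)
  dimnames(G) <- list(gid, sid)
  # link miRNAs: high-variance null probes, so both sides of a planted
  # link survive an upstream variance filter
  null_idx <- setdiff(free, prog_idx)
  hi_var <- null_idx[order(-probe_var[null_idx])]
  n_links <- min(cfg$n_target_links, cfg$n_mrna_probes, length(hi_var) * 3)
  link_mirna <- rep(utils::head(hi_var, max(1, ceiling(n_links / 3))),
                    length.out = n_links)
  link_gene <- sample(cfg$n_mrna_probes, n_links)
  link_sign <- rep_len(c(1, -1), n_links)
  for (l in seq_len(n_links)) {
    z <- as.numeric(scale(M[link_mirna[l], ]))
    eps <- stats::rnorm(n_samp)
    s <- sqrt(gene_var[link_gene[l]])
    G[link_gene[l], ] <- gene_mu[link_gene[l]] +
      s * (link_sign[l] * cfg$link_r * z + sqrt(1 - cfg$link_r^2) * eps)
  }

  ## --- validation cohort (affine-shifted, same prognostic model) --------
  set.seed(substream_seed(cfg$seed, "validation"))
  vsid <- sprintf("VAL-%03d", seq_len(cfg$n_validation))
  V <- probe_mu + sqrt(probe_var) *
    matrix(stats::rnorm(cfg$n_mirna_probes * cfg$n_validation),
           cfg$n_mirna_probes)
  dimnames(V) <- list(pid, vsid)
  if (length(de_idx)) V[de_idx, ] <- V[de_idx, ] + de_fc
  a_val <- stats::rnorm(cfg$n_validation)
  V[prog_idx, ] <- probe_mu[prog_idx] + sqrt(probe_var[prog_idx]) *
    (sqrt(0.5) * matrix(stats::rnorm(cfg$n_prognostic * cfg$n_validation),
                        cfg$n_prognostic) +
       sqrt(0.5) * matrix(a_val, cfg$n_prognostic, cfg$n_validation,
                          byrow = TRUE))
  lp_val <- drop(prog_loghr %*% t(scale(t(V[prog_idx, , drop = FALSE]))))
  efs_val <- simulate_survival(lp_val, 1, cfg$baseline_hazard, cfg$censor_rate)
  os_val <- simulate_survival(lp_val, 1, cfg$baseline_hazard / 2,
                              cfg$censor_rate)
  V <- cfg$val_shift + cfg$val_slope * V
  vann <- data.frame(sample_id = vsid, group = "MM",
                     stringsAsFactors = FALSE)
  for (fl in .aberration_flags) vann[[fl]] <- ""
  vann$iss <- ""; vann$b2m <- ""; vann$gpi <- ""; vann$uams <- ""; vann$ifm <- ""
  vann$efs_time <- sprintf("%.15g", efs_val$time)
  vann$efs_event <- as.character(as.integer(efs_val$event))
  vann$os_time <- sprintf("%.15g", os_val$time)
  vann$os_event <- as.character(as.integer(os_val$event))

  truth <- list(
    de = list(MM_vs_BMPC = data.frame(probe_id = pid[de_idx],
                                      log2fc = de_fc,
                                      stringsAsFactors = FALSE)),
    prognostic = data.frame(probe_id = pid[prog_idx], loghr = prog_loghr,
                            stringsAsFactors = FALSE),
    links = data.frame(mirna_id = pid[link_mirna], mrna_id = gid[link_gene],
                       r = link_sign * cfg$link_r,
                       stringsAsFactors = FALSE),
    hmcl_shift = data.frame(probe_id = pid[hmcl_idx], shift = hmcl_shift,
                            stringsAsFactors = FALSE),
    index_probes = lapply(index_probes, function(i) pid[i]),
    survival_samples = sid[surv_cols],
    val_affine = c(shift = cfg$val_shift, slope = cfg$val_slope))

  structure(list(mirna = expression_matrix(M, scale = "log2"),
                 mrna = expression_matrix(G, scale = "log2"),
                 annotation = annotation,
                 validation_mirna = expression_matrix(V, scale = "log2"),
                 validation_annotation = clinical_annotation(vann),
                 truth = truth, config = cfg),
            class = "SimulatedCohort")
}

#' Generate a synthetic target-prediction table
#'
#' True targets draw their number of positive tool calls from
#' `hit_tools_true` (by default concentrated on 6-7 of 7 calls), decoys
#' from `hit_tools_decoy` (mostly below the consensus threshold).
#'
#' @param true_targets,decoys disjoint character vectors of gene ids.
#' @param hit_tools_true,hit_tools_decoy probability vectors of length
#'   `n_tools + 1` over 0..n_tools positive calls.
#' @param n_tools number of prediction tools (default 7).
#' @param seed optional seed.
#' @return a `PredictionTable` covering both sets.
#' @export
generate_prediction_table <- function(true_targets, decoys,
                                      hit_tools_true = c(0, 0, 0, 0, 0, 0.05,
                                                         0.45, 0.5),
                                      hit_tools_decoy = stats::dbinom(0:7, 7, 0.2),
                                      n_tools = 7, seed = NULL) {
  if (length(intersect(true_targets, decoys)))
    stop("config error: true targets and decoys overlap", call. = FALSE)
  stopifnot(length(hit_tools_true) == n_tools + 1,
            length(hit_tools_decoy) == n_tools + 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- c(true_targets, decoys)
  n_hits <- c(sample(0:n_tools, length(true_targets), replace = TRUE,
                     prob = hit_tools_true),
              sample(0:n_tools, length(decoys), replace = TRUE,
                     prob = hit_tools_decoy))
  calls <- matrix(FALSE, length(genes), n_tools,
                  dimnames = list(genes, paste0("tool", seq_len(n_tools))))
  for (i in seq_along(genes))
    if (n_hits[i] > 0) calls[i, sample(n_tools, n_hits[i])] <- TRUE
  prediction_table(calls)
}

#' Write a complete fixture set to disk
#'
#' Emits the simulated cohort as tab-delimited files (expression matrices,
#' annotations, a prediction table for the first planted link miRNA) plus
#' a JSON truth file. Byte-identical across runs with the same config.
#'
#' @param outdir output directory (created if needed).
#' @param config a `SimulationConfig`.
#' @return invisibly, the file paths written.
#' @export
write_fixture_set <- function(outdir, config = sim_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(config)
  paths <- c(
    mirna = write_expression(sim$mirna, file.path(outdir, "mirna.tsv")),
    mrna = write_expression(sim$mrna, file.path(outdir, "mrna.tsv")),
    annotation = write_annotation(sim$annotation,
                                  file.path(outdir, "annotation.tsv")),
    validation_mirna = write_expression(
      sim$validation_mirna, file.path(outdir, "validation_mirna.tsv")),
    validation_annotation = write_annotation(
      sim$validation_annotation, file.path(outdir, "validation_annotation.tsv")))
  link_mirna <- unique(sim$truth$links$mirna_id)[1]
  if (!is.na(link_mirna)) {
    true_t <- sim$truth$links$mrna_id[sim$truth$links$mirna_id == link_mirna]
    decoys <- setdiff(probe_ids(sim$mrna), sim$truth$links$mrna_id)
    decoys <- utils::head(decoys, min(length(decoys), 200))
    pt <- generate_prediction_table(true_t, decoys,
                                    seed = substream_seed(config$seed,
                                                          "predictions"))
    paths <- c(paths, predictions = write_prediction_table(
      pt, file.path(outdir, "predictions.tsv")))
  }
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, truth = truth_path)
  invisible(paths)
}
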