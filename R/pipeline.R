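#' Pipeline configuration
#'
#' Thresholds and paths driving the end-to-end analysis: BH level
#' `alpha = 0.05`, correlation retention `r_threshold = 0.6`, variance
#' filter `keep_fraction = 0.2` (drop the 80% least variable),
#' target-consensus `min_tools = 6` of 7, maxstat quantile bounds
#' (0.1, 0.9). Round-trips through JSON.
#'
#' @param mirna_path,mrna_path,annotation_path,validation_mirna_path,validation_annotation_path,predictions_path
#'   input file paths (`NULL` entries are simulated on demand by
#'   `run-all`).
#' @param alpha adjusted-p significance level.
#' @param r_threshold absolute-correlation cutoff.
#' @param keep_fraction variance-filter retained fraction.
#' @param min_tools consensus-prediction threshold.
#' @param maxstat_bounds quantile search interval.
#' @param seed master seed.
#' @param outdir output directory.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(mirna_path = NULL, mrna_path = NULL,
                            annotation_path = NULL,
                            validation_mirna_path = NULL,
                            validation_annotation_path = NULL,
                            predictions_path = NULL,
                            alpha = 0.05, r_threshold = 0.6,
                            keep_fraction = 0.2, min_tools = 6,
                            maxstat_bounds = c(0.1, 0.9), seed = 1,
                            outdir = "myelomiR-run") {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, r_threshold > 0, r_threshold < 1,
            keep_fraction > 0, keep_fraction <= 1,
            min_tools >= 0, length(maxstat_bounds) == 2,
            maxstat_bounds[1] > 0, maxstat_bounds[2] < 1,
            maxstat_bounds[1] < maxstat_bounds[2])
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration
#' @param path JSON file path.
#' @param cfg a `PipelineConfig`.
#' @return the configuration (read) or `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj[!vapply(obj, is.null, logical(1))])
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis workflow
#'
#' Orchestrates the complete pipeline on user-supplied files or, when
#' paths are absent, on a freshly simulated cohort: differential
#' expression (myeloma vs normal plasma cells), hierarchical-clustering
#' report, per-probe survival screening (Cox on the continuous marker, BH
#' adjusted), signature construction on the top survival-relevant probes
#' with frozen-parameter transfer to the validation cohort, the
#' miRNA-mRNA correlation screen on variance-filtered matrices, and, if
#' predictions are available, consensus target sets. If the survival
#' screen retains nothing at `alpha`, the signature stage is skipped with
#' a note rather than an error. All artifacts are written under
#' `cfg$outdir` together with a `manifest.json` and a plain-text summary.
#'
#' @param cfg a `PipelineConfig`.
#' @return invisibly, a list of in-memory results.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  mir_msg("run_pipeline: resolved config: ",
          jsonlite::toJSON(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                           auto_unbox = TRUE))
  artifacts <- character(0)
  if (is.null(cfg$mirna_path)) {
    mir_msg("run_pipeline: no input paths given; simulating a cohort")
    sim <- generate_cohort(sim_config(seed = cfg$seed))
    mirna <- sim$mirna; mrna <- sim$mrna; ann <- sim$annotation
    vmirna <- sim$validation_mirna; vann <- sim$validation_annotation
  } else {
    for (p in c(cfg$mirna_path, cfg$annotation_path))
      if (!is.null(p) && !file.exists(p))
        stop("data error: missing input path: ", p, call. = FALSE)
    mirna <- read_expression(cfg$mirna_path)
    ann <- read_annotation(cfg$annotation_path)
    mrna <- if (!is.null(cfg$mrna_path)) read_expression(cfg$mrna_path)
    vmirna <- if (!is.null(cfg$validation_mirna_path))
      read_expression(cfg$validation_mirna_path)
    vann <- if (!is.null(cfg$validation_annotation_path))
      read_annotation(cfg$validation_annotation_path)
  }
  al <- align_samples(mirna, ann)
  mirna <- al$expr; ann <- al$annotation
  if (mirna$scale == "raw") mirna <- scaled_log2(mirna)
  # all downstream analysis, including signature training, runs on the
  # normalized scale; the model is frozen for documentation-by-value
  norm_model <- fit_invariant_normalization(mirna)
  mirna <- apply_normalization(norm_model, mirna)

  ## differential expression: myeloma vs normal plasma cells
  fit <- fit_probe_models(mirna, ann$group, contrast = c("MM", "BMPC"))
  fit <- ebayes_moderate(fit)
  de_tab <- differential_table(fit, alpha = cfg$alpha)
  p_de <- file.path(cfg$outdir, "differential_mm_vs_bmpc.tsv")
  write_differential_table(de_tab, p_de)
  artifacts <- c(artifacts, differential = p_de)

  ## clustering report
  hc <- average_linkage(pearson_dissimilarity(mirna))
  purity <- cluster_purity_report(hc, ann)
  p_nwk <- file.path(cfg$outdir, "dendrogram.nwk")
  writeLines(to_newick(hc), p_nwk)
  artifacts <- c(artifacts, dendrogram = p_nwk)

  ## survival screen on the myeloma survival subset
  efs <- get_outcome(ann, "efs"); os <- get_outcome(ann, "os")
  sig <- NULL; surv_tab <- NULL; scored_val <- NULL
  if (nrow(efs) >= 10) {
    sx <- mirna[, efs$sample_id]
    cox_p <- vapply(seq_len(nrow(sx$values)), function(i) {
      f <- tryCatch(cox_fit(scale(sx$values[i, ]), efs$time, efs$event),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$p
    }, numeric(1))
    ok <- !is.na(cox_p)
    adj <- rep(NA_real_, length(cox_p)); adj[ok] <- bh_adjust(cox_p[ok])
    surv_tab <- data.frame(probe_id = probe_ids(sx), p_raw = cox_p,
                           p_adj = adj)
    surv_tab <- surv_tab[order(surv_tab$p_adj), ]
    p_surv <- file.path(cfg$outdir, "survival_screen.tsv")
    utils::write.table(surv_tab, p_surv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, survival = p_surv)
    hits <- surv_tab$probe_id[!is.na(surv_tab$p_adj) &
                                surv_tab$p_adj <= cfg$alpha]
    if (length(hits) >= 2) {
      feats <- utils::head(hits, 5)
      sig <- build_signature(mirna[feats, ], efs, os,
                             bounds = cfg$maxstat_bounds,
                             normalization = norm_model)
      p_sig <- file.path(cfg$outdir, "signature.json")
      write_signature(sig, p_sig)
      artifacts <- c(artifacts, signature = p_sig)
      if (!is.null(vmirna)) {
        scored_val <- apply_signature(sig, vmirna, use_documentation = TRUE)
        p_scored <- file.path(cfg$outdir, "validation_scores.tsv")
        utils::write.table(scored_val, p_scored, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        artifacts <- c(artifacts, validation_scores = p_scored)
      }
    } else {
      mir_msg("run_pipeline: no survival-relevant features at alpha = ",
              cfg$alpha, "; signature stage skipped")
    }
  }

  ## correlation screen on variance-filtered matrices, myeloma samples
  hits_tab <- NULL
  if (!is.null(mrna)) {
    mm_ids <- intersect(ann$sample_id[ann$group == "MM"], sample_ids(mrna))
    if (length(mm_ids) >= 5) {
      fm <- variance_filter(mirna[, mm_ids], cfg$keep_fraction)
      fg <- variance_filter(mrna[, mm_ids], cfg$keep_fraction)
      hits_tab <- correlation_screen(fm, fg, r_threshold = cfg$r_threshold,
                                     alpha = cfg$alpha)
      p_hits <- file.path(cfg$outdir, "correlation_hits.tsv")
      write_correlation_hits(hits_tab, p_hits)
      artifacts <- c(artifacts, correlation = p_hits)
    }
  }

  report <- summary_report(de_tab, purity, surv_tab, sig, hits_tab,
                           alpha = cfg$alpha)
  p_rep <- file.path(cfg$outdir, "summary.txt")
  writeLines(report, p_rep)
  artifacts <- c(artifacts, summary = p_rep)
  jsonlite::write_json(as.list(stats::setNames(basename(artifacts),
                                               names(artifacts))),
                       file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(differential = de_tab, clustering = purity,
                 survival = surv_tab, signature = sig,
                 validation_scores = scored_val, correlation = hits_tab,
                 report = report, artifacts = artifacts))
}

#' Plain-text summary report
#'
#' Deterministic k/n (pct) rendering of the main results: differential
#' counts per direction, cluster purity, survival-relevant probes, and
#' correlation hits. Percentages are `100 k / n` rounded half away from
#' zero to one decimal.
#'
#' @param de_tab a `DifferentialTable` (or `NULL`).
#' @param purity a `ClusterPurityReport` (or `NULL`).
#' @param surv_tab survival screen data frame (or `NULL`).
#' @param sig a `RiskSignature` (or `NULL`).
#' @param hits_tab a `CorrelationHits` data frame (or `NULL`).
#' @param alpha significance level for the counts.
#' @return character vector of report lines.
#' @export
summary_report <- function(de_tab = NULL, purity = NULL, surv_tab = NULL,
                           sig = NULL, hits_tab = NULL, alpha = 0.05) {
  lines <- character(0)
  if (!is.null(de_tab)) {
    s <- attr(de_tab, "summary")
    lines <- c(lines,
               sprintf("Differential expression (BH %.2g): %s significant; %s up, %s down",
                       s$alpha, s$lines["total"], s$lines["up"], s$lines["down"]))
  }
  if (!is.null(purity)) {
    lines <- c(lines, "Clustering:",
               utils::capture.output(print(purity)))
  }
  if (!is.null(surv_tab)) {
    k <- sum(!is.na(surv_tab$p_adj) & surv_tab$p_adj <= alpha)
    lines <- c(lines, sprintf("Survival screen: %s probes associated with EFS (BH %.2g)",
                              format_fraction(k, nrow(surv_tab)), alpha))
  }
  if (!is.null(sig)) {
    lines <- c(lines, sprintf("Risk signature: %d features, cutoff %.4g (%s)",
                              length(sig$feature_ids), sig$cutoff,
                              sig$cutoff_outcome))
  } else {
    lines <- c(lines, "Risk signature: not built (no survival-relevant features)")
  }
  if (!is.null(hits_tab)) {
    lines <- c(lines, sprintf("Correlation screen: %d retained hit(s) of %d tested pairs",
                              nrow(hits_tab), attr(hits_tab, "n_tested")))
  }
  lines
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a fixture set), `run-all` (full
#' workflow), and the individual stages `preprocess`, `de`, `survive`,
#' `signature-build`, `signature-apply`, `correlate`, `targets`,
#' `cluster` on supplied files. Flags use `--key value` syntax;
#' `--config path.json` loads a pipeline configuration for `run-all`,
#' individual flags override it. Returns (rather than calls `quit` with)
#' the exit status so it can be tested in-process: 0 on success, 1 for
#' data/validation errors, 2 for usage errors.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: myelomiR <subcommand> [--key value ...]",
    "subcommands: simulate | run-all | preprocess | de | survive |",
    "             signature-build | signature-apply | correlate | targets | cluster",
    "common flags: --outdir DIR --seed N --config FILE --out FILE",
    "data flags: --mirna FILE --mrna FILE --annotation FILE",
    "            --validation-mirna FILE --validation-annotation FILE",
    "            --signature FILE --predictions FILE --features a,b,c",
    sep = "\n")
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(2L))
  }
  sub <- args[1]; rest <- args[-1]
  if (length(rest) %% 2 != 0) { message("bad flags\n", usage); return(invisible(2L)) }
  flags <- list()
  if (length(rest)) {
    keys <- rest[c(TRUE, FALSE)]; vals <- rest[c(FALSE, TRUE)]
    if (!all(startsWith(keys, "--"))) {
      message("bad flags\n", usage); return(invisible(2L))
    }
    flags <- stats::setNames(as.list(vals), sub("^--", "", keys))
  }
  run <- function(expr) {
    tryCatch({ expr; 0L },
             error = function(e) {
               message("error: ", conditionMessage(e)); 1L
             })
  }
  status <- switch(sub,
    simulate = run({
      outdir <- flags$outdir %||% "myelomiR-fixture"
      seed <- as.integer(flags$seed %||% 1)
      write_fixture_set(outdir, sim_config(seed = seed))
      mir_msg("fixture written to ", outdir)
    }),
    `run-all` = run({
      cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config)
             else pipeline_config()
      if (!is.null(flags$outdir)) cfg$outdir <- flags$outdir
      if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
      map <- c(mirna = "mirna_path", mrna = "mrna_path",
               annotation = "annotation_path",
               `validation-mirna` = "validation_mirna_path",
               `validation-annotation` = "validation_annotation_path")
      for (fl in names(map))
        if (!is.null(flags[[fl]])) cfg[[map[fl]]] <- flags[[fl]]
      run_pipeline(cfg)
    }),
    preprocess = run({
      if (is.null(flags$mirna))
        stop("preprocess requires --mirna", call. = FALSE)
      x <- read_expression(flags$mirna)
      if (x$scale == "raw")
        x <- scaled_log2(x, offset = if (is.null(flags$offset)) "auto"
                                     else as.numeric(flags$offset))
      res <- normalize_expression(x)
      out <- flags$out %||% "normalized.tsv"
      write_expression(res$expr, out)
      if (!is.null(flags$model)) write_normalization_model(res$model, flags$model)
      mir_msg("normalized matrix written to ", out)
    }),
    survive = run({
      if (is.null(flags$mirna) || is.null(flags$annotation))
        stop("survive requires --mirna and --annotation", call. = FALSE)
      x <- read_expression(flags$mirna)
      ann <- read_annotation(flags$annotation)
      al <- align_samples(x, ann)
      efs <- get_outcome(al$annotation, "efs")
      if (nrow(efs) < 10) stop("fewer than 10 samples with survival",
                               call. = FALSE)
      sx <- al$expr[, efs$sample_id]
      rows <- lapply(probe_ids(sx), function(p) {
        f <- tryCatch(cox_fit(scale(sx$values[p, ]), efs$time, efs$event),
                      error = function(e) NULL)
        ms <- tryCatch(maxstat_cutpoint(sx$values[p, ], efs$time, efs$event),
                       error = function(e) NULL)
        data.frame(feature_id = p,
                   cox_p = if (is.null(f)) NA_real_ else f$p,
                   hr = if (is.null(f)) NA_real_ else f$hr,
                   cutoff = if (is.null(ms)) NA_real_ else ms$cutoff,
                   max_stat = if (is.null(ms)) NA_real_ else ms$max_stat,
                   maxstat_p = if (is.null(ms)) NA_real_ else ms$p_adj)
      })
      tab <- do.call(rbind, rows)
      ok <- !is.na(tab$cox_p)
      tab$cox_p_adj <- NA_real_
      tab$cox_p_adj[ok] <- bh_adjust(tab$cox_p[ok])
      tab <- tab[order(tab$cox_p), ]
      out <- flags$out %||% "survival_screen.tsv"
      utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
      mir_msg("survival screen written to ", out)
    }),
    `signature-build` = run({
      if (is.null(flags$mirna) || is.null(flags$annotation) ||
          is.null(flags$features))
        stop("signature-build requires --mirna, --annotation and --features",
             call. = FALSE)
      x <- read_expression(flags$mirna)
      ann <- read_annotation(flags$annotation)
      al <- align_samples(x, ann)
      feats <- strsplit(flags$features, ",", fixed = TRUE)[[1]]
      nm <- fit_invariant_normalization(al$expr)
      xn <- apply_normalization(nm, al$expr)
      sig <- build_signature(xn[feats, ], get_outcome(al$annotation, "efs"),
                             get_outcome(al$annotation, "os"),
                             normalization = nm)
      out <- flags$out %||% "signature.json"
      write_signature(sig, out)
      mir_msg("signature written to ", out)
    }),
    `signature-apply` = run({
      if (is.null(flags$signature) || is.null(flags$mirna))
        stop("signature-apply requires --signature and --mirna", call. = FALSE)
      sig <- read_signature(flags$signature)
      x <- read_expression(flags$mirna)
      sc <- apply_signature(sig, x,
                            use_documentation = is.null(flags$`no-documentation`))
      out <- flags$out %||% "scores.tsv"
      utils::write.table(sc, out, sep = "\t", quote = FALSE, row.names = FALSE)
      mir_msg("scores written to ", out)
    }),
    targets = run({
      if (is.null(flags$predictions) || is.null(flags$`mirna-id`))
        stop("targets requires --predictions and --mirna-id", call. = FALSE)
      pt <- read_prediction_table(flags$predictions)
      cs <- consensus_targets(pt, flags$`mirna-id`,
                              min_tools = as.integer(flags$`min-tools` %||% 6))
      out <- flags$out %||% "consensus_targets.tsv"
      utils::write.table(data.frame(mirna_id = cs$mirna_id,
                                    gene_id = cs$gene_ids),
                         out, sep = "\t", quote = FALSE, row.names = FALSE)
      mir_msg(length(cs$gene_ids), " consensus target(s) written to ", out)
    }),
    de = run({
      if (is.null(flags$mirna) || is.null(flags$annotation))
        stop("de requires --mirna and --annotation", call. = FALSE)
      x <- read_expression(flags$mirna)
      ann <- read_annotation(flags$annotation)
      al <- align_samples(x, ann)
      fit <- ebayes_moderate(fit_probe_models(al$expr, al$annotation$group,
                                              contrast = c("MM", "BMPC")))
      tab <- differential_table(fit)
      out <- flags$out %||% "differential.tsv"
      write_differential_table(tab, out)
      mir_msg("differential table written to ", out)
    }),
    cluster = run({
      if (is.null(flags$mirna)) stop("cluster requires --mirna", call. = FALSE)
      x <- read_expression(flags$mirna)
      hc <- average_linkage(pearson_dissimilarity(x))
      out <- flags$out %||% "dendrogram.nwk"
      writeLines(to_newick(hc), out)
      mir_msg("dendrogram written to ", out)
    }),
    correlate = run({
      if (is.null(flags$mirna) || is.null(flags$mrna))
        stop("correlate requires --mirna and --mrna", call. = FALSE)
      a <- read_expression(flags$mirna); b <- read_expression(flags$mrna)
      hits <- correlation_screen(a, b)
      out <- flags$out %||% "correlation_hits.tsv"
      write_correlation_hits(hits, out)
      mir_msg(nrow(hits), " hit(s) written to ", out)
    }),
    { message("unknown subcommand: ", sub, "\n", usage); 2L })
  invisible(status)
}
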