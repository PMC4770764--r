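#' Variance filter
#'
#' Drops the least variable probes, keeping the `ceiling(keep_fraction * n)`
#' probes with the highest sample variance (ties broken deterministically
#' by probe id). Dropping the "80% least variable" probes corresponds to
#' `keep_fraction = 0.2`; on a 559-probe miRNA matrix this retains 112.
#'
#' @param x an `ExpressionMatrix`.
#' @param keep_fraction fraction of probes retained, in (0, 1].
#' @return the filtered `ExpressionMatrix` (original row order preserved).
#' @export
variance_filter <- function(x, keep_fraction) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            keep_fraction > 0, keep_fraction <= 1)
  n <- nrow(x$values)
  k <- ceiling(keep_fraction * n)
  if (k >= n) return(x)
  vars <- apply(x$values, 1, stats::var)
  ord <- order(-vars, probe_ids(x))
  keep_ids <- probe_ids(x)[sort(ord[seq_len(k)])]
  x[keep_ids, ]
}

#' Consensus target filter
#'
#' Retains genes called as targets of a miRNA by at least `min_tools` of
#' the prediction algorithms in the panel (default: at least 6 of 7) to
#' limit false-positive predictions.
#'
#' @param table a `PredictionTable` of gene-by-tool calls for `mirna_id`.
#' @param mirna_id the miRNA the table refers to.
#' @param min_tools minimum number of positive calls (default 6).
#' @return an object of class `ConsensusTargetSet`: list with `mirna_id`,
#'   `gene_ids`, `min_tools`, `n_tools`.
#' @export
consensus_targets <- function(table, mirna_id, min_tools = 6) {
  stopifnot(inherits(table, "PredictionTable"))
  n_tools <- length(table$tool_names)
  if (min_tools > n_tools)
    stop("min_tools exceeds the number of prediction tools", call. = FALSE)
  hits <- rowSums(table$calls) >= min_tools
  structure(list(mirna_id = mirna_id,
                 gene_ids = table$gene_ids[hits],
                 min_tools = min_tools, n_tools = n_tools),
            class = "ConsensusTargetSet")
}

#' miRNA-mRNA correlation screen
#'
#' All pairwise Pearson correlations between (variance-filtered) miRNA and
#' mRNA probes over their shared samples, with BH adjustment over the full
#' tested family. Hits must satisfy `|r| >= r_threshold` and
#' `p_adj <= alpha`. Each hit additionally carries a leave-one-out
#' influence flag: `TRUE` if removing any single sample drops `|r|` below
#' the threshold — an automated surrogate for manual plausibility checks
#' of single-sample-driven correlations.
#'
#' @param mirna,mrna log2-scale `ExpressionMatrix` objects sharing >= 5
#'   samples.
#' @param r_threshold absolute-correlation retention cutoff (default 0.6).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data frame of class `CorrelationHits`: `mirna_id`,
#'   `mrna_probeset`, `r`, `p_raw`, `p_adj`, `influence_flag`; attribute
#'   `n_tested` gives the family size.
#' @export
correlation_screen <- function(mirna, mrna, r_threshold = 0.6, alpha = 0.05) {
  stopifnot(inherits(mirna, "ExpressionMatrix"), inherits(mrna, "ExpressionMatrix"))
  shared <- intersect(sample_ids(mirna), sample_ids(mrna))
  if (length(shared) < 5L)
    stop("correlation screen needs >= 5 shared samples", call. = FALSE)
  A <- t(mirna$values[, shared, drop = FALSE])
  B <- t(mrna$values[, shared, drop = FALSE])
  drop_zero <- function(M, label) {
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0)) {
      warning("excluding ", sum(sds == 0), " zero-variance ", label,
              " probe(s) from the correlation screen", call. = FALSE)
      M <- M[, sds > 0, drop = FALSE]
    }
    M
  }
  A <- drop_zero(A, "miRNA"); B <- drop_zero(B, "mRNA")
  n <- length(shared)
  R <- stats::cor(A, B)
  r <- as.vector(R)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
  p_raw <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p_raw <- pmin(pmax(p_raw, .Machine$double.xmin), 1)
  p_adj <- bh_adjust(p_raw)
  idx <- which(abs(r) >= r_threshold & p_adj <= alpha)
  mir_idx <- (idx - 1) %% nrow(R) + 1
  mrna_idx <- (idx - 1) %/% nrow(R) + 1
  flag <- logical(length(idx))
  for (h in seq_along(idx)) {
    xa <- A[, mir_idx[h]]; xb <- B[, mrna_idx[h]]
    loo <- vapply(seq_len(n), function(i) stats::cor(xa[-i], xb[-i]), numeric(1))
    flag[h] <- any(abs(loo) < r_threshold)
  }
  out <- data.frame(mirna_id = rownames(R)[mir_idx],
                    mrna_probeset = colnames(R)[mrna_idx],
                    r = r[idx], p_raw = p_raw[idx], p_adj = p_adj[idx],
                    influence_flag = flag, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), ]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(r)
  class(out) <- c("CorrelationHits", "data.frame")
  out
}

#' Global association test of a feature set with an outcome
#'
#' Score-type global test of whether a set of expression features carries
#' information about an outcome: with centered feature matrix X (samples x
#' p) and null-model residuals r, the statistic is
#' `Q = t(r) %*% (X %*% t(X) / p) %*% r`, and significance is assessed by
#' permuting the residuals. Continuous and binary outcomes use residuals
#' from the intercept-only model; survival outcomes use martingale
#' residuals from a null Cox model.
#'
#' @param expr `ExpressionMatrix` of the feature set (>= 2 features, >= 10
#'   samples).
#' @param outcome numeric vector, 2-level factor, or a data frame with
#'   `time` and `event` columns (samples in matrix column order).
#' @param n_perm number of residual permutations (default 10000).
#' @return list with `statistic`, `p`, `n_perm`, `outcome_type`.
#' @export
global_association <- function(expr, outcome, n_perm = 10000) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  X <- t(expr$values)
  if (ncol(X) < 2L) stop("association error: need >= 2 features", call. = FALSE)
  if (nrow(X) < 10L) stop("association error: need >= 10 samples", call. = FALSE)
  if (is.data.frame(outcome) && all(c("time", "event") %in% names(outcome))) {
    if (nrow(outcome) != nrow(X))
      stop("association error: outcome length mismatch", call. = FALSE)
    null_fit <- survival::coxph(survival::Surv(outcome$time,
                                               as.logical(outcome$event)) ~ 1)
    r <- stats::residuals(null_fit, type = "martingale")
    type <- "survival"
  } else {
    if (is.factor(outcome) || is.character(outcome)) {
      f <- as.factor(outcome)
      if (nlevels(f) != 2L)
        stop("association error: categorical outcome must have 2 levels",
             call. = FALSE)
      outcome <- as.numeric(f) - 1
      type <- "binary"
    } else type <- "continuous"
    if (length(outcome) != nrow(X))
      stop("association error: outcome length mismatch", call. = FALSE)
    if (stats::var(outcome) == 0)
      stop("association error: constant outcome", call. = FALSE)
    r <- outcome - mean(outcome)
    type <- type
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  # Q = r' X X' r / p computed as |X' r|^2 / p
  qstat <- function(res) sum(crossprod(Xc, res)^2) / ncol(Xc)
  q0 <- qstat(r)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (qstat(sample(r)) >= q0) exceed <- exceed + 1L
  }
  list(statistic = q0, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
       outcome_type = type)
}

#' Two-group and categorical association tests
#'
#' Wilcoxon rank-sum for a continuous feature against a binary grouping;
#' Fisher's exact test for two categorical variables (2x2).
#'
#' @param feature numeric per-sample values (Wilcoxon) or a categorical
#'   vector (Fisher).
#' @param groups grouping vector with two non-empty levels.
#' @return list with `method`, `statistic` (Wilcoxon W or the 2x2 odds
#'   ratio estimate), and `p`.
#' @export
group_tests <- function(feature, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2L || min(table(g)) < 1L)
    stop("grouping error: need two non-empty groups", call. = FALSE)
  if (is.numeric(feature)) {
    ht <- stats::wilcox.test(feature ~ g, exact = NULL)
    list(method = "wilcoxon", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    f <- as.factor(feature)  # keep declared levels so empty margins surface
    tab <- table(f, g)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("grouping error: contingency table has an empty margin",
           call. = FALSE)
    ht <- stats::fisher.test(tab)
    list(method = "fisher", statistic = unname(ht$estimate %||% NA_real_),
         p = ht$p.value)
  }
}

#' Write correlation hits as TSV
#' @param hits a `CorrelationHits` data frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_correlation_hits <- function(hits, path) {
  out <- data.frame(mirna_id = hits$mirna_id,
                    mrna_probeset = hits$mrna_probeset,
                    r = sprintf("%.4f", hits$r),
                    p_adj = sprintf("%.6g", hits$p_adj),
                    influence_flag = as.integer(hits$influence_flag))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
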