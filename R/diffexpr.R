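#' Probe-wise two-group linear fits
#'
#' Ordinary least squares per probe for a two-group contrast; with two
#' groups this is the difference of group means, with the pooled
#' within-group variance as residual variance. Positive coefficients mean
#' higher expression in the first-named group.
#'
#' @param x a log2-scale `ExpressionMatrix`.
#' @param groups factor/character of group membership per sample.
#' @param contrast character pair `c(first, second)`; the coefficient is
#'   mean(first) - mean(second). Defaults to the first two factor levels.
#' @return an object of class `ModeratedFit` with per-probe `coefficients`
#'   (log2 fold changes), residual variances `sigma2`, residual df `df
#'   residual`, the unscaled coefficient variance `v`, and `ave_expr` (mean
#'   log2 expression over the contrasted samples).
#' @export
fit_probe_models <- function(x, groups, contrast = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2")
    stop("differential expression requires a log2-scale matrix", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(x$values))
    stop("design error: group vector length != sample count", call. = FALSE)
  if (is.null(contrast)) contrast <- unique(groups)[1:2]
  if (length(contrast) != 2L || anyNA(contrast))
    stop("design error: contrast must name two groups", call. = FALSE)
  i1 <- which(groups == contrast[1]); i2 <- which(groups == contrast[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("design error: each contrasted group needs >= 2 samples (",
         contrast[1], ": ", n1, ", ", contrast[2], ": ", n2, ")", call. = FALSE)
  v1 <- x$values[, i1, drop = FALSE]; v2 <- x$values[, i2, drop = FALSE]
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  ss1 <- rowSums((v1 - m1)^2); ss2 <- rowSums((v2 - m2)^2)
  df <- n1 + n2 - 2
  structure(list(probe_ids = probe_ids(x),
                 coefficients = m1 - m2,
                 sigma2 = (ss1 + ss2) / df,
                 df_residual = rep(df, nrow(x$values)),
                 v = 1 / n1 + 1 / n2,
                 ave_expr = rowMeans(cbind(v1, v2)),
                 contrast = contrast),
            class = "ModeratedFit")
}

# internal: invert the trigamma function by Newton iteration (monotone
# decreasing on (0, Inf)); needed for the moment estimator of the prior df
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of probe-wise variances
#'
#' Shrinks per-probe residual variances toward a common prior by modelling
#' them as scaled chi-square draws around a scaled inverse-chi-square prior
#' with df `d0` and scale `s0^2`, estimated by matching the first two
#' moments of the log residual variances (the log of a scaled
#' F-distribution). The moderated t-statistic uses the posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)` and gains `d0` degrees of freedom.
#' Probes with (numerically) zero residual variance are excluded from
#' hyperparameter estimation and flagged.
#'
#' @param fit a `ModeratedFit` from [fit_probe_models()].
#' @param prior_df optional override of the estimated prior df: `0` gives
#'   the ordinary t-statistic, `Inf` fully pooled variances.
#' @return the fit augmented with `d0`, `s0_2`, `s2_post`, `t_mod`,
#'   `df_total`, `p_raw` and `zero_variance` flags.
#' @export
ebayes_moderate <- function(fit, prior_df = NULL) {
  stopifnot(inherits(fit, "ModeratedFit"))
  s2 <- fit$sigma2
  d <- fit$df_residual
  if (length(s2) < 10L)
    stop("hyperparameter estimation needs >= 10 probes", call. = FALSE)
  zero <- s2 < 1e-15
  if (all(zero))
    stop("degenerate-variance error: all residual variances are zero",
         call. = FALSE)
  if (is.null(prior_df)) {
    zu <- log(s2[!zero]); du <- d[!zero]
    e <- zu - digamma(du / 2) + log(du / 2)
    ebar <- mean(e)
    evar <- stats::var(e) - mean(trigamma(du / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess dispersion beyond sampling noise: fully pooled variance
      d0 <- Inf
      s0_2 <- mean(s2[!zero])
    }
  } else {
    stopifnot(prior_df >= 0)
    d0 <- prior_df
    if (d0 == 0) {
      s0_2 <- NA_real_
    } else {
      zu <- log(s2[!zero]); du <- d[!zero]
      s0_2 <- exp(mean(zu - digamma(du / 2) + log(du / 2)) +
                    (if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0))
    }
  }
  s2_post <- if (d0 == 0) s2
             else if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + d * s2) / (d0 + d)
  t_mod <- fit$coefficients / sqrt(s2_post * fit$v)
  df_total <- d + d0
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  fit$d0 <- d0; fit$s0_2 <- s0_2; fit$s2_post <- s2_post
  fit$t_mod <- t_mod; fit$df_total <- df_total; fit$p_raw <- p_raw
  fit$zero_variance <- zero
  fit
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort p ascending, multiply by m/rank, enforce
#' monotonicity from the largest down, clip at 1. Input order is restored,
#' so the result is permutation-equivariant.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Signed linear-scale fold change
#'
#' Renders a log2 fold change on the linear scale with the sign encoding
#' direction: `2^logFC` for up-regulation, `-2^(-logFC)` for
#' down-regulation, so magnitudes are always >= 1 and a negative sign means
#' reciprocal fold down-regulation. Printed tables round half away from
#' zero to one decimal (`digits = 1`).
#'
#' @param logFC numeric vector of log2 fold changes.
#' @param digits optional decimal places (rounded half away from zero);
#'   `NULL` returns the exact value.
#' @return numeric vector of signed fold changes.
#' @export
#' @examples
#' signed_fold_change(1.64, digits = 1)    # 3.1
#' signed_fold_change(-2.20, digits = 1)   # -4.6
signed_fold_change <- function(logFC, digits = NULL) {
  stopifnot(is.numeric(logFC), all(is.finite(logFC)))
  fc <- ifelse(logFC >= 0, 2^logFC, -2^(-logFC))
  if (!is.null(digits)) fc <- round_half_away(fc, digits)
  fc
}

#' Differential expression table
#'
#' One row per probe: log2 fold change, signed fold change, average log2
#' expression, moderated t, raw and BH-adjusted p. The attached summary
#' counts significantly up-/down-regulated probes at the chosen adjusted
#' level and renders the counts as `k/n (pct%)` lines.
#'
#' @param fit a moderated `ModeratedFit` (after [ebayes_moderate()]).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return a data frame of class `DifferentialTable`, ordered by raw p,
#'   with attribute `summary`.
#' @export
differential_table <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "ModeratedFit"))
  if (is.null(fit$p_raw))
    stop("run ebayes_moderate() before building the table", call. = FALSE)
  p_adj <- bh_adjust(fit$p_raw)
  tab <- data.frame(probe_id = fit$probe_ids,
                    logFC = fit$coefficients,
                    fc_signed = signed_fold_change(fit$coefficients),
                    ave_expr = fit$ave_expr,
                    t_mod = fit$t_mod,
                    p_raw = fit$p_raw,
                    p_adj = p_adj,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_raw), ]
  rownames(tab) <- NULL
  n <- nrow(tab)
  sig <- tab$p_adj <= alpha
  n_up <- sum(sig & tab$logFC > 0)
  n_down <- sum(sig & tab$logFC < 0)
  attr(tab, "summary") <- list(
    n_total = n, n_up = n_up, n_down = n_down, n_sig = n_up + n_down,
    alpha = alpha,
    lines = c(up = format_fraction(n_up, n),
              down = format_fraction(n_down, n),
              total = format_fraction(n_up + n_down, n)))
  class(tab) <- c("DifferentialTable", "data.frame")
  tab
}

#' Write a differential table as TSV
#'
#' Columns mirror the published layout: probe id, logFC, one-decimal signed
#' FC, average expression, raw and adjusted p.
#'
#' @param tab a `DifferentialTable`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_differential_table <- function(tab, path) {
  out <- data.frame(probe_id = tab$probe_id,
                    logFC = sprintf("%.15g", tab$logFC),
                    FC = sprintf("%.1f", signed_fold_change(tab$logFC, digits = 1)),
                    average_expression = sprintf("%.15g", tab$ave_expr),
                    p_raw = sprintf("%.6g", tab$p_raw),
                    p_adj = sprintf("%.6g", tab$p_adj))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
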