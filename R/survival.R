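#' Cox proportional-hazards fit
#'
#' Thin, validated wrapper around the partial-likelihood Newton fit of
#' \pkg{survival} (Efron tie handling by default), returning log hazard
#' ratios, standard errors from the observed information, hazard ratios
#' with 95% Wald intervals, and Wald p-values. Perfect separation
#' (monotone likelihood) and singular designs are raised as errors rather
#' than returned as runaway estimates.
#'
#' @param covariates numeric matrix or data frame (samples x k) or a single
#'   numeric vector.
#' @param time positive event/censoring times.
#' @param event logical/0-1 event indicators (>= 1 event required).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return an object of class `CoxFit`: list with `coefficients`, `se`,
#'   `hr`, `ci95` (k x 2), `p`, `loglik`, `n`, `n_event`.
#' @export
cox_fit <- function(covariates, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("covariates must be finite numeric", call. = FALSE)
  event <- as.logical(event)
  if (length(time) != nrow(x) || length(event) != nrow(x))
    stop("covariate rows and outcome length differ", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (sum(event) < 1) stop("fit error: no events", call. = FALSE)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- data.frame(x, check.names = FALSE)
  df$.time <- time; df$.event <- event
  fm <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fm, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("singularity error: design matrix is rank-deficient", call. = FALSE)
  if (any(grepl("infinite|did not converge|out of iterations", warn)))
    stop("divergence error: monotone partial likelihood (perfect separation?); ",
         paste(unique(warn), collapse = "; "), call. = FALSE)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(coefficients = beta, se = se, hr = exp(beta),
                 ci95 = cbind(lower = exp(beta - 1.96 * se),
                              upper = exp(beta + 1.96 * se)),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = fit$loglik[length(fit$loglik)],
                 n = nrow(x), n_event = sum(event), ties = ties),
            class = "CoxFit")
}

# internal: two-group log-rank components for a 0/1 group vector; returns
# observed-minus-expected in group 1, its hypergeometric variance, and the
# standardized statistic
logrank_components <- function(group, time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]; group <- group[o]
  n <- length(time)
  ut <- unique(time[event > 0])
  oe <- 0; v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_i <- sum(at_risk)
    n1_i <- sum(at_risk & group == 1)
    dying <- time == t & event > 0
    d_i <- sum(dying)
    d1_i <- sum(dying & group == 1)
    oe <- oe + d1_i - d_i * n1_i / n_i
    if (n_i > 1)
      v <- v + d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1)
  }
  z <- if (v > 0) oe / sqrt(v) else 0
  list(oe = oe, var = v, z = z)
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank comparison (1 df) of survival between two
#' groups.
#'
#' @param group vector with exactly two distinct values.
#' @param time positive times.
#' @param event logical/0-1 event indicators.
#' @return list with `statistic` (chi-square), `p`, and the group labels.
#' @export
logrank_test <- function(group, time, event) {
  g <- as.factor(group)
  if (nlevels(g) != 2L)
    stop("grouping error: exactly two groups required", call. = FALSE)
  if (min(table(g)) < 1L) stop("grouping error: empty group", call. = FALSE)
  event <- as.logical(event)
  if (sum(event) < 1) stop("fit error: no events", call. = FALSE)
  cmp <- logrank_components(as.integer(g == levels(g)[2]), time, event)
  chisq <- cmp$z^2
  list(statistic = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       levels = levels(g))
}

#' Maximally selected rank statistics for an optimal survival cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic at every
#' distinct threshold of `x` whose left-tail proportion lies within the
#' quantile `bounds` (dichotomizing as `x <= c` versus `x > c`), and
#' returns the maximizing cutoff with a multiplicity-adjusted p-value. The
#' default adjustment is the Lausen-Schumacher improved-Bonferroni
#' approximation for the supremum of the absolute standardized process
#' over the bounded range; `pmethod = "permutation"` instead permutes `x`
#' against the outcomes (suitable as an exact-style reference for small
#' n).
#'
#' @param x per-sample numeric marker (>= 10 samples).
#' @param time positive times.
#' @param event logical/0-1 event indicators.
#' @param bounds quantile interval searched, default `c(0.1, 0.9)`.
#' @param pmethod `"lausen"` (default) or `"permutation"`.
#' @param n_perm permutations when `pmethod = "permutation"`.
#' @return object of class `MaxstatResult`: list with `cutoff`,
#'   `max_stat`, `p_adj`, `candidate_grid` (data frame of cutoff and
#'   standardized statistic), `bounds`, `pmethod`.
#' @export
maxstat_cutpoint <- function(x, time, event, bounds = c(0.1, 0.9),
                             pmethod = c("lausen", "permutation"),
                             n_perm = 10000) {
  pmethod <- match.arg(pmethod)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2],
            bounds[1] > 0, bounds[2] < 1)
  if (length(x) < 10L)
    stop("cutpoint error: need >= 10 samples", call. = FALSE)
  event <- as.logical(event)
  if (sum(event) < 1) stop("fit error: no events", call. = FALSE)
  n <- length(x)
  cand <- sort(unique(x))
  # left-tail proportion at each candidate; candidate kept if within bounds
  # and both sides nonempty
  props <- vapply(cand, function(c) mean(x <= c), numeric(1))
  keep <- props >= bounds[1] & props <= bounds[2] & props < 1
  cand <- cand[keep]
  if (length(cand) < 2L)
    stop("cutpoint error: fewer than 2 candidate cutoffs within bounds",
         call. = FALSE)
  stats_grid <- maxstat_grid_stats(x, cand, time, event)
  best <- which.max(stats_grid)
  max_stat <- stats_grid[best]
  cutoff <- cand[best]
  p_adj <- switch(pmethod,
    lausen = lausen_schumacher_p(max_stat, bounds[1], bounds[2]),
    permutation = {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        xp <- sample(x)
        cp <- sort(unique(xp))
        pp <- vapply(cp, function(c) mean(xp <= c), numeric(1))
        cp <- cp[pp >= bounds[1] & pp <= bounds[2] & pp < 1]
        mp <- max(maxstat_grid_stats(xp, cp, time, event))
        if (mp >= max_stat) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
  structure(list(cutoff = cutoff, max_stat = max_stat, p_adj = p_adj,
                 candidate_grid = data.frame(cutoff = cand, stat = stats_grid),
                 bounds = bounds, pmethod = pmethod),
            class = "MaxstatResult")
}

# internal: standardized log-rank statistics for every candidate cutoff at
# once. For each distinct event time we need the deaths and at-risk counts
# in the x > c group; both are inner products with the dichotomization
# indicator, so the whole grid reduces to two matrix products.
maxstat_grid_stats <- function(x, cand, time, event) {
  ut <- sort(unique(time[event > 0]))
  R <- outer(ut, time, function(t, s) as.numeric(s >= t))   # at risk
  E <- outer(ut, time, function(t, s) as.numeric(s == t)) *
    rep(as.numeric(event > 0), each = length(ut))           # dying at t
  n_i <- rowSums(R)
  d_i <- rowSums(E)
  X <- vapply(cand, function(c) as.numeric(x > c), numeric(length(x)))
  n1 <- R %*% X
  d1 <- E %*% X
  oe <- colSums(d1 - d_i * n1 / n_i)
  vterm <- d_i * (n_i - d_i) / pmax(n_i - 1, 1) / n_i^2
  v <- colSums(vterm * n1 * (n_i - n1))
  ifelse(v > 0, abs(oe) / sqrt(v), 0)
}

# internal: Lausen & Schumacher improved-Bonferroni tail approximation for
# sup |B(t)/sqrt(t(1-t))| over t in [eps1, eps2]:
# P(sup > b) ~ phi(b) (b - 1/b) log( (1-eps1) eps2 / ((1-eps2) eps1) ) + 4 phi(b)/b
lausen_schumacher_p <- function(b, eps1, eps2) {
  if (b < 1) return(1)
  phi <- stats::dnorm(b)
  p <- phi * (b - 1 / b) * log(((1 - eps1) * eps2) / ((1 - eps2) * eps1)) +
    4 * phi / b
  min(max(p, 0), 1)
}

#' Optimal-cutpoint dichotomization with log-rank comparison
#'
#' Composes [maxstat_cutpoint()] with [logrank_test()] at the selected
#' cutoff. The log-rank p at the optimized cutoff is optimistic (the
#' cutoff was selected to maximize it); the multiplicity-adjusted maxstat
#' p is the honest quantity and a caveat is logged.
#'
#' @inheritParams maxstat_cutpoint
#' @return list with `maxstat` (a `MaxstatResult`), `logrank_p`, `groups`
#'   (factor `low`/`high` per sample), and `direction` (+1 if the high
#'   group has higher hazard).
#' @export
dichotomize_and_compare <- function(x, time, event, bounds = c(0.1, 0.9),
                                    pmethod = c("lausen", "permutation"),
                                    n_perm = 10000) {
  ms <- maxstat_cutpoint(x, time, event, bounds = bounds,
                         pmethod = pmethod, n_perm = n_perm)
  groups <- factor(ifelse(x <= ms$cutoff, "low", "high"),
                   levels = c("low", "high"))
  lr <- logrank_test(groups, time, event)
  mir_msg("dichotomize_and_compare: log-rank p at the selected cutoff is ",
          "optimistic; report the adjusted maxstat p for inference")
  oe_high <- logrank_components(as.integer(groups == "high"), time, event)$oe
  list(maxstat = ms, logrank_p = lr$p, groups = groups,
       direction = sign(oe_high))
}
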