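# Shared toy builders and independent oracles used across the suite.
options(myelomiR.verbose = FALSE)

# small expression matrix with reproducible values
toy_expr <- function(n_probes = 6, n_samples = 4, seed = 1, scale = "log2",
                     baseline = 9) {
  set.seed(seed)
  expression_matrix(
    matrix(rnorm(n_probes * n_samples, baseline), n_probes,
           dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                           sprintf("S%02d", seq_len(n_samples)))),
    scale = scale)
}

# minimal annotation for a vector of sample ids / groups
toy_annotation <- function(sample_id, group, efs_time = NA, efs_event = NA,
                           os_time = NA, os_event = NA) {
  n <- length(sample_id)
  df <- data.frame(sample_id = sample_id, group = group,
                   t4_14 = "", t11_14 = "", del17p = "", gain1q21 = "",
                   del13q = "", hyperdiploid = "", iss = "", b2m = "",
                   gpi = "", uams = "", ifm = "",
                   efs_time = rep_len(ifelse(is.na(efs_time), "", efs_time), n),
                   efs_event = rep_len(ifelse(is.na(efs_event), "", efs_event), n),
                   os_time = rep_len(ifelse(is.na(os_time), "", os_time), n),
                   os_event = rep_len(ifelse(is.na(os_event), "", os_event), n),
                   stringsAsFactors = FALSE)
  clinical_annotation(df)
}

# Efron-tie Cox partial log-likelihood for a single covariate, written
# directly from the definition; independent oracle for cox_fit
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in unique(time[event > 0])) {
    D <- which(time == t & event > 0)
    R <- which(time >= t)
    d <- length(D)
    sr <- sum(exp(beta * x[R]))
    sd <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sr - (l / d) * sd)
  }
  ll
}

# brute-force maximally selected statistic: enumerate every in-bounds
# threshold and take the max standardized log-rank statistic, using
# survival::survdiff as the statistic engine (independent of the package's
# own log-rank code)
oracle_maxstat <- function(x, time, event, bounds = c(0.1, 0.9)) {
  cand <- sort(unique(x))
  props <- vapply(cand, function(c) mean(x <= c), numeric(1))
  cand <- cand[props >= bounds[1] & props <= bounds[2] & props < 1]
  stats <- vapply(cand, function(c) {
    g <- factor(x > c)
    if (nlevels(g) < 2) return(NA_real_)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sqrt(sd$chisq)
  }, numeric(1))
  list(cutoff = cand[which.max(stats)], max_stat = max(stats, na.rm = TRUE),
       grid = data.frame(cutoff = cand, stat = stats))
}

# exhaustive two-sided Fisher p for a 2x2 table: sum the probabilities of
# all tables (fixed margins) no more probable than the observed one
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# survival outcomes with a planted effect of a score (for power checks)
toy_survival <- function(score, loghr = 0, seed = 1, censor = 0.3) {
  set.seed(seed)
  simulate_survival(score, loghr, baseline_hazard = 0.05, censor_rate = censor)
}
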