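#' Build a principal-component survival risk signature
#'
#' Four-step supervised-PCA construction on a small panel of
#' survival-relevant features (e.g. five prognostic miRNAs, or the
#' consensus target genes of one miRNA):
#'
#' 1. Center each feature and compute the first two principal axes of the
#'    centered feature-by-sample matrix; project each sample to get two
#'    weighted averages (w1, w2).
#' 2. Fit a bivariate Cox model on (w1, w2), once for event-free and once
#'    for overall survival.
#' 3. Average the two coefficient pairs element-wise (`beta_bar`) and score
#'    each sample as the dot product of `beta_bar` with its (w1, w2).
#' 4. Select the optimal cutoff on the training scores by maximally
#'    selected rank statistics.
#'
#' The signature freezes everything needed to re-score an independent
#' cohort by value (feature list, centers, loadings, averaged
#' coefficients, cutoff, and optionally a frozen [NormalizationModel]); see
#' [apply_signature()]. Axis signs are fixed so the largest-magnitude
#' loading is positive; scores are invariant to this convention.
#'
#' If the second principal axis is numerically degenerate (e.g. duplicated
#' features), the signature is built on the first axis alone with zero
#' second loadings, and flagged.
#'
#' @param expr log2-scale `ExpressionMatrix` restricted to the signature
#'   features (>= 2 rows).
#' @param efs,os data frames with columns `sample_id`, `time`, `event`
#'   (e.g. from [get_outcome()]); only samples with both outcomes and
#'   expression are used (>= 10 required).
#' @param bounds maxstat quantile bounds for the cutoff search.
#' @param cutoff_outcome which endpoint drives the cutoff search
#'   (`"efs"`, the primary endpoint, by default).
#' @param normalization optional frozen `NormalizationModel` stored for
#'   documentation-by-value transfer.
#' @return an object of class `RiskSignature`.
#' @export
build_signature <- function(expr, efs, os, bounds = c(0.1, 0.9),
                            cutoff_outcome = c("efs", "os"),
                            normalization = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  cutoff_outcome <- match.arg(cutoff_outcome)
  if (nrow(expr$values) < 2L)
    stop("signature error: need >= 2 features", call. = FALSE)
  ids <- Reduce(intersect, list(sample_ids(expr), efs$sample_id, os$sample_id))
  if (length(ids) < 10L)
    stop("signature error: need >= 10 samples with both outcomes",
         call. = FALSE)
  X <- expr$values[, ids, drop = FALSE]
  ctr <- rowMeans(X)
  Xc <- X - ctr
  sv <- svd(Xc)
  degenerate2 <- length(sv$d) < 2 || sv$d[2] < 1e-10 * sv$d[1]
  fix_sign <- function(u) if (u[which.max(abs(u))] < 0) -u else u
  u1 <- fix_sign(sv$u[, 1])
  u2 <- if (degenerate2) rep(0, nrow(Xc)) else fix_sign(sv$u[, 2])
  w1 <- drop(crossprod(u1, Xc))
  w2 <- drop(crossprod(u2, Xc))
  efs <- efs[match(ids, efs$sample_id), ]
  os <- os[match(ids, os$sample_id), ]
  W <- if (degenerate2) cbind(w1 = w1) else cbind(w1 = w1, w2 = w2)
  fit_efs <- cox_fit(W, efs$time, efs$event)
  fit_os <- cox_fit(W, os$time, os$event)
  beta_bar <- (fit_efs$coefficients + fit_os$coefficients) / 2
  if (degenerate2) beta_bar <- c(beta_bar, 0)
  scores <- beta_bar[1] * w1 + beta_bar[2] * w2
  if (length(unique(scores)) < 2L)
    stop("cutpoint error: fewer than 2 distinct training scores",
         call. = FALSE)
  oc <- if (cutoff_outcome == "efs") efs else os
  ms <- maxstat_cutpoint(scores, oc$time, oc$event, bounds = bounds)
  structure(list(feature_ids = probe_ids(expr),
                 center = stats::setNames(ctr, probe_ids(expr)),
                 loadings1 = stats::setNames(u1, probe_ids(expr)),
                 loadings2 = stats::setNames(u2, probe_ids(expr)),
                 beta_bar = stats::setNames(as.numeric(beta_bar), c("w1", "w2")),
                 cutoff = ms$cutoff,
                 cutoff_outcome = cutoff_outcome,
                 bounds = bounds,
                 degenerate2 = degenerate2,
                 cox_efs = fit_efs, cox_os = fit_os,
                 training_scores = stats::setNames(scores, ids),
                 normalization = normalization,
                 metadata = list()),
            class = "RiskSignature")
}

#' @export
print.RiskSignature <- function(x, ...) {
  cat(sprintf("RiskSignature on %d features; cutoff %.4g (%s, bounds %.2g-%.2g)%s\n",
              length(x$feature_ids), x$cutoff, x$cutoff_outcome,
              x$bounds[1], x$bounds[2],
              if (x$degenerate2) "; second axis degenerate" else ""))
  invisible(x)
}

#' Score a cohort with a frozen risk signature
#'
#' Applies the signature's frozen constants to a new cohort: with
#' `use_documentation = TRUE` (documentation-by-value transfer) the frozen
#' normalization model stored in the signature is applied first, then the
#' frozen centers, loadings, averaged Cox coefficients and cutoff. Nothing
#' is refit. With `use_documentation = FALSE` the incoming expression
#' values are projected as-is — the deliberately naive transfer used to
#' quantify what the frozen preprocessing contributes.
#'
#' @param sig a `RiskSignature`.
#' @param expr log2-scale `ExpressionMatrix` containing all signature
#'   features (a full matrix is fine; when a frozen normalization model is
#'   applied the matrix should cover the model's probe universe).
#' @param use_documentation apply frozen preprocessing (default TRUE).
#' @return a data frame of class `ScoredCohort`: `sample_id`, `w1`, `w2`,
#'   `score`, `risk_group` (`"low"`/`"high"`, high = score > cutoff).
#' @export
apply_signature <- function(sig, expr, use_documentation = TRUE) {
  stopifnot(inherits(sig, "RiskSignature"), inherits(expr, "ExpressionMatrix"))
  missing_feats <- setdiff(sig$feature_ids, probe_ids(expr))
  if (length(missing_feats))
    stop("signature-application error: features absent from matrix: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  if (use_documentation && !is.null(sig$normalization))
    expr <- apply_normalization(sig$normalization, expr)
  X <- expr$values[sig$feature_ids, , drop = FALSE]
  Xc <- X - sig$center
  w1 <- drop(crossprod(sig$loadings1, Xc))
  w2 <- drop(crossprod(sig$loadings2, Xc))
  score <- sig$beta_bar[1] * w1 + sig$beta_bar[2] * w2
  # small tolerance so a sample sitting exactly on the cutoff (the cutoff
  # is itself a training score) classifies stably across serialization
  tol <- 1e-9 * (1 + abs(sig$cutoff))
  out <- data.frame(sample_id = colnames(X), w1 = w1, w2 = w2, score = score,
                    risk_group = factor(ifelse(score - sig$cutoff > tol,
                                               "high", "low"),
                                        levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ScoredCohort", "data.frame")
  out
}

#' Build a miRNA target risk score
#'
#' Runs the same principal-component signature construction on the
#' expression of a miRNA's consensus-predicted target genes, recording the
#' generating miRNA in the signature metadata.
#'
#' @param mirna_id the miRNA whose targets define the score.
#' @param targets a `ConsensusTargetSet` (see [consensus_targets()]) or a
#'   character vector of gene ids.
#' @param mrna log2-scale mRNA `ExpressionMatrix`.
#' @param efs,os outcome data frames as in [build_signature()].
#' @param ... passed to [build_signature()].
#' @return a `RiskSignature` with `metadata$mirna_id` set.
#' @export
build_target_score <- function(mirna_id, targets, mrna, efs, os, ...) {
  gene_ids <- if (inherits(targets, "ConsensusTargetSet")) targets$gene_ids
              else as.character(targets)
  present <- intersect(gene_ids, probe_ids(mrna))
  if (length(present) < 2L)
    stop("target-score error: fewer than 2 predicted targets on the mRNA ",
         "matrix for ", mirna_id, call. = FALSE)
  sig <- build_signature(mrna[present, ], efs, os, ...)
  sig$metadata$mirna_id <- mirna_id
  sig
}

#' Serialize / restore a risk signature
#'
#' Writes every frozen constant (features, centers, loadings, averaged Cox
#' coefficients, cutoff, and any embedded normalization model) as
#' structured text, sufficient to re-score a cohort bit-reproducibly.
#'
#' @param sig a `RiskSignature`.
#' @param path file path (JSON).
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   the restored signature.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "RiskSignature"))
  obj <- list(feature_ids = sig$feature_ids,
              center = as.list(sig$center),
              loadings1 = as.list(sig$loadings1),
              loadings2 = as.list(sig$loadings2),
              beta_bar = as.list(sig$beta_bar),
              cutoff = sig$cutoff,
              cutoff_outcome = sig$cutoff_outcome,
              bounds = sig$bounds,
              degenerate2 = sig$degenerate2,
              metadata = sig$metadata,
              normalization = if (!is.null(sig$normalization)) {
                nm <- unclass(sig$normalization)
                nm$reference <- as.list(nm$reference)
                nm
              })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- list(feature_ids = obj$feature_ids,
              center = unlist(obj$center),
              loadings1 = unlist(obj$loadings1),
              loadings2 = unlist(obj$loadings2),
              beta_bar = unlist(obj$beta_bar),
              cutoff = obj$cutoff,
              cutoff_outcome = obj$cutoff_outcome,
              bounds = obj$bounds,
              degenerate2 = obj$degenerate2,
              metadata = as.list(obj$metadata),
              normalization = NULL)
  if (!is.null(obj$normalization)) {
    nm <- obj$normalization
    nm$reference <- unlist(nm$reference)
    sig$normalization <- structure(nm, class = "NormalizationModel")
  }
  structure(sig, class = "RiskSignature")
}
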