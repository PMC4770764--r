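#' Constant-offset log2 transform
#'
#' Adds a constant to raw signal so that the global minimum becomes exactly
#' 1, then takes log2; the log2 minimum of the output is therefore exactly
#' 0. With `offset = "auto"` the constant is `1 - min(values)` (for the
#' miChip data modelled here the study constant was 114). The constant used
#' is recorded as attribute `offset_constant`.
#'
#' @param x an `ExpressionMatrix` with `scale = "raw"`.
#' @param offset numeric constant, or `"auto"`.
#' @return a log2-scale `ExpressionMatrix`.
#' @export
scaled_log2 <- function(x, offset = "auto") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "raw")
    stop("scaled_log2 expects a raw-scale matrix", call. = FALSE)
  if (identical(offset, "auto")) {
    offset <- 1 - min(x$values)
  } else {
    stopifnot(is.numeric(offset), length(offset) == 1L)
  }
  shifted <- x$values + offset
  if (any(shifted <= 0))
    stop("domain error: value + offset <= 0; increase the offset constant",
         call. = FALSE)
  out <- expression_matrix(log2(shifted), scale = "log2")
  attr(out, "offset_constant") <- offset
  out
}

#' Fit a rank-invariant normalization model
#'
#' The model freezes a per-probe reference profile (by default the
#' probe-wise median pseudo-sample of the training cohort) together with
#' the invariant-selection settings. [apply_normalization()] then maps each
#' sample onto this reference through an approximately rank-invariant probe
#' set: probes whose rank in the sample differs from their rank in the
#' reference by less than `threshold` (as a proportion of the probe count),
#' iterated to convergence. A monotone piecewise-linear mapping is fit
#' through matched quantiles of the invariant probes.
#'
#' The frozen model serializes to JSON ([write_normalization_model()]) so a
#' signature can ship its preprocessing by value and re-score an
#' independent cohort without refitting.
#'
#' @param x a log2-scale `ExpressionMatrix` with at least 2 samples.
#' @param reference `"median_sample"` or `"supplied"`.
#' @param ref_values named per-probe numeric vector when
#'   `reference = "supplied"`.
#' @param threshold rank-difference proportion below which a probe counts
#'   as invariant. The default (`NULL`) uses 0.05, widened to `25/n` on
#'   small arrays so the rank window never shrinks below ~25 rank units.
#' @param floor_size minimum invariant-set size; smaller sets raise an
#'   error advising threshold relaxation. Default (`NULL`): 20, reduced
#'   to n/4 (at least 5) on small arrays.
#' @param max_iter maximum selection iterations (default 10).
#' @param n_knots number of quantile knots for the monotone mapping.
#' @return an object of class `NormalizationModel`.
#' @export
fit_invariant_normalization <- function(x,
                                        reference = c("median_sample", "supplied"),
                                        ref_values = NULL,
                                        threshold = NULL, floor_size = NULL,
                                        max_iter = 10, n_knots = 30) {
  npr <- nrow(x$values)
  threshold <- threshold %||% max(0.05, 25 / npr)
  floor_size <- floor_size %||% max(5, min(20, floor(npr / 4)))
  stopifnot(inherits(x, "ExpressionMatrix"))
  reference <- match.arg(reference)
  if (x$scale != "log2")
    stop("normalization operates on log2-scale matrices", call. = FALSE)
  if (ncol(x$values) < 2 && reference == "median_sample")
    stop("need >= 2 samples to build a median reference", call. = FALSE)
  ref <- switch(reference,
    median_sample = apply(x$values, 1, stats::median),
    supplied = {
      if (is.null(ref_values) || is.null(names(ref_values)))
        stop("supplied reference requires a named per-probe vector", call. = FALSE)
      if (!all(probe_ids(x) %in% names(ref_values)))
        stop("alignment error: reference does not cover all probes", call. = FALSE)
      ref_values[probe_ids(x)]
    })
  structure(list(reference = stats::setNames(as.numeric(ref), probe_ids(x)),
                 threshold = threshold, floor_size = floor_size,
                 max_iter = max_iter, n_knots = n_knots),
            class = "NormalizationModel")
}

# internal: iterated rank-invariant probe selection for one sample
select_invariant <- function(sample_vals, ref_vals, threshold, max_iter) {
  idx <- seq_along(sample_vals)
  for (it in seq_len(max_iter)) {
    n <- length(idx)
    dr <- abs(rank(sample_vals[idx]) - rank(ref_vals[idx])) / n
    keep <- dr < threshold
    if (all(keep)) break
    idx <- idx[keep]
    if (length(idx) < 3L) break
  }
  idx
}

# internal: monotone piecewise-linear quantile mapping through the
# invariant probes; returns a vectorized function. Knot ordinates are
# quantiles of each side separately, hence non-decreasing by construction;
# tails are extended with the end-segment slopes.
invariant_mapping <- function(x_inv, y_inv, n_knots) {
  k <- min(n_knots, length(x_inv))
  qs <- seq(0, 1, length.out = max(k, 2))
  qx <- stats::quantile(x_inv, qs, names = FALSE, type = 7)
  qy <- stats::quantile(y_inv, qs, names = FALSE, type = 7)
  keep <- !duplicated(qx)
  qx <- qx[keep]; qy <- cummax(qy[keep])
  if (length(qx) < 2L) {
    delta <- qy[1] - qx[1]
    return(function(v) v + delta)
  }
  m <- length(qx)
  slope_lo <- (qy[2] - qy[1]) / (qx[2] - qx[1])
  slope_hi <- (qy[m] - qy[m - 1]) / (qx[m] - qx[m - 1])
  if (slope_lo <= 0) slope_lo <- 1
  if (slope_hi <= 0) slope_hi <- 1
  function(v) {
    out <- stats::approx(qx, qy, xout = v, rule = 2)$y
    lo <- v < qx[1]; hi <- v > qx[m]
    out[lo] <- qy[1] + slope_lo * (v[lo] - qx[1])
    out[hi] <- qy[m] + slope_hi * (v[hi] - qx[m])
    out
  }
}

#' Apply a rank-invariant normalization model
#'
#' Each sample is mapped onto the frozen reference profile by a monotone
#' non-decreasing piecewise-linear function fit through its rank-invariant
#' probes, so within-sample rank order is preserved. A sample identical to
#' the reference maps to itself.
#'
#' @param model a `NormalizationModel`.
#' @param x a log2-scale `ExpressionMatrix` whose probes all occur in the
#'   model's probe universe.
#' @return the normalized `ExpressionMatrix`.
#' @export
apply_normalization <- function(model, x) {
  stopifnot(inherits(model, "NormalizationModel"),
            inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2")
    stop("normalization operates on log2-scale matrices", call. = FALSE)
  unknown <- setdiff(probe_ids(x), names(model$reference))
  if (length(unknown))
    stop("alignment error: probes absent from the normalization model: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) " ...", call. = FALSE)
  ref <- model$reference[probe_ids(x)]
  out <- x$values
  for (j in seq_len(ncol(out))) {
    sj <- out[, j]
    idx <- select_invariant(sj, ref, model$threshold, model$max_iter)
    if (length(idx) < model$floor_size)
      stop("normalization error: invariant set for sample '",
           colnames(out)[j], "' has only ", length(idx),
           " probes (< ", model$floor_size,
           "); consider relaxing `threshold`", call. = FALSE)
    fmap <- invariant_mapping(sj[idx], ref[idx], model$n_knots)
    out[, j] <- fmap(sj)
  }
  expression_matrix(out, scale = "log2")
}

#' Fit and apply invariant normalization in one step
#'
#' @inheritParams fit_invariant_normalization
#' @return list with elements `expr` (normalized matrix) and `model`.
#' @export
normalize_expression <- function(x, ...) {
  model <- fit_invariant_normalization(x, ...)
  list(expr = apply_normalization(model, x), model = model)
}

#' Serialize / restore a normalization model
#'
#' @param model a `NormalizationModel`.
#' @param path file path (JSON).
#' @return `write_normalization_model` returns `path` invisibly;
#'   `read_normalization_model` returns the model.
#' @export
write_normalization_model <- function(model, path) {
  stopifnot(inherits(model, "NormalizationModel"))
  obj <- unclass(model)
  obj$reference <- as.list(obj$reference)  # keep probe names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization_model
#' @export
read_normalization_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$reference <- unlist(obj$reference)
  structure(obj, class = "NormalizationModel")
}
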