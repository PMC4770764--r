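#' Probe-by-sample expression matrix
#'
#' Lightweight container for array expression data: a numeric matrix with
#' unique probe (row) and sample (column) identifiers and a scale tag saying
#' whether values are raw signal or log2 expression. All downstream
#' statistics require `scale = "log2"`.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids character vector of unique probe identifiers; defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param scale `"raw"` or `"log2"`. log2 matrices must be finite.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (matrix with dimnames) and `scale`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L)
    stop("degenerate matrix: no probes", call. = FALSE)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe and sample identifiers are required", call. = FALSE)
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids))
    stop("identifier error: dimensions do not match identifier counts",
         call. = FALSE)
  if (anyDuplicated(probe_ids))
    stop("identifier error: duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("identifier error: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(probe_ids) == 0L)
    stop("degenerate matrix: no probes", call. = FALSE)
  if (anyNA(values))
    stop("expression matrices must be complete (no missing values)",
         call. = FALSE)
  if (scale == "log2" && any(!is.finite(values)))
    stop("log2-scale matrix contains non-finite values", call. = FALSE)
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (scale = %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Probe and sample identifiers
#' @param x an `ExpressionMatrix`.
#' @return character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix
#'
#' @param x an `ExpressionMatrix`.
#' @param i probe selector (ids, indices or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @return an `ExpressionMatrix` restricted to the selection.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  expression_matrix(v, scale = x$scale)
}

#' Read an expression matrix from tab-delimited text
#'
#' Expected layout: an optional `#scale=` comment line, a header row
#' `probe_id<TAB>sample1<TAB>...`, then one probe per row. Cells must all be
#' numeric; missing cells are rejected.
#'
#' @param path file path.
#' @param scale declared scale. If `NULL`, the `#scale=` sidecar line in the
#'   file is used (and is required).
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(path, scale = NULL) {
  if (!file.exists(path)) stop("IO error: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  file_scale <- NULL
  meta <- grep("^#scale=", lines, value = TRUE)
  if (length(meta)) file_scale <- sub("^#scale=", "", meta[1])
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("parse error: no data rows in ", path, call. = FALSE)
  scale <- scale %||% file_scale
  if (is.null(scale))
    stop("scale not declared and no #scale= line in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  body <- fields[-1]
  ncol_expected <- length(header)
  probes <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(samples))
  for (r in seq_along(body)) {
    row <- body[[r]]
    if (length(row) != ncol_expected)
      stop(sprintf("parse error: row %d has %d fields, expected %d",
                   r, length(row), ncol_expected), call. = FALSE)
    probes[r] <- row[1]
    cells <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(cells))
    if (length(bad))
      stop(sprintf("parse error: non-numeric or missing cell at probe '%s' (row %d), sample '%s'",
                   row[1], r, samples[bad[1]]), call. = FALSE)
    vals[r, ] <- cells
  }
  expression_matrix(vals, probes, samples, scale = scale)
}

#' Write an expression matrix as tab-delimited text
#'
#' Emits a `#scale=` metadata line followed by a header and one probe per
#' row. Values are printed with up to 15 significant digits so that decimal
#' representations round-trip exactly through [read_expression()].
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (nrow(x$values) == 0L) stop("degenerate matrix: no probes", call. = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("IO error: cannot write ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(sprintf("#scale=%s", x$scale), con)
  writeLines(paste(c("probe_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1, function(v)
    paste(sprintf("%.15g", v), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}

# fixed annotation schema (column -> required)
.annotation_columns <- c("sample_id", "group", "t4_14", "t11_14", "del17p",
                         "gain1q21", "del13q", "hyperdiploid", "iss", "b2m",
                         "gpi", "uams", "ifm", "efs_time", "efs_event",
                         "os_time", "os_event")
.aberration_flags <- c("t4_14", "t11_14", "del17p", "gain1q21", "del13q",
                       "hyperdiploid")

#' Construct a clinical annotation table
#'
#' One row per sample: diagnostic group, iFISH aberration flags, ISS stage,
#' beta-2-microglobulin, continuous gene-expression risk indices (GPI,
#' UAMS-type, IFM-type; consumed as precomputed per-sample values), and
#' event-free / overall survival outcomes. Aberration flags take values
#' `"present"`, `"absent"` or `"unknown"`; all clinical fields may be `NA`.
#'
#' @param df data frame carrying the columns named in the annotation schema
#'   (`sample_id`, `group`, `t4_14`, `t11_14`, `del17p`, `gain1q21`,
#'   `del13q`, `hyperdiploid`, `iss`, `b2m`, `gpi`, `uams`, `ifm`,
#'   `efs_time`, `efs_event`, `os_time`, `os_event`).
#' @return a validated data frame of class `ClinicalAnnotation`.
#' @export
clinical_annotation <- function(df) {
  missing_cols <- setdiff(.annotation_columns, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, .annotation_columns]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("identifier error: duplicate sample ids in annotation", call. = FALSE)
  groups <- c("BMPC", "MGUS", "MM", "HMCL")
  if (!all(df$group %in% groups))
    stop("schema error: unknown group label(s): ",
         paste(setdiff(unique(df$group), groups), collapse = ", "),
         call. = FALSE)
  df$group <- factor(df$group, levels = groups)
  for (fl in .aberration_flags) {
    v <- as.character(df[[fl]])
    v[is.na(v) | v == ""] <- "unknown"
    v[v %in% c("1", "present", "yes")] <- "present"
    v[v %in% c("0", "absent", "no")] <- "absent"
    if (!all(v %in% c("present", "absent", "unknown")))
      stop("schema error: bad aberration value in column ", fl, call. = FALSE)
    df[[fl]] <- factor(v, levels = c("present", "absent", "unknown"))
  }
  iss <- as.character(df$iss)
  iss[is.na(iss) | iss == ""] <- "unknown"
  if (!all(iss %in% c("I", "II", "III", "unknown")))
    stop("schema error: invalid ISS stage: ",
         paste(setdiff(unique(iss), c("I", "II", "III", "unknown")),
               collapse = ", "), call. = FALSE)
  df$iss <- factor(iss, levels = c("I", "II", "III", "unknown"))
  for (num in c("b2m", "gpi", "uams", "ifm", "efs_time", "os_time")) {
    df[[num]] <- suppressWarnings(as.numeric(ifelse(df[[num]] == "", NA, df[[num]])))
  }
  if (any(!is.na(df$b2m) & df$b2m < 0))
    stop("validation error: b2m must be non-negative", call. = FALSE)
  for (ev in c("efs_event", "os_event")) {
    v <- ifelse(df[[ev]] == "", NA, df[[ev]])
    v <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & !v %in% c(0, 1)))
      stop("validation error: ", ev, " must be 0/1", call. = FALSE)
    df[[ev]] <- as.logical(v)
  }
  for (pair in list(c("efs_time", "efs_event"), c("os_time", "os_event"))) {
    tm <- df[[pair[1]]]; evt <- df[[pair[2]]]
    if (any(!is.na(tm) & tm <= 0))
      stop("validation error: ", pair[1], " must be positive", call. = FALSE)
    if (any(is.na(tm) != is.na(evt)))
      stop("validation error: ", pair[1], " and ", pair[2],
           " must be jointly present or jointly missing", call. = FALSE)
  }
  rownames(df) <- df$sample_id
  class(df) <- c("ClinicalAnnotation", "data.frame")
  df
}

#' Read a clinical annotation table
#'
#' Tab-delimited with the fixed header described in
#' [clinical_annotation()]; empty cells encode missing values.
#'
#' @param path file path.
#' @return a `ClinicalAnnotation` data frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("IO error: no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  clinical_annotation(df)
}

#' Write a clinical annotation table
#'
#' @param ann a `ClinicalAnnotation` data frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "ClinicalAnnotation"))
  out <- ann
  for (fl in .aberration_flags) {
    v <- as.character(out[[fl]])
    out[[fl]] <- ifelse(v == "unknown", "", ifelse(v == "present", "1", "0"))
  }
  out$iss <- ifelse(as.character(out$iss) == "unknown", "", as.character(out$iss))
  for (num in c("b2m", "gpi", "uams", "ifm", "efs_time", "os_time")) {
    out[[num]] <- ifelse(is.na(out[[num]]), "", sprintf("%.15g", out[[num]]))
  }
  for (ev in c("efs_event", "os_event")) {
    out[[ev]] <- ifelse(is.na(out[[ev]]), "", as.integer(out[[ev]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix with its annotation
#'
#' Restricts both objects to their shared samples, in matrix column order,
#' and reports dropped identifiers. Idempotent.
#'
#' @param x an `ExpressionMatrix`.
#' @param ann a `ClinicalAnnotation` data frame.
#' @return list with elements `expr` and `annotation`.
#' @export
align_samples <- function(x, ann) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(ann, "ClinicalAnnotation"))
  shared <- intersect(sample_ids(x), ann$sample_id)
  if (length(shared) == 0L)
    stop("alignment error: no shared sample ids", call. = FALSE)
  keep <- sample_ids(x)[sample_ids(x) %in% shared]
  dropped <- c(setdiff(sample_ids(x), shared), setdiff(ann$sample_id, shared))
  if (length(dropped))
    mir_msg("align_samples: dropping ", length(dropped), " unmatched sample(s): ",
            paste(dropped, collapse = ", "))
  ann2 <- ann[match(keep, ann$sample_id), , drop = FALSE]
  class(ann2) <- class(ann)
  list(expr = x[, keep], annotation = ann2)
}

#' Construct a target-prediction table
#'
#' Boolean gene-by-tool calls from a panel of miRNA target-prediction
#' algorithms (seven by default, matching the usual consensus panel of
#' DIANA-microT, miRanda, miRWalk, miRDB, PITA, RNAhybrid and TargetScan).
#'
#' @param calls logical/0-1 matrix, genes in rows, tools in columns.
#' @param gene_ids unique gene identifiers (defaults to rownames).
#' @param tool_names tool names (defaults to colnames).
#' @return an object of class `PredictionTable`.
#' @export
prediction_table <- function(calls, gene_ids = rownames(calls),
                             tool_names = colnames(calls)) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  mode(calls) <- "logical"
  if (anyNA(calls)) stop("prediction calls must be 0/1", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("identifier error: duplicate gene ids", call. = FALSE)
  if (length(tool_names) != ncol(calls))
    stop("tool name count does not match call columns", call. = FALSE)
  dimnames(calls) <- list(gene_ids, tool_names)
  structure(list(gene_ids = gene_ids, tool_names = as.character(tool_names),
                 calls = calls), class = "PredictionTable")
}

#' Read a target-prediction table
#'
#' Tab-delimited, header `gene_id<TAB>tool1...`, cells 0/1.
#'
#' @param path file path.
#' @return a `PredictionTable`.
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) stop("IO error: no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    stop("schema error: first column must be gene_id", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1)))
    stop("parse error: prediction cells must be 0/1", call. = FALSE)
  prediction_table(m == 1, gene_ids = df$gene_id, tool_names = names(df)[-1])
}

#' Write a target-prediction table
#' @param pt a `PredictionTable`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_prediction_table <- function(pt, path) {
  stopifnot(inherits(pt, "PredictionTable"))
  df <- data.frame(gene_id = pt$gene_ids,
                   matrix(as.integer(pt$calls), nrow(pt$calls),
                          dimnames = list(NULL, pt$tool_names)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a survival outcome from an annotation
#'
#' Pulls one endpoint's (time, event) pairs, restricted to samples where
#' the outcome is recorded.
#'
#' @param ann a `ClinicalAnnotation` data frame.
#' @param endpoint `"efs"` or `"os"`.
#' @return data frame with `sample_id`, `time`, `event`.
#' @export
get_outcome <- function(ann, endpoint = c("efs", "os")) {
  endpoint <- match.arg(endpoint)
  tm <- ann[[paste0(endpoint, "_time")]]
  ev <- ann[[paste0(endpoint, "_event")]]
  ok <- !is.na(tm)
  data.frame(sample_id = ann$sample_id[ok], time = tm[ok], event = ev[ok],
             stringsAsFactors = FALSE)
}
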