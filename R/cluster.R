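#' Centered-Pearson sample dissimilarity
#'
#' `d(i, j) = 1 - r(i, j)` with r the (mean-centered) Pearson correlation
#' between samples computed over probes; d lies in \[0, 2\] with 0 on the
#' diagonal. ("Centered" distinguishes this from the uncentered cosine
#' variant in the hierarchical-clustering vocabulary.) Invariant to
#' positive affine rescaling of each sample.
#'
#' @param x an `ExpressionMatrix` with >= 2 samples and >= 2 probes.
#' @return symmetric sample-by-sample dissimilarity matrix.
#' @export
pearson_dissimilarity <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2L || nrow(x$values) < 2L)
    stop("need >= 2 samples and >= 2 probes", call. = FALSE)
  sds <- apply(x$values, 2, stats::sd)
  if (any(sds == 0))
    stop("dissimilarity error: zero-variance sample(s): ",
         paste(colnames(x$values)[sds == 0], collapse = ", "), call. = FALSE)
  d <- 1 - stats::cor(x$values)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with arithmetic-average linkage:
#' `d(A+B, C) = (|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)`. Ties in the
#' minimum inter-cluster distance are broken deterministically by the
#' lexicographically smallest leaf label contained in each cluster. The
#' result is a standard `hclust` object (so `cutree`, `as.dendrogram`
#' etc. apply).
#'
#' @param d symmetric dissimilarity matrix with dimnames, or a `dist`.
#' @return an object of class `hclust` with `method = "average"`.
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12)
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  # active clusters: id (negative leaf / positive merge row), size,
  # smallest member label (for tie-breaks)
  active <- data.frame(id = -seq_len(n), size = 1L, minlab = labels,
                       stringsAsFactors = FALSE)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- nrow(D)
    # locate minimal off-diagonal distance; tie-break by sorted pair of
    # smallest member labels
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cand <- list(val = D[i, j],
                   key = sort(c(active$minlab[i], active$minlab[j])),
                   i = i, j = j)
      if (is.null(best) || cand$val < best$val - 1e-12 ||
          (abs(cand$val - best$val) <= 1e-12 &&
           (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    ids <- sort(c(active$id[i], active$id[j]))
    merge[step, ] <- ids
    height[step] <- best$val
    ni <- active$size[i]; nj <- active$size[j]
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(id = step, size = ni + nj,
                               minlab = min(active$minlab[c(i, j)]),
                               stringsAsFactors = FALSE))
  }
  # leaf order for plotting: in-order traversal of the merge tree
  traverse <- function(node) {
    if (node < 0) return(-node)
    c(traverse(merge[node, 1]), traverse(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = if (n > 1) traverse(n - 1) else 1L,
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "pearson"),
            class = "hclust")
}

# internal: leaf label sets for every internal node of an hclust tree
clade_members <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    get <- function(id) if (id < 0) hc$labels[-id] else members[[id]]
    members[[k]] <- c(get(hc$merge[k, 1]), get(hc$merge[k, 2]))
  }
  members
}

#' Newick export of a dendrogram
#'
#' Ultrametric rendering: each leaf sits at depth `height(root) / 2`, and a
#' branch length is the half-height difference between parent and child.
#'
#' @param hc an `hclust` object.
#' @return single-element character vector (Newick string with trailing
#'   semicolon).
#' @export
to_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  node_str <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%.10g", hc$labels[-id], parent_h / 2)
    } else {
      h <- hc$height[id]
      sprintf("(%s,%s):%.10g", node_str(hc$merge[id, 1], h),
              node_str(hc$merge[id, 2], h), (parent_h - h) / 2)
    }
  }
  root <- length(hc$height)
  h <- hc$height[root]
  sprintf("(%s,%s);", node_str(hc$merge[root, 1], h),
          node_str(hc$merge[root, 2], h))
}

#' Group-coherence report for a clustering
#'
#' For each diagnostic group, finds the smallest clade containing all of
#' its members and reports whether the group forms a pure sub-branch (the
#' clade contains no other samples) — e.g. whether cell-line samples
#' segregate into their own branch.
#'
#' @param hc an `hclust` of samples.
#' @param annotation a `ClinicalAnnotation` covering every leaf.
#' @return data frame of class `ClusterPurityReport` with columns `group`,
#'   `n`, `clade_size`, `pure`.
#' @export
cluster_purity_report <- function(hc, annotation) {
  stopifnot(inherits(hc, "hclust"), inherits(annotation, "ClinicalAnnotation"))
  missing_ann <- setdiff(hc$labels, annotation$sample_id)
  if (length(missing_ann))
    stop("leaves without annotation: ", paste(missing_ann, collapse = ", "),
         call. = FALSE)
  ann <- annotation[match(hc$labels, annotation$sample_id), ]
  members <- clade_members(hc)
  sizes <- lengths(members)
  rows <- lapply(levels(ann$group), function(g) {
    leaves <- hc$labels[ann$group == g]
    if (length(leaves) == 0L)
      return(data.frame(group = g, n = 0L, clade_size = NA_integer_,
                        pure = NA))
    if (length(leaves) == length(hc$labels))
      return(data.frame(group = g, n = length(leaves),
                        clade_size = length(leaves), pure = TRUE))
    if (length(leaves) == 1L)
      return(data.frame(group = g, n = 1L, clade_size = 1L, pure = TRUE))
    contains <- vapply(members, function(mm) all(leaves %in% mm), logical(1))
    k <- which(contains)[which.min(sizes[contains])]
    data.frame(group = g, n = length(leaves), clade_size = sizes[k],
               pure = sizes[k] == length(leaves))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ClusterPurityReport", "data.frame")
  out
}

#' @export
print.ClusterPurityReport <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    if (x$n[i] == 0) {
      cat(sprintf("%-5s: no samples\n", x$group[i]))
    } else {
      cat(sprintf("%-5s: %d sample(s); smallest containing clade %d leaves; %s\n",
                  x$group[i], x$n[i], x$clade_size[i],
                  if (isTRUE(x$pure[i])) "pure sub-branch" else "interleaved"))
    }
  }
  invisible(x)
}
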