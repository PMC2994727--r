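#' Filter genes by standard deviation
#'
#' Keeps genes whose sample standard deviation (n - 1 denominator, over
#' non-missing values) meets a threshold; the `strict` flag selects between
#' the ">= min_sd" and "> min_sd" variants of the filter. Gene order is
#' preserved. Genes with fewer than two non-missing values have undefined
#' SD and are removed.
#'
#' @param x An `ExpressionMatrix` with at least two samples.
#' @param min_sd SD threshold.
#' @param strict If `TRUE`, require SD strictly greater than `min_sd`.
#' @return The filtered `ExpressionMatrix`.
#' @export
sd_filter <- function(x, min_sd, strict = FALSE) {
  v <- x$values
  if (ncol(v) < 2) stop("sd_filter needs at least two samples", call. = FALSE)
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  keep <- if (strict) sds > min_sd else sds >= min_sd
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stop(sprintf("no gene passes the SD %s %.3g filter; lower the threshold",
                 if (strict) ">" else ">=", min_sd), call. = FALSE)
  }
  expression_matrix(v[keep, , drop = FALSE], scale = x$scale,
                    study_labels = x$study_labels)
}

#' Uncentered Pearson correlation
#'
#' The cosine-like similarity sum(x*y) / sqrt(sum(x^2) * sum(y^2)) that does
#' not subtract means — the similarity metric of the Eisen Cluster software.
#' Computed over positions where both vectors are non-missing
#' (pairwise-complete); a zero norm on either side, or no overlapping
#' positions, is an error rather than a silent 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Similarity in \[-1, 1\].
#' @examples
#' uncentered_pearson(c(1, 2, 3), c(3, 2, 1))  # 10/14
#' @export
uncentered_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no overlapping non-missing positions", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) {
    stop("zero norm; uncentered correlation undefined", call. = FALSE)
  }
  max(-1, min(1, sum(x * y) / sqrt(nx * ny)))
}

#' Pairwise similarity matrix over genes or samples
#'
#' @param x An `ExpressionMatrix`.
#' @param axis Compute similarities between `"genes"` (rows) or `"samples"`
#'   (columns).
#' @param flavor `"uncentered"` (Eisen Cluster metric) or `"centered"`
#'   (classic Pearson, via [stats::cor()] with pairwise-complete
#'   observations).
#' @return A symmetric numeric matrix with unit diagonal for non-degenerate
#'   profiles; pairs whose similarity is undefined are `NA` with a warning.
#' @export
correlation_matrix <- function(x, axis = c("genes", "samples"),
                               flavor = c("uncentered", "centered")) {
  axis <- match.arg(axis)
  flavor <- match.arg(flavor)
  m <- if (axis == "genes") x$values else t(x$values)
  if (nrow(m) < 2) stop("need at least two items along the chosen axis",
                        call. = FALSE)
  if (flavor == "centered") {
    return(stats::cor(t(m), use = "pairwise.complete.obs"))
  }
  n <- nrow(m)
  if (!anyNA(m)) {
    norms <- sqrt(rowSums(m^2))
    if (any(norms == 0)) {
      warning("zero-norm profile(s); similarities set to NA", call. = FALSE)
      norms[norms == 0] <- NA_real_
    }
    s <- tcrossprod(m) / outer(norms, norms)
    s <- pmin(pmax(s, -1), 1)
    diag(s)[!is.na(diag(s))] <- 1
    return(s)
  }
  s <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  failed <- FALSE
  for (i in seq_len(n)) {
    s[i, i] <- 1
    for (j in seq_len(n)[-seq_len(i)]) {
      sim <- tryCatch(uncentered_pearson(m[i, ], m[j, ]),
                      error = function(e) NA_real_)
      if (is.na(sim)) failed <- TRUE
      s[i, j] <- s[j, i] <- sim
    }
  }
  if (failed) warning("similarity undefined for some pair(s); recorded as NA",
                      call. = FALSE)
  s
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Agglomerative clustering where the distance between two clusters is the
#' unweighted mean of all pairwise item distances. Ties in the minimum
#' distance are broken deterministically by the lowest pair of current
#' cluster indices (leaves first, in input order, then internal nodes in
#' creation order), so dendrograms are bit-reproducible.
#'
#' @param d Square symmetric distance matrix (zero diagonal), or a `dist`.
#' @param labels Item labels; default row names of `d`.
#' @return A `Dendrogram`: list with `merge` (hclust coding: negative =
#'   leaf, positive = earlier merge), `height` (merge distances,
#'   non-decreasing), `order` (leaf ordering for display), and `labels`.
#' @export
upgma <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("`d` must be a square distance matrix", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2) stop("need at least two items to cluster", call. = FALSE)
  if (anyNA(d)) stop("distance matrix contains NA", call. = FALSE)
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- d
  diag(D) <- Inf
  # cluster bookkeeping: id[i] is the hclust code of active cluster i
  id <- -seq_len(n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  D[!active, ] <- Inf
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- 0L; bj <- 0L
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[(ii + 1L):length(act)]
      dj <- D[i, js]
      mi <- min(dj)
      if (mi < best) {  # strict: ties keep the earliest (lowest-index) pair
        best <- mi
        bi <- i
        bj <- js[which(dj == mi)[1L]]
      }
    }
    merge[step, ] <- sort(c(id[bi], id[bj]))
    height[step] <- best
    # Lance-Williams update for unweighted average linkage
    for (k in act) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <-
        (size[bi] * D[bi, k] + size[bj] * D[bj, k]) / (size[bi] + size[bj])
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
    D[bj, ] <- Inf; D[, bj] <- Inf
    id[bi] <- step
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge), labels = labels),
            class = "Dendrogram")
}

# Leaf ordering by left-to-right traversal of the merge tree.
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Average-linkage clustering of an expression matrix
#'
#' Computes the similarity matrix along the chosen axis (see
#' [correlation_matrix()]), converts it to distances d = 1 - similarity, and
#' runs [upgma()].
#'
#' @inheritParams correlation_matrix
#' @return A `Dendrogram` (see [upgma()]).
#' @export
average_linkage <- function(x, axis = c("genes", "samples"),
                            flavor = c("uncentered", "centered")) {
  s <- correlation_matrix(x, axis = axis, flavor = flavor)
  if (anyNA(s)) {
    stop("similarity undefined for some pair(s); cannot cluster", call. = FALSE)
  }
  upgma(1 - s)
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d leaves, heights %.4g .. %.4g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a Dendrogram to an hclust object
#'
#' @param dend A `Dendrogram`.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(dend) {
  structure(list(merge = dend$merge, height = dend$height,
                 order = dend$order, labels = dend$labels,
                 method = "average", call = match.call(),
                 dist.method = "1 - similarity"),
            class = "hclust")
}

#' Cut a dendrogram into a fixed number of clusters
#'
#' Labels are obtained by removing the `n_clusters - 1` highest merges
#' (average linkage is monotone, so this is well defined) and numbering the
#' resulting subtrees in leaf order.
#'
#' @param dend A `Dendrogram`.
#' @param n_clusters Number of clusters, between 1 and the leaf count.
#' @return Named integer vector mapping item label to cluster id.
#' @export
cut_clusters <- function(dend, n_clusters) {
  n <- length(dend$labels)
  if (n_clusters < 1 || n_clusters > n) {
    stop("`n_clusters` must be between 1 and ", n, call. = FALSE)
  }
  stats::cutree(as_hclust(dend), k = n_clusters)
}

#' Render a dendrogram as a Newick string
#'
#' @param dend A `Dendrogram`.
#' @return A single Newick-format string with branch lengths derived from
#'   the merge heights.
#' @export
dendrogram_newick <- function(dend) {
  phy <- ape::as.phylo(as_hclust(dend))
  ape::write.tree(phy)
}

#' Write Cluster 3.0-style outputs for a gene clustering
#'
#' Writes a `.cdt` file (the matrix reordered by the dendrogram, with GID
#' annotations) and a `.gtr` file (the gene tree: one line per merge with
#' the similarity 1 - height), the plain-text dialect consumed by Java
#' TreeView.
#'
#' @param x The clustered `ExpressionMatrix`.
#' @param dend The gene `Dendrogram` from [average_linkage()].
#' @param prefix Output path prefix; `<prefix>.cdt` and `<prefix>.gtr` are
#'   written.
#' @return Character vector of the two paths, invisibly.
#' @export
write_cluster_outputs <- function(x, dend, prefix) {
  v <- x$values
  stopifnot(identical(rownames(v), dend$labels))
  n <- nrow(v)
  gid <- sprintf("GENE%dX", seq_len(n))
  node_name <- function(code) if (code < 0) gid[-code] else sprintf("NODE%dX", code)
  gtr <- vapply(seq_len(n - 1L), function(i) {
    paste(sprintf("NODE%dX", i), node_name(dend$merge[i, 1]),
          node_name(dend$merge[i, 2]), sprintf("%.6f", 1 - dend$height[i]),
          sep = "\t")
  }, character(1))
  writeLines(gtr, paste0(prefix, ".gtr"))
  ord <- dend$order
  header <- paste(c("GID", "NAME", "GWEIGHT", colnames(v)), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", rep("1", ncol(v))), collapse = "\t")
  body <- vapply(ord, function(i) {
    paste(c(gid[i], rownames(v)[i], "1", fmt_num(v[i, ], missing = "")),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, eweight, body), paste0(prefix, ".cdt"))
  invisible(c(paste0(prefix, ".cdt"), paste0(prefix, ".gtr")))
}
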