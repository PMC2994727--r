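#' Configuration for a module-map run
#'
#' @param cutoff Fold-change cut-off c (> 1) for calling a gene over- or
#'   under-expressed relative to its mean: a centered log2 value is called
#'   +1 when >= log2(c) and -1 when <= -log2(c). Typical values range from
#'   1.3 to 2.0 depending on the compendium; default 1.5.
#' @param alpha Significance level on FDR-adjusted q values; default 0.05.
#' @param directions Which call directions to test: `"both"`, `"over"` or
#'   `"under"`.
#' @param min_set_overlap Minimum number of a set's genes that must be
#'   measured in the matrix for the set to be tested; default 3.
#' @param fdr_method Multiple-testing method passed to [stats::p.adjust()];
#'   default Benjamini-Hochberg (`"BH"`).
#' @return A list of class `ModuleMapConfig`.
#' @export
module_map_config <- function(cutoff = 1.5, alpha = 0.05,
                              directions = c("both", "over", "under"),
                              min_set_overlap = 3, fdr_method = "BH") {
  directions <- match.arg(directions)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 1) {
    stop("`cutoff` must be a single fold-change > 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (min_set_overlap < 1) stop("`min_set_overlap` must be >= 1", call. = FALSE)
  structure(list(cutoff = cutoff, alpha = alpha, directions = directions,
                 min_set_overlap = min_set_overlap, fdr_method = fdr_method),
            class = "ModuleMapConfig")
}

direction_vector <- function(config) {
  switch(config$directions, both = c("over", "under"),
         over = "over", under = "under")
}

#' Ternary over/under-expression calls
#'
#' On a gene-mean-centered log2 matrix, scores each entry +1
#' (over-expressed) when the value is at least log2(cutoff), -1
#' (under-expressed) when at most -log2(cutoff), and 0 otherwise. Missing
#' entries are called 0 and excluded from each sample's testing universe.
#'
#' @param x An `ExpressionMatrix` on the `log2_centered` scale.
#' @param cutoff Fold-change cut-off (> 1).
#' @return An object of class `CallMatrix`: list with the ternary `calls`
#'   matrix, the logical `measured` mask, the `cutoff` used, and
#'   `universe_size`, the per-sample count of measured genes.
#' @export
call_expression <- function(x, cutoff = 1.5) {
  if (x$scale != "log2_centered") {
    stop("call_expression expects a gene-mean-centered log2 matrix (got '",
         x$scale, "'); see normalize_compendium()", call. = FALSE)
  }
  if (cutoff <= 1) stop("`cutoff` must be > 1", call. = FALSE)
  thr <- log2(cutoff)
  v <- x$values
  measured <- !is.na(v)
  calls <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  calls[measured & v >= thr] <- 1L
  calls[measured & v <= -thr] <- -1L
  universe_size <- colSums(measured)
  storage.mode(universe_size) <- "integer"
  structure(list(calls = calls, measured = measured, cutoff = cutoff,
                 universe_size = universe_size),
            class = "CallMatrix")
}

#' @export
print.CallMatrix <- function(x, ...) {
  cat(sprintf("CallMatrix: %d genes x %d samples, cutoff %.2f-fold (+/-%.4f log2)\n",
              nrow(x$calls), ncol(x$calls), x$cutoff, log2(x$cutoff)))
  cat(sprintf("calls: %d over, %d under\n",
              sum(x$calls == 1L), sum(x$calls == -1L)))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked items in `n` draws without replacement from a universe
#' of `N` items of which `K` are marked. Vectorized over all arguments.
#'
#' @param k Observed overlap count(s).
#' @param N Universe size(s).
#' @param K Marked item count(s), `0 <= K <= N`.
#' @param n Draw count(s), `0 <= n <= N`.
#' @return Probability in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper_tail(3, 10, 3, 4)  # 1/30
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  args <- cbind(k = k, N = N, K = K, n = n)  # recycles
  k <- args[, "k"]; N <- args[, "N"]; K <- args[, "K"]; n <- args[, "n"]
  if (any(args < 0) || any(args != floor(args))) {
    stop("all arguments must be non-negative integers", call. = FALSE)
  }
  if (any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop("need K <= N, n <= N and k <= min(K, n)", call. = FALSE)
  }
  # P(X >= k) = 1 - P(X <= k - 1), evaluated by phyper's stable upper tail
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  unname(pmin(pmax(p, .Machine$double.xmin), 1))
}

#' First-level enrichment: gene sets in individual samples
#'
#' For every sample, gene set and requested direction, tests whether the
#' fraction of genes called in that direction within the set exceeds what
#' the hypergeometric distribution predicts from the sample's overall call
#' rate. The universe of each test is the set of genes measured
#' (non-missing) in that sample: N = measured genes, K = set members among
#' them, n = genes called in the direction, k = called set members.
#'
#' @param calls A [call_expression()] result.
#' @param sets A `GeneSetCollection` (or list of `GeneSet`s). Sets with
#'   fewer than `config$min_set_overlap` measured members are skipped with
#'   a warning.
#' @param config A [module_map_config()].
#' @return A data frame of class `EnrichmentTable` with columns `sample_id`,
#'   `gene_set`, `direction`, `N`, `K`, `n`, `k`, `p` (no FDR yet; see
#'   [apply_fdr()]). Tests with `n = 0` are kept with `p = 1` so result
#'   matrices stay rectangular.
#' @export
sample_enrichment <- function(calls, sets, config = module_map_config()) {
  stopifnot(inherits(calls, "CallMatrix"))
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  genes <- rownames(calls$calls)
  samples <- colnames(calls$calls)
  keep_sample <- calls$universe_size > 0
  if (!all(keep_sample)) {
    warning("sample(s) with empty universe skipped: ",
            paste(samples[!keep_sample], collapse = ", "), call. = FALSE)
  }
  measured <- calls$measured[, keep_sample, drop = FALSE]
  samples <- samples[keep_sample]
  N <- colSums(measured)
  out <- list()
  for (s in sets) {
    member <- genes %in% s$members
    if (sum(member) < config$min_set_overlap) {
      warning("gene set '", s$name, "' has fewer than ",
              config$min_set_overlap, " measured genes; skipped",
              call. = FALSE)
      next
    }
    K <- colSums(measured & member)
    for (dir in direction_vector(config)) {
      hit <- calls$calls[, keep_sample, drop = FALSE] ==
        (if (dir == "over") 1L else -1L)
      n <- colSums(hit)
      k <- colSums(hit & member)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = samples, gene_set = s$name, direction = dir,
        N = as.integer(N), K = as.integer(K), n = as.integer(n),
        k = as.integer(k), p = hypergeom_upper_tail(k, N, K, n),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no testable gene set", call. = FALSE)
  tab <- do.call(rbind, out)
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Benjamini-Hochberg FDR adjustment of an enrichment table
#'
#' Adjusts the raw hypergeometric p values with the step-up FDR procedure,
#' pooling all tests within each direction as one family, and flags
#' significance at `q < alpha`.
#'
#' @param table An enrichment table with `p` and `direction` columns.
#' @param alpha Significance level; default 0.05.
#' @param method Method passed to [stats::p.adjust()]; default `"BH"`.
#' @return The table with `q` and logical `significant` columns added.
#' @export
apply_fdr <- function(table, alpha = 0.05, method = "BH") {
  stopifnot("p" %in% names(table))
  if (!"direction" %in% names(table)) table$direction <- "over"
  table$q <- stats::ave(table$p, table$direction,
                        FUN = function(p) stats::p.adjust(p, method = method))
  table$significant <- table$q < alpha
  table
}

#' Second-level enrichment: gene sets in experiment sets
#'
#' Tests whether the samples flagged significant for a gene set (in a given
#' direction) at the first level concentrate within particular experiment
#' sets. For each (gene set, group, direction): N = samples tested, K =
#' samples significant for that set and direction overall, n = group size,
#' k = significant samples within the group, with the hypergeometric
#' upper-tail p value and BH adjustment pooled across all
#' (set x group x direction) tests. A group can be enriched for the
#' over-direction and simultaneously under-represented via the
#' under-direction, mirroring the red/green duality of module-map displays.
#'
#' @param table A first-level table that has been through [apply_fdr()].
#' @param groups An [experiment_sets()] object; every referenced sample must
#'   appear in the table.
#' @param config A [module_map_config()].
#' @return A data frame with columns `gene_set`, `experiment_set`,
#'   `direction`, `N`, `K`, `n`, `k`, `p`, `q`, `significant`.
#' @export
experiment_set_enrichment <- function(table, groups,
                                      config = module_map_config()) {
  if (!"significant" %in% names(table)) {
    stop("first-level table has no `significant` column; run apply_fdr() first",
         call. = FALSE)
  }
  check_groups_in(groups, unique(table$sample_id), context = "enrichment table")
  out <- list()
  for (set_name in unique(table$gene_set)) {
    for (dir in unique(table$direction)) {
      sub <- table[table$gene_set == set_name & table$direction == dir, ]
      N <- nrow(sub)
      sig_samples <- sub$sample_id[sub$significant]
      K <- length(sig_samples)
      for (grp in names(groups)) {
        ids <- intersect(groups[[grp]], sub$sample_id)
        n <- length(ids)
        k <- sum(ids %in% sig_samples)
        out[[length(out) + 1L]] <- data.frame(
          gene_set = set_name, experiment_set = grp, direction = dir,
          N = as.integer(N), K = as.integer(K), n = as.integer(n),
          k = as.integer(k), p = hypergeom_upper_tail(k, N, K, n),
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, out)
  tab$q <- stats::p.adjust(tab$p, method = config$fdr_method)
  tab$significant <- tab$q < config$alpha
  tab
}

#' Run the full two-level module map
#'
#' Orchestrates the pipeline: ternary expression calls on a centered
#' compendium, per-sample gene-set enrichment with FDR, and (when
#' experiment sets are given) second-level experiment-set enrichment. The
#' three rendered matrices correspond to the classic module-map display:
#' gene hits (ternary calls), per-sample gene-set hits, and the
#' per-experiment-set gene-set map, coded +1 (enriched / over), -1
#' (under-represented / under), 0 (not significant).
#'
#' @param x An `ExpressionMatrix`. Must be on the `log2_centered` scale
#'   unless `normalize` names a strategy, in which case
#'   [normalize_compendium()] is applied first.
#' @param sets A `GeneSetCollection`.
#' @param groups Optional [experiment_sets()]; required for the second
#'   level.
#' @param config A [module_map_config()].
#' @param normalize Optional normalization strategy (`"joint_center"` or
#'   `"per_study_center"`) applied when `x` is not yet centered.
#' @return An object of class `ModuleMapResult`: list with `first_level`,
#'   `second_level` (or `NULL`), `gene_hits`, `sample_set_map`,
#'   `experiment_map`, and the `config`.
#' @export
run_module_map <- function(x, sets, groups = NULL,
                           config = module_map_config(), normalize = NULL) {
  if (!is.null(normalize)) {
    x <- normalize_compendium(x, strategy = normalize)
  }
  calls <- call_expression(x, config$cutoff)
  first <- sample_enrichment(calls, sets, config)
  first <- apply_fdr(first, alpha = config$alpha, method = config$fdr_method)
  second <- NULL
  experiment_map <- NULL
  if (!is.null(groups)) {
    second <- experiment_set_enrichment(first, groups, config)
    experiment_map <- render_hit_matrix(second, "gene_set", "experiment_set")
  }
  structure(list(
    first_level = first,
    second_level = second,
    gene_hits = calls$calls,
    sample_set_map = render_hit_matrix(first, "gene_set", "sample_id"),
    experiment_map = experiment_map,
    config = config
  ), class = "ModuleMapResult")
}

# Collapse a significance table to a ternary rows x columns matrix:
# +1 significant over, -1 significant under, 0 otherwise. A (rare) row/col
# significant in both directions nets to 0.
render_hit_matrix <- function(tab, row_col, col_col) {
  rows <- unique(tab[[row_col]])
  cols <- unique(tab[[col_col]])
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  sig <- tab[tab$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    val <- ifelse(sig$direction == "over", 1L, -1L)
    for (i in seq_len(nrow(sig))) {
      m[sig[[row_col]][i], sig[[col_col]][i]] <-
        m[sig[[row_col]][i], sig[[col_col]][i]] + val[i]
    }
  }
  m
}

#' @export
print.ModuleMapResult <- function(x, ...) {
  cat("ModuleMapResult\n")
  cat(sprintf("  first level: %d tests, %d significant (q < %.3g)\n",
              nrow(x$first_level), sum(x$first_level$significant),
              x$config$alpha))
  if (!is.null(x$second_level)) {
    sig <- x$second_level[x$second_level$significant, , drop = FALSE]
    cat(sprintf("  second level: %d tests, %d significant\n",
                nrow(x$second_level), nrow(sig)))
    if (nrow(sig) > 0) {
      for (i in seq_len(nrow(sig))) {
        cat(sprintf("    %s | %s | %s (q = %.3g)\n", sig$gene_set[i],
                    sig$experiment_set[i], sig$direction[i], sig$q[i]))
      }
    }
  }
  invisible(x)
}
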