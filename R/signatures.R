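#' Derive a gene signature by the intra-sample median rule
#'
#' Given a reference sample and a universe of genes (typically a
#' function-restricted array, e.g. a stemness- or angiogenesis-related
#' panel), the signature comprises the universe genes whose expression in
#' the reference sample is higher than or equal to the median of the
#' universe genes' values in that sample. The median is taken over the
#' universe genes actually measured (non-missing) in the reference sample,
#' not over the whole genome. Ties at the median are included, so with U
#' measured universe genes the signature has at least ceiling(U / 2)
#' members, with equality when all values are distinct.
#'
#' @param x An `ExpressionMatrix` (any scale; the rule is rank-based within
#'   one sample, so the scale does not matter).
#' @param universe A `GeneSet` or character vector of gene symbols defining
#'   the restricted panel.
#' @param reference_sample Sample identifier of the reference profile.
#' @param name Name for the returned signature.
#' @return A [gene_set()] with the selected members.
#' @export
derive_signature <- function(x, universe, reference_sample, name = "signature") {
  members <- if (inherits(universe, "GeneSet")) universe$members
             else unique(toupper(as.character(universe)))
  if (!reference_sample %in% sample_ids(x)) {
    stop("reference sample '", reference_sample, "' not present in matrix",
         call. = FALSE)
  }
  measured <- intersect(members, gene_ids(x))
  vals <- x$values[measured, reference_sample]
  measured <- measured[!is.na(vals)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("no universe gene is measured in the reference sample", call. = FALSE)
  }
  med <- stats::median(vals)
  gene_set(name, measured[vals >= med],
           description = sprintf("genes >= intra-sample median in %s (U=%d)",
                                 reference_sample, length(vals)))
}

# Shared validation for the prevalence statistics.
marker_values <- function(x, gene) {
  gene <- toupper(gene)
  if (!gene %in% gene_ids(x)) {
    stop("gene '", gene, "' not present in matrix", call. = FALSE)
  }
  lin <- linear_values(x)
  list(gene = gene, lin = lin, v = lin[gene, ])
}

#' Marker prevalence against the intra-sample whole-genome median
#'
#' The percentage of samples in which the marker's value strictly exceeds
#' `k` times the median over all (non-missing) genes of that same sample.
#' Being computed within each sample, the statistic is insensitive to
#' per-sample scale factors and to between-sample normalization error; it
#' captures whether the marker is a highly expressed gene within each
#' sample's own transcriptome.
#'
#' Values are compared on the linear scale; log2 (or log2-centered) input is
#' exponentiated first, since "k times" is a fold statement. If a sample's
#' whole-genome median is 0 the sample counts as positive iff the marker's
#' value is > 0.
#'
#' @param x An `ExpressionMatrix`.
#' @param gene Marker gene symbol.
#' @param k Fold multiplier applied to the median (default 3).
#' @return Percentage in \[0, 100\]; samples where the marker is missing are
#'   excluded from the denominator.
#' @export
marker_prevalence_intra <- function(x, gene, k = 3) {
  mk <- marker_values(x, gene)
  keep <- !is.na(mk$v)
  if (!any(keep)) stop("marker is missing in every sample", call. = FALSE)
  med <- apply(mk$lin[, keep, drop = FALSE], 2, stats::median, na.rm = TRUE)
  positive <- mk$v[keep] > k * med
  100 * sum(positive) / sum(keep)
}

#' Marker prevalence against the marker's cross-sample median
#'
#' The percentage of samples whose marker value strictly exceeds `k` times
#' the median of the marker's own values across all samples of the dataset.
#' Complementary to [marker_prevalence_intra()]: it asks whether the marker
#' is high relative to its typical level in the cohort rather than relative
#' to the sample's transcriptome.
#'
#' @inheritParams marker_prevalence_intra
#' @return Percentage in \[0, 100\].
#' @export
marker_prevalence_cross <- function(x, gene, k = 3) {
  mk <- marker_values(x, gene)
  v <- mk$v[!is.na(mk$v)]
  if (length(v) == 0) stop("marker is missing in every sample", call. = FALSE)
  med <- stats::median(v)
  100 * sum(v > k * med) / length(v)
}

#' Per-group marker prevalence report
#'
#' Computes both prevalence statistics within each experiment set's samples.
#' Both thresholds (the whole-genome intra-sample median and the marker's
#' cross-sample median) are recomputed within each group, so groups are
#' compared as self-contained datasets.
#'
#' @param x An `ExpressionMatrix`.
#' @param groups An [experiment_sets()] object; every referenced sample must
#'   exist in `x`.
#' @param gene Marker gene symbol.
#' @param k Fold multiplier (default 3).
#' @return A data frame with one row per group (columns `group`, `gene`,
#'   `k`, `n_samples`, `pct_intra`, `pct_cross`), ordered by decreasing
#'   `pct_intra`.
#' @export
prevalence_report_by_group <- function(x, groups, gene, k = 3) {
  check_groups_in(groups, sample_ids(x))
  rows <- lapply(names(groups), function(nm) {
    ids <- groups[[nm]]
    if (length(ids) == 0) {
      warning("experiment set '", nm, "' is empty; skipped", call. = FALSE)
      return(NULL)
    }
    sub <- subset_samples(x, ids)
    data.frame(group = nm, gene = toupper(gene), k = k,
               n_samples = length(ids),
               pct_intra = marker_prevalence_intra(sub, gene, k),
               pct_cross = marker_prevalence_cross(sub, gene, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$pct_intra), , drop = FALSE]
}
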