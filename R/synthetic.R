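#' Specification of a synthetic multi-study compendium
#'
#' Describes a log-normal generative model on the linear intensity scale,
#' so that the log2-transform / mean-centering / fold-cutoff pipeline is
#' exercised exactly as it is applied to real compendia. Per gene g and
#' sample s,
#'
#'   value\[g, s\] = 2^( baseline_g + batch_offset(study(s))
#'                      + delta * 1\[g in planted set, s in target group\]
#'                      + eps ),   eps ~ Normal(0, sigma)
#'
#' with per-gene baselines drawn once from Normal(baseline_mean,
#' baseline_sd). A designated marker gene (whose baseline is pinned at
#' `baseline_mean` so fold statements about it are interpretable) is
#' additionally multiplied by `fold` in a stated fraction of its target
#' group's samples, emulating a high-expression stromal/mesenchymal marker.
#'
#' The defaults describe the calibration conditions used throughout the
#' package's tests: a 500-gene, two-study compendium of 30 + 30 samples
#' with a +1 log2 batch offset on the second study, a 20-sample "stroma"
#' target group (one third of each study), one 30-gene module planted at
#' +2 log2 units in that group, five size-matched decoy sets, noise sigma
#' 0.5, and a marker at 10x baseline in 40% of the stroma samples.
#'
#' @param n_genes Number of genes (marker included).
#' @param studies Data frame with columns `name`, `n_samples`,
#'   `batch_offset` (log2 units).
#' @param groups Named numeric vector of per-study sample fractions; must
#'   sum to 1. Samples are assigned to groups in contiguous blocks within
#'   each study.
#' @param planted_modules Data frame with columns `set_size`,
#'   `target_group`, `direction` ("over"/"under"), `delta` (log2 units), or
#'   `NULL` for none.
#' @param marker List with elements `gene`, `target_group`,
#'   `positive_fraction`, `fold`, or `NULL` for no marker.
#' @param sigma Noise standard deviation in log2 units.
#' @param baseline_mean,baseline_sd Parameters of the per-gene baseline
#'   distribution (log2 units).
#' @param n_decoy_sets,decoy_size Number and size of random gene sets with
#'   no planted signal, disjoint from the planted modules and the marker.
#' @param seed Mandatory integer seed; the RNG stream order (baselines,
#'   module gene draws, decoy draws, marker-positive sample draws, noise) is
#'   fixed, so outputs are bit-reproducible.
#' @return A list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_genes = 500,
                           studies = data.frame(
                             name = c("study1", "study2"),
                             n_samples = c(30L, 30L),
                             batch_offset = c(0, 1)),
                           groups = c(tumor = 2 / 3, stroma = 1 / 3),
                           planted_modules = data.frame(
                             set_size = 30L, target_group = "stroma",
                             direction = "over", delta = 2),
                           marker = list(gene = "PTGS2",
                                         target_group = "stroma",
                                         positive_fraction = 0.4, fold = 10),
                           sigma = 0.5,
                           baseline_mean = 7, baseline_sd = 1,
                           n_decoy_sets = 5, decoy_size = 30,
                           seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (abs(sum(groups) - 1) > 1e-9) {
    stop("group fractions must sum to 1", call. = FALSE)
  }
  if (any(groups < 0 | groups > 1)) {
    stop("group fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(planted_modules)) {
    if (any(planted_modules$delta < 0)) {
      stop("`delta` must be non-negative (use direction = 'under')",
           call. = FALSE)
    }
    if (any(planted_modules$set_size > n_genes)) {
      stop("planted set larger than the gene universe", call. = FALSE)
    }
    if (!all(planted_modules$target_group %in% names(groups))) {
      stop("planted module targets an unknown group", call. = FALSE)
    }
    if (!all(planted_modules$direction %in% c("over", "under"))) {
      stop("module direction must be 'over' or 'under'", call. = FALSE)
    }
  }
  if (!is.null(marker)) {
    if (marker$positive_fraction < 0 || marker$positive_fraction > 1) {
      stop("marker positive_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (marker$fold <= 0) stop("marker fold must be positive", call. = FALSE)
    if (!marker$target_group %in% names(groups)) {
      stop("marker targets an unknown group", call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, studies = studies, groups = groups,
                 planted_modules = planted_modules, marker = marker,
                 sigma = sigma, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, n_decoy_sets = n_decoy_sets,
                 decoy_size = decoy_size, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic compendium with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `matrix` (linear-scale `ExpressionMatrix`
#'   with study labels), `groups` (`ExperimentSets`), `sets`
#'   (`GeneSetCollection`: planted modules first, then decoys), and `truth`
#'   (list with `modules`, a data frame of planted (set, group, direction,
#'   delta) rows, and `marker`, the planted marker description including the
#'   positive sample ids, or `NULL`).
#' @export
generate_compendium <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  marker_gene <- NULL
  if (!is.null(spec$marker)) {
    marker_gene <- toupper(spec$marker$gene)
    genes[1] <- marker_gene
  }

  # stream 1: per-gene baselines (marker pinned at the population mean)
  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  if (!is.null(marker_gene)) baseline[1] <- spec$baseline_mean

  # deterministic sample and group layout
  samples <- character(0)
  offsets <- numeric(0)
  group_of <- character(0)
  fracs <- spec$groups
  for (i in seq_len(nrow(spec$studies))) {
    st <- spec$studies$name[i]
    ns <- spec$studies$n_samples[i]
    ids <- sprintf("%s_S%02d", st, seq_len(ns))
    bounds <- round(cumsum(c(0, fracs)) * ns)
    g <- rep(names(fracs), diff(bounds))
    samples <- c(samples, ids)
    offsets <- c(offsets, rep(spec$studies$batch_offset[i], ns))
    group_of <- c(group_of, g)
  }
  names(group_of) <- samples
  study_labels <- stats::setNames(
    rep(spec$studies$name, spec$studies$n_samples), samples)
  groups <- experiment_sets(split(samples, group_of)[names(fracs)])

  # streams 2-3: planted module and decoy gene draws (disjoint pools)
  pool <- setdiff(genes, marker_gene)
  sets <- list()
  effects <- matrix(0, spec$n_genes, length(samples),
                    dimnames = list(genes, samples))
  truth_modules <- data.frame(set = character(0), group = character(0),
                              direction = character(0), delta = numeric(0),
                              stringsAsFactors = FALSE)
  if (!is.null(spec$planted_modules) && nrow(spec$planted_modules) > 0) {
    for (i in seq_len(nrow(spec$planted_modules))) {
      row <- spec$planted_modules[i, ]
      picked <- sample(pool, row$set_size)
      pool <- setdiff(pool, picked)
      nm <- sprintf("PLANTED%d", i)
      sets[[length(sets) + 1L]] <- gene_set(nm, picked,
                                            description = "planted module")
      target <- groups[[row$target_group]]
      sgn <- if (row$direction == "over") 1 else -1
      effects[picked, target] <- effects[picked, target] + sgn * row$delta
      truth_modules <- rbind(truth_modules, data.frame(
        set = nm, group = row$target_group, direction = row$direction,
        delta = row$delta, stringsAsFactors = FALSE))
    }
  }
  if (spec$n_decoy_sets > 0) {
    for (i in seq_len(spec$n_decoy_sets)) {
      picked <- sample(pool, min(spec$decoy_size, length(pool)))
      sets[[length(sets) + 1L]] <- gene_set(sprintf("DECOY%d", i), picked,
                                            description = "random decoy set")
    }
  }

  # stream 4: marker-positive sample draw
  truth_marker <- NULL
  positives <- character(0)
  if (!is.null(spec$marker)) {
    target <- groups[[spec$marker$target_group]]
    n_pos <- round(spec$marker$positive_fraction * length(target))
    positives <- if (n_pos > 0) sample(target, n_pos) else character(0)
    truth_marker <- list(gene = marker_gene,
                         group = spec$marker$target_group,
                         fraction = spec$marker$positive_fraction,
                         fold = spec$marker$fold,
                         positive_samples = sort(positives))
  }

  # stream 5: noise
  eps <- matrix(stats::rnorm(spec$n_genes * length(samples), 0, spec$sigma),
                spec$n_genes, length(samples))
  log2_values <- baseline + matrix(rep(offsets, each = spec$n_genes),
                                   spec$n_genes) + effects + eps
  values <- 2^log2_values
  dimnames(values) <- list(genes, samples)
  if (length(positives) > 0) {
    values[marker_gene, positives] <-
      values[marker_gene, positives] * spec$marker$fold
  }
  list(matrix = expression_matrix(values, scale = "linear",
                                  study_labels = study_labels),
       groups = groups,
       sets = gene_set_collection(sets),
       truth = list(modules = truth_modules, marker = truth_marker))
}

#' Generate a null compendium (no planted signal)
#'
#' Identical to [generate_compendium()] with all module effect sizes forced
#' to 0 and the marker fold to 1; gene sets and group structure are kept so
#' the full pipeline can be exercised under the null. The truth record is
#' empty.
#'
#' @param spec A [synthetic_spec()].
#' @return As [generate_compendium()], with empty `truth`.
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  null_spec <- spec
  if (!is.null(null_spec$planted_modules)) {
    null_spec$planted_modules$delta <- 0
  }
  if (!is.null(null_spec$marker)) null_spec$marker$fold <- 1
  out <- generate_compendium(null_spec)
  out$truth <- list(modules = out$truth$modules[0, , drop = FALSE],
                    marker = NULL)
  out
}
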