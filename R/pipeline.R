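#' Configuration for an end-to-end analysis run
#'
#' Exactly one input source must be given: either file paths to an
#' expression matrix plus gene sets (with optional groups), or a
#' [synthetic_spec()] describing a simulated compendium.
#'
#' @param matrix_path,matrix_dialect Expression matrix file and its dialect
#'   (`"tsv"` or `"gct"`).
#' @param sets_path GMT file of gene sets.
#' @param groups_path Two-column TSV of sample-group assignments (optional;
#'   enables the second-level map).
#' @param simulation A [synthetic_spec()] (alternative to file inputs).
#' @param normalization Strategy passed to [normalize_compendium()];
#'   default `"per_study_center"`.
#' @param pseudocount Pseudocount for the log2 transform.
#' @param module_map A [module_map_config()].
#' @param prevalence_gene,prevalence_k Marker gene and fold multiplier for
#'   the prevalence report (skipped when `prevalence_gene` is `NULL`).
#' @param signature Optional list with `reference_sample`, `universe`
#'   (gene set name in `sets`, character vector, or `NULL` for all measured
#'   genes) and `name`; enables signature derivation from the raw matrix.
#' @param clustering List with `min_sd`, `strict`, `axis`, `flavor`
#'   controlling the SD filter and the similarity used for clustering.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in the run log (the module map itself
#'   is deterministic; the seed drives only simulation input, via the
#'   simulation spec).
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(matrix_path = NULL, matrix_dialect = "tsv",
                       sets_path = NULL, groups_path = NULL,
                       simulation = NULL,
                       normalization = "per_study_center", pseudocount = 0,
                       module_map = module_map_config(),
                       prevalence_gene = NULL, prevalence_k = 3,
                       signature = NULL,
                       clustering = list(min_sd = 0.4, strict = FALSE,
                                         axis = "genes",
                                         flavor = "uncentered"),
                       out_dir, seed = 1L) {
  has_files <- !is.null(matrix_path)
  has_sim <- !is.null(simulation)
  if (has_files == has_sim) {
    stop("give exactly one of `matrix_path` or `simulation`", call. = FALSE)
  }
  if (has_files && is.null(sets_path)) {
    stop("file input needs `sets_path` (GMT)", call. = FALSE)
  }
  if (has_sim && !inherits(simulation, "SyntheticSpec")) {
    stop("`simulation` must be a synthetic_spec()", call. = FALSE)
  }
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  structure(list(matrix_path = matrix_path, matrix_dialect = matrix_dialect,
                 sets_path = sets_path, groups_path = groups_path,
                 simulation = simulation, normalization = normalization,
                 pseudocount = pseudocount, module_map = module_map,
                 prevalence_gene = prevalence_gene,
                 prevalence_k = prevalence_k, signature = signature,
                 clustering = clustering, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

write_tsv_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "NA"
      else if (is.finite(v) && v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
      else sprintf("%.6g", v)
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_hit_matrix <- function(m, path, row_label) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the input compendium (simulate or read), normalize, run
#' the two-level module map, derive a signature (optional), compute the
#' marker prevalence report (optional), SD-filter and cluster, and write all
#' stage outputs plus a manifest of MD5 file hashes to `out_dir`. With a
#' fixed configuration (and simulation seed) the manifest is identical
#' across runs, so each stage can be re-run and diffed from the previous
#' stage's files.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest data frame (columns `file`, `md5`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character(0)
  log_lines <- c("mesomap run", sprintf("seed: %d", config$seed),
                 sprintf("normalization: %s", config$normalization),
                 sprintf("cutoff: %g", config$module_map$cutoff),
                 sprintf("alpha: %g", config$module_map$alpha))

  # stage 1: input
  if (!is.null(config$simulation)) {
    sim <- generate_compendium(config$simulation)
    raw <- sim$matrix
    sets <- sim$sets
    groups <- sim$groups
    # GCT carries no study metadata, so provenance goes to studies.tsv
    bare <- raw; bare$study_labels <- NULL
    write_expression_matrix(bare, out("matrix.gct"), dialect = "gct")
    write_tsv_table(data.frame(sample = sample_ids(raw),
                               study = unname(raw$study_labels)),
                    out("studies.tsv"))
    write_gene_sets(sets, out("sets.gmt"))
    write_sample_groups(groups, out("groups.tsv"))
    write_tsv_table(sim$truth$modules, out("truth_modules.tsv"))
    written <- c(written, "matrix.gct", "studies.tsv", "sets.gmt",
                 "groups.tsv", "truth_modules.tsv")
    log_lines <- c(log_lines, sprintf("input: simulated (spec seed %d)",
                                      config$simulation$seed))
  } else {
    raw <- read_expression_matrix(config$matrix_path,
                                  dialect = config$matrix_dialect)
    sets <- read_gene_sets(config$sets_path)
    groups <- if (!is.null(config$groups_path)) {
      read_sample_groups(config$groups_path)
    } else NULL
    log_lines <- c(log_lines, sprintf("input: %s", config$matrix_path))
  }

  # stage 2: normalization
  norm <- if (raw$scale == "log2_centered") raw else {
    normalize_compendium(raw, strategy = config$normalization,
                         pseudocount = config$pseudocount)
  }
  write_expression_matrix(norm, out("normalized.tsv"), dialect = "tsv")
  written <- c(written, "normalized.tsv")

  # stage 3: module map
  mm <- run_module_map(norm, sets, groups, config = config$module_map)
  write_hit_matrix(mm$gene_hits, out("gene_hits.tsv"), "gene")
  write_tsv_table(mm$first_level, out("sample_enrichment.tsv"))
  write_hit_matrix(mm$sample_set_map, out("sample_set_map.tsv"), "gene_set")
  written <- c(written, "gene_hits.tsv", "sample_enrichment.tsv",
               "sample_set_map.tsv")
  if (!is.null(mm$second_level)) {
    write_tsv_table(mm$second_level, out("experimentset_map.tsv"))
    write_hit_matrix(mm$experiment_map, out("experiment_hit_matrix.tsv"),
                     "gene_set")
    written <- c(written, "experimentset_map.tsv", "experiment_hit_matrix.tsv")
  }

  # stage 4: signature derivation (optional)
  if (!is.null(config$signature)) {
    sg <- config$signature
    universe <- sg$universe
    if (is.character(universe) && length(universe) == 1 &&
        universe %in% names(sets)) {
      universe <- sets[[universe]]
    }
    if (is.null(universe)) universe <- gene_ids(raw)
    sig <- derive_signature(raw, universe, sg$reference_sample,
                            name = if (is.null(sg$name)) "signature" else sg$name)
    write_gene_sets(sig, out("signature.gmt"))
    written <- c(written, "signature.gmt")
  }

  # stage 5: marker prevalence (optional)
  if (!is.null(config$prevalence_gene) && !is.null(groups)) {
    prev <- prevalence_report_by_group(raw, groups, config$prevalence_gene,
                                       k = config$prevalence_k)
    write_tsv_table(prev, out("prevalence.tsv"))
    written <- c(written, "prevalence.tsv")
  }

  # stage 6: clustering
  cl <- config$clustering
  filtered <- sd_filter(norm, cl$min_sd, strict = isTRUE(cl$strict))
  dend <- average_linkage(filtered, axis = cl$axis, flavor = cl$flavor)
  writeLines(dendrogram_newick(dend), out("dendrogram.newick"))
  write_cluster_outputs(filtered, dend, out("clustered"))
  written <- c(written, "dendrogram.newick", "clustered.cdt", "clustered.gtr")
  log_lines <- c(log_lines,
                 sprintf("clustering: %d of %d genes pass SD filter",
                         nrow(filtered$values), nrow(norm$values)))

  # manifest + log
  md5 <- tools::md5sum(file.path(config$out_dir, written))
  manifest <- data.frame(file = written, md5 = unname(md5),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(log_lines, out("run.log"))
  invisible(manifest)
}
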