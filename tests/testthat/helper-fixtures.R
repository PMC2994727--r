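# Shared fixture: a small two-study simulated compendium driven end to end
# by the pipeline (200 genes, 15 + 15 samples, one 20-gene module planted at
# +2 log2 units in the "stroma" third of each study).
fixture_config <- function(out_dir) {
  run_config(
    simulation = synthetic_spec(
      n_genes = 200,
      studies = data.frame(name = c("study1", "study2"),
                           n_samples = c(15L, 15L), batch_offset = c(0, 1)),
      planted_modules = data.frame(set_size = 20L, target_group = "stroma",
                                   direction = "over", delta = 2),
      n_decoy_sets = 3, decoy_size = 20,
      seed = 20260101),
    prevalence_gene = "PTGS2",
    signature = list(reference_sample = "study1_S01", universe = NULL,
                     name = "ref_signature"),
    clustering = list(min_sd = 0.4, strict = FALSE, axis = "genes",
                      flavor = "uncentered"),
    out_dir = out_dir, seed = 1L)
}

# One module-map run on a simulated compendium; returns the second-level
# table. Used by the calibration and power checks.
simulated_module_map <- function(spec) {
  sim <- if (is.null(spec$planted_modules) ||
             all(spec$planted_modules$delta == 0)) {
    generate_null(spec)
  } else {
    generate_compendium(spec)
  }
  norm <- normalize_compendium(sim$matrix, "per_study_center")
  run_module_map(norm, sim$sets, sim$groups)
}
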