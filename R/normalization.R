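#' Log2-transform a linear-scale matrix
#'
#' Each value v becomes log2(v + pseudocount); missing values stay missing.
#' Non-positive arguments are a hard error (rather than silently clamped) so
#' that mis-declared scales fail loudly.
#'
#' @param x An `ExpressionMatrix` on the linear scale.
#' @param pseudocount Non-negative value added before taking logs; default 0.
#' @return The matrix on the `log2` scale.
#' @export
log2_transform <- function(x, pseudocount = 0) {
  if (x$scale != "linear") {
    stop("log2_transform expects a linear-scale matrix (got '", x$scale, "')",
         call. = FALSE)
  }
  if (pseudocount < 0) stop("`pseudocount` must be non-negative", call. = FALSE)
  v <- x$values + pseudocount
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-positive value after pseudocount at gene '%s', sample '%s'",
      rownames(x$values)[bad[1, 1]], colnames(x$values)[bad[1, 2]]),
      call. = FALSE)
  }
  expression_matrix(log2(v), scale = "log2", study_labels = x$study_labels)
}

#' Center genes on their mean across samples
#'
#' Subtracts from every data point the mean of its gene across the
#' (non-missing) samples, so a value is positive or negative according to
#' whether it lies above or below the gene's mean. Idempotent: re-centering
#' an already centered matrix changes nothing.
#'
#' @param x An `ExpressionMatrix` on the `log2` (or `log2_centered`) scale.
#' @return The matrix on the `log2_centered` scale.
#' @export
center_genes <- function(x) {
  if (!x$scale %in% c("log2", "log2_centered")) {
    stop("center_genes expects log2 values (got '", x$scale, "'); ",
         "use log2_transform first", call. = FALSE)
  }
  v <- x$values
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0)) {
    stop("gene(s) with no non-missing values: ",
         paste(rownames(v)[n_obs == 0], collapse = ", "), call. = FALSE)
  }
  centered <- v - rowMeans(v, na.rm = TRUE)
  expression_matrix(centered, scale = "log2_centered",
                    study_labels = x$study_labels)
}

#' Normalize a multi-study compendium
#'
#' Three strategies, matching how heterogeneous microarray compendia are
#' prepared for module-map analysis:
#' \describe{
#'   \item{`joint_center`}{concatenate the studies, log2-transform if on the
#'     linear scale, then mean-center each gene across the whole compendium.
#'     Appropriate when all studies share one experimental design (or were
#'     summarized together), since between-study offsets survive.}
#'   \item{`per_study_center`}{log2-transform and mean-center each study
#'     separately, then concatenate. Per-gene means are zero within every
#'     study, so additive per-study batch offsets are removed exactly.}
#'   \item{`none`}{concatenate only (single inputs pass through unchanged).}
#' }
#'
#' @param studies A single `ExpressionMatrix` or a list of them.
#' @param strategy One of `"joint_center"`, `"per_study_center"`, `"none"`.
#' @param pseudocount Passed to [log2_transform()] when inputs are linear.
#' @return An `ExpressionMatrix`; centered strategies return scale
#'   `log2_centered`.
#' @export
normalize_compendium <- function(studies,
                                 strategy = c("joint_center",
                                              "per_study_center", "none"),
                                 pseudocount = 0) {
  strategy <- match.arg(strategy)
  if (inherits(studies, "ExpressionMatrix")) studies <- list(studies)
  stopifnot(all(vapply(studies, inherits, logical(1), "ExpressionMatrix")))
  maybe_log2 <- function(m) {
    if (m$scale == "linear") log2_transform(m, pseudocount) else m
  }
  join <- function(ms) {
    if (length(ms) == 1) ms[[1]] else concatenate_studies(ms, names(ms))
  }
  switch(strategy,
    none = join(studies),
    joint_center = center_genes(maybe_log2(join(studies))),
    per_study_center = {
      # a single pre-concatenated compendium is split on its study labels
      if (length(studies) == 1 && !is.null(studies[[1]]$study_labels)) {
        studies <- split_by_study(studies[[1]])
      }
      if (length(studies) == 1 && is.null(studies[[1]]$study_labels)) {
        stop("per_study_center needs multiple studies or study labels",
             call. = FALSE)
      }
      centered <- lapply(studies, function(m) center_genes(maybe_log2(m)))
      join(centered)
    }
  )
}
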