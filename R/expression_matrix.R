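#' Construct a gene-by-sample expression matrix
#'
#' The central container of the package: a dense numeric matrix with genes
#' as rows and samples as columns, a scale tag recording how the values are
#' to be interpreted, and optional per-sample study labels recording which
#' study of a multi-study compendium each sample came from.
#'
#' Gene symbols are upper-cased at construction so that lookups are
#' case-insensitive (the minimal bridge between mouse-style `Ptgs2` and
#' human-style `PTGS2` symbols). Sample identifiers are case-sensitive.
#'
#' @param values Numeric matrix with gene row names and sample column names.
#'   `NA` entries mark missing measurements.
#' @param scale One of `"linear"` (non-negative intensities), `"log2"`
#'   (log2-transformed intensities) or `"log2_centered"` (log2 values with
#'   per-gene means subtracted).
#' @param study_labels Optional named character vector mapping every sample
#'   identifier to a study name.
#' @return An object of class `ExpressionMatrix`.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("Tp53", "Myc"), c("s1", "s2", "s3")))
#' em <- expression_matrix(m)
#' gene_ids(em)  # "TP53" "MYC"
#' @export
expression_matrix <- function(values,
                              scale = c("linear", "log2", "log2_centered"),
                              study_labels = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names",
         call. = FALSE)
  }
  rownames(values) <- toupper(rownames(values))
  x <- structure(
    list(values = values, scale = scale, study_labels = study_labels),
    class = "ExpressionMatrix"
  )
  validate_expression_matrix(x)
}

validate_expression_matrix <- function(x) {
  v <- x$values
  g <- rownames(v)
  s <- colnames(v)
  if (anyDuplicated(g)) {
    dup <- unique(g[duplicated(g)])
    stop("duplicate gene identifier(s) after case-normalization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(s)) {
    dup <- unique(s[duplicated(s)])
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (x$scale == "linear" && any(v < 0, na.rm = TRUE)) {
    stop("linear-scale values must be non-negative", call. = FALSE)
  }
  if (!is.null(x$study_labels)) {
    lab <- x$study_labels
    if (is.null(names(lab)) || !all(s %in% names(lab))) {
      stop("`study_labels` must name every sample", call. = FALSE)
    }
    x$study_labels <- lab[s]
  }
  x
}

#' Gene and sample identifiers of an expression matrix
#'
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers in matrix order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$study_labels)) {
    tab <- table(x$study_labels)
    cat("studies:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  }
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat("missing entries:", n_na, "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Linear-scale view of the values; log2 and log2-centered matrices are
# exponentiated so that fold statements ("3x the median") stay meaningful.
linear_values <- function(x) {
  if (x$scale == "linear") x$values else 2^x$values
}

subset_samples <- function(x, samples) {
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing) > 0) {
    stop("sample(s) not present in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- x$values[, samples, drop = FALSE]
  expression_matrix(v, scale = x$scale,
                    study_labels = if (is.null(x$study_labels)) NULL
                                   else x$study_labels[samples])
}

#' Construct a named gene set
#'
#' Members are upper-cased and de-duplicated; an empty member list is an
#' error.
#'
#' @param name Set name.
#' @param members Character vector of gene symbols.
#' @param description Optional free-text description.
#' @return An object of class `GeneSet`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- unique(toupper(as.character(members)))
  members <- members[nzchar(members)]
  if (length(members) == 0) {
    stop("gene set '", name, "' has no members", call. = FALSE)
  }
  structure(list(name = name, description = description, members = members),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Bundle gene sets into a named collection
#'
#' @param sets List of `GeneSet` objects with unique names.
#' @return A named list of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "GeneSet")))
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nm
  structure(sets, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets\n", length(x)))
  invisible(x)
}

#' Construct named experiment sets (sample groups)
#'
#' Experiment sets are named groups of sample identifiers used as the
#' second-level unit of the module map (e.g. "Breast Stroma", "MSCs").
#' Groups may overlap; every group must be non-empty.
#'
#' @param groups Named list of character vectors of sample identifiers.
#' @return A named list of class `ExperimentSets`.
#' @export
experiment_sets <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("every experiment set must be named", call. = FALSE)
  }
  if (anyDuplicated(names(groups))) {
    stop("duplicate experiment set name(s)", call. = FALSE)
  }
  groups <- lapply(groups, function(g) unique(as.character(g)))
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    stop("empty experiment set(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  structure(groups, class = "ExperimentSets")
}

# Check that all group members exist among the given sample ids.
check_groups_in <- function(groups, samples, context = "matrix") {
  for (nm in names(groups)) {
    missing <- setdiff(groups[[nm]], samples)
    if (length(missing) > 0) {
      stop("experiment set '", nm, "' references sample(s) absent from the ",
           context, ": ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}
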