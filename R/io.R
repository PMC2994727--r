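#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect is a plain tab-separated table with one header row
#' (first column = gene identifier) optionally preceded by comment lines
#' `#SCALE<TAB>scale` and `#STUDY<TAB>lab1<TAB>lab2...` carrying the scale
#' tag and per-sample study labels. The GCT dialect is version 1.2: a
#' `#1.2` line, a dimensions line, then a table with `Name` and
#' `Description` columns; GCT carries no scale metadata, so `scale`
#' (default `"linear"`) is taken at face value.
#'
#' Missing values are written/read as empty cells or `NA` in TSV and empty
#' cells in GCT; internally both become `NA`.
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"gct"`.
#' @param scale Scale tag to assume when the file declares none.
#' @param mapping Optional two-column data frame (`from`, `to`) of gene
#'   symbol translations (e.g. an ortholog table) applied before
#'   case-normalization.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   scale = "linear", mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    read_em_tsv(path, scale = scale, mapping = mapping)
  } else {
    read_em_gct(path, scale = scale, mapping = mapping)
  }
}

read_em_tsv <- function(path, scale, mapping) {
  lines <- readLines(path)
  study_labels <- NULL
  while (length(lines) > 0 && startsWith(lines[1], "#")) {
    fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (fields[1] == "#SCALE" && length(fields) >= 2) scale <- fields[2]
    if (fields[1] == "#STUDY") study_labels <- fields[-1]
    lines <- lines[-1]
  }
  if (length(lines) < 2) stop("TSV matrix has no data rows", call. = FALSE)
  tab <- utils::read.delim(text = lines, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  genes <- tab[[1]]
  samples <- colnames(tab)[-1]
  values <- parse_numeric_cells(tab[-1], genes, samples)
  if (!is.null(study_labels)) {
    if (length(study_labels) != length(samples)) {
      stop("#STUDY line length does not match the number of samples",
           call. = FALSE)
    }
    study_labels <- stats::setNames(study_labels, samples)
  }
  rownames(values) <- apply_gene_mapping(genes, mapping)
  colnames(values) <- samples
  expression_matrix(values, scale = scale, study_labels = study_labels)
}

read_em_gct <- function(path, scale, mapping) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    stop("not a GCT v1.2 file (missing '#1.2' header): ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][1:2])
  if (any(is.na(dims))) stop("malformed GCT dimensions line", call. = FALSE)
  tab <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3) stop("GCT table must have Name, Description and at least one sample column",
                          call. = FALSE)
  genes <- tab[[1]]
  samples <- colnames(tab)[-(1:2)]
  if (nrow(tab) != dims[1] || length(samples) != dims[2]) {
    stop(sprintf(
      "GCT header declares %d genes x %d samples but the body has %d x %d",
      dims[1], dims[2], nrow(tab), length(samples)), call. = FALSE)
  }
  values <- parse_numeric_cells(tab[-(1:2)], genes, samples)
  rownames(values) <- apply_gene_mapping(genes, mapping)
  colnames(values) <- samples
  expression_matrix(values, scale = scale)
}

# Character data frame -> numeric matrix; "", "NA" -> NA, anything else
# non-numeric is a hard error with coordinates.
parse_numeric_cells <- function(df, genes, samples) {
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(samples))
  for (j in seq_along(samples)) {
    col <- trimws(df[[j]])
    miss <- col == "" | col == "NA" | is.na(col)
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !miss)
    if (length(bad) > 0) {
      stop(sprintf(
        "non-numeric value '%s' at gene '%s', sample '%s'",
        col[bad[1]], genes[bad[1]], samples[j]), call. = FALSE)
    }
    num[miss] <- NA_real_
    out[, j] <- num
  }
  out
}

apply_gene_mapping <- function(genes, mapping) {
  if (is.null(mapping)) return(genes)
  if (ncol(mapping) < 2) stop("`mapping` needs two columns (from, to)", call. = FALSE)
  from <- toupper(as.character(mapping[[1]]))
  to <- as.character(mapping[[2]])
  idx <- match(toupper(genes), from)
  genes[!is.na(idx)] <- to[idx[!is.na(idx)]]
  genes
}

fmt_num <- function(x, missing = "NA") {
  out <- vapply(x, function(v) if (is.na(v)) missing else sprintf("%.17g", v),
                character(1))
  out
}

#' Write an expression matrix to TSV or GCT
#'
#' `write_expression_matrix` followed by [read_expression_matrix()] is the
#' identity on gene identifiers, sample identifiers, values and (for TSV)
#' the scale tag and study labels. GCT v1.2 has no place for scale metadata,
#' so non-linear matrices written as GCT must be re-read with an explicit
#' `scale` argument (a warning is emitted on write).
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file.
#' @param dialect `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  v <- x$values
  if (dialect == "tsv") {
    lines <- character(0)
    if (x$scale != "linear") lines <- c(lines, paste0("#SCALE\t", x$scale))
    if (!is.null(x$study_labels)) {
      lines <- c(lines, paste(c("#STUDY", unname(x$study_labels[colnames(v)])),
                              collapse = "\t"))
    }
    lines <- c(lines, paste(c("GENE", colnames(v)), collapse = "\t"))
    body <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], fmt_num(v[i, ], missing = "NA")), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  } else {
    if (x$scale != "linear") {
      warning("GCT carries no scale metadata; re-read with scale = \"",
              x$scale, "\"", call. = FALSE)
    }
    if (!is.null(x$study_labels)) {
      warning("GCT carries no study labels; they are dropped on write",
              call. = FALSE)
    }
    lines <- c("#1.2",
               paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("Name", "Description", colnames(v)), collapse = "\t"))
    body <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], rownames(v)[i], fmt_num(v[i, ], missing = "")),
            collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one member per tab-separated
#' field. Members are case-normalized; duplicate members within a line are
#' collapsed; duplicate set names across lines are an error.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)], description = fields[2])
  }
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param sets A `GeneSetCollection` or list of `GeneSet` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample-group assignments
#'
#' The two-column TSV dialect has a header row (`sample`, `group`) and one
#' row per (sample, group) assignment; a sample may appear under several
#' groups. The CLS dialect is the three-line categorical format whose third
#' line assigns a class to each sample by column order, so the companion
#' matrix's sample identifiers are required; CLS groups cannot overlap.
#'
#' @param path File to read.
#' @param dialect `"two_column_tsv"` or `"cls"`.
#' @param sample_ids Sample identifiers of the companion matrix, in column
#'   order (required for CLS).
#' @return An [experiment_sets()] object.
#' @export
read_sample_groups <- function(path, dialect = c("two_column_tsv", "cls"),
                               sample_ids = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "two_column_tsv") {
    tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
    if (ncol(tab) < 2) stop("group table needs two columns", call. = FALSE)
    key <- paste(tab[[1]], tab[[2]], sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (sample, group) row(s) in group table", call. = FALSE)
    }
    experiment_sets(split(tab[[1]], tab[[2]]))
  } else {
    if (is.null(sample_ids)) {
      stop("CLS dialect needs the companion matrix sample_ids", call. = FALSE)
    }
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3) stop("CLS file needs three lines", call. = FALSE)
    counts <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    n <- counts[1]
    if (is.na(n) || n != length(sample_ids)) {
      stop(sprintf("CLS declares %s samples but the matrix has %d",
                   lines[1], length(sample_ids)), call. = FALSE)
    }
    class_names <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
    labels <- strsplit(trimws(lines[3]), "\\s+")[[1]]
    if (length(labels) != n) {
      stop("CLS label line length does not match the declared sample count",
           call. = FALSE)
    }
    # labels are either 0-based class indices or the class names themselves
    if (all(grepl("^[0-9]+$", labels))) {
      idx <- as.integer(labels) + 1L
      if (any(idx < 1L | idx > length(class_names))) {
        stop("CLS label index out of range", call. = FALSE)
      }
      assigned <- class_names[idx]
    } else {
      if (!all(labels %in% class_names)) {
        stop("CLS label not among declared class names", call. = FALSE)
      }
      assigned <- labels
    }
    if (!all(class_names %in% assigned)) {
      stop("CLS class with zero members: ",
           paste(setdiff(class_names, assigned), collapse = ", "),
           call. = FALSE)
    }
    experiment_sets(split(sample_ids, factor(assigned, levels = class_names)))
  }
}

#' Write sample-group assignments as a two-column TSV
#'
#' @param groups An `ExperimentSets` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sample_groups <- function(groups, path) {
  rows <- unlist(lapply(names(groups), function(nm) {
    paste(groups[[nm]], nm, sep = "\t")
  }))
  writeLines(c("sample\tgroup", rows), path)
  invisible(path)
}

#' Concatenate per-study matrices into one compendium
#'
#' Genes are restricted to the intersection of all input gene lists, kept in
#' the first matrix's order; samples are concatenated and must be globally
#' unique; study provenance is recorded in `study_labels`.
#'
#' @param matrices List of at least two `ExpressionMatrix` objects on the
#'   same scale.
#' @param study_names Optional study names (defaults to the list names, or
#'   `study1`, `study2`, ...); ignored for matrices that already carry
#'   study labels.
#' @return A single `ExpressionMatrix`.
#' @export
concatenate_studies <- function(matrices, study_names = NULL) {
  if (length(matrices) < 2) {
    stop("need at least two matrices to concatenate", call. = FALSE)
  }
  scales <- vapply(matrices, `[[`, character(1), "scale")
  if (length(unique(scales)) > 1) {
    stop("matrices are on mixed scales: ",
         paste(unique(scales), collapse = ", "), call. = FALSE)
  }
  if (is.null(study_names)) study_names <- names(matrices)
  if (is.null(study_names)) {
    study_names <- paste0("study", seq_along(matrices))
  }
  all_samples <- unlist(lapply(matrices, sample_ids))
  if (anyDuplicated(all_samples)) {
    stop("sample identifier(s) clash across studies: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  }
  common <- gene_ids(matrices[[1]])
  for (m in matrices[-1]) common <- common[common %in% gene_ids(m)]
  if (length(common) == 0) {
    stop("the studies share no genes; nothing to concatenate", call. = FALSE)
  }
  values <- do.call(cbind, lapply(matrices, function(m) {
    m$values[common, , drop = FALSE]
  }))
  labels <- unlist(lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (!is.null(m$study_labels)) {
      m$study_labels[sample_ids(m)]
    } else {
      stats::setNames(rep(study_names[i], ncol(m$values)), sample_ids(m))
    }
  }))
  expression_matrix(values, scale = scales[1], study_labels = labels)
}

#' Split a compendium back into per-study matrices
#'
#' @param x An `ExpressionMatrix` with study labels.
#' @return Named list of `ExpressionMatrix` objects, one per study, in
#'   order of first appearance.
#' @export
split_by_study <- function(x) {
  if (is.null(x$study_labels)) {
    stop("matrix carries no study labels", call. = FALSE)
  }
  studies <- unique(unname(x$study_labels[sample_ids(x)]))
  out <- lapply(studies, function(st) {
    keep <- sample_ids(x)[x$study_labels[sample_ids(x)] == st]
    subset_samples(x, keep)
  })
  stats::setNames(out, studies)
}
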