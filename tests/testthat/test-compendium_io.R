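test_that("expression matrices round-trip through TSV and GCT", {
  v <- random_matrix(50, 20, na_frac = 0.05, seed = 101)
  em <- expression_matrix(v, scale = "linear",
                          study_labels = setNames(
                            rep(c("a", "b"), each = 10), colnames(v)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, tsv, dialect = "tsv")
  back <- read_expression_matrix(tsv, dialect = "tsv")
  expect_identical(gene_ids(back), gene_ids(em))
  expect_identical(sample_ids(back), sample_ids(em))
  expect_identical(back$values, em$values)
  expect_identical(back$scale, "linear")
  expect_identical(back$study_labels, em$study_labels)

  # log2 scale survives the TSV metadata line
  em2 <- log2_transform(em)
  write_expression_matrix(em2, tsv, dialect = "tsv")
  expect_identical(read_expression_matrix(tsv)$scale, "log2")

  gct <- withr::local_tempfile(fileext = ".gct")
  em_plain <- expression_matrix(v, scale = "linear")
  write_expression_matrix(em_plain, gct, dialect = "gct")
  back <- read_expression_matrix(gct, dialect = "gct")
  expect_identical(back$values, em_plain$values)
  expect_identical(back$scale, "linear")
})

test_that("GCT header dimensions and cell contents are validated", {
  gct <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t2", "Name\tDescription\ts1\ts2",
               "A\tA\t1\t2", "B\tB\t3\t4"), gct)
  expect_error(read_expression_matrix(gct, "gct"), "declares 3 genes")

  writeLines(c("#1.2", "2\t2", "Name\tDescription\ts1\ts2",
               "A\tA\t1\toops", "B\tB\t3\t4"), gct)
  expect_error(read_expression_matrix(gct, "gct"), "oops.*gene 'A'.*'s2'")

  # empty cells are the missing marker
  writeLines(c("#1.2", "2\t2", "Name\tDescription\ts1\ts2",
               "A\tA\t1\t", "B\tB\t3\t4"), gct)
  em <- read_expression_matrix(gct, "gct")
  expect_true(is.na(em$values["A", "s2"]))
})

test_that("duplicate gene ids are case-insensitive errors naming the offender", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GENE\ts1\ts2", "Cox2\t1\t2", "COX2\t3\t4"), tsv)
  expect_error(read_expression_matrix(tsv), "COX2")
})

test_that("gene symbol mapping hook is applied before case-folding", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GENE\ts1\ts2", "Ptgs2\t1\t2", "Actb\t3\t4"), tsv)
  em <- read_expression_matrix(
    tsv, mapping = data.frame(from = "ACTB", to = "ACTB_HUMAN"))
  expect_setequal(gene_ids(em), c("PTGS2", "ACTB_HUMAN"))
})

test_that("GMT parsing normalizes members and rejects malformed input", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tTp53\tMYC\ttp53", "SET2\tdesc\tA\tB\tC"), gmt)
  sets <- read_gene_sets(gmt)
  expect_length(sets, 2)
  expect_setequal(sets$SET1$members, c("TP53", "MYC"))  # duplicate collapsed

  writeLines(c("SET1\tdesc\tA", "SET1\tdesc\tB"), gmt)
  expect_error(read_gene_sets(gmt), "duplicate")

  writeLines("SETX\tdesc_only", gmt)
  expect_error(read_gene_sets(gmt), "line 1")

  # round trip
  writeLines(c("SET1\tdesc\tTP53\tMYC", "SET2\tna\tA\tB\tC"), gmt)
  sets <- read_gene_sets(gmt)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, out)
  back <- read_gene_sets(out)
  expect_identical(lapply(back, `[[`, "members"),
                   lapply(sets, `[[`, "members"))
})

test_that("the packaged example universe panels load as gene sets", {
  gmt <- system.file("extdata", "synthetic_universes.gmt", package = "mesomap")
  panels <- read_gene_sets(gmt)
  expect_length(panels, 3)
  expect_true(all(grepl("_SYNTHETIC$", names(panels))))
  expect_true("PTGS2" %in% panels$SIGNAL_TRANSDUCTION_PANEL_SYNTHETIC$members)
  # usable as a signature universe on a matching simulated matrix
  sim <- generate_compendium(synthetic_spec(n_genes = 50, seed = 2,
                                            planted_modules = NULL))
  expect_error(derive_signature(sim$matrix,
                                panels$STEMNESS_PANEL_SYNTHETIC,
                                sample_ids(sim$matrix)[1]),
               "no universe gene")
})

test_that("sample groups parse from two-column TSV and CLS", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup", paste0("s", 1:10, "\t",
                                       rep(paste0("g", 1:5), 2))), tsv)
  groups <- read_sample_groups(tsv)
  expect_length(groups, 5)
  expect_setequal(unlist(groups), paste0("s", 1:10))

  cls <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# tumor stroma", "0 0 1 1"), cls)
  g <- read_sample_groups(cls, "cls", sample_ids = paste0("s", 1:4))
  expect_identical(g$tumor, c("s1", "s2"))
  expect_identical(g$stroma, c("s3", "s4"))

  expect_error(read_sample_groups(cls, "cls", sample_ids = paste0("s", 1:6)),
               "declares")
  writeLines(c("4 2 1", "# tumor stroma", "0 0 0 0"), cls)
  expect_error(read_sample_groups(cls, "cls", sample_ids = paste0("s", 1:4)),
               "zero members")
})

test_that("concatenation intersects genes in first-study order and checks ids", {
  m1 <- expression_matrix(matrix(1:6, 3, 2,
         dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  m2 <- expression_matrix(matrix(1:9, 3, 3,
         dimnames = list(c("B", "C", "D"), c("s3", "s4", "s5"))))
  cc <- concatenate_studies(list(x = m1, y = m2))
  expect_identical(gene_ids(cc), c("B", "C"))
  expect_identical(ncol(cc$values), 5L)
  expect_identical(unname(cc$study_labels),
                   c("x", "x", "y", "y", "y"))
  # brute-force intersection agrees
  expect_setequal(gene_ids(cc), intersect(gene_ids(m1), gene_ids(m2)))

  m3 <- expression_matrix(matrix(1:4, 2, 2,
         dimnames = list(c("X", "Y"), c("s6", "s7"))))
  expect_error(concatenate_studies(list(m1, m3)), "share no genes")

  m4 <- expression_matrix(matrix(1:4, 2, 2,
         dimnames = list(c("A", "B"), c("s1", "s9"))))
  expect_error(concatenate_studies(list(m1, m4)), "clash")

  m5 <- log2_transform(m4)
  expect_error(concatenate_studies(list(m1, m5)), "mixed scales")
})
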