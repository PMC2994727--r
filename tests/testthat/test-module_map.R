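centered <- function(v) expression_matrix(v, scale = "log2_centered")

test_that("ternary calls apply the fold cut-off on centered log2 values", {
  v <- matrix(c(1.2, -0.5, 0.3, -1.7, 0, 1.0), 2, 3,
              dimnames = list(c("A", "B"), paste0("s", 1:3)))
  cm <- call_expression(centered(v), cutoff = 2)
  expect_identical(cm$calls["A", "s1"], 1L)   # 1.2 >= 1
  expect_identical(cm$calls["B", "s1"], 0L)   # |-0.5| < 1
  expect_identical(cm$calls["B", "s2"], -1L)  # -1.7 <= -1
  expect_identical(cm$calls["B", "s3"], 1L)   # 1.0 >= 1, boundary inclusive

  # cutoff 1.3: threshold log2(1.3) ~ 0.3785
  cm2 <- call_expression(centered(v), cutoff = 1.3)
  expect_identical(cm2$calls["B", "s1"], -1L)  # |-0.5| >= 0.3785
  expect_identical(cm2$calls["A", "s2"], 0L)   # 0.3 < 0.3785

  # missing values are called 0 and shrink the sample universe
  vna <- v; vna["A", "s2"] <- NA
  cmna <- call_expression(centered(vna), 1.5)
  expect_identical(cmna$calls["A", "s2"], 0L)
  expect_identical(unname(cmna$universe_size), c(2L, 1L, 2L))

  expect_error(call_expression(expression_matrix(2^v), 1.5), "centered")
})

test_that("hypergeometric upper tail matches enumeration on worked cases", {
  expect_equal(hypergeom_upper_tail(3, 10, 3, 4), 1 / 30)
  expect_equal(hypergeom_upper_tail(3, 10, 3, 4), enum_hyper_tail(3, 10, 3, 4))
  expect_equal(hypergeom_upper_tail(4, 20, 8, 5), 896 / 15504)
  expect_equal(hypergeom_upper_tail(0, 50, 10, 5), 1)
  expect_equal(hypergeom_upper_tail(4, 12, 4, 4), 1 / choose(12, 4))
  expect_error(hypergeom_upper_tail(5, 10, 4, 5), "min")
  expect_error(hypergeom_upper_tail(1, 10, 11, 5), "K <= N")
  # tail is non-increasing in k at fixed N, K, n
  p <- hypergeom_upper_tail(0:5, 40, 10, 12)
  expect_true(all(diff(p) <= 0))
})

test_that("per-sample enrichment assembles the right hypergeometric records", {
  # 12-gene universe; sample s1 over-expresses exactly the 4 set genes
  v <- matrix(0, 12, 2, dimnames = list(sprintf("G%02d", 1:12), c("s1", "s2")))
  v[1:4, "s1"] <- 2
  v[5, "s2"] <- 2
  sets <- gene_set_collection(list(gene_set("SIG", sprintf("G%02d", 1:4))))
  cm <- call_expression(centered(v), 1.5)
  tab <- sample_enrichment(cm, sets, module_map_config(directions = "over"))
  r1 <- tab[tab$sample_id == "s1", ]
  expect_identical(unname(unlist(r1[c("N", "K", "n", "k")])), c(12L, 4L, 4L, 4L))
  expect_equal(r1$p, 1 / choose(12, 4))
  # disjoint called genes: k = 0, p = 1
  r2 <- tab[tab$sample_id == "s2", ]
  expect_identical(r2$k, 0L)
  expect_equal(r2$p, 1)

  # under-direction mirrors over on the negated matrix
  both <- sample_enrichment(call_expression(centered(v), 1.5), sets,
                            module_map_config())
  neg <- sample_enrichment(call_expression(centered(-v), 1.5), sets,
                           module_map_config())
  over <- both[both$direction == "over", c("N", "K", "n", "k", "p")]
  under_neg <- neg[neg$direction == "under", c("N", "K", "n", "k", "p")]
  expect_equal(over, under_neg, ignore_attr = TRUE)

  # undersized sets are skipped with a warning
  tiny <- gene_set_collection(list(gene_set("TINY", c("G01", "NOPE_A", "NOPE_B")),
                                   gene_set("SIG", sprintf("G%02d", 1:4))))
  expect_warning(tab2 <- sample_enrichment(cm, tiny, module_map_config()),
                 "TINY")
  expect_false("TINY" %in% tab2$gene_set)
})

test_that("BH adjustment matches the literal step-up on worked and random input", {
  tab <- data.frame(p = c(0.005, 0.04, 0.03), direction = "over")
  adj <- apply_fdr(tab, alpha = 0.05)
  expect_equal(adj$q, c(0.015, 0.04, 0.04))
  expect_identical(adj$significant, c(TRUE, TRUE, TRUE))

  expect_equal(apply_fdr(data.frame(p = 0.02, direction = "over"))$q, 0.02)
  all1 <- apply_fdr(data.frame(p = rep(1, 6), direction = "over"))
  expect_true(all(all1$q == 1) && !any(all1$significant))

  set.seed(99)
  for (i in 1:25) {
    n <- sample(1:500, 1)
    p <- runif(n)^sample(1:3, 1)
    got <- apply_fdr(data.frame(p = p, direction = "over"))$q
    expect_equal(got, bh_stepup(p))
  }

  # directions are separate families
  tab2 <- data.frame(p = c(0.01, 0.2, 0.01, 0.2),
                     direction = c("over", "over", "under", "under"))
  adj2 <- apply_fdr(tab2)
  expect_equal(adj2$q, c(0.02, 0.2, 0.02, 0.2))
})

test_that("second-level counts derive exactly from first-level flags", {
  sim <- generate_compendium(synthetic_spec(seed = 23))
  norm <- normalize_compendium(sim$matrix, "per_study_center")
  mm <- run_module_map(norm, sim$sets, sim$groups)
  second <- mm$second_level
  first <- mm$first_level
  for (i in sample(nrow(second), 10)) {
    row <- second[i, ]
    sub <- first[first$gene_set == row$gene_set &
                 first$direction == row$direction, ]
    expect_identical(row$N, nrow(sub))
    expect_identical(row$K, sum(sub$significant))
    ids <- sim$groups[[row$experiment_set]]
    expect_identical(row$n, length(ids))
    expect_identical(row$k, sum(sub$significant & sub$sample_id %in% ids))
    expect_equal(row$p, hypergeom_upper_tail(row$k, row$N, row$K, row$n))
  }
  # q >= p and significance flag consistency
  expect_true(all(second$q >= second$p - 1e-12))
  expect_identical(second$significant, second$q < 0.05)

  # a group covering every sample is a degenerate full draw: k = K
  all_g <- experiment_sets(list(everything = sample_ids(norm)))
  sec2 <- experiment_set_enrichment(first, all_g, module_map_config())
  expect_identical(sec2$k, sec2$K)
  expect_true(all(sec2$p[sec2$K == 0] == 1))

  bad <- experiment_sets(list(ghost = c(sample_ids(norm)[1], "phantom")))
  expect_error(experiment_set_enrichment(first, bad, module_map_config()),
               "phantom")
})

test_that("module map is invariant to sample permutation and finds planted truth", {
  sim <- generate_compendium(synthetic_spec(seed = 31))
  norm <- normalize_compendium(sim$matrix, "per_study_center")
  mm <- run_module_map(norm, sim$sets, sim$groups)
  hits <- mm$second_level[mm$second_level$significant &
                          mm$second_level$direction == "over", ]
  expect_identical(hits$gene_set, "PLANTED1")
  expect_identical(hits$experiment_set, "stroma")

  # permute samples: identical tables up to row order
  perm <- sample(ncol(norm$values))
  normp <- expression_matrix(norm$values[, perm], scale = "log2_centered",
                             study_labels = norm$study_labels)
  mmp <- run_module_map(normp, sim$sets, sim$groups)
  a <- mm$first_level[order(mm$first_level$sample_id, mm$first_level$gene_set,
                            mm$first_level$direction), ]
  b <- mmp$first_level[order(mmp$first_level$sample_id, mmp$first_level$gene_set,
                             mmp$first_level$direction), ]
  expect_equal(a, b, ignore_attr = TRUE)
})
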