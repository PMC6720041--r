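test_that("subsampled set sizes follow max(1, round-half-up((1 - removal) * n))", {
  withr::local_seed(91)
  genes <- sprintf("g%03d", 1:200)
  db <- gene_set_db(list(a = genes[1:10], b = genes[11:17], c = genes[18:18],
                         d = genes[19:60]))
  for (removal in c(seq(0.1, 0.9, by = 0.1), 0.99)) {
    sub <- subsample_gene_sets(db, removal)
    for (m in names(db)) {
      n <- length(db[[m]])
      expect_equal(length(sub[[m]]), max(1, floor((1 - removal) * n + 0.5)))
      expect_true(all(sub[[m]] %in% db[[m]]))
      # original order preserved
      expect_equal(sub[[m]], db[[m]][sort(match(sub[[m]], db[[m]]))])
    }
  }
  # worked sizes: 10-gene set at 0.9 -> 1; 7-gene set at 0.5 -> 4
  expect_equal(length(subsample_gene_sets(db, 0.9)$a), 1L)
  expect_equal(length(subsample_gene_sets(db, 0.5)$b), 4L)
  expect_equal(unclass(subsample_gene_sets(db, 0)), unclass(db),
               ignore_attr = TRUE)
})

test_that("profile subsampling masks top genes with the column minimum, shape intact", {
  withr::local_seed(92)
  sig <- matrix(runif(80, 1, 10), 40, 2,
                dimnames = list(sprintf("g%02d", 1:40), c("T1", "T2")))
  for (frac in c(0.3, 1.0)) {
    sub <- subsample_profile(sig, frac)
    expect_equal(dim(sub), dim(sig))
    expect_equal(dimnames(sub), dimnames(sig))
    tops <- top_fraction_genes(sig, 0.05)
    for (j in 1:2) {
      top <- tops[[j]]
      changed <- rownames(sig)[sub[, j] != sig[, j]]
      expect_true(all(changed %in% top))
      expect_equal(length(changed), ceiling(frac * length(top)))
      expect_true(all(sub[changed, j] == min(sig[, j])))
      untouched <- setdiff(rownames(sig), top)
      expect_equal(sub[untouched, j], sig[untouched, j])
    }
  }
  # full replacement: every top-fraction entry equals the column minimum
  full <- subsample_profile(sig, 1.0)
  tops <- top_fraction_genes(sig, 0.05)
  for (j in 1:2) {
    expect_true(all(full[tops[[j]], j] == min(sig[, j])))
  }
})

test_that("the robustness experiment has exact cardinality and is seed-reproducible", {
  ds <- small_dataset()
  exy <- average_profiles(ds$cells, ds$assignment)
  rob <- robustness_experiment(exy, ds$gold, c("ora", "metaneighbor"),
                               gene_sets = ds$gene_sets,
                               profile_path = "binarize_sets",
                               fractions = c(0.2, 0.8), replicates = 3,
                               seed = 14)
  expect_equal(nrow(rob), 12L)  # 2 methods x 2 fractions x 3 replicates
  expect_true(all(rob$roc_auc >= 0 & rob$roc_auc <= 1))
  expect_true(all(rob$pr_auc >= 0 & rob$pr_auc <= 1))
  rob2 <- robustness_experiment(exy, ds$gold, c("ora", "metaneighbor"),
                                gene_sets = ds$gene_sets,
                                profile_path = "binarize_sets",
                                fractions = c(0.2, 0.8), replicates = 3,
                                seed = 14)
  expect_identical(tibble::as_tibble(rob), tibble::as_tibble(rob2))

  expect_error(robustness_experiment(exy, ds$gold, "cibersort",
                                     gene_sets = ds$gene_sets,
                                     profile_path = "mask",
                                     replicates = 1),
               "profile")
  expect_error(robustness_experiment(exy, ds$gold, "ora", profile = exy,
                                     replicates = 1),
               "gene-set")
})

test_that("mean ROC AUC declines from light to heavy gene removal on strong signal", {
  ds <- small_dataset()
  exy <- average_profiles(ds$cells, ds$assignment)
  rob <- robustness_experiment(exy, ds$gold, "ora",
                               gene_sets = ds$gene_sets,
                               fractions = c(0.1, 0.99), replicates = 30,
                               seed = 15)
  means <- glance(rob)
  expect_gte(means$mean_roc_auc[means$fraction == 0.1],
             means$mean_roc_auc[means$fraction == 0.99])
})
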