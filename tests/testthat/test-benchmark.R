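test_that("run_benchmark writes scores, summaries, and a manifest", {
  dir <- withr::local_tempdir()
  ds <- small_dataset()
  exy <- average_profiles(ds$cells, ds$assignment)
  res <- run_benchmark(exy = exy, gene_sets = ds$gene_sets, gold = ds$gold,
                       methods = c("ora", "gsva", "metaneighbor"),
                       gsea_nperm = 50, seed = 3, out_dir = dir)
  expect_setequal(names(res$scores), c("ora", "gsva", "metaneighbor"))
  expect_equal(nrow(res$auc_summary), 3L)
  expect_true(all(file.exists(file.path(dir,
    c("scores_ora.tsv", "scores_gsva.tsv", "scores_metaneighbor.tsv",
      "auc_summary.tsv", "top_hit_accuracy.tsv", "gold_ranks.tsv",
      "manifest.json")))))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 3L)
  expect_equal(manifest$n_clusters, 4L)
})

test_that("identical config and seed reproduce identical outputs", {
  ds <- small_dataset()
  exy <- average_profiles(ds$cells, ds$assignment)
  r1 <- run_benchmark(exy = exy, gene_sets = ds$gene_sets, gold = ds$gold,
                      methods = c("gsea", "ora"), gsea_nperm = 50, seed = 8)
  r2 <- run_benchmark(exy = exy, gene_sets = ds$gene_sets, gold = ds$gold,
                      methods = c("gsea", "ora"), gsea_nperm = 50, seed = 8)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$auc_summary, r2$auc_summary)
})

test_that("type restriction is evaluation-time by default, scoring-time on request", {
  ds <- small_dataset()
  exy <- average_profiles(ds$cells, ds$assignment)
  keep <- names(ds$gene_sets)[1:3]
  r_eval <- run_benchmark(exy = exy, gene_sets = ds$gene_sets,
                          gold = ds$gold, methods = "ora",
                          restrict = keep, seed = 1)
  # scoring still used the full signature database; the cluster whose gold
  # type is outside the restriction drops out of the evaluation vector
  expect_equal(nrow(r_eval$scores$ora), length(ds$gene_sets))
  expect_equal(r_eval$auc_summary$n_pairs, 3L * 3L)
  r_score <- run_benchmark(exy = exy, gene_sets = ds$gene_sets,
                           gold = ds$gold, methods = "ora",
                           restrict = keep, restrict_scoring = TRUE,
                           seed = 1)
  expect_equal(nrow(r_score$scores$ora), 3L)
})

test_that("tidy, glance and autoplot methods return usable objects", {
  ds <- small_dataset()
  exy <- average_profiles(ds$cells, ds$assignment)
  s <- score_clusters(exy, "ora", gene_sets = ds$gene_sets)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(s) * ncol(s))

  ls <- suppressMessages(concatenate_with_truth(s, ds$gold))
  roc <- roc_curve(ls)
  expect_s3_class(tidy(roc), "tbl_df")
  expect_equal(glance(roc)$auc, roc$auc)
  expect_s3_class(ggplot2::autoplot(roc), "ggplot")
  expect_s3_class(ggplot2::autoplot(s), "ggplot")

  rob <- robustness_experiment(exy, ds$gold, "ora",
                               gene_sets = ds$gene_sets,
                               fractions = c(0.2, 0.8), replicates = 2,
                               seed = 5)
  expect_s3_class(ggplot2::autoplot(rob), "ggplot")
})

test_that("the command-line wrapper drives a full synthetic run", {
  skip_if_not_installed("optparse")
  script <- system.file("scripts", "sctypebench.R",
                        package = "scTypeBench")
  skip_if(script == "", "wrapper script not installed")
  dir <- withr::local_tempdir()
  fixture <- file.path(dir, "fix")
  out <- file.path(dir, "out")
  rscript <- file.path(R.home("bin"), "Rscript")
  status1 <- system2(rscript, c(script, "synth", "--genes", "200",
                                "--types", "3", "--markers", "8",
                                "--cells", "10", "--seed", "2",
                                "--out", fixture),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status1, 0L)
  status2 <- system2(rscript, c(script, "profiles",
                                "--cells", file.path(fixture, "cells.tsv"),
                                "--clusters", file.path(fixture, "clusters.tsv"),
                                "--out", file.path(dir, "exy.tsv")),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 0L)
  status3 <- system2(rscript, c(script, "run",
                                "--exy", file.path(dir, "exy.tsv"),
                                "--gmt", file.path(fixture, "gene_sets.gmt"),
                                "--gold", file.path(fixture, "gold.tsv"),
                                "--methods", "ora,metaneighbor",
                                "--seed", "2", "--out", out),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status3, 0L)
  expect_true(file.exists(file.path(out, "auc_summary.tsv")))
})
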