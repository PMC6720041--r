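test_that("the running-sum enrichment score matches hand-worked examples", {
  # full hit mass at step 1
  w <- c(g1 = 5, g2 = 1, g3 = 1)
  expect_equal(gsea_enrichment_score(w, "g1"), 1.0)

  # walk 0.75, 0.25, 0.5, 0 -> extreme deviation 0.75
  w4 <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 1)
  expect_equal(gsea_enrichment_score(w4, c("g1", "g3")), 0.75)

  # reversing the ranking with the set at the bottom flips the sign
  w_rev <- rev(w4)
  es_rev <- gsea_enrichment_score(w_rev, c("g1", "g3"))
  expect_lt(es_rev, 0)

  expect_error(gsea_enrichment_score(w4, "absent"), "no gene")
})

test_that("enrichment score equals the literal walk oracle on random instances", {
  withr::local_seed(41)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    genes <- paste0("g", sample(n))
    w <- stats::setNames(round(runif(n, 0, 5), 2), genes)
    set <- sample(genes, sample(1:n, 1))
    p_exp <- sample(c(0, 1, 1.5), 1)
    expect_equal(gsea_enrichment_score(w, set, p_exp),
                 oracle_gsea_es(w, set, p_exp), tolerance = 1e-12)
  }
})

test_that("the fast positive-side statistic matches the oracle walk maximum", {
  withr::local_seed(42)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    genes <- paste0("g", seq_len(n))
    w <- stats::setNames(sort(runif(n, 0, 3), decreasing = TRUE), genes)
    k <- sample(1:(n - 1), 1)
    hit_pos <- sample(n, k)
    set <- genes[hit_pos]
    expect_equal(scTypeBench:::es_positive_at(hit_pos, w, n),
                 oracle_gsea_es_pos(w, set), tolerance = 1e-12)
  }
})

test_that("planted top-ranked markers reach the permutation floor", {
  # 8 markers at the top of a 200-gene ranking: the chance that a random
  # gene-label permutation ties the maximal enrichment score is 1/C(200, 8),
  # negligible over 1000 permutations, so p sits at the add-one floor
  withr::local_seed(44)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  vals <- c(seq(100, 93), runif(n - 8, 0, 5))
  exy <- matrix(c(vals, rep(1, n)), n, 2,
                dimnames = list(genes, c("c1", "c2")))
  db <- gene_set_db(list(planted = genes[1:8]))
  s <- gsea_scores(exy, db, nperm = 1000, seed = 99)
  expect_equal(s["planted", "c1"], -log10(1 / 1001), tolerance = 1e-10)
})

test_that("permutation p-values agree with an independent second implementation", {
  withr::local_seed(43)
  n <- 40
  genes <- sprintf("g%02d", 1:n)
  exy <- matrix(runif(n * 2, 0, 10), n, 2,
                dimnames = list(genes, c("c1", "c2")))
  set <- sample(genes, 6)
  db <- gene_set_db(list(s = set))
  nperm <- 1000
  s <- gsea_scores(exy, db, nperm = nperm, seed = 7)
  p_impl <- 10^(-s["s", "c1"])
  # independent loop: rank, observe, permute with a different RNG stream
  ord <- order(-exy[, "c1"], genes)
  w <- stats::setNames(exy[ord, "c1"], genes[ord])
  obs <- oracle_gsea_es_pos(w, set)
  null <- replicate(nperm, oracle_gsea_es_pos(w, sample(genes, length(set))))
  p_oracle <- (1 + sum(null >= obs)) / (nperm + 1)
  # binomial 99% interval around the oracle estimate
  half_width <- 2.58 * sqrt(p_oracle * (1 - p_oracle) / nperm)
  expect_lt(abs(p_impl - p_oracle), half_width + 2 / nperm)
})

test_that("gsea_scores is deterministic under a seed and flags absent sets", {
  ds <- small_dataset()
  exy <- average_profiles(ds$cells, ds$assignment)[1:100, ]
  db <- gene_set_db(list(present = rownames(exy)[1:5], gone = "not_a_gene"))
  s1 <- gsea_scores(exy, db, nperm = 50, seed = 5)
  s2 <- gsea_scores(exy, db, nperm = 50, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(is.na(s1["gone", ])))
})
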