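make_scores <- function(m, method = "test") {
  scTypeBench:::new_score_matrix(m, method)
}

test_that("concatenation yields one labeled entry per (type, cluster) pair", {
  withr::local_seed(81)
  m <- matrix(runif(10 * 20), 10, 20,
              dimnames = list(paste0("T", 1:10), paste0("c", 1:20)))
  gold <- stats::setNames(paste0("T", rep(1:10, 2)), paste0("c", 1:20))
  ls <- concatenate_with_truth(make_scores(m), gold)
  expect_equal(nrow(ls), 200L)
  expect_equal(sum(ls$truth), 20L)

  # restriction to 6 types: clusters whose gold type falls outside the
  # restricted set have no attainable positive and drop out
  expect_message(
    ls6 <- concatenate_with_truth(make_scores(m), gold,
                                  restrict = paste0("T", 1:6)),
    "outside the evaluated set")
  kept <- sum(gold %in% paste0("T", 1:6))
  expect_equal(nrow(ls6), 6L * kept)
  expect_equal(sum(ls6$truth), kept)

  # unlabeled clusters contribute nothing
  expect_message(
    ls_drop <- concatenate_with_truth(make_scores(m), gold[1:15]),
    "5 cluster")
  expect_equal(nrow(ls_drop), 150L)

  # NA scores are excluded pairwise
  m_na <- m; m_na[1, 1] <- NA
  expect_message(
    ls_na <- concatenate_with_truth(make_scores(m_na), gold),
    "missing score")
  expect_equal(nrow(ls_na), 199L)

  expect_error(concatenate_with_truth(make_scores(m), gold,
                                      restrict = "T99"), "absent")
})

test_that("ROC handles perfect, tied, and the worked 4-entry example", {
  perfect <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1),
                            truth = c(1, 1, 0, 0))
  expect_equal(roc_curve(perfect)$auc, 1)

  tied <- tibble::tibble(score = rep(0.5, 6), truth = c(1, 1, 0, 0, 0, 1))
  expect_equal(roc_curve(tied)$auc, 0.5)

  worked <- tibble::tibble(score = c(0.9, 0.8, 0.7, 0.6),
                           truth = c(1, 0, 1, 0))
  expect_equal(roc_curve(worked)$auc, 0.75)

  expect_error(roc_curve(tibble::tibble(score = 1:3, truth = c(1, 1, 1))),
               "positive")
})

test_that("ROC AUC equals the Mann-Whitney closed form on random instances", {
  withr::local_seed(82)
  for (i in 1:50) {
    n <- sample(4:200, 1)
    score <- sample(seq_len(40), n, replace = TRUE) / 40  # force ties
    truth <- rbinom(n, 1, 0.4)
    if (sum(truth) == 0 || sum(truth) == n) next
    ls <- tibble::tibble(score = score, truth = truth)
    expect_equal(roc_curve(ls)$auc, oracle_auc_mw(score, truth),
                 tolerance = 1e-12)
  }
})

test_that("PR curve uses step-wise average precision", {
  worked <- tibble::tibble(score = c(0.9, 0.8, 0.7, 0.6),
                           truth = c(1, 0, 1, 0))
  expect_equal(pr_curve(worked)$auc, (1 + 2 / 3) / 2, tolerance = 1e-12)

  perfect <- tibble::tibble(score = 4:1 / 4, truth = c(1, 1, 0, 0))
  expect_equal(pr_curve(perfect)$auc, 1)

  # constant scores: AP = prevalence
  const <- tibble::tibble(score = rep(1, 10), truth = c(rep(1, 3), rep(0, 7)))
  expect_equal(pr_curve(const)$auc, 0.3)

  withr::local_seed(83)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    score <- sample(seq_len(15), n, replace = TRUE) / 15
    truth <- rbinom(n, 1, 0.3)
    if (sum(truth) == 0 || sum(truth) == n) next
    ls <- tibble::tibble(score = score, truth = truth)
    expect_equal(pr_curve(ls)$auc, oracle_average_precision(score, truth),
                 tolerance = 1e-12)
  }
})

test_that("curve metrics are invariant under monotone score transforms", {
  withr::local_seed(84)
  score <- runif(50)
  truth <- rbinom(50, 1, 0.5)
  truth[1] <- 1; truth[2] <- 0
  ls <- tibble::tibble(score = score, truth = truth)
  ls2 <- tibble::tibble(score = exp(3 * score) + 1, truth = truth)
  expect_equal(roc_curve(ls)$auc, roc_curve(ls2)$auc, tolerance = 1e-12)
  expect_equal(pr_curve(ls)$auc, pr_curve(ls2)$auc, tolerance = 1e-12)
})

test_that("top-hit accuracy counts unique argmax matches only", {
  m <- matrix(c(5, 1, 1,   # c1 -> T1 correct
                1, 5, 1,   # c2 -> T2 correct
                5, 5, 1,   # c3 tie at top including gold: not correct
                1, 2, 5),  # c4 -> T3, gold T1: wrong
              3, 4, dimnames = list(paste0("T", 1:3), paste0("c", 1:4)))
  gold <- c(c1 = "T1", c2 = "T2", c3 = "T1", c4 = "T1")
  expect_equal(top_hit_accuracy(make_scores(m), gold), 50)
  expect_equal(top_hit_accuracy(make_scores(m[, 1:2]), gold[1:2]), 100)
  # 3 of 4 correct is 75%
  m2 <- m; m2[, "c3"] <- c(9, 0, 0)
  expect_equal(top_hit_accuracy(make_scores(m2), gold), 75)
})

test_that("gold ranks match an exhaustive per-column sort oracle", {
  withr::local_seed(85)
  m <- matrix(runif(20), 5, 4,
              dimnames = list(paste0("T", 1:5), paste0("c", 1:4)))
  gold <- stats::setNames(paste0("T", c(2, 4, 1, 5)), paste0("c", 1:4))
  ranks <- gold_rank_distribution(make_scores(m), gold)
  for (i in 1:4) {
    y <- paste0("c", i)
    expect_equal(ranks$rank[ranks$cluster == y],
                 rank(-m[, y])[[gold[[y]]]])
  }

  # perfect method: all ranks 1; inverted: all ranks = number of types
  perfect <- matrix(0.1, 5, 4, dimnames = dimnames(m))
  for (i in 1:4) perfect[gold[i], i] <- 1
  expect_true(all(gold_rank_distribution(make_scores(perfect), gold)$rank == 1))
  inverted <- -perfect
  expect_true(all(gold_rank_distribution(make_scores(inverted),
                                         gold)$rank == 5))
})

test_that("gold ranks bin by signature size", {
  m <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("T1", "T2"), c("c1", "c2")))
  db <- gene_set_db(list(T1 = paste0("g", 1:2), T2 = paste0("g", 1:15)))
  gold <- c(c1 = "T1", c2 = "T2")
  out <- gold_rank_distribution(make_scores(m), gold, db = db)
  expect_equal(as.character(out$size_bin), c("1-2", "11-20"))
  expect_equal(out$signature_size, c(2L, 15L))
})
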