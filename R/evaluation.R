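# Evaluation harness: all (cell type, cluster) prediction scores are
# concatenated into one vector, labeled against the gold standard, and
# swept over thresholds to produce ROC and precision-recall curves, plus
# the per-cluster summary metrics (percent correctly assigned, rank of the
# gold type).

#' Concatenate a score matrix with gold-standard truth labels
#'
#' Produces one row per (cell type, cluster) pair with `truth = 1` iff the
#' gold standard assigns that type to that cluster. Clusters without a gold
#' label are dropped (a message reports how many), as are NA score entries
#' flagged upstream. `restrict` implements the "expected cell types only"
#' analysis variants by keeping only the named types.
#'
#' @param scores A score matrix (cell types x clusters).
#' @param gold Named character vector, cluster -> gold cell-type label.
#' @param restrict Optional character vector of cell types to keep.
#' @return A tibble with columns `cluster`, `cell_type`, `score`, `truth`.
#' @export
concatenate_with_truth <- function(scores, gold, restrict = NULL) {
  types <- rownames(scores)
  if (!is.null(restrict)) {
    missing <- setdiff(restrict, types)
    if (length(missing) > 0) {
      stop("restricted type(s) absent from the score matrix: ",
           paste(missing, collapse = ", "))
    }
    types <- intersect(types, restrict)
  }
  labeled <- intersect(colnames(scores), names(gold))
  dropped <- setdiff(colnames(scores), labeled)
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " cluster(s) without a gold label")
  }
  # under restriction, clusters whose gold type falls outside the evaluated
  # set have no attainable positive and are excluded as unlabeled
  bad_label <- labeled[!(gold[labeled] %in% types)]
  if (length(bad_label) > 0) {
    message("dropping ", length(bad_label),
            " cluster(s) whose gold type is outside the evaluated set")
    labeled <- setdiff(labeled, bad_label)
  }
  if (length(labeled) == 0) {
    stop("no positives: no cluster has a gold label among the evaluated cell types")
  }
  out <- tibble::tibble(
    cluster = rep(labeled, each = length(types)),
    cell_type = rep(types, times = length(labeled)),
    score = as.vector(unclass_score_matrix(scores)[types, labeled,
                                                   drop = FALSE]),
    truth = as.integer(gold[.data_rep(labeled, length(types))] == rep(types, times = length(labeled)))
  )
  n_na <- sum(is.na(out$score))
  if (n_na > 0) {
    message("dropping ", n_na, " missing score entr",
            if (n_na == 1) "y" else "ies")
    out <- out[!is.na(out$score), , drop = FALSE]
  }
  if (sum(out$truth) == 0) stop("no positives after restriction")
  out
}

.data_rep <- function(x, each) rep(x, each = each)

# Threshold sweep shared by both curves: one step per distinct score,
# descending; equal scores collapse into a single threshold step.
threshold_sweep <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  if (anyNA(score) || anyNA(truth)) stop("scores and truth must not contain NA")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("curve analysis needs >= 1 positive and >= 1 negative")
  }
  ord <- order(-score)
  score <- score[ord]
  truth <- truth[ord]
  last <- !duplicated(score, fromLast = TRUE)  # last index of each tie group
  tibble::tibble(
    threshold = score[last],
    tp = cumsum(truth == 1)[last],
    fp = cumsum(truth == 0)[last],
    n_pos = n_pos,
    n_neg = n_neg
  )
}

new_curve_result <- function(points, auc, kind, n_pos, n_neg) {
  structure(list(points = points, auc = auc, kind = kind,
                 n_pos = n_pos, n_neg = n_neg),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  cat("<curve_result> ", x$kind, " AUC = ", format(x$auc, digits = 4),
      " (", x$n_pos, " positives, ", x$n_neg, " negatives, ",
      nrow(x$points), " threshold steps)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.curve_result <- function(x, ...) x$points

#' @importFrom generics glance
#' @export
glance.curve_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, auc = x$auc,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps thresholds over the distinct scores of a labeled score vector
#' (ties grouped into one step) and integrates TPR against FPR by the
#' trapezoid rule, which equals the Mann-Whitney statistic with half credit
#' for ties.
#'
#' @param ls A data frame with columns `score` and `truth` (0/1), e.g. from
#'   [concatenate_with_truth()].
#' @return A `curve_result` with points (FPR, TPR) and the AUC; use
#'   [generics::tidy()] for the points, [generics::glance()] for the AUC,
#'   and `autoplot()` to draw it.
#' @export
roc_curve <- function(ls) {
  sw <- threshold_sweep(ls$score, ls$truth)
  fpr <- c(0, sw$fp / sw$n_neg[1])
  tpr <- c(0, sw$tp / sw$n_pos[1])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  points <- tibble::tibble(threshold = c(Inf, sw$threshold),
                           x = fpr, y = tpr)
  new_curve_result(points, auc, "ROC", sw$n_pos[1], sw$n_neg[1])
}

#' Precision-recall curve and average precision
#'
#' Same grouped threshold sweep as [roc_curve()]; points are (recall,
#' precision) and the area is the step-wise average-precision sum
#' `AP = sum_k (R_k - R_{k-1}) * P_k`. Step integration (rather than the
#' nonlinear interpolation some curve libraries use) is exactly
#' reproducible by enumeration, at the cost of small numeric differences
#' from interpolating implementations.
#'
#' @param ls A data frame with columns `score` and `truth` (0/1).
#' @return A `curve_result` with points (recall, precision) and the AP.
#' @export
pr_curve <- function(ls) {
  sw <- threshold_sweep(ls$score, ls$truth)
  recall <- sw$tp / sw$n_pos[1]
  precision <- sw$tp / (sw$tp + sw$fp)
  ap <- sum(diff(c(0, recall)) * precision)
  points <- tibble::tibble(threshold = sw$threshold,
                           x = recall, y = precision)
  new_curve_result(points, ap, "PR", sw$n_pos[1], sw$n_neg[1])
}

#' Percentage of clusters whose top-scoring type is the gold type
#'
#' A cluster counts as correct only when the gold type is the unique
#' maximum of its score column; ties at the top are conservative misses.
#' NA scores are ignored when locating the maximum.
#'
#' @param scores A score matrix.
#' @param gold Named character vector, cluster -> gold label.
#' @return Percentage in \[0, 100\].
#' @export
top_hit_accuracy <- function(scores, gold) {
  labeled <- intersect(colnames(scores), names(gold))
  if (length(labeled) == 0) stop("no cluster has a gold label")
  m <- unclass_score_matrix(scores)
  correct <- vapply(labeled, function(y) {
    v <- m[, y]
    g <- gold[[y]]
    if (!(g %in% rownames(m)) || is.na(v[g])) return(FALSE)
    mx <- max(v, na.rm = TRUE)
    v[g] == mx && sum(v == mx, na.rm = TRUE) == 1L
  }, logical(1))
  100 * mean(correct)
}

#' Rank of the gold type per cluster, binned by signature size
#'
#' For each labeled cluster, ranks the gold type's score among all types
#' (1 = best; average rank on ties) and, when a gene-set database is
#' supplied, bins the result by the gene count of the gold type's
#' signature. A perfect method ranks every gold prediction 1.
#'
#' @param scores A score matrix.
#' @param gold Named character vector, cluster -> gold label.
#' @param db Optional [gene_set_db()]; supplies per-type signature sizes.
#' @param size_breaks Right-closed bin edges for signature size (defaults
#'   to 1-2, 3-5, 6-10, 11-20, 21-50, >50).
#' @return A tibble with columns `cluster`, `gold_type`, `rank`,
#'   `signature_size`, `size_bin`.
#' @export
gold_rank_distribution <- function(scores, gold, db = NULL,
                                   size_breaks = c(0, 2, 5, 10, 20, 50, Inf)) {
  labeled <- intersect(colnames(scores), names(gold))
  if (length(labeled) == 0) stop("no cluster has a gold label")
  bad <- labeled[!(gold[labeled] %in% rownames(scores))]
  if (length(bad) > 0) {
    stop("gold type(s) absent from score rows for cluster(s): ",
         paste(bad, collapse = ", "))
  }
  m <- unclass_score_matrix(scores)
  ranks <- vapply(labeled, function(y) {
    v <- m[, y]
    keep <- !is.na(v)
    r <- rank(-v[keep], ties.method = "average")
    r[[gold[[y]]]]
  }, numeric(1))
  sizes <- if (is.null(db)) {
    rep(NA_integer_, length(labeled))
  } else {
    db <- as_gene_set_db(db)
    unname(vapply(gold[labeled], function(t) {
      if (t %in% names(db)) length(db[[t]]) else NA_integer_
    }, integer(1)))
  }
  labels <- paste0(utils::head(size_breaks, -1) + 1, "-",
                   utils::tail(size_breaks, -1))
  labels[utils::tail(size_breaks, -1) == Inf] <-
    paste0(">", size_breaks[length(size_breaks) - 1])
  tibble::tibble(
    cluster = labeled,
    gold_type = unname(gold[labeled]),
    rank = unname(ranks),
    signature_size = sizes,
    size_bin = cut(sizes, breaks = size_breaks, labels = labels)
  )
}
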