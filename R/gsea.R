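# Preranked gene-set enrichment analysis, adapted to score cell clusters:
# per cluster, genes are ranked (by default by descending average
# expression within that cluster), the weighted Kolmogorov-Smirnov-like
# running sum gives an enrichment score per cell-type marker set, and a
# gene-label permutation test turns it into an empirical p-value.

#' Weighted running-sum enrichment score
#'
#' Walks down a ranked gene list; genes in the set ("hits") add
#' `|w|^p / sum(|w_hits|^p)`, genes outside it subtract `1/(N - N_hits)`.
#' The enrichment score is the maximum deviation of the walk from zero,
#' signed (the extreme of largest magnitude). When the set covers all genes
#' the miss step is defined as 0; when all hit weights are 0 the hit mass is
#' uniform `1/N_hits`.
#'
#' @param weights Named numeric vector of ranking weights, already ordered
#'   from best to worst rank; names are gene ids.
#' @param set Character vector of gene ids; must intersect `names(weights)`.
#' @param p_exp Weighting exponent (1 = weighted, 0 = classic).
#' @return The signed enrichment score, in \[-1, 1\].
#' @examples
#' w <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 1)
#' gsea_enrichment_score(w, c("g1", "g3"))  # 0.75
#' @export
gsea_enrichment_score <- function(weights, set, p_exp = 1) {
  if (length(weights) == 0 || any(!is.finite(weights))) {
    stop("`weights` must be a non-empty finite vector")
  }
  if (is.null(names(weights))) stop("`weights` must be named by gene ids")
  hits <- names(weights) %in% set
  if (!any(hits)) stop("set has no gene in the ranked list")
  walk <- running_sum(abs(weights)^p_exp, hits)
  unname(walk[which.max(abs(walk))])
}

# Full running sum of the GSEA walk; wabs_p are |w|^p in rank order.
running_sum <- function(wabs_p, hits) {
  n <- length(hits)
  n_hit <- sum(hits)
  hit_mass <- wabs_p * hits
  total <- sum(hit_mass)
  incr <- if (total > 0) hit_mass / total else hits / n_hit
  miss_step <- if (n > n_hit) 1 / (n - n_hit) else 0
  cumsum(incr - (!hits) * miss_step)
}

# Maximum positive deviation reached by the walk, evaluated only at hit
# positions (between hits the walk decreases, so the maximum over the whole
# walk is attained immediately after a hit). O(k log k) per evaluation,
# which makes the permutation null cheap for small sets.
es_positive_at <- function(hit_pos, wabs_p, n) {
  k <- length(hit_pos)
  hit_pos <- sort.int(hit_pos)
  w <- wabs_p[hit_pos]
  total <- sum(w)
  cw <- if (total > 0) cumsum(w) / total else seq_len(k) / k
  miss_step <- if (n > k) 1 / (n - k) else 0
  max(cw - (hit_pos - seq_len(k)) * miss_step)
}

#' Preranked GSEA scores for every (cell type, cluster) pair
#'
#' For each cluster the genes of the cluster-average matrix are ranked and
#' each marker set's positive-side enrichment score is computed; an
#' empirical p-value comes from `nperm` gene-label permutations with the
#' add-one estimator `p = (1 + #{null >= observed}) / (nperm + 1)`, tested
#' one-sided on the enrichment direction. Scores are `-log10(p)` with floor
#' `1/(nperm + 1)`, so the maximum attainable score is `log10(nperm + 1)`.
#' The permutation null for a given cluster depends only on set size, so it
#' is cached across sets of equal size.
#'
#' @param exy Cluster-average matrix, genes x clusters.
#' @param db A [gene_set_db()] of marker sets.
#' @param nperm Number of gene-label permutations (the reference invocation
#'   uses 1000).
#' @param p_exp Weighting exponent of the running sum (default 1).
#' @param ranking `"expression"` ranks genes by descending average
#'   expression in the cluster; `"zscore"` ranks by the gene's z-score in
#'   the cluster relative to the other clusters.
#' @param seed Integer seed making the permutations reproducible; `NULL`
#'   uses the current RNG state.
#' @return A score matrix, cell types x clusters; sets sharing no gene with
#'   the matrix give NA.
#' @export
gsea_scores <- function(exy, db, nperm = 1000, p_exp = 1,
                        ranking = c("expression", "zscore"), seed = NULL) {
  validate_expression_table(exy, allow_negative = TRUE)
  db <- as_gene_set_db(db)
  ranking <- match.arg(ranking)
  if (nperm < 1) stop("`nperm` must be >= 1")
  if (ranking == "zscore" && ncol(exy) < 2) {
    stop("z-score ranking needs >= 2 clusters")
  }
  run <- function() {
    n <- nrow(exy)
    floor_p <- 1 / (nperm + 1)
    scores <- matrix(NA_real_, length(db), ncol(exy),
                     dimnames = list(names(db), colnames(exy)))
    for (j in seq_len(ncol(exy))) {
      metric <- switch(ranking,
        expression = exy[, j],
        zscore = {
          others <- exy[, -j, drop = FALSE]
          mu <- rowMeans(others)
          sdv <- apply(others, 1, stats::sd)
          (exy[, j] - mu) / (sdv + 1e-8)
        })
      ord <- order(-metric, rownames(exy), method = "radix")
      wabs_p <- abs(metric[ord])^p_exp
      ranked_genes <- rownames(exy)[ord]
      gene_rank <- stats::setNames(seq_len(n), ranked_genes)
      null_cache <- list()
      for (i in seq_along(db)) {
        hit_pos <- unname(gene_rank[db[[i]][db[[i]] %in% ranked_genes]])
        k <- length(hit_pos)
        if (k == 0) next
        obs <- es_positive_at(hit_pos, wabs_p, n)
        key <- as.character(k)
        if (is.null(null_cache[[key]])) {
          null_cache[[key]] <- vapply(seq_len(nperm), function(b) {
            es_positive_at(sample.int(n, k), wabs_p, n)
          }, numeric(1))
        }
        p <- (1 + sum(null_cache[[key]] >= obs)) / (nperm + 1)
        scores[i, j] <- neglog10_transform(p, floor_p)
      }
    }
    new_score_matrix(scores, "gsea")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
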