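#' Over-representation analysis scores
#'
#' Scores each (cell type, cluster) pair by the one-sided Fisher exact test
#' for enrichment of the type's marker set in the cluster's expressed-gene
#' list. The gene universe is the intersection of the signature's genes
#' (the union over all sets) with the expression matrix's genes; both the
#' cluster lists and the sets are intersected with this universe before
#' the 2x2 table is formed. Scores are `-log10(p)`.
#'
#' @param gene_lists Per-cluster expressed-gene lists from
#'   [top_fraction_genes()] (the attribute `"universe"` supplies the
#'   expression matrix's gene ids).
#' @param db A [gene_set_db()] of cell-type marker sets.
#' @param p_floor Floor for the `-log10` transform (see
#'   [neglog10_transform()]).
#' @return A score matrix, cell types x clusters.
#' @export
ora_scores <- function(gene_lists, db, p_floor = .Machine$double.xmin) {
  if (!inherits(gene_lists, "cluster_gene_lists")) {
    stop("`gene_lists` must come from top_fraction_genes()")
  }
  db <- as_gene_set_db(db)
  matrix_genes <- attr(gene_lists, "universe")
  universe <- intersect(unique(unlist(db, use.names = FALSE)), matrix_genes)
  if (length(universe) == 0) {
    stop("empty universe: no signature gene is present in the expression matrix")
  }
  n_u <- length(universe)
  sets <- lapply(db, intersect, y = universe)
  lists <- lapply(gene_lists, intersect, y = universe)
  scores <- matrix(NA_real_, length(db), length(gene_lists),
                   dimnames = list(names(db), names(gene_lists)))
  for (j in seq_along(lists)) {
    lst <- lists[[j]]
    for (i in seq_along(sets)) {
      set <- sets[[i]]
      if (length(set) == 0) next  # no shared gene: flagged missing
      a <- length(intersect(lst, set))
      tab <- matrix(c(a, length(lst) - a,
                      length(set) - a, n_u - length(lst) - length(set) + a),
                    nrow = 2)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      scores[i, j] <- neglog10_transform(min(p, 1), p_floor)
    }
  }
  new_score_matrix(scores, "ora")
}
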