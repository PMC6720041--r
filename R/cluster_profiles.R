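# Cluster-average expression profiles and their thresholded gene lists.
#
# The cluster-average matrix (genes x clusters, arithmetic mean of raw
# counts over member cells) is the test-side input to every scoring method
# in the package. "Raw" means exactly that: no log transform and no
# library-size scaling, so averaging commutes with rescaling all counts.

#' Average a cell-level matrix into cluster profiles
#'
#' Column `y` of the result is the per-gene arithmetic mean of raw values
#' over the cells assigned to cluster `y`. Cells present in the matrix but
#' absent from `assign` are dropped (a message reports how many); a cluster
#' with no cells in the matrix is an error.
#'
#' @param cells Numeric matrix, genes x cells, raw counts.
#' @param assign Named character (or factor) vector mapping cell id to
#'   cluster id; names are cell ids.
#' @return Numeric matrix, genes x clusters.
#' @examples
#' m <- matrix(c(2, 4, 0, 6), 1, 4,
#'             dimnames = list("g1", paste0("c", 1:4)))
#' average_profiles(m, c(c1 = "A", c2 = "A", c3 = "B", c4 = "B"))
#' @export
average_profiles <- function(cells, assign) {
  validate_expression_table(cells)
  if (is.null(names(assign)) || anyDuplicated(names(assign))) {
    stop("`assign` must be named by unique cell ids")
  }
  assign <- stats::setNames(as.character(assign), names(assign))
  missing_cells <- setdiff(names(assign), colnames(cells))
  if (length(missing_cells) > 0) {
    stop("assigned cell(s) not present in the matrix: ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  unassigned <- setdiff(colnames(cells), names(assign))
  if (length(unassigned) > 0) {
    message("dropping ", length(unassigned), " unassigned cell(s)")
  }
  clusters <- sort(unique(assign))
  profile <- vapply(clusters, function(y) {
    members <- names(assign)[assign == y]
    rowMeans(cells[, members, drop = FALSE])
  }, numeric(nrow(cells)))
  dim(profile) <- c(nrow(cells), length(clusters))
  dimnames(profile) <- list(rownames(cells), clusters)
  profile
}

# Deterministic per-column top-k selection: value descending, then gene id
# ascending (C-locale radix order), so ties at the cutoff are reproducible.
top_k_genes <- function(values, gene_ids, k) {
  ord <- order(-values, gene_ids, method = "radix")
  gene_ids[ord[seq_len(k)]]
}

#' Per-column lists of top-expressed genes
#'
#' For each column, returns the `ceiling(fraction * n_genes)` genes with the
#' highest values. Ceiling (never rounding) guarantees a non-empty list for
#' any positive fraction. Ties at the cutoff are broken by descending value
#' then ascending gene id. This is both the expressed-gene threshold used by
#' over-representation analysis and the rule behind signature binarization.
#'
#' @param profile Numeric matrix, genes x columns (cluster profiles or a
#'   continuous signature).
#' @param fraction Fraction of genes to keep per column, in (0, 1].
#' @return Named list of character vectors, one per column, carrying the
#'   matrix's gene ids as attribute `"universe"`.
#' @export
top_fraction_genes <- function(profile, fraction = 0.05) {
  validate_expression_table(profile)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single value in (0, 1]")
  }
  k <- as.integer(ceiling(fraction * nrow(profile)))
  genes <- rownames(profile)
  zero_cols <- colnames(profile)[apply(profile, 2, function(v) all(v == 0))]
  if (length(zero_cols) > 0) {
    stop("all-zero column(s) have no expressed genes: ",
         paste(zero_cols, collapse = ", "))
  }
  lists <- lapply(seq_len(ncol(profile)), function(j) {
    top_k_genes(profile[, j], genes, k)
  })
  names(lists) <- colnames(profile)
  structure(lists, universe = genes, class = "cluster_gene_lists")
}

#' @export
print.cluster_gene_lists <- function(x, ...) {
  cat("<cluster_gene_lists> ", length(x), " columns x ",
      length(x[[1]]), " genes each (universe ",
      length(attr(x, "universe")), ")\n", sep = "")
  invisible(x)
}
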