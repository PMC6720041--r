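# Cell-type signatures come in three interchangeable forms:
#   * continuous profile: genes x types matrix of expression values
#     (LM22-shaped: e.g. 547 genes x 22 leukocyte types);
#   * binary matrix: 1 marks each type's top-expressed genes;
#   * gene sets: the named marker lists behind the ones.
# The conversions below are the bridges between the profile-based methods
# (deconvolution, neighbor voting) and the gene-set methods (ORA, GSEA,
# GSVA-style scoring).

#' Binarize a continuous profile signature
#'
#' Assigns 1 to the top `fraction` of genes by expression within each
#' cell-type column and 0 otherwise (ties at the cutoff: value descending,
#' then gene id ascending). With the default `fraction = 0.05` this is the
#' top-5-percent rule used throughout the package.
#'
#' @param sig Numeric matrix, genes x cell types.
#' @param fraction Fraction of genes marked 1 per column, in (0, 1].
#' @return Integer matrix of the same dimensions with entries in {0, 1};
#'   every column sums to `ceiling(fraction * n_genes)`.
#' @export
binarize_profile <- function(sig, fraction = 0.05) {
  validate_expression_table(sig)
  const_cols <- colnames(sig)[apply(sig, 2, function(v) length(unique(v)) == 1L)]
  if (length(const_cols) > 0) {
    stop("constant column(s) cannot be binarized: ",
         paste(const_cols, collapse = ", "))
  }
  lists <- top_fraction_genes(sig, fraction)
  b <- matrix(0L, nrow(sig), ncol(sig), dimnames = dimnames(sig))
  for (j in seq_len(ncol(sig))) b[lists[[j]], j] <- 1L
  b
}

#' Convert a binary signature matrix to gene sets
#'
#' Set `m` is the list of genes with a 1 in column `m`, ordered by their row
#' order in the matrix.
#'
#' @param b Binary matrix, genes x cell types, entries in {0, 1}, every
#'   column with at least one 1.
#' @return A [gene_set_db()].
#' @export
binary_to_gene_sets <- function(b) {
  validate_binary_signature(b)
  sets <- lapply(seq_len(ncol(b)), function(j) rownames(b)[b[, j] == 1])
  names(sets) <- colnames(b)
  gene_set_db(sets)
}

#' Convert gene sets to a binary signature matrix
#'
#' Rows are the union of all set genes (first-occurrence order across sets);
#' entry `(g, m)` is 1 iff gene `g` belongs to set `m`. Genes absent from a
#' set but present in other sets get 0; genes outside every set do not
#' appear. Inverse of [binary_to_gene_sets()] on the union support.
#'
#' @param db A [gene_set_db()] (or plain named list of character vectors).
#' @return Integer matrix, union-genes x cell types, entries in {0, 1}.
#' @export
gene_sets_to_binary <- function(db) {
  db <- as_gene_set_db(db)
  genes <- unique(unlist(db, use.names = FALSE))
  b <- matrix(0L, length(genes), length(db),
              dimnames = list(genes, names(db)))
  for (j in seq_along(db)) b[db[[j]], j] <- 1L
  b
}

validate_binary_signature <- function(b) {
  if (!is.matrix(b) || !all(b %in% c(0, 1))) {
    stop("binary signature must be a genes x types matrix of 0/1")
  }
  if (is.null(rownames(b)) || is.null(colnames(b))) {
    stop("binary signature must have gene rownames and type column names")
  }
  empty <- colnames(b)[colSums(b) == 0]
  if (length(empty) > 0) {
    stop("binary signature column(s) with no marker genes: ",
         paste(empty, collapse = ", "))
  }
  invisible(b)
}
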