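# MetaNeighbor-style scoring, modified to be directional: cell-type
# signature columns act as the "training" study and cluster-average columns
# as the "testing" study, and the usual averaging of the train->test and
# test->train AUROC matrices is removed, so votes flow only from signatures
# to clusters.

#' Build the rank-normalized voting network
#'
#' Concatenates the cluster columns and the signature columns over their
#' shared genes, computes all pairwise Spearman correlations, and replaces
#' every entry of the correlation matrix by its average-tie rank over the
#' whole flattened matrix (diagonal included), scaled into (0, 1].
#'
#' @param exy Cluster-average matrix, genes x clusters (>= 2 clusters).
#' @param sig Signature matrix, genes x cell types (>= 2 types), continuous
#'   or binary.
#' @return Symmetric affinity matrix over clusters + types with attributes
#'   `"clusters"` and `"types"` giving the column indices of each block.
#' @export
build_voting_network <- function(exy, sig) {
  if (ncol(exy) < 2) stop("need >= 2 clusters")
  if (ncol(sig) < 2) stop("need >= 2 cell types")
  shared <- intersect(rownames(exy), rownames(sig))
  if (length(shared) < 3) stop("fewer than 3 genes shared between matrix and signature")
  m <- cbind(exy[shared, , drop = FALSE], sig[shared, , drop = FALSE])
  storage.mode(m) <- "double"
  cors <- suppressWarnings(stats::cor(m, method = "spearman"))
  cors[is.na(cors)] <- 0  # constant columns correlate with nothing
  net <- matrix(rank(cors, ties.method = "average") / length(cors),
                nrow(cors), ncol(cors), dimnames = dimnames(cors))
  structure(net,
            clusters = seq_len(ncol(exy)),
            types = ncol(exy) + seq_len(ncol(sig)),
            cluster_ids = colnames(exy),
            type_ids = colnames(sig))
}

#' Directional neighbor-voting scores
#'
#' For each cell type `t`, the single training column `t` casts votes on
#' every test cluster: `v_y = A[y, t] / deg(y)`, the affinity from cluster
#' `y` to signature `t` normalized by cluster `y`'s total degree over the
#' whole network (every cluster and signature column, self included) — the
#' votes-received-over-votes-possible convention of neighbor voting. The
#' score of cluster `y` for type `t` is the one-sided AUROC of `v_y` among
#' all clusters' votes with `y` as the single positive:
#' `(rank_y - 1) / (n_clusters - 1)`, with average ranks on ties. No
#' train/test averaging is performed.
#'
#' @param exy Cluster-average matrix, genes x clusters (>= 2 clusters).
#' @param sig Signature matrix, genes x cell types.
#' @return A score matrix, cell types x clusters, entries in \[0, 1\].
#' @export
metaneighbor_scores <- function(exy, sig) {
  net <- build_voting_network(exy, sig)
  cl <- attr(net, "clusters")
  ty <- attr(net, "types")
  n_cl <- length(cl)
  if (n_cl < 2) stop("need >= 2 clusters")
  aff <- net[cl, ty, drop = FALSE]           # cluster x type affinities
  votes <- aff / rowSums(net[cl, , drop = FALSE])  # degree-normalized votes
  scores <- apply(votes, 2, function(v) {
    (rank(v, ties.method = "average") - 1) / (n_cl - 1)
  })
  dim(scores) <- c(n_cl, length(ty))
  scores <- t(scores)
  dimnames(scores) <- list(attr(net, "type_ids"), attr(net, "cluster_ids"))
  new_score_matrix(scores, "metaneighbor")
}
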