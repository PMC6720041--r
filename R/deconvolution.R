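# CIBERSORT-style scoring: each cluster-average column is treated as a
# mixture and deconvolved against the signature matrix (continuous or
# binary) by linear nu-support-vector regression; the estimated cell-type
# fractions are the prediction scores.

#' Deconvolve one mixture profile against a signature matrix
#'
#' Genes are intersected between mixture and signature; the mixture and
#' every signature column are z-scored over the shared genes; a linear
#' nu-SVR of the mixture on the signature columns is fitted for each value
#' of the nu grid and the fit with the lowest root-mean-square error
#' between mixture and reconstruction wins. Negative coefficients are
#' clipped to 0 and the result is normalized to sum to 1. If every
#' coefficient is clipped, the uniform vector is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param mixture Named numeric vector (gene -> value), e.g. one column of
#'   a cluster-average matrix.
#' @param sig Signature matrix, genes x cell types (continuous values or
#'   0/1), >= 2 cell types and >= 2 genes shared with the mixture.
#' @param nu_grid Values of nu to try, each in (0, 1).
#' @param standardize Z-score the shared-gene vectors first (default TRUE).
#' @return Named numeric vector of fractions over cell types, non-negative,
#'   summing to 1.
#' @export
svr_deconvolve <- function(mixture, sig,
                           nu_grid = c(0.25, 0.5, 0.75),
                           standardize = TRUE) {
  if (is.null(names(mixture))) stop("`mixture` must be named by gene ids")
  if (any(nu_grid <= 0 | nu_grid >= 1)) stop("nu values must lie in (0, 1)")
  if (ncol(sig) < 2) stop("signature needs >= 2 cell types")
  shared <- intersect(names(mixture), rownames(sig))
  if (length(shared) < 2) stop("fewer than 2 genes shared between mixture and signature")
  y <- mixture[shared]
  x <- sig[shared, , drop = FALSE]
  storage.mode(x) <- "double"
  if (stats::sd(y) == 0) stop("mixture is constant over the shared genes")
  if (standardize) {
    y <- (y - mean(y)) / stats::sd(y)
    x <- apply(x, 2, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    dim(x) <- c(length(shared), ncol(sig))
    dimnames(x) <- list(shared, colnames(sig))
  }
  fits <- lapply(nu_grid, function(nu) {
    e1071::svm(x = x, y = y, type = "nu-regression", kernel = "linear",
               nu = nu, scale = FALSE)
  })
  rmse <- vapply(fits, function(f) sqrt(mean((stats::predict(f, x) - y)^2)),
                 numeric(1))
  best <- fits[[which.min(rmse)]]
  w <- drop(crossprod(best$coefs, best$SV))
  w <- stats::setNames(as.numeric(w)[match(colnames(x), colnames(best$SV))],
                       colnames(x))
  w[is.na(w)] <- 0
  w[w < 0] <- 0
  if (sum(w) == 0) {
    out <- stats::setNames(rep(1 / ncol(sig), ncol(sig)), colnames(sig))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  w / sum(w)
}

#' Deconvolution scores for every (cell type, cluster) pair
#'
#' Applies [svr_deconvolve()] to each column of the cluster-average matrix;
#' `score(m, y)` is the estimated fraction of cell type `m` in cluster `y`.
#' Fractions (not p-values) are used directly as prediction scores. The
#' same entry point accepts continuous (e.g. LM22) and binarized
#' signatures, matching the "continuous" and "binary" method variants.
#'
#' @param exy Cluster-average matrix, genes x clusters.
#' @param sig Signature matrix, genes x cell types.
#' @param nu_grid,standardize Passed to [svr_deconvolve()].
#' @return A score matrix, cell types x clusters.
#' @export
cibersort_scores <- function(exy, sig, nu_grid = c(0.25, 0.5, 0.75),
                             standardize = TRUE) {
  validate_expression_table(exy, allow_negative = TRUE)
  scores <- vapply(seq_len(ncol(exy)), function(j) {
    svr_deconvolve(exy[, j], sig, nu_grid = nu_grid,
                   standardize = standardize)
  }, numeric(ncol(sig)))
  dim(scores) <- c(ncol(sig), ncol(exy))
  dimnames(scores) <- list(colnames(sig), colnames(exy))
  new_score_matrix(scores, "cibersort")
}
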