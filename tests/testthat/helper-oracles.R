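# Independent oracles used to pin the implementations. Each is a literal,
# unoptimized transcription of the defining computation and shares no code
# with the package internals.

# Upper-tail hypergeometric probability P(X >= a) by explicit enumeration
# of the overlap distribution.
oracle_hypergeom_tail <- function(a, n_list, n_set, n_universe) {
  ks <- max(0, a):min(n_list, n_set)
  sum(vapply(ks, function(k) {
    choose(n_set, k) * choose(n_universe - n_set, n_list - k) /
      choose(n_universe, n_list)
  }, numeric(1)))
}

# Literal position-by-position GSEA running sum; returns the full walk.
oracle_gsea_walk <- function(weights, set, p_exp = 1) {
  n <- length(weights)
  hits <- names(weights) %in% set
  n_hit <- sum(hits)
  denom <- sum(abs(weights[hits])^p_exp)
  miss <- if (n > n_hit) 1 / (n - n_hit) else 0
  walk <- numeric(n)
  run <- 0
  for (i in seq_len(n)) {
    run <- run + if (hits[i]) {
      if (denom > 0) abs(weights[i])^p_exp / denom else 1 / n_hit
    } else {
      -miss
    }
    walk[i] <- run
  }
  walk
}

oracle_gsea_es <- function(weights, set, p_exp = 1) {
  walk <- oracle_gsea_walk(weights, set, p_exp)
  walk[which.max(abs(walk))]
}

oracle_gsea_es_pos <- function(weights, set, p_exp = 1) {
  max(oracle_gsea_walk(weights, set, p_exp))
}

# Stage-by-stage GSVA statistic: Gaussian kernel cdf, symmetric rank
# statistic, weighted walk, difference-mode enrichment score.
oracle_gsva <- function(exy, sets, tau = 1) {
  g <- nrow(exy)
  z <- matrix(0.5, g, ncol(exy), dimnames = dimnames(exy))
  for (i in seq_len(g)) {
    e <- exy[i, ]
    h <- stats::sd(e) / 4
    if (h == 0) next
    for (y in seq_along(e)) {
      z[i, y] <- mean(stats::pnorm((e[y] - e) / h))
    }
  }
  out <- matrix(NA_real_, length(sets), ncol(exy),
                dimnames = list(names(sets), colnames(exy)))
  for (y in seq_len(ncol(exy))) {
    ord <- order(-z[, y], rownames(exy), method = "radix")
    ranked <- rownames(exy)[ord]
    r <- abs(g / 2 - seq_len(g))^tau
    for (m in seq_along(sets)) {
      hits <- ranked %in% sets[[m]]
      k <- sum(hits)
      if (k == 0) next
      denom <- sum(r[hits])
      walk <- numeric(g)
      run <- 0
      for (i in seq_len(g)) {
        run <- run + if (hits[i]) {
          if (denom > 0) r[i] / denom else 1 / k
        } else {
          -1 / (g - k)
        }
        walk[i] <- run
      }
      out[m, y] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  out
}

# Brute-force directional neighbor voting: Spearman network by hand
# (correlation of column ranks), whole-matrix rank normalization, votes,
# then the single-positive rank AUROC per type.
oracle_metaneighbor <- function(exy, sig) {
  shared <- intersect(rownames(exy), rownames(sig))
  m <- cbind(exy[shared, , drop = FALSE], sig[shared, , drop = FALSE])
  rk <- apply(m, 2, rank)
  cors <- stats::cor(rk)
  net <- matrix(rank(cors, ties.method = "average") / length(cors),
                nrow(cors), ncol(cors))
  n_cl <- ncol(exy)
  idx_cl <- seq_len(n_cl)
  idx_ty <- n_cl + seq_len(ncol(sig))
  out <- matrix(NA_real_, ncol(sig), n_cl,
                dimnames = list(colnames(sig), colnames(exy)))
  for (t in seq_len(ncol(sig))) {
    v <- numeric(n_cl)
    for (y in idx_cl) {
      v[y] <- net[y, idx_ty[t]] / sum(net[y, ])
    }
    for (y in idx_cl) {
      out[t, y] <- (rank(v, ties.method = "average")[y] - 1) / (n_cl - 1)
    }
  }
  out
}

# Mann-Whitney AUC over all positive-negative pairs, half credit on ties.
oracle_auc_mw <- function(score, truth) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Step-integrated average precision by explicit threshold enumeration.
oracle_average_precision <- function(score, truth) {
  thresholds <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(truth == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    sel <- score >= t
    precision <- sum(truth[sel] == 1) / sum(sel)
    recall <- sum(truth[sel] == 1) / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Random gene-set database over a gene vocabulary.
random_gene_set_db <- function(n_sets, genes, min_size = 1,
                               max_size = length(genes)) {
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample(min_size:max_size, 1))
  })
  names(sets) <- paste0("set", seq_len(n_sets))
  gene_set_db(sets)
}
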