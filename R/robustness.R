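# Signature-subsampling robustness: degrade the cell-type signatures at a
# grid of removal fractions, re-score, re-evaluate, and aggregate the ROC
# and PR AUC distributions over replicates. Two degradation protocols
# mirror the two signature kinds: gene-set signatures lose randomly chosen
# genes outright; continuous profile signatures keep their dimensions but
# have a random share of each type's top-expressed genes masked down to the
# column minimum.

round_half_up <- function(x) floor(x + 0.5)

#' Randomly remove genes from every set of a signature
#'
#' Each set of size `n` keeps a uniform random subset of
#' `max(1, round((1 - removal) * n))` genes (round half away from zero),
#' preserving original order; at least one gene always survives.
#'
#' @param db A [gene_set_db()].
#' @param removal Fraction of genes to remove, in \[0, 1).
#' @return A [gene_set_db()] with the same labels.
#' @export
subsample_gene_sets <- function(db, removal) {
  db <- as_gene_set_db(db)
  if (removal < 0 || removal >= 1) stop("`removal` must lie in [0, 1)")
  if (removal == 0) return(db)
  sets <- lapply(unclass(db), function(g) {
    keep <- max(1L, round_half_up((1 - removal) * length(g)))
    g[sort.int(sample.int(length(g), keep))]
  })
  gene_set_db(sets, descriptions = attr(db, "descriptions"))
}

#' Mask top-expressed genes of a continuous profile signature
#'
#' Two-stage protocol: per cell-type column, the top 5 percent
#' highest-expressed genes are identified (same rule as
#' [binarize_profile()]); then a uniform random `ceiling(fraction * k)` of
#' them are overwritten with that column's minimum value. All other entries
#' are untouched, so the output has identical dimensions to the input.
#'
#' @param sig Numeric matrix, genes x cell types.
#' @param fraction Fraction of the top genes to mask, in (0, 1].
#' @param top_fraction Fraction defining the top-expressed pool (default
#'   0.05).
#' @return A matrix of identical dimensions.
#' @export
subsample_profile <- function(sig, fraction, top_fraction = 0.05) {
  validate_expression_table(sig)
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  tops <- top_fraction_genes(sig, top_fraction)
  out <- sig
  for (j in seq_len(ncol(sig))) {
    top <- tops[[j]]
    n_mask <- ceiling(fraction * length(top))
    masked <- top[sample.int(length(top), n_mask)]
    out[masked, j] <- min(sig[, j])
  }
  out
}

#' Signature-subsampling robustness experiment
#'
#' For every removal fraction and replicate, degrades the signature
#' (gene-set path for ORA/GSEA/GSVA; profile path for
#' CIBERSORT/METANEIGHBOR), re-scores every requested method, evaluates the
#' concatenated score vector against the gold standard, and records both
#' AUCs. Replicates use independent seeded substreams, so the whole
#' experiment is reproducible from `seed`.
#'
#' @param exy Cluster-average matrix, genes x clusters.
#' @param gold Named character vector, cluster -> gold label.
#' @param methods Character vector among `"ora"`, `"gsea"`, `"gsva"`,
#'   `"cibersort"`, `"metaneighbor"`.
#' @param gene_sets A [gene_set_db()]; required by the gene-set methods.
#' @param profile Continuous (or binary) signature matrix; required by the
#'   profile methods unless `profile_path = "binarize_sets"`.
#' @param fractions Removal-fraction grid (default 0.10, ..., 0.90, 0.99;
#'   the last point approximates near-total removal while the one-gene
#'   floor keeps every set alive).
#' @param replicates Replicates per fraction (the reference protocol uses
#'   1000; scale down for interactive use).
#' @param profile_path `"mask"` degrades `profile` with
#'   [subsample_profile()]; `"binarize_sets"` instead feeds the profile
#'   methods the binary matrix of each gene-set subsample, the protocol
#'   used when the signature exists only in gene-set form.
#' @param seed Integer seed.
#' @param ora_fraction Expressed-gene fraction for the ORA threshold.
#' @param gsea_nperm Permutations for GSEA (reduce for large grids).
#' @param nu_grid nu grid for the deconvolution method.
#' @return A tibble of class `robustness_result` with columns `method`,
#'   `fraction`, `replicate`, `roc_auc`, `pr_auc`; `autoplot()` draws the
#'   violin summary.
#' @export
robustness_experiment <- function(exy, gold, methods,
                                  gene_sets = NULL, profile = NULL,
                                  fractions = c(seq(0.1, 0.9, by = 0.1), 0.99),
                                  replicates = 100,
                                  profile_path = c("mask", "binarize_sets"),
                                  seed = 1L,
                                  ora_fraction = 0.05,
                                  gsea_nperm = 100,
                                  nu_grid = c(0.25, 0.5, 0.75)) {
  methods <- match.arg(methods, c("ora", "gsea", "gsva", "cibersort",
                                  "metaneighbor"), several.ok = TRUE)
  profile_path <- match.arg(profile_path)
  set_methods <- intersect(methods, c("ora", "gsea", "gsva"))
  prof_methods <- intersect(methods, c("cibersort", "metaneighbor"))
  if (length(set_methods) > 0 && is.null(gene_sets)) {
    stop("methods ", paste(set_methods, collapse = ", "),
         " need a gene-set signature (`gene_sets`)")
  }
  if (length(prof_methods) > 0) {
    if (profile_path == "mask" && is.null(profile)) {
      stop("methods ", paste(prof_methods, collapse = ", "),
           " need a profile signature (`profile`), or profile_path = \"binarize_sets\"")
    }
    if (profile_path == "binarize_sets" && is.null(gene_sets)) {
      stop("profile_path = \"binarize_sets\" needs `gene_sets`")
    }
  }
  if (replicates < 1) stop("`replicates` must be >= 1")
  ora_lists_cache <- if ("ora" %in% methods) top_fraction_genes(exy, ora_fraction)
  grid <- expand.grid(replicate = seq_len(replicates),
                      fraction = fractions, KEEP.OUT.ATTRS = FALSE)
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, nrow(grid)))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    frac <- grid$fraction[g]
    rows[[g]] <- withr::with_seed(sub_seeds[g], {
      db_sub <- if (length(set_methods) > 0 ||
                    profile_path == "binarize_sets") {
        subsample_gene_sets(gene_sets, min(frac, 0.99))
      }
      prof_sub <- if (length(prof_methods) > 0) {
        if (profile_path == "mask") {
          subsample_profile(profile, frac)
        } else {
          gene_sets_to_binary(db_sub)
        }
      }
      purrr::map_dfr(methods, function(meth) {
        scores <- switch(meth,
          ora = ora_scores(ora_lists_cache, db_sub),
          gsea = gsea_scores(exy, db_sub, nperm = gsea_nperm,
                             seed = sample.int(.Machine$integer.max, 1)),
          gsva = gsva_scores(exy, db_sub),
          cibersort = cibersort_scores(exy, prof_sub, nu_grid = nu_grid),
          metaneighbor = metaneighbor_scores(exy, prof_sub))
        ls <- suppressMessages(concatenate_with_truth(scores, gold))
        tibble::tibble(method = meth,
                       fraction = frac,
                       replicate = grid$replicate[g],
                       roc_auc = roc_curve(ls)$auc,
                       pr_auc = pr_curve(ls)$auc)
      })
    })
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$method, .data$fraction, .data$replicate)
  class(out) <- c("robustness_result", class(out))
  out
}

#' Summarize a robustness experiment per method and fraction
#'
#' @param x A `robustness_result`.
#' @param ... Unused.
#' @return A tibble with mean and sd of both AUCs per (method, fraction).
#' @importFrom generics glance
#' @export
glance.robustness_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$method, .data$fraction),
    n = dplyr::n(),
    mean_roc_auc = mean(.data$roc_auc),
    sd_roc_auc = stats::sd(.data$roc_auc),
    mean_pr_auc = mean(.data$pr_auc),
    sd_pr_auc = stats::sd(.data$pr_auc),
    .groups = "drop"
  )
}
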