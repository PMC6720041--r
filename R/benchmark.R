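# End-to-end orchestration: cluster averaging -> signature preparation ->
# scoring with any subset of the five methods -> evaluation (and optional
# robustness), with every output written to disk alongside a manifest that
# records parameters and seeds.

#' Score clusters with one method
#'
#' Uniform dispatcher over the five scorers. Gene-set methods (`"ora"`,
#' `"gsea"`, `"gsva"`) need `gene_sets`; profile methods (`"cibersort"`,
#' `"metaneighbor"`) need `profile` (continuous or binary; pass
#' `gene_sets_to_binary(db)` for the "binary" variants).
#'
#' @param exy Cluster-average matrix, genes x clusters.
#' @param method One of `"ora"`, `"gsea"`, `"gsva"`, `"cibersort"`,
#'   `"metaneighbor"`.
#' @param gene_sets A [gene_set_db()] (gene-set methods).
#' @param profile Signature matrix, genes x types (profile methods).
#' @param ora_fraction Expressed-gene fraction for the ORA threshold.
#' @param gsea_nperm,gsea_ranking,seed GSEA parameters.
#' @param gsva_kernel,gsva_tau GSVA parameters.
#' @param nu_grid Deconvolution nu grid.
#' @return A score matrix, cell types x clusters.
#' @export
score_clusters <- function(exy, method,
                           gene_sets = NULL, profile = NULL,
                           ora_fraction = 0.05,
                           gsea_nperm = 1000,
                           gsea_ranking = "expression",
                           seed = NULL,
                           gsva_kernel = "gaussian", gsva_tau = 1,
                           nu_grid = c(0.25, 0.5, 0.75)) {
  method <- match.arg(method, c("ora", "gsea", "gsva", "cibersort",
                                "metaneighbor"))
  if (method %in% c("ora", "gsea", "gsva") && is.null(gene_sets)) {
    stop("method ", method, " needs `gene_sets`")
  }
  if (method %in% c("cibersort", "metaneighbor") && is.null(profile)) {
    stop("method ", method, " needs `profile`")
  }
  switch(method,
    ora = ora_scores(top_fraction_genes(exy, ora_fraction), gene_sets),
    gsea = gsea_scores(exy, gene_sets, nperm = gsea_nperm,
                       ranking = gsea_ranking, seed = seed),
    gsva = gsva_scores(exy, gene_sets, kernel = gsva_kernel, tau = gsva_tau),
    cibersort = cibersort_scores(exy, profile, nu_grid = nu_grid),
    metaneighbor = metaneighbor_scores(exy, profile))
}

#' Run the full benchmark workflow
#'
#' Averages cells into cluster profiles (when cell-level input is given),
#' scores every requested method, evaluates ROC/PR AUC, percent-correct,
#' and gold-rank tables against the gold standard, optionally runs the
#' subsampling robustness experiment, and writes everything under
#' `out_dir`: one `scores_<method>.tsv` per method, `auc_summary.tsv`,
#' `top_hit_accuracy.tsv`, `gold_ranks.tsv`, `robustness.tsv` (if
#' requested), and `manifest.json`.
#'
#' @param exy Cluster-average matrix; alternatively pass `cells` +
#'   `assignment` and it is computed.
#' @param gene_sets A [gene_set_db()] (for gene-set methods; also the
#'   source of binary profiles when `profile` is absent).
#' @param profile Continuous signature matrix (profile methods).
#' @param gold Named character vector, cluster -> gold label.
#' @param methods Methods to run (default: all five; profile methods fall
#'   back to the binary matrix of `gene_sets` when `profile` is `NULL`).
#' @param cells,assignment Optional cell-level matrix and cell -> cluster
#'   map used to build `exy`.
#' @param restrict Optional cell-type restriction applied at evaluation
#'   time; set `restrict_scoring = TRUE` to also restrict the signatures
#'   fed to the scorers (the stricter variant).
#' @param restrict_scoring See `restrict`.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param seed Global seed.
#' @param gsea_nperm,ora_fraction,nu_grid Method parameters.
#' @param robustness `NULL`, or a list of arguments forwarded to
#'   [robustness_experiment()] (e.g. `list(replicates = 100)`).
#' @return A list with `exy`, `scores` (named list of score matrices),
#'   `auc_summary` tibble, `accuracy` tibble, `gold_ranks` tibble, and
#'   `robustness` (or `NULL`), invisibly when writing to disk.
#' @export
run_benchmark <- function(exy = NULL, gene_sets = NULL, profile = NULL,
                          gold = NULL, methods = c("ora", "gsea", "gsva",
                                                   "cibersort",
                                                   "metaneighbor"),
                          cells = NULL, assignment = NULL,
                          restrict = NULL, restrict_scoring = FALSE,
                          out_dir = NULL, seed = 1L,
                          gsea_nperm = 1000, ora_fraction = 0.05,
                          nu_grid = c(0.25, 0.5, 0.75),
                          robustness = NULL) {
  if (is.null(exy)) {
    if (is.null(cells) || is.null(assignment)) {
      stop("provide `exy`, or `cells` plus `assignment`")
    }
    exy <- average_profiles(cells, assignment)
  }
  if (is.null(gold)) stop("`gold` is required")
  methods <- match.arg(methods, c("ora", "gsea", "gsva", "cibersort",
                                  "metaneighbor"), several.ok = TRUE)
  if (is.null(profile) &&
      any(methods %in% c("cibersort", "metaneighbor"))) {
    if (is.null(gene_sets)) stop("profile methods need `profile` or `gene_sets`")
    profile <- gene_sets_to_binary(gene_sets)
  }
  scoring_sets <- gene_sets
  scoring_profile <- profile
  if (!is.null(restrict) && restrict_scoring) {
    if (!is.null(scoring_sets)) {
      scoring_sets <- scoring_sets[intersect(names(scoring_sets), restrict)]
    }
    if (!is.null(scoring_profile)) {
      keep <- intersect(colnames(scoring_profile), restrict)
      scoring_profile <- scoring_profile[, keep, drop = FALSE]
    }
  }
  method_seeds <- withr::with_seed(seed,
    stats::setNames(sample.int(.Machine$integer.max, length(methods)),
                    methods))
  scores <- lapply(methods, function(m) {
    score_clusters(exy, m, gene_sets = scoring_sets,
                   profile = scoring_profile,
                   ora_fraction = ora_fraction, gsea_nperm = gsea_nperm,
                   seed = method_seeds[[m]], nu_grid = nu_grid)
  })
  names(scores) <- methods
  auc_summary <- purrr::map_dfr(methods, function(m) {
    ls <- suppressMessages(
      concatenate_with_truth(scores[[m]], gold, restrict = restrict))
    tibble::tibble(method = m,
                   roc_auc = roc_curve(ls)$auc,
                   pr_auc = pr_curve(ls)$auc,
                   n_pairs = nrow(ls))
  })
  accuracy <- purrr::map_dfr(methods, function(m) {
    tibble::tibble(method = m,
                   top_hit_accuracy = top_hit_accuracy(scores[[m]], gold))
  })
  gold_ranks <- purrr::map_dfr(methods, function(m) {
    gold_m <- gold[gold %in% rownames(scores[[m]])]
    dplyr::mutate(gold_rank_distribution(scores[[m]], gold_m,
                                         db = gene_sets),
                  method = m, .before = 1)
  })
  rob <- if (!is.null(robustness)) {
    do.call(robustness_experiment,
            c(list(exy = exy, gold = gold, methods = methods,
                   gene_sets = gene_sets, profile = profile, seed = seed),
              robustness))
  }
  result <- list(exy = exy, scores = scores, auc_summary = auc_summary,
                 accuracy = accuracy, gold_ranks = gold_ranks,
                 robustness = rob)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in methods) {
      write_score_matrix(scores[[m]],
                         file.path(out_dir, paste0("scores_", m, ".tsv")))
    }
    utils::write.table(auc_summary, file.path(out_dir, "auc_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(accuracy,
                       file.path(out_dir, "top_hit_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gold_ranks, file.path(out_dir, "gold_ranks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rob)) {
      utils::write.table(rob, file.path(out_dir, "robustness.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("scTypeBench")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = seed, methods = methods,
      parameters = list(gsea_nperm = gsea_nperm,
                        ora_fraction = ora_fraction, nu_grid = nu_grid,
                        restrict = restrict,
                        restrict_scoring = restrict_scoring,
                        robustness = robustness),
      n_genes = nrow(exy), n_clusters = ncol(exy),
      n_types = if (!is.null(gene_sets)) length(gene_sets)
                else ncol(profile))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(result))
  }
  result
}
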