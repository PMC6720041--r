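# Synthetic scRNA-seq fixtures with planted marker structure. One cluster
# per cell type; counts follow a negative-binomial model whose mean is a
# flat background everywhere except that each type's marker genes are
# multiplied by the effect size inside that type's own cluster; Bernoulli
# dropout zeroes a fraction of entries. Every downstream artifact (gene
# sets, continuous profile, gold standard) derives from the same planted
# markers, so all five scoring methods can be exercised end-to-end with no
# external data.

#' Configuration for the synthetic fixture generator
#'
#' @param n_genes Number of genes.
#' @param n_types Number of cell types (= number of clusters).
#' @param markers_per_type Marker genes planted per type.
#' @param cells_per_cluster Cells drawn per cluster.
#' @param effect_size Multiplier (> 1) applied to a marker's mean in its
#'   own type's cluster.
#' @param background_mean Average negative-binomial mean of non-marker
#'   expression.
#' @param baseline_sdlog Log-scale standard deviation of per-gene baseline
#'   means (0 = identical baselines). Real expression data and profile
#'   signatures have strongly heterogeneous per-gene baselines; a flat
#'   background would leave rank-based methods with an unrealistic mass of
#'   tied values.
#' @param dispersion Negative-binomial size parameter (smaller = noisier).
#' @param marker_overlap Fraction of each type's markers shared with the
#'   previous type's set, in \[0, 1).
#' @param dropout Probability that any count is zeroed, in \[0, 1).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_types = 8,
                             markers_per_type = 25, cells_per_cluster = 50,
                             effect_size = 8, background_mean = 0.5,
                             baseline_sdlog = 0.5,
                             dispersion = 2, marker_overlap = 0,
                             dropout = 0.1) {
  cfg <- list(n_genes = as.integer(n_genes), n_types = as.integer(n_types),
              markers_per_type = as.integer(markers_per_type),
              cells_per_cluster = as.integer(cells_per_cluster),
              effect_size = effect_size, background_mean = background_mean,
              baseline_sdlog = baseline_sdlog,
              dispersion = dispersion, marker_overlap = marker_overlap,
              dropout = dropout)
  if (cfg$baseline_sdlog < 0) stop("`baseline_sdlog` must be >= 0")
  if (cfg$effect_size <= 1) stop("`effect_size` must be > 1")
  if (cfg$marker_overlap < 0 || cfg$marker_overlap >= 1) {
    stop("`marker_overlap` must lie in [0, 1)")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("`dropout` must lie in [0, 1)")
  fresh_per_type <- cfg$markers_per_type -
    round_half_up(cfg$marker_overlap * cfg$markers_per_type)
  need <- cfg$markers_per_type + (cfg$n_types - 1L) * fresh_per_type
  if (need > cfg$n_genes) {
    stop("not enough genes for ", cfg$n_types, " x ", cfg$markers_per_type,
         " markers at overlap ", cfg$marker_overlap)
  }
  if (cfg$cells_per_cluster < 1) stop("`cells_per_cluster` must be >= 1")
  structure(cfg, class = "synthetic_config")
}

plant_markers <- function(cfg) {
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  types <- sprintf("type%02d", seq_len(cfg$n_types))
  n_shared <- round_half_up(cfg$marker_overlap * cfg$markers_per_type)
  sets <- vector("list", cfg$n_types)
  cursor <- 0L
  for (t in seq_len(cfg$n_types)) {
    if (t == 1L || n_shared == 0L) {
      fresh <- cfg$markers_per_type
      inherited <- character(0)
    } else {
      fresh <- cfg$markers_per_type - n_shared
      inherited <- utils::tail(sets[[t - 1L]], n_shared)
    }
    sets[[t]] <- c(inherited, genes[cursor + seq_len(fresh)])
    cursor <- cursor + fresh
  }
  names(sets) <- types
  list(genes = genes, types = types, sets = sets)
}

#' Generate a complete synthetic benchmark fixture
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; the same seed reproduces the fixture
#'   bit-for-bit.
#' @return A list of class `synthetic_dataset` with elements `cells`
#'   (genes x cells count matrix), `assignment` (named cell -> cluster
#'   vector), `gene_sets` ([gene_set_db()] of planted markers), `profile`
#'   (noiseless expected mean profile, genes x types), `gold` (cluster ->
#'   type), and `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config(), seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  planted <- plant_markers(cfg)
  clusters <- sprintf("cluster%02d", seq_len(cfg$n_types))
  n_cells <- cfg$n_types * cfg$cells_per_cluster
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  assignment <- stats::setNames(rep(clusters, each = cfg$cells_per_cluster),
                                cell_ids)
  drawn <- withr::with_seed(seed, {
    # per-gene baseline means, mean-preserving lognormal heterogeneity
    baseline <- cfg$background_mean *
      stats::rlnorm(cfg$n_genes, meanlog = -cfg$baseline_sdlog^2 / 2,
                    sdlog = cfg$baseline_sdlog)
    mu <- matrix(baseline, cfg$n_genes, cfg$n_types,
                 dimnames = list(planted$genes, clusters))
    for (t in seq_len(cfg$n_types)) {
      mu[planted$sets[[t]], t] <- baseline[match(planted$sets[[t]],
                                                 planted$genes)] *
        cfg$effect_size
    }
    m <- matrix(stats::rnbinom(cfg$n_genes * n_cells,
                               mu = mu[, rep(seq_len(cfg$n_types),
                                             each = cfg$cells_per_cluster)],
                               size = cfg$dispersion),
                cfg$n_genes, n_cells,
                dimnames = list(planted$genes, cell_ids))
    if (cfg$dropout > 0) {
      keep <- matrix(stats::runif(length(m)) >= cfg$dropout,
                     nrow(m), ncol(m))
      m <- m * keep
    }
    list(counts = m, mu = mu)
  })
  counts <- drawn$counts
  mu <- drawn$mu
  profile <- (1 - cfg$dropout) * mu
  colnames(profile) <- planted$types
  structure(list(cells = counts,
                 assignment = assignment,
                 gene_sets = gene_set_db(planted$sets),
                 profile = profile,
                 gold = stats::setNames(planted$types, clusters),
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_dataset> ", cfg$n_genes, " genes x ",
      ncol(x$cells), " cells, ", cfg$n_types,
      " types (", cfg$markers_per_type, " markers each, effect ",
      cfg$effect_size, ", dropout ", cfg$dropout, ")\n", sep = "")
  invisible(x)
}

#' Derive a continuous profile signature from gene sets
#'
#' Builds an LM22-shaped continuous signature directly from marker lists:
#' marker genes sit at `background_mean * effect_size` in their own type's
#' column and at `background_mean` elsewhere. Genes are the union of all
#' sets plus (optionally) background genes named by `genes`.
#'
#' @param db A [gene_set_db()].
#' @param cfg A [synthetic_config()] supplying effect size and background
#'   level.
#' @param genes Optional full gene vocabulary for the rows (default: union
#'   of the sets).
#' @return Numeric matrix, genes x cell types.
#' @export
derive_profile_signature <- function(db, cfg = synthetic_config(),
                                     genes = NULL) {
  db <- as_gene_set_db(db)
  if (is.null(genes)) genes <- unique(unlist(db, use.names = FALSE))
  missing <- setdiff(unique(unlist(db, use.names = FALSE)), genes)
  if (length(missing) > 0) stop("`genes` must cover every set gene")
  sig <- matrix(cfg$background_mean, length(genes), length(db),
                dimnames = list(genes, names(db)))
  for (t in seq_along(db)) {
    sig[db[[t]], t] <- cfg$background_mean * cfg$effect_size
  }
  sig
}

#' Write every artifact of a synthetic fixture to a directory
#'
#' Emits `cells.tsv`, `clusters.tsv`, `gene_sets.gmt`, `profile.tsv`, and
#' `gold.tsv` in the package's interchange formats.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(ds$cells, file.path(dir, "cells.tsv"))
  writeLines(c("cell\tcluster",
               paste(names(ds$assignment), ds$assignment, sep = "\t")),
             file.path(dir, "clusters.tsv"))
  write_gmt(ds$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_expression_table(ds$profile, file.path(dir, "profile.tsv"))
  write_gold_standard(ds$gold, file.path(dir, "gold.tsv"))
  invisible(dir)
}

#' Read a cell-to-cluster assignment table
#'
#' Two-column TSV (cell id, cluster id), header tolerated.
#'
#' @param path Path to the TSV.
#' @return Named character vector, cell -> cluster.
#' @export
read_cluster_assignment <- function(path) {
  lines <- read_lines_lf(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1]][1]) %in% c("cell", "cell_id")) fields <- fields[-1]
  if (length(fields) == 0) stop("empty cluster assignment: ", path)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0) stop("malformed assignment line ", bad[1], " in ", path)
  cells <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(cells)) stop("duplicate cell id(s) in ", path)
  stats::setNames(vapply(fields, `[[`, character(1), 2L), cells)
}
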