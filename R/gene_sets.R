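#' Construct a gene-set database
#'
#' A `gene_set_db` is the gene-set form of a cell-type signature: a named
#' list mapping each cell-type label to a character vector of marker gene
#' identifiers. Gene identifiers are matched by exact, case-sensitive string
#' comparison everywhere in the package (see [fold_gene_case()] for the
#' optional upper-case fold when mixing mouse and human symbol conventions).
#'
#' @param sets Named list of character vectors; names are cell-type labels.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled to `length(sets)`; defaults to `"na"`.
#' @return An object of class `gene_set_db`.
#' @examples
#' db <- gene_set_db(list(Tcell = c("CD3D", "CD3E"), Bcell = c("MS4A1")))
#' @export
gene_set_db <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || length(sets) == 0) {
    stop("`sets` must be a non-empty named list of character vectors")
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("every gene set must have a non-empty label")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate set labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  sizes <- lengths(sets)
  if (any(sizes == 0)) {
    stop("empty gene set(s): ", paste(labels[sizes == 0], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- labels
  structure(sets, descriptions = descriptions, class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat("<gene_set_db> ", length(x), " sets, ",
      length(unique(unlist(x, use.names = FALSE))), " distinct genes\n",
      sep = "")
  show <- utils::head(seq_along(x), 6L)
  for (i in show) {
    g <- x[[i]]
    cat("  ", names(x)[i], " (", length(g), "): ",
        paste(utils::head(g, 5L), collapse = ", "),
        if (length(g) > 5L) ", ..." else "", "\n", sep = "")
  }
  if (length(x) > 6L) cat("  ... and ", length(x) - 6L, " more\n", sep = "")
  invisible(x)
}

#' @export
`[.gene_set_db` <- function(x, i) {
  gene_set_db(unclass(x)[i], descriptions = attr(x, "descriptions")[i])
}

is_gene_set_db <- function(x) inherits(x, "gene_set_db")

as_gene_set_db <- function(x) {
  if (is_gene_set_db(x)) x else gene_set_db(x)
}

#' Optionally fold gene identifiers to upper case
#'
#' Gene matching is exact and case-sensitive by default because silent case
#' folding can corrupt a benchmark. Mouse symbols (`Cd3d`) and human symbols
#' (`CD3D`) differ only in case, so when signatures and expression data come
#' from different organisms an explicit fold is sometimes wanted.
#'
#' @param x A `gene_set_db`, a matrix with gene rownames, or a character
#'   vector of gene ids.
#' @return The same object with all gene identifiers upper-cased.
#' @export
fold_gene_case <- function(x) {
  if (is_gene_set_db(x)) {
    sets <- lapply(unclass(x), toupper)
    return(gene_set_db(sets, descriptions = attr(x, "descriptions")))
  }
  if (is.matrix(x)) {
    rn <- toupper(rownames(x))
    if (anyDuplicated(rn)) stop("case folding creates duplicate gene ids")
    rownames(x) <- rn
    return(x)
  }
  toupper(x)
}
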