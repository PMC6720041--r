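# Readers and writers for the external representations the framework
# touches: GMT gene sets, genes-by-columns expression tables (TSV), and the
# two-column gold-standard map. All readers reject malformed input rather
# than repairing it, and error messages carry line numbers.

read_lines_lf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)  # CRLF tolerated
}

#' Read a GMT gene-set file
#'
#' GMT is the de-facto gene-set exchange format: one set per line, with
#' tab-separated fields `name`, `description`, then gene identifiers.
#' Duplicate genes within a line are collapsed, keeping first-occurrence
#' order.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_db()].
#' @export
read_gmt <- function(path) {
  lines <- read_lines_lf(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    stop("malformed GMT line ", bad[1], " in ", path,
         ": expected >= 3 tab-separated fields, found ",
         lengths(fields)[bad[1]])
  }
  labels <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(labels)) {
    stop("duplicate set name(s) in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- labels
  gene_set_db(sets, descriptions = descriptions)
}

#' Write a gene-set database to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(db, path))` reproduces `db`.
#' Empty descriptions are filled with `"na"`. Labels or genes containing a
#' tab character cannot be represented and raise an error.
#'
#' @param db A [gene_set_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  db <- as_gene_set_db(db)
  desc <- attr(db, "descriptions")
  desc[!nzchar(desc)] <- "na"
  all_tokens <- c(names(db), desc, unlist(db, use.names = FALSE))
  if (any(grepl("\t", all_tokens, fixed = TRUE))) {
    stop("labels, descriptions and gene ids must not contain tab characters")
  }
  lines <- vapply(seq_along(db), function(i) {
    paste(c(names(db)[i], desc[i], db[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a genes-by-columns expression table
#'
#' Parses a rectangular tab-separated table whose first row holds column
#' identifiers (cells, clusters, or cell types) and whose first column holds
#' gene identifiers, into a named numeric matrix. This carries every matrix
#' the framework touches: raw count matrices, cluster-average matrices, and
#' continuous profile signatures such as LM22. There is no row cap.
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file is columns-by-genes and is
#'   transposed after reading so that genes end up in rows.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression_table <- function(path, transpose = FALSE) {
  lines <- read_lines_lf(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression table needs a header and >= 1 row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # a leading corner cell for the gene-id column is tolerated; the first
  # data row decides which layout the file uses
  body_width <- lengths(fields[-1])
  ncol_data <- if (body_width[1] == length(header)) {
    length(header) - 1L
  } else if (body_width[1] == length(header) + 1L) {
    length(header)
  } else {
    stop("ragged row at line 2 in ", path, ": ", body_width[1],
         " fields do not fit a ", length(header), "-column header")
  }
  col_ids <- utils::tail(header, ncol_data)
  ragged <- which(body_width != ncol_data + 1L)
  if (length(ragged) > 0) {
    stop("ragged row at line ", ragged[1] + 1L, " in ", path,
         ": expected ", ncol_data + 1L, " fields, found ", body_width[ragged[1]])
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate column ids in ", path, ": ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  gene_ids <- vapply(fields[-1], `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5), collapse = ", "))
  }
  cells <- unlist(lapply(fields[-1], `[`, -1L), use.names = FALSE)
  values <- suppressWarnings(as.numeric(cells))
  if (anyNA(values)) {
    first_bad <- which(is.na(values))[1]
    row <- (first_bad - 1L) %/% ncol_data + 2L
    stop("non-numeric value ", dQuote(cells[first_bad]), " at line ", row,
         " in ", path)
  }
  m <- matrix(values, nrow = length(gene_ids), ncol = ncol_data, byrow = TRUE,
              dimnames = list(gene_ids, col_ids))
  if (transpose) m <- t(m)
  validate_expression_table(m)
  m
}

#' Write an expression table as TSV
#'
#' @param m Numeric matrix with gene rownames and column ids.
#' @param path Output path.
#' @param corner Label for the top-left corner cell (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, corner = "gene") {
  validate_expression_table(m, allow_negative = TRUE)
  header <- paste(c(corner, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            format(m[i, ], trim = TRUE, digits = 15, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

validate_expression_table <- function(m, allow_negative = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression table must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression table must have gene rownames and column ids")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate column ids")
  if (any(!is.finite(m))) stop("expression values must all be finite")
  if (!allow_negative && any(m < 0)) stop("expression values must be non-negative")
  invisible(m)
}

#' Read a gold-standard cluster-to-cell-type map
#'
#' Two-column TSV: cluster id, cell-type label. Clusters left out of the
#' file are permitted and are simply excluded from evaluation later; a
#' cluster appearing twice is an error. A header line whose first field is
#' `cluster` is skipped.
#'
#' @param path Path to a 2-column TSV.
#' @return Named character vector: `gold[cluster] == cell type`.
#' @export
read_gold_standard <- function(path) {
  lines <- read_lines_lf(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty gold-standard file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  offset <- 0L
  if (tolower(fields[[1]][1]) %in% c("cluster", "cluster_id")) {
    fields <- fields[-1]
    offset <- 1L
    if (length(fields) == 0) stop("gold-standard file has only a header: ", path)
  }
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0) {
    stop("malformed gold-standard line ", bad[1] + offset, " in ", path,
         ": expected 2 tab-separated fields")
  }
  clusters <- vapply(fields, `[[`, character(1), 1L)
  labels <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(clusters)) {
    stop("duplicate cluster id(s) in ", path, ": ",
         paste(unique(clusters[duplicated(clusters)]), collapse = ", "))
  }
  stats::setNames(labels, clusters)
}

#' Write a gold-standard map as 2-column TSV
#'
#' @param gold Named character vector (cluster -> label).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  if (is.null(names(gold)) || anyDuplicated(names(gold))) {
    stop("`gold` must be a named vector with unique cluster ids")
  }
  writeLines(c("cluster\tcell_type",
               paste(names(gold), gold, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}
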