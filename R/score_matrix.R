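# Every scorer returns a "score matrix": cell types in rows, clusters in
# columns, higher = stronger support for "this cluster is this type".
# Entries that cannot be computed (a signature with no gene shared with the
# expression matrix) are NA and are excluded pairwise downstream, never
# imputed as 0.

new_score_matrix <- function(values, method) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  structure(values, method = method,
            class = c("score_matrix", class(values)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> method = ", attr(x, "method"), ", ",
      nrow(x), " cell types x ", ncol(x), " clusters\n", sep = "")
  print(unclass_score_matrix(x), ...)
  invisible(x)
}

unclass_score_matrix <- function(x) {
  attr(x, "method") <- NULL
  class(x) <- setdiff(class(x), "score_matrix")
  x
}

#' Tidy a score matrix into a long tibble
#'
#' @param x A score matrix as returned by the scoring functions.
#' @param ... Unused.
#' @return A tibble with columns `cell_type`, `cluster`, `score`, `method`.
#' @importFrom generics tidy
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble::tibble(
    cell_type = rep(rownames(x), times = ncol(x)),
    cluster = rep(colnames(x), each = nrow(x)),
    score = as.vector(unclass_score_matrix(x)),
    method = attr(x, "method")
  )
}

#' Write a score matrix as TSV with a method header comment
#'
#' @param scores A score matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", attr(scores, "method") %||% "unknown"), con)
  m <- unclass_score_matrix(scores)
  writeLines(paste(c("cell_type", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i],
                       format(m[i, ], trim = TRUE, digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @param path Path to a score TSV.
#' @return A score matrix (NA entries preserved).
#' @export
read_score_matrix <- function(path) {
  lines <- read_lines_lf(path)
  method <- "unknown"
  if (length(lines) > 0 && startsWith(lines[1], "# method:")) {
    method <- trimws(sub("^# method:", "", lines[1]))
    lines <- lines[-1]
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  df <- utils::read.delim(tmp, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  new_score_matrix(m, method)
}

#' Transform a p-value to a -log10 score
#'
#' Converts P-values from the p-value-producing scorers (ORA, GSEA) to a
#' scale where higher means stronger support. The floor keeps the transform
#' finite; for permutation tests the natural floor is `1 / (nperm + 1)`.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param floor Smallest p-value distinguished, in (0, 1].
#' @return `-log10(pmax(p, floor))`, monotone decreasing in `p`.
#' @examples
#' neglog10_transform(0.001)            # 3
#' neglog10_transform(0, floor = 1/1001) # -log10(1/1001)
#' @export
neglog10_transform <- function(p, floor = .Machine$double.xmin) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (floor <= 0 || floor > 1) stop("`floor` must lie in (0, 1]")
  -log10(pmax(p, floor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
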