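#' Two-condition expression matrix
#'
#' Genes-by-samples expression values with a binary condition labelling, the
#' data object behind the differential-expression (node) and co-expression
#' (edge) potentials.
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param groups per-sample group assignment: a vector of length
#'   `ncol(values)` with exactly two distinct values, or a named vector whose
#'   names match the sample identifiers.
#' @return object of class `impala_expression`: list with `values` (matrix)
#'   and `groups` (factor of two levels, aligned with columns).
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric",
                                call. = FALSE)
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames",
                                      call. = FALSE)
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0L) {
    stop("duplicated gene identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (!is.null(names(groups))) {
    unknown <- setdiff(names(groups), colnames(values))
    if (length(unknown) > 0L) {
      stop("group label(s) for unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    miss <- setdiff(colnames(values), names(groups))
    if (length(miss) > 0L) {
      stop("no group label for sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values)) {
    stop("need one group label per sample (", ncol(values), " samples, ",
         length(groups), " labels)", call. = FALSE)
  }
  groups <- factor(as.vector(groups))
  if (nlevels(groups) != 2L) {
    stop("exactly two condition groups are required, got ",
         nlevels(groups), call. = FALSE)
  }
  sizes <- table(groups)
  # Welch variance needs two samples per group; the correlation z needs
  # four samples overall (Fisher's sqrt(m - 3) scaling).
  if (any(sizes < 2L) || ncol(values) < 4L) {
    stop("need >= 2 samples per condition group and >= 4 overall (got ",
         paste(sizes, collapse = "/"), ")", call. = FALSE)
  }
  structure(list(values = values, groups = groups),
            class = "impala_expression")
}

#' @export
print.impala_expression <- function(x, ...) {
  cat("impala expression matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples; groups",
      paste(table(x$groups), collapse = "/"), "\n")
  invisible(x)
}

#' Read an expression matrix with group labels
#'
#' The TSV layout is genes in rows, samples in columns, with a header of
#' sample identifiers and gene identifiers in the first column. Genes absent
#' from any network are retained; filtering to the landscape happens later.
#'
#' @param path TSV file path.
#' @param labels per-sample group assignment: a (possibly named) vector, or a
#'   path to a two-column TSV `sample<TAB>group`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, labels) {
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t",
                     fixed = TRUE)[[1L]]
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    colClasses = c("character", rep("character",
                                                    length(header) - 1L)))
  gene_ids <- tab[[1L]]
  body <- tab[-1L]
  suppressWarnings(num <- vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(gene_ids, names(body)))
  if (anyNA(num) && !anyNA(body)) {
    bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s': '%s'",
                 gene_ids[bad[1L]], names(body)[bad[2L]],
                 body[bad[1L], bad[2L]]), call. = FALSE)
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lab <- read.table(labels, sep = "\t", header = FALSE, quote = "",
                      colClasses = "character")
    labels <- setNames(lab[[2L]], lab[[1L]])
  }
  expression_matrix(num, labels)
}

#' Write an expression matrix (with optional label sidecar)
#'
#' @param expr an [expression_matrix()].
#' @param path output TSV path.
#' @param labels_path optional path for a two-column `sample<TAB>group` TSV.
#' @return invisibly, `expr`.
#' @export
write_expression <- function(expr, path, labels_path = NULL) {
  # %.17g guarantees the decimal text parses back to the identical double
  chr <- matrix(sprintf("%.17g", expr$values), nrow = nrow(expr$values),
                dimnames = dimnames(expr$values))
  tab <- data.frame(gene = rownames(expr$values), chr, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    write.table(data.frame(colnames(expr$values), as.character(expr$groups)),
                labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(expr)
}
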