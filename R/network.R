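#' Undirected protein-interaction network
#'
#' Container for the interaction landscape: a set of gene identifiers, an
#' undirected edge set stored once per unordered pair, and an optional
#' subcellular-location label per gene. Gene identifiers are opaque,
#' case-sensitive strings; no symbol mapping is attempted.
#'
#' @param edges two-column character matrix or data.frame of interacting gene
#'   pairs. Duplicate pairs (in either order) are collapsed and self-loops are
#'   dropped; counts of both are reported via a message.
#' @param genes optional character vector of gene identifiers; the union of
#'   edge endpoints is always included, so this only adds isolated genes.
#' @param locations optional named character vector mapping genes to one of
#'   `"membrane"`, `"cytoplasm"`, `"nucleus"`, `"other"`. Unlisted genes get
#'   `"other"`.
#' @return An object of class `impala_network` with elements `genes`
#'   (character), `edges` (two-column character matrix, each row sorted so
#'   column 1 < column 2), and `location` (named character vector).
#' @export
interaction_network <- function(edges, genes = NULL, locations = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("'edges' must have exactly two columns", call. = FALSE)
  }
  mode(edges) <- "character"
  self <- edges[, 1L] == edges[, 2L]
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- cbind(a[!dup], b[!dup])
  colnames(edges) <- c("gene_a", "gene_b")
  if (n_self > 0L) impala_log(n_self, " self-loop(s) dropped")
  if (n_dup > 0L) impala_log(n_dup, " duplicate edge(s) collapsed")
  genes <- sort(unique(c(as.character(genes), edges[, 1L], edges[, 2L])))
  if (length(genes) == 0L) {
    stop("network is empty: no genes and no edges", call. = FALSE)
  }
  loc <- rep("other", length(genes))
  names(loc) <- genes
  if (!is.null(locations)) {
    locations <- validate_locations(locations)
    known <- intersect(names(locations), genes)
    loc[known] <- locations[known]
  }
  structure(list(genes = genes, edges = edges, location = loc),
            class = "impala_network")
}

valid_locations <- c("membrane", "cytoplasm", "nucleus", "other")

validate_locations <- function(locations) {
  locations <- unlist(locations)
  if (is.null(names(locations)) || any(names(locations) == "")) {
    stop("locations must be a named character vector", call. = FALSE)
  }
  bad <- setdiff(unique(locations), valid_locations)
  if (length(bad) > 0L) {
    stop("unknown location label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(valid_locations, collapse = ", "),
         call. = FALSE)
  }
  locations
}

#' @export
print.impala_network <- function(x, ...) {
  cat("impala interaction network:", length(x$genes), "genes,",
      nrow(x$edges), "undirected edges\n")
  invisible(x)
}

#' Number of genes / edges in a network
#' @param network an `impala_network`
#' @return integer count
#' @export
network_gene_count <- function(network) length(network$genes)

#' @rdname network_gene_count
#' @export
network_edge_count <- function(network) nrow(network$edges)

# Integer-indexed adjacency used by the landscape and the sampler.
# Returns list(genes, index (named int), adj = list of sorted int vectors).
adjacency_index <- function(network) {
  genes <- network$genes
  idx <- seq_along(genes)
  names(idx) <- genes
  adj <- vector("list", length(genes))
  for (i in idx) adj[[i]] <- integer()
  if (nrow(network$edges) > 0L) {
    ia <- idx[network$edges[, 1L]]
    ib <- idx[network$edges[, 2L]]
    adj <- split(c(ib, ia), c(ia, ib))
    full <- vector("list", length(genes))
    for (k in seq_along(full)) full[[k]] <- integer()
    full[as.integer(names(adj))] <- lapply(adj, function(v) sort(unname(v)))
    adj <- full
  }
  list(genes = genes, index = idx, adj = adj)
}

as_igraph <- function(network, directed = FALSE) {
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g, length(network$genes),
                            name = network$genes,
                            location = unname(network$location[network$genes]))
  if (nrow(network$edges) > 0L) {
    g <- igraph::add_edges(g, t(network$edges))
  }
  g
}

#' Read an undirected interaction network
#'
#' Accepts the two common plain-text exchange formats: SIF
#' (`geneA relation geneB`, whitespace separated) and two-column TSV
#' (`geneA<TAB>geneB`). Duplicate rows and both orders of the same pair are
#' collapsed; self-loops are dropped (counts logged).
#'
#' @param path file path.
#' @param format `"auto"` (default: 3+ columns means SIF), `"sif"`, or
#'   `"tsv"`.
#' @param locations optional named character vector of location labels (see
#'   [interaction_network()]), or a path to a two-column TSV `gene<TAB>label`.
#' @return an [interaction_network()].
#' @export
read_network <- function(path, format = c("auto", "sif", "tsv"),
                         locations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (format == "auto") {
    format <- if (any(nf >= 3L)) "sif" else "tsv"
  }
  want <- if (format == "sif") 3L else 2L
  bad <- which(nf < want)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s row at line %d: '%s' (%d field(s), need >= %d)",
                 format, bad[1L], lines[bad[1L]], nf[bad[1L]], want),
         call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), want)
  if (is.character(locations) && length(locations) == 1L &&
      is.null(names(locations)) && file.exists(locations)) {
    locations <- read_locations(locations)
  }
  interaction_network(cbind(a, b), locations = locations)
}

#' Read a gene-to-subcellular-location table
#'
#' @param path two-column TSV `gene<TAB>location` with location in
#'   `{membrane, cytoplasm, nucleus, other}`.
#' @return named character vector of locations.
#' @export
read_locations <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", colClasses = "character")
  if (ncol(tab) < 2L) stop("location table needs two columns", call. = FALSE)
  validate_locations(setNames(tab[[2L]], tab[[1L]]))
}

#' Read a gene set (plain text or GMT)
#'
#' Plain text is one gene per line. GMT rows are
#' `name<TAB>description<TAB>gene1<TAB>gene2...`; all member genes across all
#' rows are pooled.
#'
#' @param path file path.
#' @param format `"auto"` (GMT if any line has >= 3 tab fields), `"txt"`, or
#'   `"gmt"`.
#' @return character vector of unique gene identifiers, in first-seen order.
#' @export
read_gene_set <- function(path, format = c("auto", "txt", "gmt")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene set file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (any(lengths(fields) >= 3L)) "gmt" else "txt"
  }
  genes <- if (format == "gmt") {
    unlist(lapply(fields, function(f) f[-(1:2)]))
  } else {
    trimws(lines)
  }
  unique(genes[nzchar(genes)])
}

#' Write a directed network with edge-direction probabilities
#'
#' Serializes a set of directed edges annotated with orientation probability
#' and support, plus optional per-gene attributes (sampling frequency, log2
#' fold change), to GraphML, SIF or TSV. GraphML and TSV carry all
#' attributes and round-trip losslessly through [read_directed_network()];
#' SIF is structure-only by design of the format.
#'
#' @param edges data.frame with columns `from`, `to`, `p`, `support` (as
#'   produced by [estimate_edge_probabilities()]).
#' @param path output file path.
#' @param format `"graphml"`, `"sif"`, or `"tsv"` (default guessed from the
#'   file extension, falling back to `"tsv"`).
#' @param gene_attrs optional data.frame with column `gene` plus numeric
#'   attribute columns (e.g. `frequency`, `log2fc`) attached to nodes in
#'   GraphML output.
#' @return invisibly, the normalized `edges` data.frame.
#' @export
write_directed_network <- function(edges, path,
                                   format = c("auto", "graphml", "sif", "tsv"),
                                   gene_attrs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("graphml", "sif", "tsv")) ext else "tsv"
  }
  edges <- normalize_directed_edges(edges)
  if (format == "tsv") {
    out <- edges
    out$p <- sprintf("%.17g", out$p)       # exact decimal round-trip
    out$support <- sprintf("%.17g", out$support)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    if (nrow(edges) == 0L) {
      writeLines(character(), path)
    } else {
      writeLines(paste(edges$from, "dir", edges$to, sep = "\t"), path)
    }
  } else {
    nodes <- unique(c(edges$from, edges$to,
                      if (!is.null(gene_attrs)) as.character(gene_attrs$gene)))
    nodes <- sort(nodes)
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    if (!is.null(gene_attrs)) {
      stopifnot("gene" %in% names(gene_attrs))
      m <- match(nodes, as.character(gene_attrs$gene))
      for (col in setdiff(names(gene_attrs), "gene")) {
        g <- igraph::set_vertex_attr(g, col, value = gene_attrs[[col]][m])
      }
    }
    if (nrow(edges) > 0L) {
      g <- igraph::add_edges(g, rbind(edges$from, edges$to))
      g <- igraph::set_edge_attr(g, "p", value = edges$p)
      g <- igraph::set_edge_attr(g, "support", value = edges$support)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(edges)
}

#' Read back a directed network written by [write_directed_network()]
#'
#' @param path file path.
#' @param format `"graphml"`, `"sif"`, `"tsv"`, or `"auto"` (extension-based).
#' @return data.frame with columns `from`, `to`, `p`, `support` (`p` and
#'   `support` are `NA` for SIF input).
#' @export
read_directed_network <- function(path,
                                  format = c("auto", "graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("graphml", "sif", "tsv")) ext else "tsv"
  }
  if (format == "tsv") {
    tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                      colClasses = c("character", "character",
                                     "numeric", "numeric"))
    return(normalize_directed_edges(tab))
  }
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      return(normalize_directed_edges(
        data.frame(from = character(), to = character(),
                   p = numeric(), support = numeric())))
    }
    f <- strsplit(lines, "[\t ]+")
    return(normalize_directed_edges(data.frame(
      from = vapply(f, `[[`, character(1L), 1L),
      to = vapply(f, `[[`, character(1L), 3L),
      p = NA_real_, support = NA_real_)))
  }
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  n_e <- nrow(el)
  grab <- function(attr) {
    if (attr %in% igraph::edge_attr_names(g)) {
      igraph::edge_attr(g, attr)
    } else {
      rep(NA_real_, n_e)
    }
  }
  normalize_directed_edges(data.frame(
    from = as.character(el[, 1L]), to = as.character(el[, 2L]),
    p = grab("p"), support = grab("support")))
}

normalize_directed_edges <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from", "to", "p", "support")
  missing <- setdiff(need, names(edges))
  if (length(missing) > 0L) {
    stop("directed edge table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  edges <- edges[need]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$p <- as.numeric(edges$p)
  edges$support <- as.numeric(edges$support)
  if (any(!is.na(edges$p) & (edges$p < 0 | edges$p > 1))) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
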