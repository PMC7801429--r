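#' Differential-expression node potential (V1)
#'
#' Score of a single gene's differential expression between the two
#' conditions: the absolute z-score obtained by mapping the Welch two-sample
#' t statistic through the standard-normal quantile of its two-sided p-value.
#' A gene absent from the expression matrix scores 0 (neutral), as does a
#' gene with zero variance and equal means in both groups.
#'
#' @param gene gene identifier.
#' @param expr an [expression_matrix()].
#' @param cap_p p-values below this floor are capped before the z mapping, so
#'   infinite t statistics yield a finite maximal score (default `1e-16`).
#' @return non-negative scalar.
#' @export
gene_potential <- function(gene, expr, cap_p = 1e-16) {
  if (!gene %in% rownames(expr$values)) return(0)
  unname(node_scores(expr, cap_p = cap_p)[gene])
}

# Vectorized Welch-t -> |z| for every gene in the matrix.
node_scores <- function(expr, cap_p = 1e-16) {
  x <- expr$values
  g1 <- expr$groups == levels(expr$groups)[1L]
  x1 <- x[, g1, drop = FALSE]
  x2 <- x[, !g1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t <- ifelse(se2 > 0, abs(diff) / sqrt(se2), ifelse(diff == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               1)
  p <- 2 * pt(t, df = df, lower.tail = FALSE)
  p <- pmax(p, cap_p)
  z <- qnorm(p / 2, lower.tail = FALSE)
  setNames(pmax(z, 0), rownames(x))
}

#' Co-expression edge potential (V2)
#'
#' Significance z-score of the Pearson correlation between two interacting
#' genes across all samples, via Fisher's transform:
#' `|atanh(r)| * sqrt(m - 3)`. Symmetric in its gene arguments. A pair
#' involving a gene that is missing from the matrix or constant scores 0;
#' `|r| = 1` is capped at the z equivalent of the two-sided p-value `cap_p`.
#'
#' @param gene_a,gene_b gene identifiers.
#' @param expr an [expression_matrix()]; needs at least 4 samples.
#' @param cap_p cap on significance as in [gene_potential()].
#' @return non-negative scalar.
#' @export
edge_potential <- function(gene_a, gene_b, expr, cap_p = 1e-16) {
  m <- ncol(expr$values)
  if (m < 4L) stop("insufficient samples for correlation z (m = ", m,
                   " < 4)", call. = FALSE)
  rn <- rownames(expr$values)
  if (!(gene_a %in% rn) || !(gene_b %in% rn)) return(0)
  a <- expr$values[gene_a, ]
  b <- expr$values[gene_b, ]
  if (sd(a) == 0 || sd(b) == 0) return(0)
  r <- cor(a, b)
  fisher_z(r, m, cap_p)
}

fisher_z <- function(r, m, cap_p = 1e-16) {
  z_cap <- qnorm(cap_p / 2, lower.tail = FALSE)
  z <- abs(atanh(pmin(pmax(r, -1), 1))) * sqrt(m - 3)
  unname(pmin(z, z_cap))
}

# Vectorized V2 over an edge index matrix (2 columns of row indices into x).
edge_scores <- function(expr, pairs, cap_p = 1e-16) {
  m <- ncol(expr$values)
  if (m < 4L) stop("insufficient samples for correlation z (m = ", m,
                   " < 4)", call. = FALSE)
  if (nrow(pairs) == 0L) return(numeric())
  x <- expr$values
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (m - 1))
  xs <- (x - mu) / ifelse(s > 0, s, 1)
  r <- rowSums(xs[pairs[, 1L], , drop = FALSE] *
                 xs[pairs[, 2L], , drop = FALSE]) / (m - 1)
  r[s[pairs[, 1L]] == 0 | s[pairs[, 2L]] == 0] <- 0
  fisher_z(r, m, cap_p)
}

#' Location-flow potential (V3)
#'
#' Concordance of a pathway with the canonical direction of signal flow
#' through cellular compartments, membrane -> cytoplasm -> nucleus. A
#' transition is concordant when the compartment rank does not decrease
#' (`membrane` = 1, `cytoplasm` = 2, `nucleus` = 3); genes labelled `other`
#' match anything. The potential is `lambda` times the fraction of concordant
#' consecutive transitions.
#'
#' @param genes ordered character vector of pathway genes (length >= 2).
#' @param locations named character vector of location labels; genes missing
#'   from it count as `"other"`.
#' @param lambda scale factor putting V3 on the same footing as the node
#'   potentials (see [build_potential_tables()]).
#' @param reverse logical; score against the reversed compartment order
#'   (used by the reverse-search chain).
#' @return scalar in `[0, lambda]`.
#' @export
flow_potential <- function(genes, locations, lambda = 1, reverse = FALSE) {
  ranks <- location_ranks(genes, locations)
  if (reverse) ranks <- ifelse(ranks == 0L, 0L, 4L - ranks)
  lambda * concordant_fraction(ranks)
}

location_ranks <- function(genes, locations) {
  loc <- rep("other", length(genes))
  known <- genes %in% names(locations)
  loc[known] <- locations[genes[known]]
  c(membrane = 1L, cytoplasm = 2L, nucleus = 3L, other = 0L)[loc]
}

concordant_fraction <- function(ranks) {
  L <- length(ranks)
  if (L < 2L) return(0)
  a <- ranks[-L]; b <- ranks[-1L]
  mean(a == 0L | b == 0L | b >= a)
}

#' Precompute potential tables over a (sub)network
#'
#' Scores every gene (V1) and every undirected edge (V2) of the landscape
#' once; the sampler then only looks scores up. The V3 scale `lambda`
#' defaults to the mean of the nonzero node scores so the flow potential is
#' commensurate with a typical V1 term.
#'
#' @param subnetwork an [interaction_network()] restricted to the candidate
#'   landscape.
#' @param expr an [expression_matrix()]; landscape genes missing from it
#'   score 0 for V1 and V2 (kept for connectivity, neutral in energy).
#' @param weights numeric length 3, the `(w1, w2, w3)` multipliers of the
#'   three potentials in the energy (default `c(1, 1, 1)`).
#' @param temperature Boltzmann temperature `T > 0` (default 1).
#' @param lambda `"auto"` (mean nonzero node score; 0 if all node scores are
#'   zero) or a fixed non-negative number.
#' @param cap_p significance cap, see [gene_potential()].
#' @return object of class `impala_tables`: list with `genes`, `node` (named
#'   numeric), `edge` (named numeric keyed `"a|b"`, `a < b`), `location`,
#'   `lambda`, `weights`, `temperature`, `cap_p`.
#' @export
build_potential_tables <- function(subnetwork, expr, weights = c(1, 1, 1),
                                   temperature = 1, lambda = "auto",
                                   cap_p = 1e-16) {
  stopifnot(length(weights) == 3L, all(is.finite(weights)))
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  genes <- subnetwork$genes
  node <- setNames(numeric(length(genes)), genes)
  present <- intersect(genes, rownames(expr$values))
  if (length(present) > 0L) {
    all_scores <- node_scores(expr, cap_p = cap_p)
    node[present] <- all_scores[present]
  }
  e <- subnetwork$edges
  edge <- setNames(numeric(nrow(e)), paste(e[, 1L], e[, 2L], sep = "|"))
  rows <- match(e, rownames(expr$values))
  dim(rows) <- dim(e)
  ok <- !is.na(rows[, 1L]) & !is.na(rows[, 2L])
  if (any(ok)) {
    edge[ok] <- edge_scores(expr, rows[ok, , drop = FALSE], cap_p = cap_p)
  }
  if (identical(lambda, "auto")) {
    nz <- node[node > 0]
    lambda <- if (length(nz) > 0L) mean(nz) else 0
  }
  stopifnot(is.numeric(lambda), lambda >= 0)
  if (any(!is.finite(node)) || any(!is.finite(edge))) {
    stop("non-finite potential encountered", call. = FALSE)
  }
  structure(list(genes = genes, node = node, edge = edge,
                 location = subnetwork$location, lambda = lambda,
                 weights = as.numeric(weights),
                 temperature = as.numeric(temperature),
                 cap_p = cap_p),
            class = "impala_tables")
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

lookup_node <- function(tables, genes) {
  miss <- setdiff(genes, names(tables$node))
  if (length(miss) > 0L) {
    stop("gene(s) not scored in potential tables: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tables$node[genes]
}

lookup_edge <- function(tables, a, b) {
  key <- edge_key(a, b)
  val <- tables$edge[key]
  if (anyNA(val)) {
    stop("edge(s) not scored in potential tables: ",
         paste(key[is.na(val)], collapse = ", "), call. = FALSE)
  }
  unname(val)
}

#' Pathway object
#'
#' An ordered gene vector together with its three potential components and
#' total energy under a set of precomputed tables.
#'
#' @param genes ordered character vector of pathway genes.
#' @param tables an [build_potential_tables()] object covering the pathway.
#' @param reverse score V3 against the reversed compartment order.
#' @return object of class `impala_pathway`: list with `genes`, `v1`, `v2`,
#'   `v3`, `energy` (`= w1 v1 + w2 v2 + w3 v3`).
#' @export
pathway <- function(genes, tables, reverse = FALSE) {
  genes <- as.character(genes)
  L <- length(genes)
  if (L < 2L) stop("a pathway needs >= 2 genes", call. = FALSE)
  if (anyDuplicated(genes)) stop("pathway is not simple: repeated gene",
                                 call. = FALSE)
  v1 <- sum(lookup_node(tables, genes))
  v2 <- sum(lookup_edge(tables, genes[-L], genes[-1L]))
  v3 <- flow_potential(genes, tables$location, lambda = tables$lambda,
                       reverse = reverse)
  w <- tables$weights
  structure(list(genes = genes, v1 = v1, v2 = v2, v3 = v3,
                 energy = w[1L] * v1 + w[2L] * v2 + w[3L] * v3),
            class = "impala_pathway")
}

#' @export
print.impala_pathway <- function(x, ...) {
  cat("impala pathway:", paste(x$genes, collapse = " -> "),
      sprintf("(U = %.4g)", x$energy), "\n")
  invisible(x)
}

#' Pathway energy
#'
#' Additive energy `U = w1 * sum(V1) + w2 * sum(V2) + w3 * V3` of a pathway
#' under precomputed tables. Higher energy means stronger support (more
#' aberrant expression, tighter co-expression, better location flow).
#'
#' @inheritParams pathway
#' @return scalar energy.
#' @export
pathway_energy <- function(genes, tables, reverse = FALSE) {
  if (inherits(genes, "impala_pathway")) genes <- genes$genes
  pathway(genes, tables, reverse = reverse)$energy
}

#' Boltzmann distribution over an enumerated pathway set
#'
#' `P(theta) = exp(U(theta) / T) / Z` normalized over the supplied list,
#' computed with a max-shift for overflow safety. Exact only when the list
#' exhausts the landscape.
#'
#' @param pathways list of pathway gene vectors (or `impala_pathway`
#'   objects), or a numeric vector of precomputed energies.
#' @param tables potential tables (ignored when energies are supplied).
#' @param temperature Boltzmann temperature `T > 0`; defaults to the tables'.
#' @return numeric vector of probabilities summing to 1.
#' @export
boltzmann_distribution <- function(pathways, tables = NULL,
                                   temperature = NULL) {
  if (is.numeric(pathways)) {
    u <- pathways
    if (is.null(temperature)) {
      temperature <- if (!is.null(tables)) tables$temperature else 1
    }
  } else {
    if (length(pathways) == 0L) stop("empty pathway list", call. = FALSE)
    u <- vapply(pathways, pathway_energy, numeric(1L), tables = tables)
    if (is.null(temperature)) temperature <- tables$temperature
  }
  if (length(u) == 0L) stop("empty pathway list", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  s <- u / temperature
  w <- exp(s - max(s))
  w / sum(w)
}
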