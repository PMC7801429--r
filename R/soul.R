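#' Structural similarity of two pathways
#'
#' Jaccard index of the two pathways' gene sets (order and orientation are
#' ignored): shared genes over union.
#'
#' @param a,b pathways as character vectors (or `impala_pathway` objects).
#' @return scalar in `[0, 1]`.
#' @export
pathway_similarity <- function(a, b) {
  if (inherits(a, "impala_pathway")) a <- a$genes
  if (inherits(b, "impala_pathway")) b <- b$genes
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Hierarchically cluster distinct sampled pathways
#'
#' Agglomerative clustering of the distinct pathways of a sample set on
#' distance `1 - Jaccard(gene sets)`. Pathways are put in canonical
#' (lexicographic) order before clustering so the result is invariant to the
#' input order of samples even under tied distances.
#'
#' @param samples an `impala_samples` object with >= 2 distinct pathways (a
#'   single pathway yields a degenerate one-leaf clustering).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return object of class `impala_clustering`: list with `paths`, `counts`,
#'   `similarity` (matrix), `hclust` (or `NULL` when degenerate),
#'   `leaf_order` (indices into `paths`).
#' @export
cluster_pathways <- function(samples, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  keys <- vapply(samples$paths, path_key, character(1L))
  o <- order(keys)
  paths <- samples$paths[o]
  counts <- samples$counts[o]
  n <- length(paths)
  if (n == 0L) stop("empty sample set", call. = FALSE)
  gene_sets <- lapply(paths, unique)
  sim <- diag(1, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s <- length(intersect(gene_sets[[i]], gene_sets[[j]])) /
          length(union(gene_sets[[i]], gene_sets[[j]]))
        sim[i, j] <- s
        sim[j, i] <- s
      }
    }
  }
  if (n < 2L) {
    return(structure(list(paths = paths, counts = counts, similarity = sim,
                          hclust = NULL, leaf_order = 1L),
                     class = "impala_clustering"))
  }
  hc <- hclust(stats::as.dist(1 - sim), method = linkage)
  # Deterministic leaf order: at every merge the subtree with the smaller
  # total sampling mass comes first. Heavily sampled pathways end up at the
  # right edge of their cluster block, so frequency humps of adjacent
  # clusters stay a block width apart and smoothing cannot fuse them.
  dend <- stats::reorder(stats::as.dendrogram(hc), wts = counts,
                         agglo.FUN = sum)
  structure(list(paths = paths, counts = counts, similarity = sim,
                 hclust = hc, leaf_order = stats::order.dendrogram(dend)),
            class = "impala_clustering")
}

#' @export
print.impala_clustering <- function(x, ...) {
  cat("impala pathway clustering:", length(x$paths), "distinct pathways\n")
  invisible(x)
}

#' Cluster assignments at a cut
#'
#' @param clustering an [cluster_pathways()] result.
#' @param k number of clusters, or `h` a cut height.
#' @param h cut height (used when `k` is `NULL`).
#' @return integer cluster labels, one per distinct pathway (in the
#'   clustering's canonical path order).
#' @export
cut_clusters <- function(clustering, k = NULL, h = NULL) {
  if (is.null(clustering$hclust)) return(rep(1L, length(clustering$paths)))
  if (is.null(k) && is.null(h)) stop("supply k or h", call. = FALSE)
  as.integer(cutree(clustering$hclust, k = k, h = h))
}

#' Reorder the sampling-frequency landscape by cluster structure
#'
#' Arranges the distinct pathways' sampling frequencies along the dendrogram
#' leaf order, so structurally similar pathways sit next to each other and
#' pathway families show up as contiguous humps of sampling mass.
#'
#' @param clustering an [cluster_pathways()] result.
#' @return data.frame `(position, pathway, count)` where `pathway` is the
#'   index into `clustering$paths`; total mass is preserved.
#' @export
reorder_frequency_landscape <- function(clustering) {
  o <- clustering$leaf_order
  data.frame(position = seq_along(o), pathway = o,
             count = clustering$counts[o])
}

#' Call pathway modules from the reordered frequency landscape
#'
#' Smooths the reordered frequencies with a centered moving average, finds
#' local maxima whose prominence exceeds `min_prominence` times the maximum
#' smoothed frequency, and grows each kept peak into a contiguous
#' leaf-order segment; the boundary between two adjacent peaks is placed at
#' the junction where the dendrogram separates deepest (ties broken by the
#' lower smoothed frequency), so modules respect the cluster structure.
#' Every distinct pathway is assigned to exactly one module. If no peak
#' passes the prominence bar, a single module covering the whole landscape
#' is returned (logged).
#'
#' @param clustering an [cluster_pathways()] result.
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   (raw) frequency (default 0.1).
#' @param smoothing_window centered moving-average window in leaves (default
#'   5; forced odd).
#' @return object of class `impala_modules`: list with `modules` (each a
#'   list: `pathways` (indices into `clustering$paths`), `genes`,
#'   `gene_weights` (count-weighted gene mass), `edges` (directed edge
#'   matrix), `peak` (leaf-order position), `mass`), plus `assignment` (leaf
#'   position -> module), `landscape` (the reordered frequencies) and
#'   `crosstalk` (see [crosstalk()]).
#' @export
detect_modules <- function(clustering, min_prominence = 0.1,
                           smoothing_window = 5L) {
  land <- reorder_frequency_landscape(clustering)
  y <- as.numeric(land$count)
  n <- length(y)
  sm <- moving_average(y, smoothing_window)
  peaks <- find_peaks(sm)
  # prominence and reference level live on the same (smoothed) scale
  keep <- peaks$prominence >= min_prominence * max(sm)
  pk <- peaks$position[keep]
  if (length(pk) == 0L) {
    impala_log("no peak passes prominence ", min_prominence,
               "; returning a single module")
    bounds <- c(0L, n)
    pk <- which.max(sm)
  } else {
    # One module per kept peak: cut at the (npeaks - 1) junctions where the
    # dendrogram separates deepest (largest cophenetic distance between
    # adjacent leaves), so module boundaries follow the cluster structure
    # rather than the smoothing-blurred frequency valley; ties broken by
    # the lower smoothed frequency at the junction, then by position.
    cuts <- integer(0)
    if (length(pk) > 1L) {
      o <- clustering$leaf_order
      coph <- as.matrix(stats::cophenetic(clustering$hclust))
      jh <- coph[cbind(o[-n], o[-1L])]
      jlow <- pmin(sm[-n], sm[-1L])
      ord <- order(-jh, jlow, seq_len(n - 1L))
      cuts <- sort(ord[seq_len(length(pk) - 1L)])
    }
    bounds <- c(0L, cuts, n)
  }
  modules <- vector("list", length(bounds) - 1L)
  assignment <- integer(n)
  for (m in seq_along(modules)) {
    pos <- seq(bounds[m] + 1L, bounds[m + 1L])
    assignment[pos] <- m
    idx <- land$pathway[pos]
    paths <- clustering$paths[idx]
    counts <- clustering$counts[idx]
    gw <- new.env(parent = emptyenv())
    for (k in seq_along(paths)) {
      for (g in unique(paths[[k]])) {
        assign(g, get0(g, envir = gw, ifnotfound = 0) + counts[k],
               envir = gw)
      }
    }
    genes <- sort(ls(gw))
    edges <- unique(do.call(rbind, lapply(paths, function(p) {
      L <- length(p)
      cbind(from = p[-L], to = p[-1L])
    })))
    modules[[m]] <- list(pathways = idx, genes = genes,
                         gene_weights = unlist(mget(genes, envir = gw)),
                         edges = edges,
                         peak = pk[min(m, length(pk))],
                         mass = sum(counts))
  }
  res <- structure(list(modules = modules, assignment = assignment,
                        landscape = land,
                        smoothed = sm,
                        parameters = list(min_prominence = min_prominence,
                                          smoothing_window = smoothing_window)),
                   class = "impala_modules")
  res$crosstalk <- crosstalk(res)
  res
}

#' @export
print.impala_modules <- function(x, ...) {
  cat("impala module set:", length(x$modules), "module(s);",
      nrow(x$crosstalk$genes), "crosstalk gene(s)\n")
  invisible(x)
}

# Centered moving average with reflection padding, so the effective window
# width is constant and series-end values are not over- or under-weighted.
moving_average <- function(y, window) {
  window <- as.integer(window)
  if (window < 1L) window <- 1L
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- length(y)
  if (n == 1L || half == 0L) return(as.numeric(y))
  pad <- min(half, n - 1L)  # window shrinks for series shorter than it
  yy <- c(y[pad:1 + 1L], y, y[n - seq_len(pad)])
  vapply(seq_len(n), function(i) mean(yy[i:(i + 2L * pad)]), numeric(1L))
}

# Local maxima with topographic prominence. A peak is strictly higher than
# its left neighbour (or sits at the left border) and higher than the first
# differing value to its right, so a plateau counts once, at its leftmost
# point; an all-constant series yields no interior peak and is handled by
# the caller's single-module fallback. Prominence = peak height minus the
# higher of the two saddle minima on the way to higher terrain; the range
# ends count as open terrain, giving border-reaching peaks their full drop.
find_peaks <- function(y) {
  n <- length(y)
  if (n == 0L) return(list(position = integer(), prominence = numeric()))
  if (n == 1L) return(list(position = 1L, prominence = y[1L]))
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || y[i] > y[i - 1L]
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    right_ok <- j == n || y[j + 1L] < y[i]
    if (i == 1L && j == n) right_ok <- FALSE  # constant series: no peak
    is_peak[i] <- left_ok && right_ok
  }
  pos <- which(is_peak)
  prom <- vapply(pos, function(p) {
    lmin <- y[p]
    i <- p - 1L
    while (i >= 1L && y[i] <= y[p]) { lmin <- min(lmin, y[i]); i <- i - 1L }
    lkey <- if (i >= 1L) lmin else -Inf
    rmin <- y[p]
    i <- p + 1L
    while (i <= n && y[i] <= y[p]) { rmin <- min(rmin, y[i]); i <- i + 1L }
    rkey <- if (i <= n) rmin else -Inf
    base <- max(lkey, rkey)
    if (!is.finite(base)) base <- min(lmin, rmin)
    y[p] - base
  }, numeric(1L))
  list(position = pos, prominence = prom)
}

#' Crosstalk genes between modules
#'
#' Genes shared by two or more modules indicate communication between the
#' corresponding pathways. Returns the gene-to-module membership table for
#' all genes in at least two modules and the shared-gene counts per module
#' pair. With fewer than two modules the table is empty.
#'
#' @param modules an [detect_modules()] result (or a bare list of character
#'   gene vectors, one per module).
#' @return list with `genes` (data.frame `gene, modules` where `modules` is
#'   a comma-separated module index list) and `pairs` (data.frame
#'   `module_a, module_b, shared, genes`).
#' @export
crosstalk <- function(modules) {
  gene_sets <- if (inherits(modules, "impala_modules")) {
    lapply(modules$modules, `[[`, "genes")
  } else {
    lapply(modules, function(m) unique(as.character(m)))
  }
  k <- length(gene_sets)
  empty <- list(
    genes = data.frame(gene = character(), modules = character()),
    pairs = data.frame(module_a = integer(), module_b = integer(),
                       shared = integer(), genes = character()))
  if (k < 2L) return(empty)
  all_genes <- sort(unique(unlist(gene_sets)))
  member <- vapply(gene_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes))
  hubs <- rowSums(member) >= 2L
  genes <- data.frame(
    gene = all_genes[hubs],
    modules = vapply(which(hubs), function(r)
      paste(which(member[r, ]), collapse = ","), character(1L)))
  pairs <- do.call(rbind, lapply(seq_len(k - 1L), function(a) {
    do.call(rbind, lapply(seq(a + 1L, k), function(b) {
      shared <- intersect(gene_sets[[a]], gene_sets[[b]])
      data.frame(module_a = a, module_b = b, shared = length(shared),
                 genes = paste(sort(shared), collapse = ","))
    }))
  }))
  rownames(genes) <- NULL; rownames(pairs) <- NULL
  list(genes = genes, pairs = pairs)
}

#' Run SOUL: cluster pathway samples into modules with crosstalk
#'
#' @param samples pooled `impala_samples` (e.g. `run_gist(...)$samples`).
#' @param linkage hierarchical linkage, `"average"` (default) or
#'   `"complete"`.
#' @param min_prominence,smoothing_window peak-calling parameters, see
#'   [detect_modules()].
#' @return an `impala_modules` object (carries the clustering in
#'   `$clustering`).
#' @export
run_soul <- function(samples, linkage = "average", min_prominence = 0.1,
                     smoothing_window = 5L) {
  clustering <- cluster_pathways(samples, linkage = linkage)
  mods <- detect_modules(clustering, min_prominence = min_prominence,
                         smoothing_window = smoothing_window)
  mods$clustering <- clustering
  mods
}
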