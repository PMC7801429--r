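#' Candidate-landscape configuration
#'
#' Bundles the choices that define the candidate pathway landscape: the
#' declared source genes (e.g. membrane receptors), target genes (e.g.
#' transcription factors), the neighborhood radius used to pre-screen the
#' interaction network around the sources, and the pathway length(s) sampled.
#'
#' @param sources character vector of source genes.
#' @param targets character vector of target genes.
#' @param radius neighborhood radius in steps from a seed (default 2,
#'   mirroring the two-step receptor-centered subnetwork typically used).
#' @param lengths integer vector of pathway lengths to sample; each length is
#'   run as an independent chain and the samples pooled. Default `4:8`.
#' @param location_prior logical; use the membrane -> cytoplasm -> nucleus
#'   flow potential (default `TRUE`).
#' @return object of class `impala_landscape_config`.
#' @export
landscape_config <- function(sources, targets, radius = 2L, lengths = 4:8,
                             location_prior = TRUE) {
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (length(sources) == 0L || length(targets) == 0L) {
    stop("need at least one source and one target gene", call. = FALSE)
  }
  radius <- as.integer(radius)
  lengths <- sort(unique(as.integer(lengths)))
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  if (any(lengths < 3L)) {
    stop("pathway lengths must be >= 3 (source, >= 1 intermediate, target)",
         call. = FALSE)
  }
  structure(list(sources = sources, targets = targets, radius = radius,
                 lengths = lengths, location_prior = isTRUE(location_prior)),
            class = "impala_landscape_config")
}

#' Extract a seed-centered subnetwork
#'
#' Induced subgraph on the union of closed k-step neighborhoods of the seed
#' genes — the pre-screen that replaces a genome-scale interaction network
#' with a tractable candidate landscape (e.g. all genes within two steps of a
#' receptor). Seeds are retained even when isolated.
#'
#' @param network an [interaction_network()].
#' @param seeds character vector of seed genes; must all be in the network.
#' @param k neighborhood radius in steps; `k = 0` returns the seeds alone.
#' @return an [interaction_network()] on the selected genes.
#' @export
extract_subnetwork <- function(network, seeds, k) {
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, network$genes)
  if (length(missing) > 0L) {
    stop("seed gene(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  g <- as_igraph(network)
  hood <- igraph::ego(g, order = k, nodes = seeds, mode = "all")
  keep <- sort(unique(c(seeds, unlist(lapply(hood, function(v) v$name)))))
  e <- network$edges
  sel <- e[, 1L] %in% keep & e[, 2L] %in% keep
  interaction_network(e[sel, , drop = FALSE], genes = keep,
                      locations = network$location[keep])
}

#' Per-position candidate domains for a fixed-length pathway
#'
#' For a pathway of length `L` from `source` to `target`, position `i` can
#' only hold genes reachable from the source in at most `i - 1` steps and
#' from the target in at most `L - i` steps; any other gene can never sit on
#' a connected completion. Position 1 is pinned to the source and position
#' `L` to the target.
#'
#' @param subnetwork an [interaction_network()] (normally the output of
#'   [extract_subnetwork()]).
#' @param source,target distinct genes in the subnetwork.
#' @param L pathway length (number of genes), >= 3 for interior sampling;
#'   `L = 2` is permitted when the source-target edge exists.
#' @return list of `L` character vectors, `domains[[i]]` = candidate genes
#'   for position `i`.
#' @export
candidate_domains <- function(subnetwork, source, target, L) {
  L <- as.integer(L)
  if (identical(source, target)) stop("source and target must differ",
                                      call. = FALSE)
  for (g in c(source, target)) {
    if (!g %in% subnetwork$genes) {
      stop("gene not in subnetwork: ", g, call. = FALSE)
    }
  }
  if (L < 2L) stop("pathway length must be >= 2", call. = FALSE)
  g <- as_igraph(subnetwork)
  d_src <- igraph::distances(g, v = source)[1L, subnetwork$genes]
  d_tgt <- igraph::distances(g, v = target)[1L, subnetwork$genes]
  if (d_src[[target]] > L - 1L) {
    infeasible_error("infeasible landscape: no path of length <= ", L,
                     " between ", source, " and ", target)
  }
  lapply(seq_len(L), function(i) {
    keep <- d_src <= i - 1L & d_tgt <= L - i
    # the endpoints are pinned to positions 1 and L and a simple path can
    # never revisit them, so interior domains exclude them outright
    if (i > 1L && i < L) keep[c(source, target)] <- FALSE
    sort(names(keep)[keep])
  })
}

#' Build the sampling landscape for one (source, target, length)
#'
#' Integer-indexed form of the candidate landscape consumed by
#' [run_chain()], [initialize_pathway()], [conditional_sample_position()]
#' and [enumerate_exact()]: adjacency over the subnetwork genes plus the
#' per-position candidate domains of [candidate_domains()].
#'
#' @inheritParams candidate_domains
#' @return list with the subnetwork, gene index, adjacency lists, the
#'   domain matrix (`L` rows, one column per subnetwork gene), and the
#'   source/target indices.
#' @export
build_landscape <- function(subnetwork, source, target, L) {
  domains <- candidate_domains(subnetwork, source, target, L)
  ai <- adjacency_index(subnetwork)
  dom <- matrix(FALSE, nrow = L, ncol = length(ai$genes))
  for (i in seq_len(L)) dom[i, ai$index[domains[[i]]]] <- TRUE
  list(network = subnetwork, genes = ai$genes, index = ai$index,
       adj = ai$adj, domains = domains, dom = dom,
       source = source, target = target,
       source_i = unname(ai$index[source]),
       target_i = unname(ai$index[target]), L = L)
}
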