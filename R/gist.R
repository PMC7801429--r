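infeasible_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("impala_infeasible", "error")))
}

#' Sampler configuration
#'
#' @param iterations total number of full Gibbs sweeps in the sampling budget
#'   (default 10000). When `chains > 1` the budget is split evenly across
#'   independent chains (each gets `ceiling(iterations / chains)` sweeps).
#' @param burnin fraction of each chain's sweeps discarded before samples are
#'   recorded (default 0.2).
#' @param temperature Boltzmann temperature `T > 0` (default 1).
#' @param seed integer random seed for the whole run.
#' @param direction `"both"` (default), `"forward"` or `"reverse"`; reverse
#'   chains sample the transposed problem (target to source, compartment
#'   order reversed) so both orientations of every edge get estimated.
#' @param top_k number of top-ranked distinct pathways collapsed into the
#'   consensus network (default 200).
#' @param chains independent chains per (source, target, length, direction)
#'   combination (default 32). Multiple uniformly-initialized chains guard
#'   against the single-site sampler getting trapped in one pathway family
#'   when alternative pathways share no genes.
#' @return object of class `impala_sampler_config`.
#' @export
sampler_config <- function(iterations = 10000L, burnin = 0.2,
                           temperature = 1, seed = 1L,
                           direction = c("both", "forward", "reverse"),
                           top_k = 200L, chains = 32L) {
  direction <- match.arg(direction)
  iterations <- as.integer(iterations)
  chains <- as.integer(chains)
  top_k <- as.integer(top_k)
  if (iterations < 1L || chains < 1L) {
    stop("iterations and chains must be >= 1", call. = FALSE)
  }
  if (burnin < 0 || burnin >= 1) stop("burnin fraction must be in [0, 1)",
                                      call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  structure(list(iterations = iterations, burnin = burnin,
                 temperature = temperature, seed = as.integer(seed),
                 direction = direction, top_k = top_k, chains = chains),
            class = "impala_sampler_config")
}

# ---- pathway sample sets ---------------------------------------------------

path_key <- function(genes) paste(genes, collapse = "\t")

new_sample_set <- function(paths, counts, halves, energy, meta) {
  keys <- vapply(paths, path_key, character(1L))
  o <- order(keys)
  structure(list(paths = paths[o], counts = as.integer(counts[o]),
                 halves = halves[o, , drop = FALSE],
                 energy = as.numeric(energy[o]),
                 total = sum(as.integer(counts)), meta = meta),
            class = "impala_samples")
}

#' @export
print.impala_samples <- function(x, ...) {
  cat("impala pathway samples:", x$total, "samples over",
      length(x$paths), "distinct pathways",
      sprintf("(direction: %s)\n", x$meta$direction %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge pathway sample sets
#'
#' Pools samples over the same underlying network, summing counts of
#' identical pathways. Used to pool chains, lengths and source/target pairs.
#'
#' @param sets list of `impala_samples` objects.
#' @param meta optional replacement metadata list.
#' @return a pooled `impala_samples` object.
#' @export
merge_sample_sets <- function(sets, meta = NULL) {
  sets <- sets[!vapply(sets, is.null, logical(1L))]
  if (length(sets) == 0L) stop("no sample sets to merge", call. = FALSE)
  keys <- unlist(lapply(sets, function(s)
    vapply(s$paths, path_key, character(1L))))
  paths <- do.call(c, lapply(sets, `[[`, "paths"))
  counts <- unlist(lapply(sets, `[[`, "counts"))
  halves <- do.call(rbind, lapply(sets, `[[`, "halves"))
  energy <- unlist(lapply(sets, `[[`, "energy"))
  grp <- match(keys, unique(keys))
  uk <- !duplicated(grp)
  agg_counts <- as.integer(rowsum(counts, grp)[, 1L])
  agg_halves <- rowsum(halves, grp)
  if (is.null(meta)) {
    meta <- sets[[1L]]$meta
    dirs <- unique(vapply(sets, function(s) s$meta$direction %||% "?",
                          character(1L)))
    meta$direction <- if (length(dirs) == 1L) dirs else "mixed"
    meta$pooled_from <- length(sets)
  }
  new_sample_set(paths[uk], agg_counts, agg_halves, energy[uk], meta)
}

# Flip a reverse-search sample set back into source -> target orientation,
# rescoring energies with the forward compartment order.
reorient_samples <- function(samples, tables) {
  paths <- lapply(samples$paths, rev)
  energy <- vapply(paths, pathway_energy, numeric(1L), tables = tables)
  meta <- samples$meta
  meta$direction <- "forward"
  meta$reoriented <- TRUE
  tmp <- c(meta$source, meta$target)
  meta$source <- tmp[2L]; meta$target <- tmp[1L]
  new_sample_set(paths, samples$counts, samples$halves, energy, meta)
}

#' Serialize / read a pathway sample set (JSON)
#'
#' @param samples an `impala_samples` object.
#' @param path file path.
#' @return `read_sample_set` returns an `impala_samples` object;
#'   `write_sample_set` returns `samples` invisibly.
#' @export
write_sample_set <- function(samples, path) {
  obj <- list(
    meta = samples$meta, total = samples$total,
    pathways = lapply(seq_along(samples$paths), function(k) list(
      genes = samples$paths[[k]], count = samples$counts[k],
      energy = samples$energy[k],
      count_half1 = unname(samples$halves[k, 1L]),
      count_half2 = unname(samples$halves[k, 2L]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(samples)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  paths <- lapply(obj$pathways, function(p) unlist(p$genes))
  counts <- vapply(obj$pathways, function(p) as.integer(p$count), integer(1L))
  energy <- vapply(obj$pathways, function(p) as.numeric(p$energy),
                   numeric(1L))
  halves <- cbind(
    vapply(obj$pathways, function(p) as.numeric(p$count_half1), numeric(1L)),
    vapply(obj$pathways, function(p) as.numeric(p$count_half2), numeric(1L)))
  new_sample_set(paths, counts, halves, energy, obj$meta)
}

# ---- initialization --------------------------------------------------------

# Reverse view of a landscape: swap source/target, mirror the domains.
transpose_landscape <- function(land) {
  land$dom <- land$dom[rev(seq_len(land$L)), , drop = FALSE]
  land$domains <- rev(land$domains)
  tmp <- c(land$source, land$target)
  land$source <- tmp[2L]; land$target <- tmp[1L]
  tmp <- c(land$source_i, land$target_i)
  land$source_i <- tmp[2L]; land$target_i <- tmp[1L]
  land
}

dense_adjacency <- function(land) {
  S <- length(land$genes)
  a <- matrix(FALSE, S, S)
  for (g in seq_len(S)) a[g, land$adj[[g]]] <- TRUE
  a
}

#' Draw a uniformly distributed valid starting pathway
#'
#' Samples uniformly among all simple source-to-target paths of the
#' landscape's length that respect the per-position domains. A random walk is
#' drawn exactly uniformly over domain-respecting walks via dynamic
#' programming on walk counts, then rejected unless simple, which makes the
#' accepted draw uniform over simple paths.
#'
#' @param landscape internal landscape as built by the sampler (see
#'   [run_gist()]); exposed for testing via `build_landscape`.
#' @param max_restarts bound on rejection restarts before declaring the
#'   landscape infeasible.
#' @return character vector of pathway genes.
#' @export
initialize_pathway <- function(landscape, max_restarts = 10000L) {
  L <- landscape$L
  S <- length(landscape$genes)
  adjmat <- landscape$adjmat %||% dense_adjacency(landscape)
  counts <- matrix(0, L, S)
  counts[L, landscape$target_i] <- if (landscape$dom[L, landscape$target_i])
    1 else 0
  for (i in seq(L - 1L, 1L)) {
    counts[i, ] <- as.numeric(adjmat %*% counts[i + 1L, ]) *
      landscape$dom[i, ]
  }
  if (counts[1L, landscape$source_i] <= 0) {
    infeasible_error("no domain-respecting walk from ", landscape$source,
                     " to ", landscape$target, " of length ", L)
  }
  for (attempt in seq_len(max_restarts)) {
    path <- integer(L)
    path[1L] <- landscape$source_i
    ok <- TRUE
    for (i in seq(2L, L)) {
      cand <- landscape$adj[[path[i - 1L]]]
      w <- counts[i, cand]
      keep <- w > 0
      cand <- cand[keep]; w <- w[keep]
      if (length(cand) == 0L) { ok <- FALSE; break }
      nxt <- cand[sample.int(length(cand), 1L, prob = w)]
      if (nxt %in% path[seq_len(i - 1L)]) { ok <- FALSE; break }
      path[i] <- nxt
    }
    if (ok) return(landscape$genes[path])
  }
  infeasible_error("no valid simple path found after ", max_restarts,
                   " restarts (", landscape$source, " -> ",
                   landscape$target, ", L = ", L, ")")
}

# ---- conditional updates ---------------------------------------------------

#' Resample one interior pathway position from its full conditional
#'
#' Reference R implementation of the Gibbs conditional used by the compiled
#' sweep kernel: the candidate set for position `i` is every gene adjacent to
#' both neighbours, inside the position's domain and not already used
#' elsewhere on the path (the incumbent stays eligible); candidates are drawn
#' with probability proportional to
#' `exp((V1 + V2(prev, g) + V2(g, next) + dV3(g)) / T)` (with the configured
#' potential weights applied).
#'
#' @param genes current pathway as a character vector.
#' @param i interior position to resample (`1 < i < length(genes)`).
#' @param tables potential tables from [build_potential_tables()].
#' @param landscape internal landscape (see [run_gist()]).
#' @param reverse logical; score the flow potential against the reversed
#'   compartment order (reverse-search chains).
#' @return the updated pathway as an `impala_pathway`.
#' @export
conditional_sample_position <- function(genes, i, tables, landscape,
                                        reverse = FALSE) {
  L <- length(genes)
  if (i <= 1L || i >= L) stop("i must be an interior position", call. = FALSE)
  idx <- landscape$index[genes]
  prev <- idx[i - 1L]; nxt <- idx[i + 1L]; cur <- idx[i]
  cand <- intersect(landscape$adj[[prev]], landscape$adj[[nxt]])
  cand <- cand[landscape$dom[i, cand]]
  cand <- cand[!(cand %in% idx[-i]) ]
  stopifnot(cur %in% cand)
  w <- conditional_weights(cand, prev, nxt, tables, landscape, reverse)
  pick <- cand[sample.int(length(cand), 1L, prob = w)]
  genes[i] <- landscape$genes[pick]
  pathway(genes, tables, reverse = reverse)
}

conditional_weights <- function(cand, prev, nxt, tables, landscape, reverse) {
  g <- landscape$genes
  w123 <- tables$weights
  lam <- w123[3L] * tables$lambda / (landscape$L - 1L)
  ranks <- location_ranks(g, tables$location)
  if (reverse) ranks <- ifelse(ranks == 0L, 0L, 4L - ranks)
  cc <- function(a, b) as.numeric(a == 0L | b == 0L | b >= a)
  s <- w123[1L] * unname(tables$node[g[cand]]) +
    w123[2L] * (lookup_edge(tables, g[prev], g[cand]) +
                  lookup_edge(tables, g[cand], g[nxt])) +
    lam * (cc(ranks[prev], ranks[cand]) + cc(ranks[cand], ranks[nxt]))
  exp(s / tables$temperature - max(s / tables$temperature))
}

# ---- chains ----------------------------------------------------------------

#' Run one Gibbs chain over pathway space
#'
#' Performs `config$iterations` full sweeps (a sweep resamples every interior
#' position in order 2..L-1 from its exact conditional), discards the burn-in
#' prefix, and records one pathway sample per remaining sweep.
#'
#' @param config an [sampler_config()]; `config$direction` must be
#'   `"forward"` or `"reverse"` here (a chain runs one orientation).
#' @param landscape internal landscape for one (source, target, L), from
#'   `build_landscape`.
#' @param tables potential tables over the landscape's subnetwork.
#' @param seed integer seed, or `NULL` to consume the ambient RNG stream
#'   (used when an orchestrator seeds once and runs many chains).
#' @param dense optional precomputed dense score structures (internal).
#' @return an `impala_samples` object; reverse chains store pathways in
#'   sampling orientation (target to source) with `meta$direction =
#'   "reverse"`.
#' @export
run_chain <- function(config, landscape, tables, seed = config$seed,
                      dense = NULL) {
  if (config$direction == "both") {
    stop("run_chain runs a single orientation; set direction to 'forward' ",
         "or 'reverse'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  reverse <- config$direction == "reverse"
  land <- if (reverse) transpose_landscape(landscape) else landscape
  if (is.null(dense)) dense <- dense_tables(tables, landscape)
  land$adjmat <- dense$adjmat
  init <- initialize_pathway(land)
  burn <- floor(config$burnin * config$iterations)
  if (burn >= config$iterations) burn <- config$iterations - 1L
  locrank <- dense$locrank
  if (reverse) locrank <- ifelse(locrank == 0L, 0L, 4L - locrank)
  res <- .gibbs_sweeps(unname(land$index[init]), land$adj, dense$adjmat,
                       dense$wnode, dense$wedge, land$dom,
                       as.integer(locrank),
                       tables$weights[3L] * tables$lambda / (land$L - 1L),
                       config$temperature, config$iterations, burn)
  paths <- lapply(seq_len(nrow(res$paths)), function(r)
    land$genes[res$paths[r, ]])
  counts <- res$count_half1 + res$count_half2
  energy <- vapply(paths, pathway_energy, numeric(1L), tables = tables,
                   reverse = reverse)
  meta <- list(iterations = config$iterations, burnin = burn,
               temperature = config$temperature, seed = seed,
               direction = config$direction,
               source = land$source, target = land$target, L = land$L,
               chains = 1L)
  new_sample_set(paths, counts, cbind(res$count_half1, res$count_half2),
                 energy, meta)
}

# Dense score structures shared by all chains over one subnetwork.
dense_tables <- function(tables, landscape) {
  S <- length(landscape$genes)
  adjmat <- dense_adjacency(landscape)
  wedge <- matrix(0, S, S)
  e <- landscape$network$edges
  ia <- landscape$index[e[, 1L]]
  ib <- landscape$index[e[, 2L]]
  val <- tables$weights[2L] * unname(tables$edge[paste(e[, 1L], e[, 2L],
                                                       sep = "|")])
  wedge[cbind(ia, ib)] <- val
  wedge[cbind(ib, ia)] <- val
  list(adjmat = adjmat, wedge = wedge,
       wnode = tables$weights[1L] * unname(tables$node[landscape$genes]),
       locrank = as.integer(location_ranks(landscape$genes,
                                           tables$location)))
}

# Total-variation distance between the first- and second-half empirical
# distributions of a chain; a crude convergence diagnostic.
#' Split-half total-variation convergence diagnostic
#' @param samples an `impala_samples` object.
#' @return TV distance in `[0, 1]` between the two half-chain empirical
#'   pathway distributions.
#' @export
chain_split_tv <- function(samples) {
  h <- samples$halves
  p <- h[, 1L] / max(sum(h[, 1L]), 1)
  q <- h[, 2L] / max(sum(h[, 2L]), 1)
  sum(abs(p - q)) / 2
}

# ---- exact oracle ----------------------------------------------------------

#' Exhaustive enumeration oracle for small landscapes
#'
#' Enumerates every simple domain-respecting source-to-target path of the
#' landscape's length by depth-first search, computes exact Boltzmann
#' probabilities, and derives exact directed-edge probabilities by summing
#' pathway mass over the paths containing each oriented edge. Intended as a
#' test oracle; refuses instances with more paths than `cap`.
#'
#' @param landscape internal landscape (see [run_gist()]).
#' @param tables potential tables.
#' @param temperature Boltzmann temperature; defaults to the tables'.
#' @param cap maximum number of paths (default 10000).
#' @param reverse score V3 with the reversed compartment order.
#' @return list with `paths` (list of gene vectors), `energy`, `prob`
#'   (exact Boltzmann probabilities), and `edges`: data.frame
#'   `(from, to, mass, p)` where `mass` is the summed pathway probability of
#'   the oriented edge and `p = mass(i,j) / (mass(i,j) + mass(j,i))`.
#' @export
enumerate_exact <- function(landscape, tables, temperature = NULL,
                            cap = 10000L, reverse = FALSE) {
  L <- landscape$L
  found <- vector("list", 0L)
  path <- integer(L)
  path[1L] <- landscape$source_i
  n_found <- 0L
  dfs <- function(i) {
    if (i > L) return(invisible())
    for (g in landscape$adj[[path[i - 1L]]]) {
      if (!landscape$dom[i, g] || g %in% path[seq_len(i - 1L)]) next
      path[i] <<- g
      if (i == L) {
        if (g == landscape$target_i) {
          n_found <<- n_found + 1L
          if (n_found > cap) {
            stop("instance too large for exact oracle (> ", cap, " paths)",
                 call. = FALSE)
          }
          found[[n_found]] <<- landscape$genes[path]
        }
      } else {
        dfs(i + 1L)
      }
    }
    path[i] <<- 0L
  }
  if (L >= 2L) dfs(2L)
  if (n_found == 0L) {
    infeasible_error("no simple path of length ", L, " from ",
                     landscape$source, " to ", landscape$target)
  }
  energy <- vapply(found, pathway_energy, numeric(1L), tables = tables,
                   reverse = reverse)
  prob <- boltzmann_distribution(energy, temperature = temperature %||%
                                   tables$temperature)
  mass <- new.env(parent = emptyenv())
  for (k in seq_along(found)) {
    p <- found[[k]]
    for (j in seq_len(L - 1L)) {
      key <- paste(p[j], p[j + 1L], sep = "\t")
      assign(key, get0(key, envir = mass, ifnotfound = 0) + prob[k],
             envir = mass)
    }
  }
  keys <- sort(ls(mass))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[[`, character(1L), 1L),
    to = vapply(parts, `[[`, character(1L), 2L),
    mass = unname(unlist(mget(keys, envir = mass))))
  rev_mass <- vapply(seq_len(nrow(edges)), function(r) {
    get0(paste(edges$to[r], edges$from[r], sep = "\t"),
         envir = mass, ifnotfound = 0)
  }, numeric(1L))
  edges$p <- edges$mass / (edges$mass + rev_mass)
  rownames(edges) <- NULL
  list(paths = found, energy = energy, prob = prob, edges = edges)
}

# ---- edge probabilities ----------------------------------------------------

#' Estimate directed-edge probabilities from pooled pathway samples
#'
#' Each undirected interaction observed in any sampled pathway is modelled as
#' a Bernoulli orientation: `p(i -> j) = n(i -> j) / (n(i -> j) + n(j -> i))`
#' over pooled counts, where reverse-search samples are flipped back to
#' source-to-target orientation before counting. Equal counts give `p = 0.5`
#' (no directional confidence).
#'
#' @param forward `impala_samples` (any orientation metadata; sets whose
#'   `meta$direction == "reverse"` are flipped before counting).
#' @param reverse optional second `impala_samples` treated the same way.
#' @return data.frame `(from, to, p, support)` with one row per orientation
#'   of every observed interaction; `p(i,j) + p(j,i) = 1` and `support` is
#'   the number of samples containing the interaction in either orientation.
#' @export
estimate_edge_probabilities <- function(forward, reverse = NULL) {
  sets <- list(forward)
  if (!is.null(reverse)) sets <- c(sets, list(reverse))
  counts <- new.env(parent = emptyenv())
  n_total <- 0L
  for (s in sets) {
    flip <- identical(s$meta$direction %||% "forward", "reverse")
    n_total <- n_total + s$total
    for (k in seq_along(s$paths)) {
      p <- s$paths[[k]]
      if (flip) p <- rev(p)
      cnt <- s$counts[k]
      for (j in seq_len(length(p) - 1L)) {
        key <- paste(p[j], p[j + 1L], sep = "\t")
        assign(key, get0(key, envir = counts, ifnotfound = 0L) + cnt,
               envir = counts)
      }
    }
  }
  if (n_total == 0L) stop("empty pooled sample set", call. = FALSE)
  keys <- ls(counts)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  from <- vapply(parts, `[[`, character(1L), 1L)
  to <- vapply(parts, `[[`, character(1L), 2L)
  pair_a <- pmin(from, to); pair_b <- pmax(from, to)
  pairs <- unique(data.frame(a = pair_a, b = pair_b))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs$a[r]; b <- pairs$b[r]
    n_ab <- get0(paste(a, b, sep = "\t"), envir = counts, ifnotfound = 0L)
    n_ba <- get0(paste(b, a, sep = "\t"), envir = counts, ifnotfound = 0L)
    sup <- n_ab + n_ba
    data.frame(from = c(a, b), to = c(b, a),
               p = c(n_ab / sup, n_ba / sup), support = as.numeric(sup))
  }))
  normalize_directed_edges(out)
}

# ---- consensus -------------------------------------------------------------

#' Consensus network from the top sampled pathways
#'
#' Collapses the `top_k` distinct pathways with the highest sampling counts
#' (ties broken by higher energy, then lexicographic gene order) into one
#' directed network. Each gene is annotated with its total sampling
#' frequency over the full sample set and each edge with its pooled
#' directional probability.
#'
#' @param samples pooled `impala_samples` in source-to-target orientation.
#' @param top_k number of distinct pathways to collapse (default 200); when
#'   fewer are available all are used and a notice is logged.
#' @param edge_probs optional precomputed [estimate_edge_probabilities()]
#'   table; computed from `samples` when `NULL`.
#' @return object of class `impala_consensus`: list with `edges`
#'   (`from, to, p, support`, one row per directed consensus edge), `genes`
#'   (`gene, frequency`), `pathways` (the top paths), `top_k_used`.
#' @export
consensus_network <- function(samples, top_k = 200L, edge_probs = NULL) {
  top_k <- as.integer(top_k)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  n <- length(samples$paths)
  if (n < top_k) {
    impala_log("only ", n, " distinct pathways available for top_k = ",
               top_k, "; using all")
  }
  keys <- vapply(samples$paths, path_key, character(1L))
  o <- order(-samples$counts, -samples$energy, keys)
  take <- o[seq_len(min(top_k, n))]
  top_paths <- samples$paths[take]
  if (is.null(edge_probs)) edge_probs <- estimate_edge_probabilities(samples)
  ekey <- paste(edge_probs$from, edge_probs$to, sep = "\t")
  edge_set <- unique(do.call(rbind, lapply(top_paths, function(p) {
    L <- length(p)
    cbind(p[-L], p[-1L])
  })))
  m <- match(paste(edge_set[, 1L], edge_set[, 2L], sep = "\t"), ekey)
  edges <- normalize_directed_edges(data.frame(
    from = edge_set[, 1L], to = edge_set[, 2L],
    p = edge_probs$p[m], support = edge_probs$support[m]))
  genes <- sort(unique(as.vector(edge_set)))
  freq <- setNames(numeric(length(genes)), genes)
  for (k in seq_along(samples$paths)) {
    hit <- intersect(samples$paths[[k]], genes)
    freq[hit] <- freq[hit] + samples$counts[k]
  }
  structure(list(edges = edges,
                 genes = data.frame(gene = genes, frequency = unname(freq)),
                 pathways = top_paths, top_k_used = length(top_paths)),
            class = "impala_consensus")
}

#' @export
print.impala_consensus <- function(x, ...) {
  cat("impala consensus network:", nrow(x$genes), "genes,",
      nrow(x$edges), "directed edges from", x$top_k_used,
      "top pathways\n")
  invisible(x)
}

# ---- full GIST run ---------------------------------------------------------

#' Run GIST: Gibbs sampling of signal-transduction pathways
#'
#' End-to-end pathway inference: extract the source-centered candidate
#' subnetwork, precompute the potential tables, run forward and reverse
#' Gibbs chains for every (source, target, length) combination, pool the
#' samples, estimate edge-direction probabilities, and collapse the top
#' pathways into a consensus network.
#'
#' @param network an [interaction_network()] (carries location labels).
#' @param expr an [expression_matrix()].
#' @param config a [landscape_config()].
#' @param sampler a [sampler_config()].
#' @param weights numeric length 3: energy weights `(w1, w2, w3)`.
#' @param lambda `"auto"` or fixed V3 scale (see
#'   [build_potential_tables()]).
#' @param cap_p significance cap for the potential z-scores.
#' @return object of class `impala_gist`: list with `samples` (pooled,
#'   source-to-target oriented), `forward`, `reverse` (orientation-specific
#'   pools, possibly `NULL`), `edges` (directed-edge probabilities),
#'   `consensus`, `tables`, `subnetwork`, `landscape_config`,
#'   `sampler_config`, and `skipped` (infeasible combinations).
#' @export
run_gist <- function(network, expr, config, sampler = sampler_config(),
                     weights = c(1, 1, 1), lambda = "auto", cap_p = 1e-16) {
  stopifnot(inherits(config, "impala_landscape_config"),
            inherits(sampler, "impala_sampler_config"))
  set.seed(sampler$seed)
  subnet <- extract_subnetwork(network, config$sources, config$radius)
  if (!config$location_prior) weights[3L] <- 0
  tables <- build_potential_tables(subnet, expr, weights = weights,
                                   temperature = sampler$temperature,
                                   lambda = lambda, cap_p = cap_p)
  dirs <- switch(sampler$direction, both = c("forward", "reverse"),
                 sampler$direction)
  per_chain <- as.integer(ceiling(sampler$iterations / sampler$chains))
  chain_cfg <- sampler
  chain_cfg$iterations <- per_chain
  fwd <- list(); rev_ <- list(); skipped <- character()
  base <- NULL
  for (src in config$sources) {
    for (tgt in config$targets) {
      if (identical(src, tgt)) next
      if (!tgt %in% subnet$genes) {
        skipped <- c(skipped, paste0(src, "->", tgt, " (target outside ",
                                     "radius-", config$radius, " landscape)"))
        next
      }
      for (L in config$lengths) {
        land <- tryCatch(build_landscape(subnet, src, tgt, L),
                         impala_infeasible = function(e) NULL,
                         error = function(e) {
                           if (inherits(e, "impala_infeasible")) NULL
                           else stop(e)
                         })
        if (is.null(land)) {
          skipped <- c(skipped, paste0(src, "->", tgt, " L=", L))
          next
        }
        if (is.null(base)) base <- dense_tables(tables, land)
        for (dir in dirs) {
          chain_cfg$direction <- dir
          for (ch in seq_len(sampler$chains)) {
            s <- tryCatch(run_chain(chain_cfg, land, tables, seed = NULL,
                                    dense = base),
                          impala_infeasible = function(e) NULL)
            if (is.null(s)) {
              skipped <- c(skipped, paste0(src, "->", tgt, " L=", L,
                                           " ", dir))
              break
            }
            if (dir == "forward") fwd <- c(fwd, list(s))
            else rev_ <- c(rev_, list(s))
          }
        }
      }
    }
  }
  if (length(fwd) + length(rev_) == 0L) {
    infeasible_error("no feasible (source, target, length) combination; ",
                     "skipped: ", paste(skipped, collapse = "; "))
  }
  fwd_all <- if (length(fwd) > 0L) merge_sample_sets(fwd) else NULL
  rev_all <- if (length(rev_) > 0L) merge_sample_sets(rev_) else NULL
  edges <- estimate_edge_probabilities(fwd_all %||% rev_all,
                                       if (!is.null(fwd_all)) rev_all)
  pooled <- merge_sample_sets(c(
    if (!is.null(fwd_all)) list(fwd_all),
    if (!is.null(rev_all)) list(reorient_samples(rev_all, tables))))
  pooled$meta$direction <- "forward"
  pooled$meta$combination <- "pooled forward + flipped reverse counts"
  consensus <- consensus_network(pooled, top_k = sampler$top_k,
                                 edge_probs = edges)
  structure(list(samples = pooled, forward = fwd_all, reverse = rev_all,
                 edges = edges, consensus = consensus, tables = tables,
                 subnetwork = subnet, landscape_config = config,
                 sampler_config = sampler, skipped = skipped),
            class = "impala_gist")
}

#' @export
print.impala_gist <- function(x, ...) {
  cat("impala GIST run:", x$samples$total, "pooled samples,",
      length(x$samples$paths), "distinct pathways,",
      nrow(x$edges) / 2, "oriented interactions\n")
  invisible(x)
}
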