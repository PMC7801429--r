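#' Simulation scenario
#'
#' Describes one synthetic benchmark world: planted directed pathways between
#' source and target genes, decoy genes and false interactions diluting the
#' network, and a two-condition expression matrix with latent co-expression
#' along the planted paths.
#'
#' @param type `"I"` (alternative pathways between a single source and a
#'   single target) or `"II"` (multiple pathways with crosstalk among
#'   multiple sources and targets).
#' @param n_paths number of planted true pathways (>= 1).
#' @param length_range integer vector of admissible pathway lengths (genes
#'   per path), default `4:6`.
#' @param intermediate_pool size of the shared intermediate gene pool.
#'   `NULL` (default) allocates disjoint intermediates to each path
#'   (strictly alternative routes); a finite pool makes paths share genes.
#'   Type II always shares (default pool `round(0.7 *` total needed`)`).
#' @param decoy_genes number of decoy genes carrying no pathway signal
#'   (default 0); decoy interactions attach to true and decoy genes alike.
#' @param phi false-interaction fraction in `[0, 1]`: `round(phi * n)` decoy
#'   edges are added, `n` = number of true undirected interactions.
#' @param sigma2 Gaussian expression noise variance, relative to the unit
#'   variance of the latent pathway signal.
#' @param samples_per_group samples in each of the two condition groups
#'   (equal sizes; >= 4 so correlation z-scores are defined).
#' @param effect_size between-group mean shift applied to every true-pathway
#'   gene (sign fixed per gene), default 1.
#' @param decay latent-signal propagation coefficient along a path edge
#'   (default 0.8); adjacent true genes have correlation about
#'   `decay / (1 + sigma2)`.
#' @param n_sources,n_targets source/target counts for type II (default 2
#'   each; forced to 1 for type I).
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class `impala_scenario`.
#' @export
simulation_scenario <- function(type = c("I", "II"), n_paths,
                                length_range = 4:6,
                                intermediate_pool = NULL, decoy_genes = 0L,
                                phi = 0, sigma2 = 0, samples_per_group = 20L,
                                effect_size = 1, decay = 0.8,
                                n_sources = 2L, n_targets = 2L, seed = 1L) {
  type <- match.arg(type)
  n_paths <- as.integer(n_paths)
  length_range <- sort(unique(as.integer(length_range)))
  if (n_paths < 1L) stop("need >= 1 true pathway", call. = FALSE)
  if (any(length_range < 3L)) stop("pathway lengths must be >= 3",
                                   call. = FALSE)
  if (phi < 0 || phi > 1) stop("phi must be in [0, 1]", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  samples_per_group <- as.integer(samples_per_group)
  if (samples_per_group < 4L) {
    stop("samples per group must be >= 4 (correlation z needs m >= 4)",
         call. = FALSE)
  }
  if (type == "I") { n_sources <- 1L; n_targets <- 1L }
  structure(list(type = type, n_paths = n_paths,
                 length_range = length_range,
                 intermediate_pool = intermediate_pool,
                 decoy_genes = as.integer(decoy_genes), phi = phi,
                 sigma2 = sigma2, samples_per_group = samples_per_group,
                 effect_size = effect_size, decay = decay,
                 n_sources = as.integer(n_sources),
                 n_targets = as.integer(n_targets),
                 seed = as.integer(seed)),
            class = "impala_scenario")
}

#' Simulate a network with planted pathways and decoy interactions
#'
#' Plants `n_paths` directed source-to-target pathways (each intermediate
#' gene carries a global depth, and path intermediates are laid out in depth
#' order, so the planted edge set is conflict-free: no interaction is planted
#' in both orientations). The observed network is the planted edge set with
#' direction stripped plus `round(phi * |true edges|)` uniformly random decoy
#' interactions that never duplicate a true one. Locations follow signal
#' flow: sources are membrane, intermediates cytoplasm, targets nucleus;
#' decoy genes get random labels.
#'
#' @param scenario an [simulation_scenario()].
#' @return list with `network` (an [interaction_network()] with locations)
#'   and `truth`: list with `paths` (list of gene vectors), `genes`,
#'   `edges` (directed two-column matrix), `sources`, `targets`, `depth`
#'   (named numeric used for topological ordering).
#' @export
simulate_network <- function(scenario) {
  set.seed(scenario$seed)
  sources <- sprintf("SRC%02d", seq_len(scenario$n_sources))
  targets <- sprintf("TGT%02d", seq_len(scenario$n_targets))
  lengths <- scenario$length_range[sample.int(length(scenario$length_range),
                                              scenario$n_paths,
                                              replace = TRUE)]
  need <- sum(lengths - 2L)
  pool_n <- scenario$intermediate_pool
  if (is.null(pool_n)) {
    pool_n <- if (scenario$type == "I") need else max(3L, round(0.7 * need))
  }
  pool_n <- as.integer(pool_n)
  pool <- sprintf("G%04d", seq_len(pool_n))
  depth <- setNames(runif(pool_n), pool)
  paths <- vector("list", scenario$n_paths)
  if (is.null(scenario$intermediate_pool) && scenario$type == "I") {
    # disjoint allocation: strictly alternative routes
    if (pool_n < need) stop("intermediate pool too small", call. = FALSE)
    alloc <- split(sample(pool, need), rep(seq_len(scenario$n_paths),
                                           lengths - 2L))
  } else {
    if (pool_n < max(lengths) - 2L) {
      stop("intermediate pool smaller than the longest path's interior",
           call. = FALSE)
    }
    alloc <- lapply(seq_len(scenario$n_paths), function(k)
      sample(pool, lengths[k] - 2L))
  }
  pair_src <- rep_len(sources, scenario$n_paths)
  pair_tgt <- rep_len(rep(targets, each = length(sources)),
                      scenario$n_paths)
  for (k in seq_len(scenario$n_paths)) {
    mid <- alloc[[k]][order(depth[alloc[[k]]])]
    paths[[k]] <- c(pair_src[k], mid, pair_tgt[k])
  }
  if (scenario$type == "II" && scenario$n_paths >= 2L) {
    # construction guarantee: the first two paths share an intermediate
    shared <- paths[[1L]][2L]
    p2 <- paths[[2L]]
    if (!shared %in% p2) {
      mid <- unique(c(shared, p2[-c(1L, length(p2))]))[seq_len(length(p2) - 2L)]
      paths[[2L]] <- c(p2[1L], mid[order(depth[mid])], p2[length(p2)])
    }
  }
  tedges <- unique(do.call(rbind, lapply(paths, function(p) {
    L <- length(p)
    cbind(p[-L], p[-1L])
  })))
  true_genes <- sort(unique(unlist(paths)))
  decoys <- if (scenario$decoy_genes > 0L)
    sprintf("D%04d", seq_len(scenario$decoy_genes)) else character()
  all_genes <- c(true_genes, decoys)
  n_true <- nrow(tedges)
  n_decoy_edges <- round(scenario$phi * n_true)
  true_key <- paste(pmin(tedges[, 1L], tedges[, 2L]),
                    pmax(tedges[, 1L], tedges[, 2L]))
  dedges <- matrix(character(), ncol = 2L)
  if (n_decoy_edges > 0L) {
    ng <- length(all_genes)
    max_edges <- ng * (ng - 1L) / 2 - n_true
    if (n_decoy_edges > max_edges) {
      stop("requested decoy edges exceed available non-edges", call. = FALSE)
    }
    got <- character(0)
    rows <- list()
    while (length(got) < n_decoy_edges) {
      a <- sample(all_genes, 1L); b <- sample(all_genes, 1L)
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (key %in% true_key || key %in% got) next
      got <- c(got, key)
      rows[[length(rows) + 1L]] <- c(a, b)
    }
    dedges <- do.call(rbind, rows)
  }
  loc <- setNames(rep("cytoplasm", length(all_genes)), all_genes)
  loc[sources] <- "membrane"
  loc[targets] <- "nucleus"
  if (length(decoys) > 0L) {
    loc[decoys] <- sample(valid_locations, length(decoys), replace = TRUE)
  }
  net <- interaction_network(rbind(tedges, dedges), genes = all_genes,
                             locations = loc)
  depth_all <- c(setNames(rep(-1, length(sources)), sources),
                 depth,
                 setNames(rep(2, length(targets)), targets))
  list(network = net,
       truth = list(paths = paths, genes = true_genes, edges = tedges,
                    sources = sources, targets = targets,
                    depth = depth_all),
       scenario = scenario)
}

#' Simulate two-condition expression over a planted network
#'
#' True-pathway genes carry a latent signal propagated along the planted
#' paths (`signal(child) = decay * mean(signal(parents)) +
#' sqrt(1 - decay^2) * innovation`, unit marginal variance), inducing
#' positive correlation along true edges; condition two additionally shifts
#' each true gene's mean by `effect_size` with a per-gene fixed sign. The
#' two equal-sized groups share the latent draws by within-group sample
#' index (a paired design), so at `sigma2 = 0` the group mean difference of
#' every true gene equals the effect size exactly. Decoy genes get
#' independent noise only. Gaussian noise of variance `sigma2` (relative to
#' the unit signal variance) is added everywhere.
#'
#' @param network the simulated [interaction_network()].
#' @param truth ground truth from [simulate_network()].
#' @param scenario the [simulation_scenario()].
#' @return an [expression_matrix()] over all network genes; group labels are
#'   `"A"`/`"B"`.
#' @export
simulate_expression <- function(network, truth, scenario) {
  set.seed(scenario$seed + 1000003L)
  genes <- network$genes
  spg <- scenario$samples_per_group
  m <- 2L * spg
  # latent signals for true genes, propagated in depth order
  tg <- truth$genes
  ord <- tg[order(truth$depth[tg])]
  parents <- lapply(setNames(ord, ord), function(g)
    unique(truth$edges[truth$edges[, 2L] == g, 1L]))
  sig <- matrix(0, nrow = length(ord), ncol = spg,
                dimnames = list(ord, NULL))
  dec <- scenario$decay
  for (g in ord) {
    innov <- rnorm(spg)
    pa <- parents[[g]]
    sig[g, ] <- if (length(pa) == 0L) innov else
      dec * colMeans(sig[pa, , drop = FALSE]) + sqrt(1 - dec^2) * innov
  }
  sign_g <- setNames(sample(c(-1, 1), length(tg), replace = TRUE), tg)
  x <- matrix(0, nrow = length(genes), ncol = m,
              dimnames = list(genes, sprintf("S%03d", seq_len(m))))
  x[ord, seq_len(spg)] <- sig
  x[ord, spg + seq_len(spg)] <- sig +
    scenario$effect_size * sign_g[ord]
  decoys <- setdiff(genes, tg)
  if (length(decoys) > 0L) {
    x[decoys, ] <- rnorm(length(decoys) * m)
  }
  if (scenario$sigma2 > 0) {
    x <- x + rnorm(length(x), sd = sqrt(scenario$sigma2))
  }
  expression_matrix(x, rep(c("A", "B"), each = spg))
}

#' Precision / recall / F1 of predicted pathway genes
#'
#' @param predicted character vector of predicted genes.
#' @param truth ground truth from [simulate_network()] (or a character
#'   vector of true genes).
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`, and
#'   `empty_prediction` flag (empty predictions report precision 0).
#' @export
evaluate_genes <- function(predicted, truth) {
  true_genes <- if (is.list(truth)) truth$genes else as.character(truth)
  predicted <- unique(as.character(predicted))
  tp <- length(intersect(predicted, true_genes))
  fp <- length(setdiff(predicted, true_genes))
  fn <- length(setdiff(true_genes, predicted))
  empty <- length(predicted) == 0L
  precision <- if (empty) 0 else tp / (tp + fp)
  recall <- if (length(true_genes) == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, empty_prediction = empty)
}

#' Precision / recall / F1 of predicted directed edges
#'
#' An edge is called `i -> j` when its direction probability meets the
#' threshold. A predicted edge whose gene pair is true but whose orientation
#' is wrong counts as a false positive (and the true orientation stays a
#' false negative).
#'
#' @param edges data.frame `(from, to, p, ...)` as produced by
#'   [estimate_edge_probabilities()] or found in `run_gist(...)$consensus`.
#' @param truth ground truth from [simulate_network()] (or a two-column
#'   directed edge matrix).
#' @param threshold direction-probability call threshold in `(0.5, 1]`
#'   (default 0.6).
#' @return as [evaluate_genes()].
#' @export
evaluate_edges <- function(edges, truth, threshold = 0.6) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must be in (0.5, 1]", call. = FALSE)
  }
  te <- if (is.list(truth) && !is.data.frame(truth)) truth$edges else truth
  true_keys <- unique(paste(te[, 1L], te[, 2L], sep = "\t"))
  called <- edges[!is.na(edges$p) & edges$p >= threshold, , drop = FALSE]
  pred_keys <- unique(paste(called$from, called$to, sep = "\t"))
  tp <- length(intersect(pred_keys, true_keys))
  fp <- length(setdiff(pred_keys, true_keys))
  fn <- length(setdiff(true_keys, pred_keys))
  empty <- length(pred_keys) == 0L
  precision <- if (empty) 0 else tp / (tp + fp)
  recall <- if (length(true_keys) == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, empty_prediction = empty)
}

#' Run the simulation benchmark grid
#'
#' For every (noise variance, false-interaction fraction, seed) cell:
#' simulate a network and expression matrix, run GIST end to end, and score
#' gene and edge identification of the consensus network against the planted
#' truth. Cell failures are recorded and the run continues.
#'
#' @param sigma2_levels,phi_levels numeric grids (defaults `c(0.2, 0.5,
#'   0.8)` and `c(0.1, 0.3, 0.5)`).
#' @param seeds integer vector of replicate seeds (default `1:5`).
#' @param base_scenario an [simulation_scenario()] providing every field
#'   except `sigma2`, `phi`, `seed`; the default is the type I world at the
#'   reference scale (~260 genes, ~1000 interactions at `phi = 0.3`):
#'   250 planted paths of length 4-6 over a 158-gene intermediate pool with
#'   100 decoy genes.
#' @param sampler an [sampler_config()] for the GIST runs.
#' @param threshold edge-call threshold, see [evaluate_edges()].
#' @return data.frame with one row per cell: `type, sigma2, phi, seed,
#'   gene_precision, gene_recall, gene_f1, edge_precision, edge_recall,
#'   edge_f1, n_genes, n_edges, error`. The summary (mean and sd by
#'   `(sigma2, phi)`) is attached as attribute `"summary"`.
#' @export
run_benchmark <- function(sigma2_levels = c(0.2, 0.5, 0.8),
                          phi_levels = c(0.1, 0.3, 0.5), seeds = 1:5,
                          base_scenario = NULL,
                          sampler = sampler_config(), threshold = 0.6) {
  if (is.null(base_scenario)) {
    base_scenario <- simulation_scenario(
      type = "I", n_paths = 250L, length_range = 4:6,
      intermediate_pool = 158L, decoy_genes = 100L,
      samples_per_group = 20L, effect_size = 1)
  }
  rows <- list()
  for (s2 in sigma2_levels) for (ph in phi_levels) for (sd_ in seeds) {
    scen <- base_scenario
    scen$sigma2 <- s2; scen$phi <- ph; scen$seed <- as.integer(sd_)
    row <- data.frame(type = scen$type, sigma2 = s2, phi = ph, seed = sd_,
                      gene_precision = NA_real_, gene_recall = NA_real_,
                      gene_f1 = NA_real_, edge_precision = NA_real_,
                      edge_recall = NA_real_, edge_f1 = NA_real_,
                      n_genes = NA_integer_, n_edges = NA_integer_,
                      error = "")
    res <- tryCatch({
      cell <- benchmark_cell(scen, sampler, threshold)
      row[names(cell)] <- cell
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out[out$error == "", , drop = FALSE]
  if (nrow(ok) > 0L) {
    agg <- stats::aggregate(
      ok[c("gene_precision", "edge_precision", "gene_recall",
           "edge_recall")],
      by = ok[c("sigma2", "phi")], FUN = mean)
    attr(out, "summary") <- agg
  }
  out
}

# One benchmark cell: simulate, run GIST, score.
benchmark_cell <- function(scenario, sampler, threshold) {
  sim <- simulate_network(scenario)
  expr <- simulate_expression(sim$network, sim$truth, scenario)
  cfg <- landscape_config(
    sources = sim$truth$sources, targets = sim$truth$targets,
    radius = max(scenario$length_range) - 1L,
    lengths = scenario$length_range)
  sampler$seed <- scenario$seed + 20000L
  fit <- run_gist(sim$network, expr, cfg, sampler)
  # gene identification: the consensus network's nodes (top-k pathways);
  # edge identification: every interaction whose pooled direction
  # probability passes the call threshold
  g <- evaluate_genes(fit$consensus$genes$gene, sim$truth)
  e <- evaluate_edges(fit$edges, sim$truth, threshold = threshold)
  list(gene_precision = g$precision, gene_recall = g$recall, gene_f1 = g$f1,
       edge_precision = e$precision, edge_recall = e$recall,
       edge_f1 = e$f1, n_genes = network_gene_count(sim$network),
       n_edges = network_edge_count(sim$network))
}

#' Planted pathway-family sample sets (SOUL fixture generator)
#'
#' Builds a synthetic pooled sample set made of `k` structurally coherent
#' pathway families: pathways within a family share most of a family core
#' (Jaccard >= ~0.6 within), families are mutually near-disjoint except for
#' designated shared hub genes, and the families carry unequal sampling
#' masses. This is the stated world for module-recovery checks: what the
#' clustering stage sees after a well-mixed GIST run on a multi-modal
#' landscape.
#'
#' @param k number of families (>= 2).
#' @param paths_per_family distinct pathways per family (default 10).
#' @param core_size genes in a family core (default 10).
#' @param n_swap intermediates swapped out per non-modal pathway (default 1;
#'   pairwise within-family Jaccard is then at least
#'   `(core_size - 2 * n_swap) / (core_size + 2 * n_swap)`).
#' @param hub_genes character vector of hub genes included in **every**
#'   family (crosstalk ground truth); default none.
#' @param masses per-family total sampling counts (default
#'   `600 * (k - f + 2)` for family `f`: clearly unequal but of one order of
#'   magnitude, as in a reordered sampling landscape with several credible
#'   modules; mass ratios much beyond ~4x push the lightest module's hump
#'   below the default 10% prominence bar, see the methods vignette).
#' @param seed integer seed.
#' @return list with `samples` (an `impala_samples` object), `family` (named
#'   integer: distinct pathway key -> family), `hubs`.
#' @export
simulate_pathway_families <- function(k, paths_per_family = 10L,
                                      core_size = 10L, n_swap = 1L,
                                      hub_genes = character(), masses = NULL,
                                      seed = 1L) {
  stopifnot(k >= 2L, core_size >= 4L, n_swap >= 1L,
            n_swap < core_size - 2L)
  set.seed(seed)
  if (is.null(masses)) masses <- 600L * (k - seq_len(k) + 2L)
  stopifnot(length(masses) == k)
  paths <- list(); counts <- integer(); family <- integer()
  for (f in seq_len(k)) {
    core <- c(sprintf("F%d_SRC", f),
              sprintf("F%d_G%02d", f, seq_len(core_size - 2L -
                                                length(hub_genes))),
              hub_genes, sprintf("F%d_TGT", f))
    spares <- sprintf("F%d_X%02d", f, seq_len(n_swap * paths_per_family))
    # modal pathway = the core itself; the rest swap a few interiors
    fam_paths <- list(core)
    for (p in seq_len(paths_per_family - 1L)) {
      pp <- core
      interior <- seq(2L, length(core) - 1L)
      swap_at <- sample(interior, n_swap)
      pp[swap_at] <- spares[(p - 1L) * n_swap + seq_len(n_swap)]
      fam_paths[[p + 1L]] <- pp
    }
    # modal pathway dominates the family mass
    w <- c(0.5, rep(0.5 / (paths_per_family - 1L), paths_per_family - 1L))
    cnt <- pmax(1L, round(masses[f] * w))
    paths <- c(paths, fam_paths)
    counts <- c(counts, cnt)
    family <- c(family, rep(f, paths_per_family))
  }
  names(family) <- vapply(paths, path_key, character(1L))
  energy <- rep(0, length(paths))
  halves <- cbind(floor(counts / 2), ceiling(counts / 2))
  samples <- new_sample_set(paths, counts, halves, energy,
                            meta = list(direction = "forward",
                                        synthetic = "planted families",
                                        seed = seed))
  list(samples = samples, family = family, hubs = hub_genes)
}
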