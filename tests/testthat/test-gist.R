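# A small ergodic landscape used by several chain tests: diamond with a
# shared middle gene so single-site updates can hop between the two routes.
#   A - B - C - T
#   A - D - C - T   (paths of length 4 differing at position 2 only)
diamond_fixture <- function(node = NULL) {
  edges <- cbind(c("A", "A", "B", "D", "C"),
                 c("B", "D", "C", "C", "T"))
  net <- suppressMessages(interaction_network(edges))
  if (is.null(node)) node <- setNames(rep(0, 5), net$genes)
  tab <- manual_tables(node, net$edges,
                       rep(0, nrow(net$edges))[seq_len(nrow(net$edges))],
                       lambda = 0)
  land <- build_landscape(net, "A", "T", 4L)
  list(net = net, tab = tab, land = land)
}

test_that("initialize_pathway is deterministic and exact on a forced path", {
  tri <- suppressMessages(interaction_network(
    cbind(c("A", "B", "A"), c("B", "C", "C"))))
  tab <- manual_tables(c(A = 0, B = 0, C = 0), tri$edges, rep(0, 3))
  land <- build_landscape(tri, "A", "C", 3L)
  set.seed(1)
  expect_equal(initialize_pathway(land), c("A", "B", "C"))
  set.seed(42); p1 <- initialize_pathway(land)
  set.seed(42); p2 <- initialize_pathway(land)
  expect_identical(p1, p2)
})

test_that("initialize_pathway draws uniformly over the enumeration oracle's paths", {
  edges <- oracle_er_edges(30, 0.15, seed = 13)
  net <- suppressMessages(interaction_network(
    edges, genes = sprintf("g%02d", 1:30)))
  adj <- oracle_adjacency(edges, genes = net$genes)
  L <- 4L
  oracle_paths <- oracle_enumerate_paths(adj, "g01", "g30", L)
  expect_gte(length(oracle_paths), 3L)   # 8 paths at this seed
  land <- build_landscape(net, "g01", "g30", L)
  set.seed(99)
  n_draw <- 10000L
  draws <- vapply(seq_len(n_draw), function(i)
    paste(initialize_pathway(land), collapse = "|"), character(1L))
  keys <- vapply(oracle_paths, paste, character(1L), collapse = "|")
  expect_setequal(unique(draws), keys)
  k <- length(keys)
  p0 <- 1 / k
  sigma <- sqrt(p0 * (1 - p0) / n_draw)
  freq <- as.vector(table(factor(draws, levels = keys))) / n_draw
  expect_true(all(abs(freq - p0) < 4 * sigma))
})

test_that("initialize_pathway flags infeasible landscapes", {
  # the only A-B route is the direct edge: no simple path with 3 genes
  seg <- suppressMessages(interaction_network(cbind("A", "B")))
  land <- build_landscape(seg, "A", "B", 3L)
  expect_error(initialize_pathway(land), class = "impala_infeasible")
  # and a target further than L - 1 steps is rejected when domains are built
  chain <- suppressMessages(interaction_network(
    cbind(c("A", "B", "C"), c("B", "C", "D"))))
  expect_error(build_landscape(chain, "A", "D", 3L),
               class = "impala_infeasible")
})

test_that("conditional_sample_position keeps forced positions and honours ratios", {
  fx <- diamond_fixture()
  # position 3 (gene C) has a single candidate: unchanged
  set.seed(2)
  out <- conditional_sample_position(c("A", "B", "C", "T"), 3L, fx$tab,
                                     fx$land)
  expect_equal(out$genes, c("A", "B", "C", "T"))

  # two equal-energy candidates at position 2: 50/50 within 3 sigma
  set.seed(3)
  picks <- vapply(seq_len(10000L), function(i)
    conditional_sample_position(c("A", "B", "C", "T"), 2L, fx$tab,
                                fx$land)$genes[2L], character(1L))
  p_hat <- mean(picks == "B")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))

  # unequal node scores: empirical ratio matches exp(dU/T)
  node <- c(A = 0, B = 1.2, C = 0, D = 0.4, T = 0)
  fx2 <- diamond_fixture(node)
  w <- exp(c(1.2, 0.4))
  p_b <- w[1] / sum(w)
  set.seed(4)
  picks <- vapply(seq_len(10000L), function(i)
    conditional_sample_position(c("A", "D", "C", "T"), 2L, fx2$tab,
                                fx2$land)$genes[2L], character(1L))
  p_hat <- mean(picks == "B")
  expect_lt(abs(p_hat - p_b), 3 * sqrt(p_b * (1 - p_b) / 10000))
})

test_that("run_chain is exact on a forced landscape and bitwise reproducible", {
  tri <- suppressMessages(interaction_network(
    cbind(c("A", "B"), c("B", "C"))))
  tab <- manual_tables(c(A = 0, B = 0, C = 0), tri$edges, rep(0, 2))
  land <- build_landscape(tri, "A", "C", 3L)
  cfg <- sampler_config(iterations = 200, burnin = 0.2,
                        direction = "forward", seed = 5)
  s <- run_chain(cfg, land, tab)
  expect_equal(length(s$paths), 1L)
  expect_equal(s$paths[[1L]], c("A", "B", "C"))
  expect_equal(s$total, 200L - 40L)   # one sample per post-burn-in sweep
  expect_identical(run_chain(cfg, land, tab), s)
  expect_error(run_chain(sampler_config(direction = "both"), land, tab),
               "single orientation")
})

test_that("chain frequencies converge to the exact Boltzmann distribution", {
  node <- c(A = 0, B = 0.9, C = 0, D = 0.1, T = 0)
  fx <- diamond_fixture(node)
  exact <- enumerate_exact(fx$land, fx$tab)
  expect_equal(length(exact$prob), 2L)
  s <- run_chain(sampler_config(iterations = 20000, direction = "forward",
                                seed = 11), fx$land, fx$tab)
  emp <- empirical_over(s, exact$paths)
  expect_lt(tv_distance(emp, exact$prob), 0.02)
  # doubling the sweeps with the same seed keeps the modal pathway
  s2 <- run_chain(sampler_config(iterations = 40000, direction = "forward",
                                 seed = 11), fx$land, fx$tab)
  expect_equal(s$paths[[which.max(s$counts)]],
               s2$paths[[which.max(s2$counts)]])
})

test_that("reverse chains sample the transposed problem", {
  loc <- c(A = "membrane", B = "cytoplasm", C = "cytoplasm",
           D = "other", T = "nucleus")
  edges <- cbind(c("A", "A", "B", "D", "C"), c("B", "D", "C", "C", "T"))
  net <- suppressMessages(interaction_network(edges, locations = loc))
  tab <- manual_tables(setNames(rep(0, 5), sort(unique(as.vector(edges)))),
                       net$edges, rep(0, nrow(net$edges)),
                       locations = net$location, lambda = 1)
  land <- build_landscape(net, "A", "T", 4L)
  s <- run_chain(sampler_config(iterations = 500, direction = "reverse",
                                seed = 13), land, tab)
  # sampled in target -> source orientation
  expect_true(all(vapply(s$paths, function(p) p[1L] == "T", logical(1L))))
  expect_equal(s$meta$direction, "reverse")
  # energies stored under the reversed compartment order
  expect_equal(s$energy,
               vapply(s$paths, pathway_energy, numeric(1L), tables = tab,
                      reverse = TRUE))
})

test_that("enumerate_exact agrees with an independent normalization", {
  set.seed(31)
  for (trial in 1:5) {
    edges <- oracle_er_edges(9, 0.5, seed = 300 + trial)
    net <- suppressMessages(interaction_network(
      edges, genes = sprintf("g%02d", 1:9)))
    adj <- oracle_adjacency(edges, genes = net$genes)
    node <- setNames(runif(9, 0, 2), net$genes)
    scores <- runif(nrow(net$edges))
    tab <- manual_tables(node, net$edges, scores, temperature = 0.8)
    land <- tryCatch(build_landscape(net, "g01", "g09", 4L),
                     error = function(e) NULL)
    if (is.null(land)) next
    oracle_paths <- oracle_enumerate_paths(adj, "g01", "g09", 4L)
    if (length(oracle_paths) == 0L) next
    ex <- enumerate_exact(land, tab)
    expect_setequal(vapply(ex$paths, paste, character(1L), collapse = "|"),
                    vapply(oracle_paths, paste, character(1L),
                           collapse = "|"))
    u <- vapply(oracle_paths, pathway_energy, numeric(1L), tables = tab)
    w <- exp(u / 0.8 - max(u / 0.8))
    p_oracle <- w / sum(w)
    o <- match(vapply(ex$paths, paste, character(1L), collapse = "|"),
               vapply(oracle_paths, paste, character(1L), collapse = "|"))
    expect_equal(ex$prob, p_oracle[o], tolerance = 1e-12)
    # edge probabilities: mass ratios per unordered pair
    for (r in seq_len(nrow(ex$edges))) {
      fr <- ex$edges$from[r]; to <- ex$edges$to[r]
      m_f <- sum(p_oracle[vapply(oracle_paths, function(p) {
        i <- match(fr, p); !is.na(i) && i < length(p) && p[i + 1L] == to
      }, logical(1L))])
      expect_equal(ex$edges$mass[r], m_f, tolerance = 1e-12)
    }
  }
  # degenerate cases
  tri <- suppressMessages(interaction_network(cbind(c("A", "B"),
                                                    c("B", "C"))))
  tab <- manual_tables(c(A = 0, B = 0, C = 0), tri$edges, rep(0, 2))
  land <- build_landscape(tri, "A", "C", 3L)
  ex <- enumerate_exact(land, tab)
  expect_equal(ex$prob, 1)
  fx <- diamond_fixture()
  ex2 <- enumerate_exact(fx$land, fx$tab)
  expect_equal(sort(ex2$prob), c(0.5, 0.5))
  expect_error(enumerate_exact(fx$land, fx$tab, cap = 1), "too large")
})

test_that("estimate_edge_probabilities pools, flips and normalizes", {
  mk <- function(paths, counts, direction = "forward") {
    impala:::new_sample_set(paths, counts,
                            cbind(counts, 0L), rep(0, length(paths)),
                            meta = list(direction = direction))
  }
  fwd <- mk(list(c("A", "B", "C")), 10L)
  e <- estimate_edge_probabilities(fwd)
  expect_equal(e$p[e$from == "A" & e$to == "B"], 1)
  expect_equal(e$p[e$from == "B" & e$to == "A"], 0)

  # equal counts in both orientations -> 0.5 (no directional confidence)
  both <- mk(list(c("A", "B"), c("B", "A")), c(5L, 5L))
  e2 <- estimate_edge_probabilities(both)
  expect_equal(e2$p, c(0.5, 0.5))
  expect_equal(e2$support, c(10, 10))

  # reverse sets are flipped back before counting
  rev_ <- mk(list(c("C", "B", "A")), 10L, direction = "reverse")
  e3 <- estimate_edge_probabilities(fwd, rev_)
  expect_equal(e3$p[e3$from == "A" & e3$to == "B"], 1)
  expect_equal(e3$support[e3$from == "A" & e3$to == "B"], 20)

  # p(i,j) + p(j,i) = 1 on arbitrary pooled sets
  set.seed(17)
  genes <- sprintf("z%d", 1:8)
  paths <- lapply(1:30, function(i) sample(genes, 4))
  pool <- mk(paths, sample(1:20, 30, replace = TRUE))
  ep <- estimate_edge_probabilities(pool)
  key <- paste(ep$from, ep$to)
  rkey <- paste(ep$to, ep$from)
  expect_equal(ep$p + ep$p[match(key, rkey)], rep(1, nrow(ep)))
  expect_true(all(ep$p >= 0 & ep$p <= 1))
})

test_that("consensus_network ranks deterministically and unions edges", {
  mk <- function(paths, counts, energy) {
    impala:::new_sample_set(paths, counts, cbind(counts, 0L), energy,
                            meta = list(direction = "forward"))
  }
  s <- mk(list(c("A", "B", "T"), c("A", "C", "T"), c("A", "D", "T")),
          c(50L, 30L, 30L), c(1, 2, 5))
  top1 <- consensus_network(s, top_k = 1)
  expect_equal(top1$pathways, list(c("A", "B", "T")))
  expect_equal(top1$edges$from, c("A", "B"))
  # count tie at 30 broken by higher energy: D-path ranks above C-path
  top2 <- consensus_network(s, top_k = 2)
  expect_equal(top2$pathways[[2L]], c("A", "D", "T"))
  # top_k beyond the distinct count uses all (with a notice)
  expect_message(all3 <- consensus_network(s, top_k = 10), "using all")
  expect_equal(nrow(all3$edges), 6L)
  # gene frequency = total count of pathways containing the gene
  expect_equal(all3$genes$frequency[all3$genes$gene == "A"], 110)
  expect_equal(all3$genes$frequency[all3$genes$gene == "C"], 30)
})

test_that("consensus top-k matches an independent ranking oracle", {
  set.seed(23)
  genes <- sprintf("y%02d", 1:25)
  paths <- unique(lapply(1:300, function(i) sample(genes, 5)))
  counts <- sample(1:40, length(paths), replace = TRUE)
  energy <- runif(length(paths))
  s <- impala:::new_sample_set(paths, counts, cbind(counts, 0L), energy,
                               meta = list(direction = "forward"))
  cons <- consensus_network(s, top_k = 200)
  # oracle: order by count desc, energy desc, lexicographic key
  key <- vapply(s$paths, paste, character(1L), collapse = "\t")
  o <- order(-s$counts, -s$energy, key)[1:200]
  oracle_nodes <- sort(unique(unlist(s$paths[o])))
  expect_equal(sort(cons$genes$gene), oracle_nodes)
  oracle_edges <- unique(do.call(rbind, lapply(s$paths[o], function(p)
    cbind(p[-5L], p[-1L]))))
  expect_equal(nrow(cons$edges), nrow(oracle_edges))
})

test_that("run_gist end-to-end is reproducible and skips infeasible lengths", {
  scen <- simulation_scenario(type = "I", n_paths = 2, length_range = 5,
                              phi = 0, sigma2 = 0.1,
                              samples_per_group = 5, seed = 9)
  sim <- simulate_network(scen)
  expr <- simulate_expression(sim$network, sim$truth, scen)
  cfg <- landscape_config(sim$truth$sources, sim$truth$targets,
                          radius = 4, lengths = 4:6)
  smp <- sampler_config(iterations = 800, chains = 8, seed = 31)
  f1 <- suppressMessages(run_gist(sim$network, expr, cfg, smp))
  f2 <- suppressMessages(run_gist(sim$network, expr, cfg, smp))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$edges, f2$edges)
  # disjoint length-5 paths: lengths 4 and 6 are infeasible and skipped
  expect_true(any(grepl("L=4", f1$skipped)))
  expect_true(all(lengths(f1$samples$paths) == 5L))
  # forward and reverse pools both present; probabilities complementary
  expect_false(is.null(f1$forward))
  expect_false(is.null(f1$reverse))
  key <- paste(f1$edges$from, f1$edges$to)
  rkey <- paste(f1$edges$to, f1$edges$from)
  expect_equal(f1$edges$p + f1$edges$p[match(key, rkey)],
               rep(1, nrow(f1$edges)))
})

test_that("sample sets merge with conserved counts and serialize to JSON", {
  mk <- function(paths, counts, direction = "forward") {
    impala:::new_sample_set(paths, counts, cbind(counts, 0L),
                            rep(0, length(paths)),
                            meta = list(direction = direction))
  }
  a <- mk(list(c("A", "B"), c("A", "C")), c(3L, 4L))
  b <- mk(list(c("A", "B")), 5L)
  m <- merge_sample_sets(list(a, b))
  expect_equal(m$total, 12L)
  expect_equal(m$counts[vapply(m$paths, paste, character(1),
                               collapse = "") == "AB"], 8L)
  f <- withr::local_tempfile(fileext = ".json")
  write_sample_set(m, f)
  back <- read_sample_set(f)
  expect_equal(back$paths, m$paths)
  expect_equal(back$counts, m$counts)
  expect_equal(back$total, m$total)
})
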