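test_that("gene_potential matches an independent Welch-t -> z computation", {
  set.seed(21)
  x <- matrix(rnorm(8, sd = 2) + rep(c(0, 1.5), each = 4), 1, 8,
              dimnames = list("g", paste0("s", 1:8)))
  expr <- expression_matrix(x, rep(c("A", "B"), each = 4))
  got <- gene_potential("g", expr)
  tt <- t.test(x[1, 1:4], x[1, 5:8])          # Welch by default
  expect_equal(got, qnorm(tt$p.value / 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # no differential expression -> 0; missing gene -> 0
  flat <- expression_matrix(
    matrix(rep(c(1, 2), 4), 2, 4, byrow = FALSE,
           dimnames = list(c("a", "b"), paste0("s", 1:4))),
    c("A", "A", "B", "B"))
  expect_equal(gene_potential("a", flat), 0)
  expect_equal(gene_potential("nope", flat), 0)

  # stronger separation scores strictly higher; zero-variance split is
  # capped, not infinite
  set.seed(22)
  y <- rbind(weak = rnorm(8, rep(c(0, 0.2), each = 4)),
             strong = rep(c(0, 5), each = 4))
  colnames(y) <- paste0("s", 1:8)
  e2 <- expression_matrix(y, rep(c("A", "B"), each = 4))
  expect_gt(gene_potential("strong", e2), gene_potential("weak", e2))
  expect_true(is.finite(gene_potential("strong", e2)))
  expect_equal(gene_potential("strong", e2),
               qnorm(1e-16 / 2, lower.tail = FALSE))
})

test_that("gene and edge potentials ignore which group is which", {
  set.seed(23)
  x <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  a <- expression_matrix(x, rep(c("A", "B"), each = 4))
  b <- expression_matrix(x, rep(c("B", "A"), each = 4))
  for (g in rownames(x)) {
    expect_equal(gene_potential(g, a), gene_potential(g, b))
  }
  expect_equal(edge_potential("g1", "g2", a), edge_potential("g2", "g1", a))
})

test_that("edge_potential is the Fisher z of the Pearson correlation", {
  set.seed(31)
  m <- 20
  x <- rbind(u = rnorm(m), v = rnorm(m))
  x <- rbind(x, w = x["u", ])       # exact copy -> |r| = 1 -> capped
  colnames(x) <- paste0("s", 1:m)
  expr <- expression_matrix(x, rep(c("A", "B"), each = m / 2))
  r <- cor(x["u", ], x["v", ])
  expect_equal(edge_potential("u", "v", expr),
               abs(atanh(r)) * sqrt(m - 3), tolerance = 1e-12)
  expect_equal(edge_potential("u", "w", expr),
               qnorm(1e-16 / 2, lower.tail = FALSE))
  # constant gene scores 0; too few samples is an error
  x2 <- rbind(x, k = rep(1, m))
  e2 <- expression_matrix(x2, rep(c("A", "B"), each = m / 2))
  expect_equal(edge_potential("u", "k", e2), 0)
  tiny <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), NULL))
  # m = 4 is allowed (sqrt(m - 3) = 1); m < 4 cannot be built at all
  e4 <- expression_matrix(tiny, c("A", "A", "B", "B"))
  expect_true(is.finite(edge_potential("a", "b", e4)))
})

test_that("null-model edge potential has mean |z| near sqrt(2/pi)", {
  set.seed(99)
  m <- 100
  reps <- 1000
  vals <- vapply(seq_len(reps), function(i) {
    abs(atanh(cor(rnorm(m), rnorm(m)))) * sqrt(m - 3)
  }, numeric(1L))
  # Fisher z of a null correlation is ~ N(0, 1): E|Z| = sqrt(2/pi)
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - sqrt(2 / pi)), 3 * se)
  # and the package's own scorer agrees with the closed form used above
  x <- rbind(p = rnorm(m), q = rnorm(m))
  colnames(x) <- paste0("s", 1:m)
  expr <- expression_matrix(x, rep(c("A", "B"), each = m / 2))
  expect_equal(edge_potential("p", "q", expr),
               abs(atanh(cor(x["p", ], x["q", ]))) * sqrt(m - 3))
})

test_that("flow_potential counts concordant compartment transitions", {
  loc <- c(a = "membrane", b = "cytoplasm", c = "nucleus",
           d = "other", e = "membrane")
  expect_equal(flow_potential(c("a", "b", "c"), loc, lambda = 2), 2)
  expect_equal(flow_potential(c("c", "b", "a"), loc, lambda = 2), 0)
  # unknown locations match anything
  expect_equal(flow_potential(c("c", "zz", "a"), loc, lambda = 1), 1)
  # reverse chain scores against the reversed order
  expect_equal(flow_potential(c("c", "b", "a"), loc, lambda = 1,
                              reverse = TRUE), 1)

  # recount oracle on random paths
  set.seed(5)
  genes <- sprintf("r%02d", 1:30)
  rloc <- setNames(sample(c("membrane", "cytoplasm", "nucleus", "other"),
                          30, replace = TRUE), genes)
  rank_of <- c(membrane = 1, cytoplasm = 2, nucleus = 3, other = 0)
  for (i in 1:200) {
    p <- sample(genes, 6)
    r <- rank_of[rloc[p]]
    conc <- mean(vapply(1:5, function(j)
      r[j] == 0 || r[j + 1] == 0 || r[j + 1] >= r[j], logical(1L)))
    expect_equal(flow_potential(p, rloc, lambda = 3.7), 3.7 * conc)
  }
})

test_that("pathway_energy is the weighted sum of the three potentials", {
  node <- c(A = 1, B = 2, C = 3)
  edges <- cbind(c("A", "B"), c("B", "C"))
  loc <- c(A = "membrane", B = "cytoplasm", C = "nucleus")
  tab <- manual_tables(node, edges, c(0.5, 0.5), locations = loc, lambda = 1)
  # V1 = 6, V2 = 1, V3 = 1 (fully concordant) -> U = 8
  expect_equal(pathway_energy(c("A", "B", "C"), tab), 8)
  p <- pathway(c("A", "B", "C"), tab)
  expect_equal(p$energy, p$v1 + p$v2 + p$v3)

  # all-zero tables give zero energy
  tab0 <- manual_tables(c(A = 0, B = 0, C = 0), edges, c(0, 0), lambda = 0)
  expect_equal(pathway_energy(c("A", "B", "C"), tab0), 0)
  # unscored edges are an error, not a silent zero
  expect_error(pathway_energy(c("A", "C"), tab), "not scored")
  expect_error(pathway(c("A", "B", "A"), tab), "simple")
})

test_that("energy additivity holds on random pathways", {
  set.seed(61)
  genes <- sprintf("g%02d", 1:15)
  node <- setNames(runif(15, 0, 5), genes)
  pairs <- t(combn(genes, 2))
  scores <- runif(nrow(pairs), 0, 3)
  loc <- setNames(sample(c("membrane", "cytoplasm", "nucleus", "other"),
                         15, replace = TRUE), genes)
  tab <- manual_tables(node, pairs, scores, locations = loc, lambda = 1.3,
                       weights = c(2, 0.5, 3))
  key <- paste(pmin(pairs[, 1], pairs[, 2]),
               pmax(pairs[, 1], pairs[, 2]), sep = "|")
  for (i in 1:100) {
    p <- sample(genes, sample(3:6, 1))
    ek <- paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]),
                sep = "|")
    u_oracle <- 2 * sum(node[p]) +
      0.5 * sum(scores[match(ek, key)]) +
      3 * flow_potential(p, loc, lambda = 1.3)
    expect_equal(pathway_energy(p, tab), u_oracle, tolerance = 1e-12)
  }
})

test_that("boltzmann_distribution has the closed forms and limits", {
  expect_equal(boltzmann_distribution(c(2, 2)), c(0.5, 0.5))
  expect_equal(boltzmann_distribution(c(1, 2), temperature = 1),
               c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))),
               tolerance = 1e-12)
  set.seed(3)
  u <- rnorm(20, sd = 4)
  p <- boltzmann_distribution(u, temperature = 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # shift invariance
  expect_equal(boltzmann_distribution(u + 100, temperature = 1), p,
               tolerance = 1e-12)
  # T -> infinity flattens
  expect_lt(max(abs(boltzmann_distribution(u, temperature = 1e9) - 0.05)),
            1e-6)
  # lowering T sharpens the argmax
  p_cold <- boltzmann_distribution(u, temperature = 0.5)
  expect_gt(p_cold[which.max(u)], p[which.max(u)])
  expect_error(boltzmann_distribution(u, temperature = 0), "> 0")
  expect_error(boltzmann_distribution(numeric()), "empty")
})

test_that("build_potential_tables precomputes finite scores and auto-lambda", {
  set.seed(71)
  edges <- oracle_er_edges(12, 0.4, seed = 71)
  net <- suppressMessages(interaction_network(
    edges, genes = sprintf("g%02d", 1:12)))
  x <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(net$genes, paste0("s", 1:10)))
  expr <- expression_matrix(x, rep(c("A", "B"), each = 5))
  tab <- build_potential_tables(net, expr)
  expect_true(all(is.finite(tab$node)))
  expect_true(all(is.finite(tab$edge)))
  expect_equal(tab$lambda, mean(tab$node[tab$node > 0]))
  # genes missing from the expression matrix score 0 but stay in the table
  net2 <- suppressMessages(interaction_network(
    rbind(edges, c("g01", "EXTRA")), genes = c(net$genes, "EXTRA")))
  tab2 <- build_potential_tables(net2, expr)
  expect_equal(unname(tab2$node["EXTRA"]), 0)
  expect_equal(unname(tab2$edge[impala:::edge_key("g01", "EXTRA")]), 0)
})
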