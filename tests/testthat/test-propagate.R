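test_that("alpha = 1 returns the initial vector immediately", {
  net <- four_node_net()
  W <- transition_matrix(net)
  p0 <- initial_vector(net, seed_set(phenotypes = "p1"))
  p <- propagate(W, p0, alpha = 1)
  expect_equal(as.numeric(p), as.numeric(p0))
  expect_equal(as.numeric(solve_steady_state(W, p0, alpha = 1)), as.numeric(p0))
})

test_that("two nodes joined by one edge give the closed-form (2/3, 1/3)", {
  net <- composite_network(gg = edge_list("a", "b", 1, "gene", "gene"))
  W <- transition_matrix(net)
  p <- propagate(W, c(1, 0), alpha = 0.5, tol = 1e-14)
  expect_equal(as.numeric(p), c(2/3, 1/3), tolerance = 1e-10)
})

test_that("uniform start on a k-regular graph is a fixed point", {
  # 6-cycle: 2-regular, so W is doubly stochastic
  ids <- paste0("g", 1:6)
  net <- composite_network(gg = edge_list(ids, c(ids[-1], ids[1]),
                                          rep(1, 6), "gene", "gene"))
  W <- transition_matrix(net)
  p0 <- rep(1/6, 6)
  for (alpha in c(0.2, 0.7, 0.95)) {
    p <- propagate(W, p0, alpha = alpha, tol = 1e-13)
    expect_equal(as.numeric(p), p0, tolerance = 1e-10)
  }
})

test_that("iteration matches the direct linear solve on random networks", {
  for (seed in 1:25) {
    net <- random_composite(seed, ng = 8L, np = 5L, nm = 6L)
    W <- transition_matrix(net)
    p0 <- initial_vector(net, seed_set(genes = net$nodes$gene[1],
                                       metabolites = net$nodes$metabolite[1]))
    for (alpha in c(0.1, 0.7)) {
      p_it <- propagate(W, p0, alpha, tol = 1e-12)
      p_cf <- solve_steady_state(W, p0, alpha)
      expect_lt(sum(abs(p_it - p_cf)), 1e-8)
    }
  }
})

test_that("iterates conserve mass when no column is dangling", {
  net <- random_composite(11, d_within = 0.6, d_cross = 0.5)
  W <- transition_matrix(net)
  expect_length(attr(W, "dangling"), 0L)
  p0 <- initial_vector(net, seed_set(phenotypes = net$nodes$phenotype[1]))
  p <- propagate(W, p0, alpha = 0.4, tol = 1e-13)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
})

test_that("a fully isolated node keeps exactly its restart mass", {
  net <- composite_network(gg = edge_list("g1", "g2", 1, "gene", "gene"))
  net <- metprior:::.reindex(net, list(gene = c("g1", "g2", "g9"),
                                       phenotype = character(),
                                       metabolite = character()))
  W <- transition_matrix(net)
  p0 <- setNames(c(0.5, 0, 0.5), rownames(W))
  p <- propagate(W, p0, alpha = 0.3, tol = 1e-13)
  expect_equal(as.numeric(p["gene:g9"]), 0.3 * 0.5, tolerance = 1e-10)
})

test_that("steady score decays with hop distance in the restart-dominated regime", {
  # note the alpha -> 0 limit is the degree-proportional stationary
  # distribution, which ranks interior chain nodes above the first hop, so
  # strict locality is only expected once the restart term dominates
  net <- metabolite_chain_net(3L)
  W <- transition_matrix(net)
  p0 <- initial_vector(net, seed_set(phenotypes = "p1"))
  for (alpha in c(0.5, 0.7, 0.9)) {
    p <- propagate(W, p0, alpha, tol = 1e-13)
    s <- p[paste0("metabolite:", c("m1", "m2", "m3"))]
    expect_true(all(diff(as.numeric(s)) < 0))
  }
})

test_that("non-convergence warns and flags the result", {
  net <- four_node_net()
  W <- transition_matrix(net)
  p0 <- initial_vector(net, seed_set(phenotypes = "p1"))
  expect_warning(p <- propagate(W, p0, alpha = 0.01, tol = 1e-14, max_iter = 3),
                 "did not converge")
  expect_false(attr(p, "converged"))
  expect_equal(attr(p, "n_iter"), 3L)
})

test_that("initial vector splits seed mass per layer and redistributes empty layers", {
  net <- random_composite(2)
  gs <- net$nodes$gene; ps <- net$nodes$phenotype; ms <- net$nodes$metabolite

  # phenotype-only seeds absorb all mass
  p0 <- initial_vector(net, seed_set(phenotypes = ps[1]))
  expect_equal(as.numeric(p0[paste0("phenotype:", ps[1])]), 1)
  expect_equal(sum(p0), 1)

  # one seed per layer at equal weights: 1/3 each
  p0 <- initial_vector(net, seed_set(phenotypes = ps[1], genes = gs[1],
                                     metabolites = ms[1]))
  expect_equal(as.numeric(p0[c(paste0("gene:", gs[1]), paste0("phenotype:", ps[1]),
                               paste0("metabolite:", ms[1]))]),
               rep(1/3, 3))

  # metabolite layer unseeded at a = b = 0.5: genes split 0.5, phenotype 0.5
  p0 <- initial_vector(net, seed_set(genes = gs[1:2], phenotypes = ps[1]),
                       a = 0.5, b = 0.5)
  expect_equal(as.numeric(p0[paste0("gene:", gs[1:2])]), c(0.25, 0.25))
  expect_equal(as.numeric(p0[paste0("phenotype:", ps[1])]), 0.5)

  # degenerate: only metabolite seeds but their nominal mass is 0
  p0 <- initial_vector(net, seed_set(metabolites = ms[1]), a = 0.5, b = 0.5)
  expect_equal(sum(p0), 1)
  expect_equal(as.numeric(p0[paste0("metabolite:", ms[1])]), 1)

  expect_error(seed_set(), "at least one")
  expect_error(initial_vector(net, seed_set(genes = "nope")), "not in network")
})
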