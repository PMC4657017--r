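test_that("hand-worked 4-node transition matrix is exact", {
  W <- transition_matrix(four_node_net(), 1/3, 1/3, 1/3)
  w <- function(to, from) W[to, from]
  # out of g1: no metabolite edge, so y joins the within-layer budget (R1)
  expect_equal(w("phenotype:p1", "gene:g1"), 1/3)
  expect_equal(w("gene:g2", "gene:g1"), 2/3)
  # out of p1: no phenotype neighbors, mass split across present cross
  # blocks pro rata to x and z (R2)
  expect_equal(w("gene:g1", "phenotype:p1"), 1/2)
  expect_equal(w("metabolite:m1", "phenotype:p1"), 1/2)
  expect_equal(w("gene:g1", "gene:g2"), 1)
  expect_equal(w("phenotype:p1", "metabolite:m1"), 1)
  expect_equal(Matrix::nnzero(W), 6)
})

test_that("columns are stochastic across a randomized suite of networks", {
  # spans all absent-block situations: full networks, single layers,
  # missing cross blocks, missing within blocks
  cases <- list(
    list(drop = character()),
    list(drop = c("gm")), list(drop = c("pg")), list(drop = c("pm")),
    list(drop = c("gg")), list(drop = c("pp")), list(drop = c("mm")),
    list(drop = c("gg", "pp", "mm")),
    list(drop = c("gm", "pg", "pm")),
    list(drop = c("pp", "pm", "pg")))
  n_checked <- 0L
  for (case in cases) {
    for (seed in 1:12) {
      net <- random_composite(seed, d_within = 0.4, d_cross = 0.3,
                              drop_blocks = case$drop)
      if (sum(lengths(net$nodes)) == 0L) next
      xyz <- runif(3) / 2
      W <- transition_matrix(net, xyz[1], xyz[2], xyz[3])
      expect_column_stochastic(W)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("a single-layer network reduces to the plain column-normalized adjacency", {
  set.seed(5)
  net <- random_composite(5, drop_blocks = c("pp", "mm", "gm", "pg", "pm"))
  W <- transition_matrix(net, 0.2, 0.4, 0.1)
  ref <- as.matrix(net$gg) %*% diag(1 / pmax(Matrix::colSums(net$gg), 1e-300))
  expect_equal(unname(as.matrix(W)), unname(ref), tolerance = 1e-12)
})

test_that("isolated nodes give zero columns and are reported as dangling", {
  net <- composite_network(
    gg = edge_list("g1", "g2", 1, "gene", "gene"),
    mm = edge_list("m1", "m2", 1, "metabolite", "metabolite"),
    gm = edge_list("g1", "m9", 0.0001, "gene", "metabolite"))
  # m3 only appears via a registered-but-unwired id
  net <- metprior:::.reindex(net, list(gene = c("g1", "g2"),
                                       phenotype = character(),
                                       metabolite = c("m1", "m2", "m3", "m9")))
  W <- transition_matrix(net)
  expect_equal(attr(W, "dangling"), "metabolite:m3")
  expect_equal(sum(W[, "metabolite:m3"]), 0)
})

test_that("per-block scale invariance: rescaling one sub-network leaves W unchanged", {
  net <- random_composite(9)
  W1 <- transition_matrix(net, 0.3, 0.2, 0.25)
  net2 <- net
  net2$mm <- net$mm * 37.5
  net2$pg <- net$pg * 0.004
  W2 <- transition_matrix(net2, 0.3, 0.2, 0.25)
  expect_equal(as.matrix(W1), as.matrix(W2), tolerance = 1e-12)
})

test_that("R2 splits pro rata to nominal budgets, equally when both are zero", {
  # phenotype p1 has gene and metabolite edges but no phenotype neighbors
  net <- composite_network(
    pg = edge_list("p1", "g1", 1, "phenotype", "gene"),
    pm = edge_list("p1", "m1", 1, "phenotype", "metabolite"),
    gg = edge_list("g1", "g2", 1, "gene", "gene"),
    mm = edge_list("m1", "m2", 1, "metabolite", "metabolite"))
  W <- transition_matrix(net, x = 0.3, y = 0, z = 0.1)
  expect_equal(W["gene:g1", "phenotype:p1"], 0.3 / 0.4)
  expect_equal(W["metabolite:m1", "phenotype:p1"], 0.1 / 0.4)
  W0 <- transition_matrix(net, x = 0, y = 0, z = 0)
  expect_equal(W0["gene:g1", "phenotype:p1"], 0.5)
  expect_equal(W0["metabolite:m1", "phenotype:p1"], 0.5)
})

test_that("jumping-probability budgets are enforced", {
  expect_error(rwr_params(x = 0.8, y = 0.4), "budget")
  expect_error(rwr_params(a = 0.9, b = 0.2), "a \\+ b")
  expect_error(transition_matrix(four_node_net(), 0.8, 0.4, 0.1), "budget")
})
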