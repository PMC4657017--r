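# shared fixture builders; everything is generated in code

# the hand-worked 4-node network: genes g1-g2, phenotype p1 wired to g1 and
# m1; used to pin down the transition reallocation rules
four_node_net <- function() {
  composite_network(
    gg = edge_list("g1", "g2", 1, "gene", "gene"),
    pg = edge_list("p1", "g1", 1, "phenotype", "gene"),
    pm = edge_list("p1", "m1", 1, "phenotype", "metabolite"))
}

# phenotype seed attached to a metabolite chain m1 - m2 - m3
metabolite_chain_net <- function(n = 3L) {
  ms <- paste0("m", seq_len(n))
  composite_network(
    mm = edge_list(ms[-n], ms[-1], rep(1, n - 1L), "metabolite", "metabolite"),
    pm = edge_list("p1", "m1", 1, "phenotype", "metabolite"))
}

# small random composite network; densities of 0 exercise the absent-block
# reallocation rules (R1/R2)
random_composite <- function(seed, ng = 6L, np = 4L, nm = 5L,
                             d_within = 0.5, d_cross = 0.4,
                             drop_blocks = character()) {
  set.seed(seed)
  gs <- paste0("g", seq_len(ng)); ps <- paste0("p", seq_len(np))
  ms <- paste0("m", seq_len(nm))
  er <- function(ids, d, sl) {
    n <- length(ids)
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(idx)) < d
    idx <- idx[keep, , drop = FALSE]
    edge_list(ids[idx[, 1]], ids[idx[, 2]], runif(nrow(idx)), sl, sl)
  }
  bip <- function(r, c, d, sl, tl) {
    grid <- expand.grid(i = seq_along(r), j = seq_along(c))
    keep <- runif(nrow(grid)) < d
    grid <- grid[keep, , drop = FALSE]
    edge_list(r[grid$i], c[grid$j], runif(nrow(grid)), sl, tl)
  }
  lists <- list(
    gg = er(gs, d_within, "gene"),
    pp = er(ps, d_within, "phenotype"),
    mm = er(ms, d_within, "metabolite"),
    gm = bip(gs, ms, d_cross, "gene", "metabolite"),
    pg = bip(ps, gs, d_cross, "phenotype", "gene"),
    pm = bip(ps, ms, d_cross, "phenotype", "metabolite"))
  for (b in drop_blocks) lists[[b]] <- NULL
  do.call(composite_network, lists)
}

# annotations sampled from a simulation, shrunk for cheap LOOCV calls
small_simulation <- function(seed = 7L, n_genes = 60L, n_phenotypes = 10L,
                             n_metabolites = 50L, n_diseases = 3L, ...) {
  simulate_composite(synthetic_config(
    n_genes = n_genes, n_phenotypes = n_phenotypes,
    n_metabolites = n_metabolites, n_diseases = n_diseases,
    rng_seed = seed, ...))
}

expect_column_stochastic <- function(W, tol = 1e-12) {
  cs <- Matrix::colSums(W)
  expect_true(all(abs(cs[cs != 0] - 1) <= tol))
}

# independent pairwise AUC oracle: for each fold, the positive's score is
# compared against every negative's score directly (ties count 1/2)
brute_force_auc_scores <- function(fold_scores) {
  per_fold <- vapply(fold_scores, function(f) {
    (sum(f$pos > f$neg) + 0.5 * sum(f$pos == f$neg)) / length(f$neg)
  }, numeric(1))
  mean(per_fold)
}

# midrank of the positive among all candidate scores (descending)
midrank_of <- function(pos, neg) sum(c(pos, neg) > pos) + (sum(c(pos, neg) == pos) + 1) / 2
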