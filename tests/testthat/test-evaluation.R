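test_that("rank-based AUC matches hand-computable cases", {
  expect_equal(auc_from_ranks(data.frame(rank = c(1, 1, 1),
                                         n_candidates = c(10, 50, 100))), 1)
  expect_equal(auc_from_ranks(data.frame(rank = 51, n_candidates = 101)), 0.5)
  expect_equal(auc_from_ranks(data.frame(rank = c(1, 6), n_candidates = 11)),
               0.75)
  expect_warning(
    auc <- auc_from_ranks(data.frame(rank = c(1, 1), n_candidates = c(1, 5))),
    "fewer than 2")
  expect_equal(auc, 1)
  expect_error(auc_from_ranks(data.frame(rank = 7, n_candidates = 5)),
               "must lie")
})

test_that("rank-based AUC equals the brute-force pairwise oracle", {
  set.seed(99)
  for (rep in 1:60) {
    # random fold sets with ties to exercise the midrank convention
    fold_scores <- lapply(seq_len(sample(2:8, 1)), function(i) {
      n <- sample(5:40, 1)
      vals <- round(runif(n, 0, 1), sample(c(1, 2), 1)) # coarse grid -> ties
      list(pos = vals[1], neg = vals[-1])
    })
    folds <- data.frame(
      rank = vapply(fold_scores, function(f) midrank_of(f$pos, f$neg), 0),
      n_candidates = vapply(fold_scores, function(f) length(f$neg) + 1L, 0L))
    expect_equal(auc_from_ranks(folds), brute_force_auc_scores(fold_scores),
                 tolerance = 1e-12)
  }
})

test_that("LOOCV separates a perfectly planted clique", {
  # each disease metabolite clique is wired straight to its phenotype and
  # background metabolites are isolated -> the held-out metabolite must
  # always win
  ms <- paste0("m", 1:8); known <- ms[1:4]
  pairs <- t(combn(known, 2))
  net <- composite_network(
    mm = edge_list(pairs[, 1], pairs[, 2], rep(1, nrow(pairs)),
                   "metabolite", "metabolite"),
    pm = edge_list(rep("p1", 4), known, rep(1, 4), "phenotype", "metabolite"))
  net <- metprior:::.reindex(net, list(gene = character(),
                                       phenotype = "p1", metabolite = ms))
  ann <- disease_annotations("p1", list(known), list(character()))
  v <- loocv(net, ann)
  expect_equal(v$auc, 1)
  expect_equal(nrow(v$folds), 4L)
  expect_true(all(v$folds$rank == 1))
})

test_that("LOOCV never leaks the held-out link and excludes other knowns from candidates", {
  sim <- small_simulation(4)
  v <- loocv(sim$network, sim$annotations)
  for (i in seq_len(nrow(v$folds))) {
    f <- v$folds[i, ]
    known <- sim$annotations$metabolites[[
      match(f$phenotype, sim$annotations$phenotype)]]
    # candidate count = all metabolites minus the *other* known seeds
    expect_equal(f$n_candidates,
                 length(sim$network$nodes$metabolite) - (length(known) - 1L))
  }
})

test_that("random-candidate LOOCV uses k candidates including the test metabolite", {
  sim <- small_simulation(4)
  v <- loocv(sim$network, sim$annotations, candidate_mode = "random_k", k = 20L)
  expect_true(all(v$folds$n_candidates == 20L))
  expect_true(all(v$folds$rank >= 1 & v$folds$rank <= 20))
})

test_that("baseline ablation equals full mode when the ablated layers are absent", {
  # network whose phenotype/gene layers carry no information beyond the
  # held-out links: no genes, no phenotype-phenotype edges, annotations
  # with no known genes
  set.seed(31)
  ms <- paste0("m", 1:12)
  pairs <- t(combn(ms, 2)); keep <- runif(nrow(pairs)) < 0.35
  known <- list(ms[1:3], ms[4:6])
  net <- composite_network(
    mm = edge_list(pairs[keep, 1], pairs[keep, 2], runif(sum(keep)),
                   "metabolite", "metabolite"))
  net <- metprior:::.reindex(net, list(gene = character(),
                                       phenotype = c("p1", "p2"),
                                       metabolite = ms))
  ann <- disease_annotations(c("p1", "p2"), known,
                             list(character(), character()))
  v_full <- loocv(net, ann, ablation = "full")
  v_base <- loocv(net, ann, ablation = "metabolite_only")
  expect_equal(v_base$folds[c("phenotype", "test_metabolite", "rank",
                              "n_candidates")],
               v_full$folds[c("phenotype", "test_metabolite", "rank",
                              "n_candidates")])
  expect_equal(v_base$auc, v_full$auc)
})

test_that("per-class AUC recomputes from each class's folds", {
  sim <- small_simulation(9)
  v <- loocv(sim$network, sim$annotations)
  cw <- classwise_auc(v)
  # classwise AUCs recompute from the fold subsets
  for (i in seq_len(nrow(cw))) {
    sub <- v$folds[v$folds$class == cw$class[i] |
                     (is.na(v$folds$class) & cw$class[i] == "unclassified"), ]
    expect_equal(cw$auc[i], auc_from_ranks(sub))
    expect_equal(cw$n_folds[i], nrow(sub))
  }
  # single class: classwise equals overall
  one <- sim$annotations
  one$class <- "only"
  v1 <- loocv(sim$network, one)
  cw1 <- classwise_auc(v1)
  expect_equal(nrow(cw1), 1L)
  expect_equal(cw1$auc, v1$auc)
  # mean/SE recomputable
  expect_equal(attr(cw, "mean_auc"), mean(cw$auc))
})

test_that("noise sweep at sigma = 0 reproduces the clean AUC exactly", {
  sim <- small_simulation(10)
  v <- loocv(sim$network, sim$annotations)
  ns <- noise_sweep(sim$network, sim$annotations, sigmas = c(0, 1),
                    rng_seed = 4)
  expect_equal(ns$auc[ns$sigma == 0], v$auc)
  expect_lt(ns$auc[ns$sigma == 1], ns$auc[ns$sigma == 0])
})

test_that("parameter sweep rejects infeasible grid points and returns one row per valid point", {
  sim <- small_simulation(10)
  grid <- data.frame(alpha = c(0.1, 0.5, 0.9, 0.5), x = c(1/3, 1/3, 1/3, 0.9),
                     y = c(1/3, 1/3, 1/3, 0.8))
  expect_warning(res <- parameter_sweep(sim$network, sim$annotations, grid),
                 "rejecting 1")
  expect_equal(nrow(res), 3L)
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_error(parameter_sweep(sim$network, sim$annotations,
                               data.frame(alpha = numeric())),
               "non-empty")
})

test_that("alpha = 1 collapses to restart mass and midranks give AUC 0.5", {
  sim <- small_simulation(12)
  res <- parameter_sweep(sim$network, sim$annotations,
                         data.frame(alpha = 1))
  expect_equal(res$auc, 0.5, tolerance = 1e-12)
})

test_that("score matrix rows are metabolite-layer probability restrictions", {
  sim <- small_simulation(13)
  sm <- score_matrix(sim$network, sim$annotations)
  expect_equal(dim(sm), c(nrow(sim$annotations),
                          length(sim$network$nodes$metabolite)))
  # identical seed sets give identical rows
  ann2 <- sim$annotations[c(1, 1), ]
  ann2$phenotype[2] <- ann2$phenotype[1]
  sm2 <- score_matrix(sim$network, ann2)
  expect_equal(unname(sm2[1, ]), unname(sm2[2, ]))
  # each row sums to the phenotype's metabolite-layer steady mass (< 1)
  expect_true(all(rowSums(sm) > 0 & rowSums(sm) < 1))

  top <- top_scores(sm, k = 5)
  expect_equal(nrow(top), 5L * nrow(sim$annotations))
  excl <- attr(sm, "seed_metabolites")
  for (p in names(excl)) {
    expect_false(any(excl[[p]] %in% top$metabolite[top$phenotype == p]))
  }
})

test_that("annotations round-trip through TSV including empty fields", {
  ann <- disease_annotations(
    c("p1", "p2"), list(c("m1", "m2"), character()),
    list(character(), c("g1")), c("classA", NA))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  ann2 <- read_annotations(f)
  expect_equal(as.data.frame(ann2), as.data.frame(ann))
})

test_that("simulation outputs round-trip through the file readers", {
  sim <- small_simulation(14)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  net2 <- read_composite(dir)
  expect_equal(as.data.frame(network_edges(net2)),
               as.data.frame(network_edges(sim$network)))
  ann2 <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(as.data.frame(ann2), as.data.frame(sim$annotations))
})
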