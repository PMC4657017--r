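#' Candidate metabolite set
#'
#' Describes which metabolites are scored and ranked. Three modes:
#'
#' * `"metabolome_wide"`: every metabolite node except the metabolite
#'   seeds (the default, and the mode used for genome-scale scans).
#' * `"explicit_list"`: exactly the supplied `ids` (seed metabolites are
#'   still excluded).
#' * `"random_k"`: `k - 1` non-seed metabolites drawn uniformly without
#'   replacement, plus the designated `test_metabolite` — the
#'   random-candidate protocol used in cross-validation.
#'
#' @param mode One of `"metabolome_wide"`, `"explicit_list"`, `"random_k"`.
#' @param ids Metabolite ids for `"explicit_list"`.
#' @param k Candidate-set size for `"random_k"`.
#' @param test_metabolite The metabolite guaranteed to be included in
#'   `"random_k"` mode.
#' @param rng_seed Integer seed for the `"random_k"` draw.
#' @return A list of class `candidate_set`.
#' @export
candidate_set <- function(mode = c("metabolome_wide", "explicit_list", "random_k"),
                          ids = NULL, k = NULL, test_metabolite = NULL,
                          rng_seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "explicit_list" && (is.null(ids) || length(ids) == 0L)) {
    abort("`ids` is required for an explicit_list candidate set")
  }
  if (mode == "random_k") {
    if (is.null(k) || k < 2L) abort("`k` (>= 2) is required for a random_k candidate set")
    if (is.null(test_metabolite)) abort("`test_metabolite` is required for a random_k candidate set")
  }
  structure(list(mode = mode, ids = as.character(ids %||% character()),
                 k = k, test_metabolite = test_metabolite,
                 rng_seed = as.integer(rng_seed)),
            class = "candidate_set")
}

# resolve a candidate_set against a network and seed set -> metabolite ids
.resolve_candidates <- function(net, seeds, candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  pool <- setdiff(net$nodes$metabolite, seeds$metabolite)
  out <- switch(candidates$mode,
    metabolome_wide = pool,
    explicit_list = {
      missing <- setdiff(candidates$ids, net$nodes$metabolite)
      if (length(missing) > 0L) {
        abort(sprintf("candidate metabolite(s) not in network: %s",
                      paste(missing, collapse = ", ")))
      }
      setdiff(candidates$ids, seeds$metabolite)
    },
    random_k = {
      test <- candidates$test_metabolite
      if (!test %in% net$nodes$metabolite) {
        abort(sprintf("test metabolite %s not in network", dQuote(test)))
      }
      rest <- setdiff(pool, test)
      n_draw <- min(candidates$k - 1L, length(rest))
      drawn <- withr_seed(candidates$rng_seed, sample(rest, n_draw))
      c(test, drawn)
    })
  out <- .sort_ids(out)
  if (length(out) == 0L) abort("candidate set is empty after excluding seed metabolites")
  out
}

#' Prioritize candidate metabolites for a phenotype
#'
#' Runs the full pipeline — transition matrix, seed-weighted initial
#' vector, propagation to the steady state — and ranks the candidate
#' metabolites by their steady-state probability. Higher scores mean
#' greater global proximity to the seeds in the composite network. Seed
#' metabolites never appear among the candidates. Ties (bitwise-equal
#' scores) are broken by lexicographic metabolite id and flagged in the
#' `tied` column.
#'
#' @param net A `composite_network`.
#' @param seeds A [seed_set()]: the query phenotype plus its known genes
#'   and metabolites.
#' @param params An [rwr_params()].
#' @param candidates A [candidate_set()]; defaults to metabolome-wide.
#' @return A tibble of class `metprior_ranking` with columns `metabolite`,
#'   `score`, `rank`, `tied`; attributes carry the full steady-state
#'   vector, convergence info and the dangling-node report.
#' @examples
#' sim <- simulate_composite(synthetic_config(n_genes = 40, n_phenotypes = 6,
#'                                            n_metabolites = 30, n_diseases = 2))
#' ann <- sim$annotations[1, ]
#' pr <- prioritize(sim$network,
#'                  seed_set(phenotypes = ann$phenotype,
#'                           genes = ann$genes[[1]],
#'                           metabolites = ann$metabolites[[1]]))
#' head(pr)
#' @export
prioritize <- function(net, seeds, params = rwr_params(),
                       candidates = candidate_set("metabolome_wide")) {
  stopifnot(inherits(net, "composite_network"), inherits(params, "rwr_params"))
  .check_seeds(net, seeds)
  cand <- .resolve_candidates(net, seeds, candidates)

  W <- transition_matrix(net, params$x, params$y, params$z)
  p0 <- initial_vector(net, seeds, params$a, params$b)
  steady <- propagate(W, p0, params$alpha, params$tol, params$max_iter)

  scores <- steady[paste0("metabolite:", cand)]
  ord <- order(-scores, cand, method = "radix")
  scores <- as.numeric(scores[ord]); cand <- cand[ord]
  tied <- duplicated(scores) | duplicated(scores, fromLast = TRUE)

  out <- tibble::tibble(metabolite = cand, score = scores,
                        rank = seq_along(cand), tied = tied)
  structure(out,
            class = c("metprior_ranking", class(out)),
            steady = steady,
            seeds = seeds,
            params = params,
            n_iter = attr(steady, "n_iter"),
            converged = attr(steady, "converged"),
            dangling = attr(W, "dangling"))
}

#' @export
print.metprior_ranking <- function(x, ...) {
  cat(sprintf("# metabolite ranking (%d candidates%s)\n", nrow(x),
              if (isTRUE(attr(x, "converged"))) "" else ", NOT converged"))
  NextMethod()
}

#' Degree-preserving rewiring of a composite network
#'
#' Randomizes each of the six sub-networks independently by repeated
#' double-edge swaps: two edges (u1, v1), (u2, v2) are replaced by
#' (u1, v2), (u2, v1), with each weight travelling with the edge that
#' keeps its source endpoint. Swaps that would create a self-loop or a
#' duplicate edge are rejected, so every sub-network stays a simple
#' graph and every node's degree in every sub-network (both sides, for
#' the bipartite ones) is exactly preserved. This is the null model
#' behind [permutation_pvalues()].
#'
#' A sub-network with fewer than 2 edges cannot be swapped and is
#' returned unchanged.
#'
#' @param net A `composite_network`.
#' @param rng_seed Integer seed.
#' @param swaps_per_edge Number of attempted swaps per edge (default 10).
#' @return A rewired `composite_network` with identical node index and
#'   per-sub-network degree sequences.
#' @export
rewire_network <- function(net, rng_seed = 1L, swaps_per_edge = 10L) {
  stopifnot(inherits(net, "composite_network"))
  if (swaps_per_edge < 1L) abort("`swaps_per_edge` must be >= 1")
  e <- network_edges(net)
  subs <- unique(e$subnetwork)
  within_labels <- c("gene-gene", "phenotype-phenotype", "metabolite-metabolite")
  withr_seed(rng_seed, {
    parts <- lapply(split(e, e$subnetwork), function(ei) {
      lab <- ei$subnetwork[1]
      .rewire_edges(ei, undirected = lab %in% within_labels,
                    swaps_per_edge = swaps_per_edge)
    })
  })
  edges_to_network(dplyr::bind_rows(parts), nodes = net$nodes)
}

# double-edge swaps on one edge table; the O(1)-duplicate-check swap loop
# lives in compiled code (src/rewire.cpp) and draws from R's RNG stream
.rewire_edges <- function(ei, undirected, swaps_per_edge) {
  n_e <- nrow(ei)
  if (n_e < 2L) return(ei)
  ids <- .sort_ids(c(ei$source, if (undirected) ei$target))
  tids <- if (undirected) ids else .sort_ids(ei$target)
  res <- rewire_edges_impl(match(ei$source, ids), match(ei$target, tids),
                           length(ids), length(tids), undirected,
                           as.integer(swaps_per_edge) * n_e)
  out <- ei
  out$source <- ids[res$si]
  out$target <- tids[res$ti]
  out
}

#' Permutation p-values for a metabolite ranking
#'
#' Attaches an empirical p-value to every candidate: the probability of a
#' candidate scoring at least as high under a degree-preserving null. For
#' each permutation the composite network is rewired with
#' [rewire_network()], a random seed set with the same per-layer sizes as
#' the observed one is drawn, the walk is re-run, and each candidate's
#' null score recorded. The add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_perm)` is used, so p-values lie
#' in `[1/(n_perm + 1), 1]` and never reach 0.
#'
#' @inheritParams prioritize
#' @param n_perm Number of permutations (default 1000).
#' @param rng_seed Integer seed governing rewiring and null-seed draws.
#' @param swaps_per_edge Passed to [rewire_network()].
#' @return The [prioritize()] tibble with an additional `p_value` column.
#' @export
permutation_pvalues <- function(net, seeds, params = rwr_params(),
                                candidates = candidate_set("metabolome_wide"),
                                n_perm = 1000L, rng_seed = 1L,
                                swaps_per_edge = 10L) {
  if (n_perm < 1L) abort("`n_perm` must be >= 1")
  obs <- prioritize(net, seeds, params, candidates)
  cand_ids <- obs$metabolite
  n_layer <- vapply(.layers, function(l) length(seeds[[l]]), integer(1))

  exceed <- setNames(numeric(length(cand_ids)), cand_ids)
  obs_score <- setNames(obs$score, obs$metabolite)
  sub_seeds <- withr_seed(rng_seed, sample.int(.Machine$integer.max - 1L, 2L * n_perm))

  for (b in seq_len(n_perm)) {
    perm_net <- rewire_network(net, rng_seed = sub_seeds[2L * b - 1L],
                               swaps_per_edge = swaps_per_edge)
    null_seeds <- withr_seed(sub_seeds[2L * b], {
      seed_set(
        genes = if (n_layer[["gene"]]) sample(perm_net$nodes$gene, n_layer[["gene"]]) else character(),
        phenotypes = if (n_layer[["phenotype"]]) sample(perm_net$nodes$phenotype, n_layer[["phenotype"]]) else character(),
        metabolites = if (n_layer[["metabolite"]]) sample(perm_net$nodes$metabolite, n_layer[["metabolite"]]) else character())
    })
    W <- transition_matrix(perm_net, params$x, params$y, params$z)
    p0 <- initial_vector(perm_net, null_seeds, params$a, params$b)
    steady <- propagate(W, p0, params$alpha, params$tol, params$max_iter)
    null_scores <- steady[paste0("metabolite:", cand_ids)]
    exceed <- exceed + as.numeric(null_scores >= obs_score[cand_ids])
  }

  out <- obs
  out$p_value <- as.numeric((1 + exceed[out$metabolite]) / (1 + n_perm))
  out
}
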