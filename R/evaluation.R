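#' Disease annotation table
#'
#' Builds the table of known disease knowledge consumed by the validation
#' machinery: one row per phenotype with its known disease metabolites,
#' known disease genes, and an optional disease-class label.
#'
#' @param phenotype Character vector of phenotype ids.
#' @param metabolites List of character vectors (known metabolites per
#'   phenotype); may be empty vectors.
#' @param genes List of character vectors (known genes per phenotype).
#' @param class Optional character vector of disease-class labels.
#' @return A tibble with columns `phenotype`, `metabolites` (list),
#'   `genes` (list), `class`.
#' @export
disease_annotations <- function(phenotype, metabolites, genes,
                                class = NA_character_) {
  tibble::tibble(phenotype = as.character(phenotype),
                 metabolites = purrr::map(metabolites, as.character),
                 genes = purrr::map(genes, as.character),
                 class = as.character(class))
}

#' Read / write disease annotations as TSV
#'
#' The file has four tab-separated columns: phenotype id, comma-joined
#' known metabolite ids, comma-joined known gene ids, and an optional
#' class label (empty for unlabeled phenotypes). No header.
#'
#' @param path File path.
#' @return `read_annotations()`: the annotations tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  split_ids <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1]]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    abort(sprintf("malformed annotation line %d: expected at least 3 tab-separated fields",
                  which(lengths(fields) < 3L)[1]))
  }
  disease_annotations(
    phenotype = vapply(fields, `[`, "", 1L),
    metabolites = lapply(fields, function(f) split_ids(f[2L])),
    genes = lapply(fields, function(f) split_ids(f[3L])),
    class = vapply(fields, function(f) {
      if (length(f) >= 4L && nzchar(f[4L])) f[4L] else NA_character_
    }, ""))
}

#' @rdname read_annotations
#' @param annotations An annotations tibble.
#' @export
write_annotations <- function(annotations, path) {
  join <- function(x) vapply(x, paste, "", collapse = ",")
  cls <- ifelse(is.na(annotations$class), "", annotations$class)
  writeLines(paste(annotations$phenotype, join(annotations$metabolites),
                   join(annotations$genes), cls, sep = "\t"),
             path)
  invisible(path)
}

.check_annotations <- function(net, annotations) {
  for (i in seq_len(nrow(annotations))) {
    p <- annotations$phenotype[i]
    if (!p %in% net$nodes$phenotype) {
      abort(sprintf("annotated phenotype %s not in network", dQuote(p)))
    }
    mm <- setdiff(annotations$metabolites[[i]], net$nodes$metabolite)
    gm <- setdiff(annotations$genes[[i]], net$nodes$gene)
    if (length(mm)) abort(sprintf("known metabolite(s) of %s not in network: %s",
                                  p, paste(mm, collapse = ", ")))
    if (length(gm)) abort(sprintf("known gene(s) of %s not in network: %s",
                                  p, paste(gm, collapse = ", ")))
  }
  invisible(annotations)
}

#' Rank-based AUC over leave-one-out folds
#'
#' Each fold contributes the (mid)rank of its held-out metabolite among
#' `n_candidates` candidates; the AUC is the mean over folds of
#' `(n_candidates - rank) / (n_candidates - 1)` — the Mann-Whitney
#' probability that a held-out disease metabolite outranks a randomly
#' chosen non-disease candidate. Folds with fewer than 2 candidates carry
#' no ranking information and are skipped with a warning.
#'
#' @param folds A data frame with numeric columns `rank` (1 to
#'   `n_candidates`; midranks may be fractional) and `n_candidates`.
#' @return The AUC, a number in `[0, 1]`.
#' @export
auc_from_ranks <- function(folds) {
  stopifnot(is.data.frame(folds), all(c("rank", "n_candidates") %in% names(folds)))
  bad <- folds$n_candidates < 2
  if (any(bad)) {
    warn(sprintf("skipping %d fold(s) with fewer than 2 candidates", sum(bad)))
    folds <- folds[!bad, , drop = FALSE]
  }
  if (nrow(folds) == 0L) abort("no usable folds")
  if (any(folds$rank < 1 | folds$rank > folds$n_candidates)) {
    abort("fold ranks must lie in [1, n_candidates]")
  }
  mean((folds$n_candidates - folds$rank) / (folds$n_candidates - 1))
}

# midrank of score s among the candidate scores (descending: rank 1 = best)
.midrank <- function(scores, s) sum(scores > s) + (sum(scores == s) + 1) / 2

# metabolite-only walk: propagation restricted to the metabolite
# sub-network from metabolite seeds (the single-layer baseline comparator)
.metabolite_only_scores <- function(net, metabolite_seeds, params) {
  W <- .colnorm(net$mm)
  ids <- net$nodes$metabolite
  p0 <- setNames(numeric(length(ids)), ids)
  p0[metabolite_seeds] <- 1 / length(metabolite_seeds)
  p <- propagate(W, p0, params$alpha, params$tol, params$max_iter)
  setNames(as.numeric(p), ids)
}

#' Leave-one-out cross-validation of metabolite prioritization
#'
#' For every (phenotype, known metabolite) pair, hides the
#' phenotype-metabolite link, rebuilds the seeds, re-ranks the candidates
#' (which always include the held-out metabolite), and records the
#' held-out metabolite's midrank. Folds are pooled into one ROC over
#' normalized ranks, and the AUC is computed with the rank-sum identity
#' of [auc_from_ranks()].
#'
#' Ablation modes:
#' * `"full"` — seeds are the target phenotype, its known genes, and its
#'   other known metabolites. A phenotype with exactly one known
#'   metabolite contributes a fold seeded by phenotype + genes only.
#' * `"metabolite_only"` — the baseline comparator: propagation restricted
#'   to the metabolite sub-network, seeded by the other known metabolites
#'   only. Folds without a remaining metabolite seed are skipped.
#' * `"no_known_metabolites"` — every phenotype-metabolite link of the
#'   target phenotype is removed and seeds are phenotype + genes only;
#'   each known metabolite is still scored as a positive.
#'
#' @param net A `composite_network`.
#' @param annotations A [disease_annotations()] tibble.
#' @param params An [rwr_params()].
#' @param candidate_mode `"metabolome_wide"` (all non-seed metabolites) or
#'   `"random_k"` (the held-out metabolite plus `k - 1` random others).
#' @param k Candidate-set size for `"random_k"`.
#' @param ablation One of `"full"`, `"metabolite_only"`,
#'   `"no_known_metabolites"`.
#' @param rng_seed Integer seed (used only by `"random_k"` draws).
#' @return An object of class `metprior_validation`: a list with `folds`
#'   (tibble: phenotype, test_metabolite, rank, n_candidates, score,
#'   class), `roc` (tibble of FPR/TPR points), `auc`, `ablation` and
#'   `candidate_mode`.
#' @export
loocv <- function(net, annotations, params = rwr_params(),
                  candidate_mode = c("metabolome_wide", "random_k"), k = 100L,
                  ablation = c("full", "metabolite_only", "no_known_metabolites"),
                  rng_seed = 1L) {
  stopifnot(inherits(net, "composite_network"))
  candidate_mode <- match.arg(candidate_mode)
  ablation <- match.arg(ablation)
  .check_annotations(net, annotations)

  fold_rows <- list()
  fold_seed <- 0L
  pidx <- function(p) match(p, net$nodes$phenotype)

  for (i in seq_len(nrow(annotations))) {
    p <- annotations$phenotype[i]
    known_m <- .sort_ids(annotations$metabolites[[i]])
    known_g <- .sort_ids(annotations$genes[[i]])
    cls <- annotations$class[i]
    if (length(known_m) == 0L) next

    if (ablation == "no_known_metabolites") {
      net_f <- net
      net_f$pm[pidx(p), match(known_m, net$nodes$metabolite)] <- 0
      stopifnot(all(net_f$pm[pidx(p), match(known_m, net$nodes$metabolite)] == 0))
      seeds <- seed_set(phenotypes = p, genes = known_g)
      W <- transition_matrix(net_f, params$x, params$y, params$z)
      p0 <- initial_vector(net_f, seeds, params$a, params$b)
      steady <- propagate(W, p0, params$alpha, params$tol, params$max_iter)
      all_scores <- setNames(
        as.numeric(steady[paste0("metabolite:", net_f$nodes$metabolite)]),
        net_f$nodes$metabolite)
      for (t in known_m) {
        fold_seed <- fold_seed + 1L
        cand <- .loocv_candidates(net, character(), t, candidate_mode, k,
                                  rng_seed + fold_seed)
        sc <- all_scores[cand]
        fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
          phenotype = p, test_metabolite = t,
          rank = .midrank(sc, all_scores[[t]]),
          n_candidates = length(cand), score = all_scores[[t]], class = cls)
      }
      next
    }

    for (t in known_m) {
      fold_seed <- fold_seed + 1L
      other_m <- setdiff(known_m, t)
      if (ablation == "metabolite_only" && length(other_m) == 0L) {
        warn(sprintf("skipping fold (%s, %s): no metabolite seed remains for the metabolite-only baseline",
                     p, t))
        next
      }
      net_f <- net
      net_f$pm[pidx(p), match(t, net$nodes$metabolite)] <- 0
      stopifnot(net_f$pm[pidx(p), match(t, net$nodes$metabolite)] == 0)

      cand <- .loocv_candidates(net, other_m, t, candidate_mode, k,
                                rng_seed + fold_seed)

      if (ablation == "metabolite_only") {
        sc_all <- .metabolite_only_scores(net_f, other_m, params)
      } else {
        seeds <- if (length(other_m) == 0L) {
          seed_set(phenotypes = p, genes = known_g)
        } else {
          seed_set(phenotypes = p, genes = known_g, metabolites = other_m)
        }
        W <- transition_matrix(net_f, params$x, params$y, params$z)
        p0 <- initial_vector(net_f, seeds, params$a, params$b)
        steady <- propagate(W, p0, params$alpha, params$tol, params$max_iter)
        sc_all <- setNames(
          as.numeric(steady[paste0("metabolite:", net_f$nodes$metabolite)]),
          net_f$nodes$metabolite)
      }
      if (!t %in% cand) abort(sprintf("protocol violation: held-out metabolite %s absent from candidates", t))
      sc <- sc_all[cand]
      fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
        phenotype = p, test_metabolite = t,
        rank = .midrank(sc, sc_all[[t]]),
        n_candidates = length(cand), score = sc_all[[t]], class = cls)
    }
  }

  folds <- dplyr::bind_rows(fold_rows)
  if (nrow(folds) == 0L) abort("no LOOCV folds could be formed from the annotations")
  new_validation(folds, ablation, candidate_mode)
}

# candidate ids for one fold: metabolome-wide minus seed metabolites, or
# the held-out metabolite plus k-1 random non-seed metabolites
.loocv_candidates <- function(net, seed_metabolites, test, candidate_mode, k,
                              rng_seed) {
  pool <- setdiff(net$nodes$metabolite, seed_metabolites)
  if (candidate_mode == "metabolome_wide") return(pool)
  rest <- setdiff(pool, test)
  c(test, withr_seed(rng_seed, sample(rest, min(k - 1L, length(rest)))))
}

new_validation <- function(folds, ablation, candidate_mode) {
  u <- (folds$rank - 1) / (folds$n_candidates - 1)
  us <- sort(u)
  roc <- tibble::tibble(fpr = c(0, us, 1),
                        tpr = c(0, seq_along(us) / length(us), 1))
  structure(list(folds = folds, roc = roc, auc = auc_from_ranks(folds),
                 ablation = ablation, candidate_mode = candidate_mode),
            class = "metprior_validation")
}

#' @export
print.metprior_validation <- function(x, ...) {
  cat(sprintf("<metprior_validation> %s ablation, %s candidates: AUC = %.4f over %d folds (%d phenotypes)\n",
              x$ablation, x$candidate_mode, x$auc, nrow(x$folds),
              length(unique(x$folds$phenotype))))
  invisible(x)
}

#' Per-disease-class AUC
#'
#' Recomputes the rank-based AUC separately for the folds of each disease
#' class, plus the mean and standard error of the per-class AUCs.
#'
#' @param result A `metprior_validation` from [loocv()].
#' @param class_map Optional tibble with columns `phenotype`, `class`
#'   overriding the classes stored in the folds. Folds without a label are
#'   grouped under `"unclassified"`.
#' @return A tibble (class `metprior_classwise`) with columns `class`,
#'   `auc`, `n_folds`; attributes `mean_auc` and `se_auc` summarize across
#'   classes.
#' @export
classwise_auc <- function(result, class_map = NULL) {
  stopifnot(inherits(result, "metprior_validation"))
  folds <- result$folds
  if (!is.null(class_map)) {
    folds$class <- class_map$class[match(folds$phenotype, class_map$phenotype)]
  }
  folds$class[is.na(folds$class)] <- "unclassified"
  out <- folds |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(auc = auc_from_ranks(dplyr::pick(dplyr::everything())),
                     n_folds = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$class)
  structure(out,
            class = c("metprior_classwise", class(out)),
            mean_auc = mean(out$auc),
            se_auc = if (nrow(out) > 1) sd(out$auc) / sqrt(nrow(out)) else NA_real_)
}

#' Noise-robustness sweep
#'
#' Re-runs LOOCV on copies of the network whose edge weights are mixed
#' with uniform noise at each `sigma` (see [perturb_weights()]);
#' `sigma = 0` is the unperturbed network. Deterministic given `rng_seed`.
#'
#' @inheritParams loocv
#' @param sigmas Noise proportions in `[0, 1]`.
#' @param rng_seed Seed for the per-sigma noise draws.
#' @param ... Passed on to [loocv()] (e.g. `candidate_mode`, `ablation`).
#' @return A tibble with columns `sigma`, `auc`, `n_folds`.
#' @export
noise_sweep <- function(net, annotations, params = rwr_params(),
                        sigmas = c(0, 0.25, 0.5, 0.75, 1), rng_seed = 1L, ...) {
  stopifnot(all(sigmas >= 0 & sigmas <= 1))
  noise_seeds <- withr_seed(rng_seed, sample.int(.Machine$integer.max - 1L,
                                                 length(sigmas)))
  purrr::map2_dfr(sigmas, noise_seeds, function(s, ns) {
    net_s <- if (s == 0) net else perturb_weights(net, s, rng_seed = ns)
    v <- loocv(net_s, annotations, params, rng_seed = rng_seed, ...)
    tibble::tibble(sigma = s, auc = v$auc, n_folds = nrow(v$folds))
  })
}

#' Parameter sweep over the walk's knobs
#'
#' Runs LOOCV at every row of a parameter grid. Grid rows violating the
#' [rwr_params()] budget constraints are rejected up front with a warning
#' listing them.
#'
#' @inheritParams loocv
#' @param grid A data frame with any subset of columns `alpha`, `x`, `y`,
#'   `z`, `a`, `b`; missing columns take the defaults.
#' @param ... Passed on to [loocv()].
#' @return The valid grid rows with an added `auc` column.
#' @export
parameter_sweep <- function(net, annotations, grid, params = rwr_params(), ...) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) abort("`grid` must be a non-empty data frame")
  known <- c("alpha", "x", "y", "z", "a", "b")
  extra <- setdiff(names(grid), known)
  if (length(extra)) abort(sprintf("unknown grid column(s): %s", paste(extra, collapse = ", ")))

  mk <- function(row) {
    args <- as.list(row)
    base <- params[c("alpha", "x", "y", "z", "a", "b", "tol", "max_iter")]
    base[names(args)] <- args
    do.call(rwr_params, base)
  }
  parsed <- purrr::map(seq_len(nrow(grid)),
                       function(i) tryCatch(mk(grid[i, , drop = FALSE]),
                                            error = function(e) e))
  bad <- vapply(parsed, inherits, logical(1), "error")
  if (any(bad)) {
    warn(sprintf("rejecting %d grid point(s) violating parameter budgets (rows %s)",
                 sum(bad), paste(which(bad), collapse = ", ")))
  }
  if (all(bad)) abort("no valid grid points")

  res <- purrr::map_dfr(which(!bad), function(i) {
    v <- loocv(net, annotations, parsed[[i]], ...)
    dplyr::bind_cols(tibble::as_tibble(grid[i, , drop = FALSE]),
                     tibble::tibble(auc = v$auc, n_folds = nrow(v$folds)))
  })
  res
}

#' Phenotype-by-metabolite score matrix
#'
#' Runs the walk once per annotated phenotype with its full knowledge as
#' seeds (nothing held out) and collects the steady-state scores of every
#' metabolite node: the global disease-metabolite landscape. Seed
#' metabolites keep their scores in the matrix (each row is the
#' metabolite-layer restriction of a probability vector); their ids are
#' reported in the `"seed_metabolites"` attribute so downstream exports
#' can exclude them.
#'
#' @inheritParams loocv
#' @return A numeric matrix (rows = phenotypes, columns = metabolites) of
#'   class `metprior_score_matrix`, with attribute `seed_metabolites`
#'   (named list of each row's seed metabolites).
#' @export
score_matrix <- function(net, annotations, params = rwr_params()) {
  .check_annotations(net, annotations)
  W <- transition_matrix(net, params$x, params$y, params$z)
  ids <- net$nodes$metabolite
  out <- matrix(NA_real_, nrow(annotations), length(ids),
                dimnames = list(annotations$phenotype, ids))
  excl <- list()
  for (i in seq_len(nrow(annotations))) {
    seeds <- seed_set(phenotypes = annotations$phenotype[i],
                      genes = annotations$genes[[i]],
                      metabolites = annotations$metabolites[[i]])
    p0 <- initial_vector(net, seeds, params$a, params$b)
    steady <- propagate(W, p0, params$alpha, params$tol, params$max_iter)
    out[i, ] <- as.numeric(steady[paste0("metabolite:", ids)])
    excl[[annotations$phenotype[i]]] <- seeds$metabolite
  }
  structure(out, class = c("metprior_score_matrix", "matrix", "array"),
            seed_metabolites = excl)
}

#' Top-k metabolites per phenotype from a score matrix
#'
#' Long-format export of the highest-scoring non-seed metabolites of each
#' phenotype, suitable for writing as TSV.
#'
#' @param scores A [score_matrix()] result.
#' @param k Number of metabolites per phenotype.
#' @return A tibble with columns `phenotype`, `metabolite`, `score`,
#'   `rank`.
#' @export
top_scores <- function(scores, k = 50L) {
  stopifnot(inherits(scores, "metprior_score_matrix"))
  excl <- attr(scores, "seed_metabolites")
  purrr::map_dfr(rownames(scores), function(p) {
    s <- scores[p, ]
    s <- s[!names(s) %in% excl[[p]]]
    ord <- order(-s, names(s), method = "radix")
    top <- head(ord, k)
    tibble::tibble(phenotype = p, metabolite = names(s)[top],
                   score = as.numeric(s[top]), rank = seq_along(top))
  })
}
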