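#' Tidy a metabolite ranking
#'
#' @param x A `metprior_ranking` from [prioritize()] or
#'   [permutation_pvalues()].
#' @param ... Unused.
#' @return A plain tibble with one row per candidate metabolite.
#' @export
tidy.metprior_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("metabolite", "score", "rank", "tied",
                                 intersect("p_value", names(x)))])
}

#' @rdname tidy.metprior_ranking
#' @export
glance.metprior_ranking <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x),
                 top_metabolite = x$metabolite[1],
                 top_score = x$score[1],
                 n_iter = attr(x, "n_iter") %||% NA_integer_,
                 converged = attr(x, "converged") %||% NA,
                 n_dangling = length(attr(x, "dangling") %||% character()))
}

#' Tidy a validation result
#'
#' @param x A `metprior_validation` from [loocv()].
#' @param ... Unused.
#' @return The per-fold tibble (`tidy`) or a one-row summary (`glance`).
#' @export
tidy.metprior_validation <- function(x, ...) x$folds

#' @rdname tidy.metprior_validation
#' @export
glance.metprior_validation <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_folds = nrow(x$folds),
                 n_phenotypes = length(unique(x$folds$phenotype)),
                 ablation = x$ablation, candidate_mode = x$candidate_mode)
}

#' Tidy a per-class AUC table
#'
#' @param x A `metprior_classwise` from [classwise_auc()].
#' @param ... Unused.
#' @export
tidy.metprior_classwise <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.metprior_classwise
#' @export
glance.metprior_classwise <- function(x, ...) {
  tibble::tibble(mean_auc = attr(x, "mean_auc"), se_auc = attr(x, "se_auc"),
                 n_classes = nrow(x))
}
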