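#' Random-walk-with-restart parameters
#'
#' Bundles every knob of the propagation model. `alpha` is the restart
#' probability: at each step the walker returns to the seed distribution
#' with probability `alpha` and otherwise moves along an edge. `x`, `y`
#' and `z` are the jumping probabilities between the gene and phenotype
#' networks, the gene and metabolite networks, and the phenotype and
#' metabolite networks respectively: the fraction of a node's outgoing
#' mass budgeted for crossing into the other layer (the remainder stays
#' within its own layer). `a`, `b` and `1 - a - b` weight the initial
#' restart mass given to gene, phenotype and metabolite seeds.
#'
#' Budget constraints: `x + y <= 1` (out of a gene), `x + z <= 1` (out of
#' a phenotype), `y + z <= 1` (out of a metabolite), and `a + b <= 1`.
#'
#' @param alpha Restart probability in `(0, 1]`. Default 0.7.
#' @param x,y,z Jumping probabilities in `[0, 1]`. Default 1/3 each.
#' @param a,b Seed-layer weights in `[0, 1]`. Default 1/3 each.
#' @param tol L1 convergence threshold for the iterative solver.
#' @param max_iter Iteration cap for the iterative solver.
#' @return A list of class `rwr_params`.
#' @export
rwr_params <- function(alpha = 0.7, x = 1/3, y = 1/3, z = 1/3,
                       a = 1/3, b = 1/3, tol = 1e-10, max_iter = 1e6) {
  num1 <- function(v, arg, lo, hi, lo_open = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v > hi || (if (lo_open) v <= lo else v < lo)) {
      abort(sprintf("`%s` must be a single number in %s%g, %g]",
                    arg, if (lo_open) "(" else "[", lo, hi))
    }
    as.numeric(v)
  }
  alpha <- num1(alpha, "alpha", 0, 1, lo_open = TRUE)
  x <- num1(x, "x", 0, 1); y <- num1(y, "y", 0, 1); z <- num1(z, "z", 0, 1)
  a <- num1(a, "a", 0, 1); b <- num1(b, "b", 0, 1)
  eps <- 1e-12
  if (x + y > 1 + eps || x + z > 1 + eps || y + z > 1 + eps) {
    abort("jumping probabilities violate the layer budgets: need x + y <= 1, x + z <= 1 and y + z <= 1")
  }
  if (a + b > 1 + eps) abort("seed-layer weights must satisfy a + b <= 1")
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    abort("`tol` must be a positive number")
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1) {
    abort("`max_iter` must be a positive integer")
  }
  structure(list(alpha = alpha, x = x, y = y, z = z, a = a, b = b,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

#' @export
print.rwr_params <- function(x, ...) {
  cat(sprintf("<rwr_params> alpha=%g x=%g y=%g z=%g a=%g b=%g tol=%g max_iter=%d\n",
              x$alpha, x$x, x$y, x$z, x$a, x$b, x$tol, x$max_iter))
  invisible(x)
}

#' Seed set for a prioritization query
#'
#' The prior knowledge a walk restarts from: the phenotype(s) of interest,
#' their known disease genes and known disease metabolites. At least one
#' seed is required overall; any of the three layers may be empty.
#'
#' @param phenotypes,genes,metabolites Character vectors of node ids.
#' @return A list of class `seed_set`.
#' @export
seed_set <- function(phenotypes = character(), genes = character(),
                     metabolites = character()) {
  s <- list(gene = .sort_ids(as.character(genes)),
            phenotype = .sort_ids(as.character(phenotypes)),
            metabolite = .sort_ids(as.character(metabolites)))
  if (sum(lengths(s)) == 0L) abort("seed set is empty: at least one seed node is required")
  structure(s, class = "seed_set")
}

.check_seeds <- function(net, seeds) {
  stopifnot(inherits(seeds, "seed_set"))
  for (layer in .layers) {
    missing <- setdiff(seeds[[layer]], net$nodes[[layer]])
    if (length(missing) > 0L) {
      abort(sprintf("seed %s node(s) not in network: %s",
                    layer, paste(missing, collapse = ", ")))
    }
  }
  invisible(seeds)
}

# column-normalize a sparse block; zero columns stay zero
.colnorm <- function(M) {
  cs <- Matrix::colSums(M)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  M %*% Matrix::Diagonal(x = scale)
}

#' Column-stochastic transition matrix of the composite network
#'
#' Builds the transition matrix of the walk on the composite network.
#' Out of a node, mass is budgeted per destination block — from a gene:
#' `x` to phenotypes, `y` to metabolites, the remainder to genes; from a
#' phenotype: `x` to genes, `z` to metabolites, remainder to phenotypes;
#' from a metabolite: `y` to genes, `z` to phenotypes, remainder to
#' metabolites — and distributed within each block proportionally to edge
#' weight. Two reallocation rules keep columns stochastic when a node
#' lacks edges into a budgeted block:
#'
#' * R1: the budget of a cross-layer block with no edges is reassigned to
#'   the node's within-layer block.
#' * R2: if the within-layer block is also empty, the mass is split among
#'   the present cross-layer blocks proportionally to their nominal
#'   budgets (equally, if those budgets are all zero).
#'
#' A node with no edges at all yields an all-zero (dangling) column; the
#' dangling nodes are listed in the `"dangling"` attribute.
#'
#' @param net A `composite_network`.
#' @param x,y,z Jumping probabilities (see [rwr_params()]).
#' @return A sparse column-stochastic matrix over the composite nodes
#'   (order: genes, phenotypes, metabolites), where entry (j, i) is the
#'   probability of stepping from node i to node j. The matrix
#'   left-multiplies probability vectors. Attribute `"dangling"` holds the
#'   names of all-isolated nodes.
#' @export
transition_matrix <- function(net, x = 1/3, y = 1/3, z = 1/3) {
  stopifnot(inherits(net, "composite_network"))
  p <- rwr_params(x = x, y = y, z = z) # reuse budget validation
  x <- p$x; y <- p$y; z <- p$z
  if (sum(vapply(net$nodes, length, integer(1))) == 0L) {
    abort("cannot build a transition matrix for an empty network")
  }

  # destination-block weight matrices per source layer (rows = destination)
  blocks <- list(
    gene = list(within = net$gg,
                cross = list(list(M = net$pg, budget = x),           # -> phenotype
                             list(M = Matrix::t(net$gm), budget = y))), # -> metabolite
    phenotype = list(within = net$pp,
                     cross = list(list(M = Matrix::t(net$pg), budget = x),    # -> gene
                                  list(M = Matrix::t(net$pm), budget = z))),  # -> metabolite
    metabolite = list(within = net$mm,
                      cross = list(list(M = net$gm, budget = y),   # -> gene
                                   list(M = net$pm, budget = z)))) # -> phenotype

  cols <- list()
  for (layer in .layers) {
    b <- blocks[[layer]]
    n_src <- length(net$nodes[[layer]])
    if (n_src == 0L) { cols[[layer]] <- NULL; next }
    w_present <- Matrix::colSums(b$within) > 0
    c1_present <- Matrix::colSums(b$cross[[1]]$M) > 0
    c2_present <- Matrix::colSums(b$cross[[2]]$M) > 0
    b1 <- b$cross[[1]]$budget; b2 <- b$cross[[2]]$budget

    # per-column budget for each block (R1/R2 reallocation, vectorized)
    bud_w <- numeric(n_src); bud_1 <- numeric(n_src); bud_2 <- numeric(n_src)
    has_w <- w_present
    bud_1[has_w & c1_present] <- b1
    bud_2[has_w & c2_present] <- b2
    bud_w[has_w] <- 1 - bud_1[has_w] - bud_2[has_w]
    no_w <- !w_present & (c1_present | c2_present)
    if (any(no_w)) {
      s <- b1 * c1_present[no_w] + b2 * c2_present[no_w]
      both0 <- s == 0
      bud_1[no_w] <- ifelse(both0,
                            c1_present[no_w] / pmax(1, c1_present[no_w] + c2_present[no_w]),
                            b1 * c1_present[no_w] / pmax(s, .Machine$double.eps))
      bud_2[no_w] <- ifelse(both0,
                            c2_present[no_w] / pmax(1, c1_present[no_w] + c2_present[no_w]),
                            b2 * c2_present[no_w] / pmax(s, .Machine$double.eps))
    }

    scale <- function(M, bud) .colnorm(M) %*% Matrix::Diagonal(x = bud)
    wb <- scale(b$within, bud_w)
    c1 <- scale(b$cross[[1]]$M, bud_1)
    c2 <- scale(b$cross[[2]]$M, bud_2)
    # stack destination blocks into composite row order (gene, phenotype, metabolite)
    stacked <- switch(layer,
      gene = rbind(wb, c1, c2),
      phenotype = rbind(c1, wb, c2),
      metabolite = rbind(c1, c2, wb))
    cols[[layer]] <- stacked
  }

  W <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
  nm <- node_names(net)
  dimnames(W) <- list(nm, nm)
  dangling <- nm[Matrix::colSums(W) == 0]
  W <- methods::as(W, "CsparseMatrix")
  attr(W, "dangling") <- dangling
  W
}

#' Seed-weighted initial probability vector
#'
#' Distributes the restart mass over the seeds: gene seeds share mass `a`
#' equally, phenotype seeds share `b`, metabolite seeds share `1 - a - b`.
#' The mass of a layer without seeds is redistributed proportionally to
#' the layers that do have seeds, so the vector always sums to 1 (if the
#' seeded layers all have nominal mass 0, the mass is split equally among
#' them).
#'
#' @param net A `composite_network`.
#' @param seeds A [seed_set()].
#' @param a,b Seed-layer weights (see [rwr_params()]).
#' @return A named numeric vector over the composite nodes, summing to 1.
#' @export
initial_vector <- function(net, seeds, a = 1/3, b = 1/3) {
  stopifnot(inherits(net, "composite_network"))
  .check_seeds(net, seeds)
  p <- rwr_params(a = a, b = b)
  nominal <- c(gene = p$a, phenotype = p$b, metabolite = 1 - p$a - p$b)
  seeded <- vapply(.layers, function(l) length(seeds[[l]]) > 0L, logical(1))
  mass <- nominal * seeded
  if (sum(mass) > 0) mass <- mass / sum(mass) else mass[seeded] <- 1 / sum(seeded)

  nm <- node_names(net)
  p0 <- setNames(numeric(length(nm)), nm)
  for (layer in .layers) {
    if (!seeded[[layer]]) next
    ids <- paste0(layer, ":", seeds[[layer]])
    p0[ids] <- mass[[layer]] / length(ids)
  }
  p0
}

#' Iterate the walk to its steady state
#'
#' Runs `p_{k+1} = (1 - alpha) * W %*% p_k + alpha * p0` until the L1
#' change between successive iterates drops below `tol` or `max_iter` is
#' reached. With dangling (all-zero) columns the walk loses the mass that
#' enters them at each step, but the restart term keeps re-injecting seed
#' mass, so the iteration still converges; a fully isolated node retains
#' exactly its restart mass `alpha * p0[node]`, and mass conservation
#' (iterates summing to 1) holds exactly only when no column is dangling.
#'
#' @param W Column-stochastic transition matrix from [transition_matrix()].
#' @param p0 Initial vector from [initial_vector()].
#' @param alpha Restart probability.
#' @param tol L1 convergence threshold.
#' @param max_iter Iteration cap.
#' @return The steady-state vector with attributes `n_iter` and
#'   `converged`. Non-convergence raises a warning, never a silent return.
#' @export
propagate <- function(W, p0, alpha = 0.7, tol = 1e-10, max_iter = 1e6) {
  stopifnot(length(p0) == nrow(W))
  if (abs(sum(p0) - 1) > 1e-9) abort("`p0` must sum to 1")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1]")
  p <- p0
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    p_new <- as.numeric((1 - alpha) * (W %*% p)) + alpha * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("propagation did not converge within %d iterations (last L1 change %.3g)",
                 n_iter, delta))
  }
  names(p) <- rownames(W)
  attr(p, "n_iter") <- n_iter
  attr(p, "converged") <- converged
  p
}

#' Closed-form steady state of the walk
#'
#' Solves the fixed-point equation `p = (1 - alpha) W p + alpha p0`
#' directly as `(I - (1 - alpha) W) p = alpha p0`. Serves as an
#' independent check on [propagate()] for networks small enough for a
#' direct solve.
#'
#' @inheritParams propagate
#' @return The steady-state vector.
#' @export
solve_steady_state <- function(W, p0, alpha = 0.7) {
  stopifnot(length(p0) == nrow(W))
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1]")
  if (nrow(W) > 20000L) {
    abort("direct solve guarded to networks of at most 20,000 nodes; use propagate()")
  }
  A <- Matrix::Diagonal(nrow(W)) - (1 - alpha) * W
  p <- as.numeric(Matrix::solve(A, alpha * p0))
  names(p) <- rownames(W)
  p
}
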