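#' Assemble a three-layer composite network from six edge lists
#'
#' Builds the composite gene/phenotype/metabolite network from its six
#' weighted sub-networks: three within-layer association networks
#' (gene-gene, phenotype-phenotype, metabolite-metabolite) and three
#' cross-layer bipartite networks (gene-metabolite, phenotype-gene,
#' phenotype-metabolite). The node index of each layer is the union of all
#' ids seen for that layer across the six lists, so a node referenced only
#' by a cross-layer edge is still registered (with no within-layer edges).
#' The full block adjacency implied by the six matrices and their
#' transposes is symmetric by construction.
#'
#' @param gg,pp,mm Within-layer `metprior_edges` (gene-gene,
#'   phenotype-phenotype, metabolite-metabolite) or `NULL` for an empty
#'   sub-network.
#' @param gm,pg,pm Cross-layer `metprior_edges` (gene-metabolite,
#'   phenotype-gene, phenotype-metabolite) or `NULL`.
#'
#' @return A `composite_network` object: a list with `nodes` (character
#'   vectors `gene`, `phenotype`, `metabolite`) and sparse weight matrices
#'   `gg` (gene x gene, symmetric), `pp`, `mm`, `gm` (gene x metabolite),
#'   `pg` (phenotype x gene), `pm` (phenotype x metabolite).
#'
#' @examples
#' gg <- edge_list("g1", "g2", 1, "gene", "gene")
#' pg <- edge_list("p1", "g1", 1, "phenotype", "gene")
#' pm <- edge_list("p1", "m1", 1, "phenotype", "metabolite")
#' net <- composite_network(gg = gg, pg = pg, pm = pm)
#' net
#' @export
composite_network <- function(gg = NULL, pp = NULL, mm = NULL,
                              gm = NULL, pg = NULL, pm = NULL) {
  chk <- function(e, arg, sl, tl) {
    if (is.null(e)) return(edge_list(character(), character(), numeric(), sl, tl))
    if (!inherits(e, "metprior_edges")) {
      abort(sprintf("`%s` must be a metprior_edges object (see edge_list())", arg))
    }
    if (!identical(attr(e, "source_layer"), sl) ||
        !identical(attr(e, "target_layer"), tl)) {
      abort(sprintf("`%s` must have layers (%s, %s), got (%s, %s)",
                    arg, sl, tl, attr(e, "source_layer"), attr(e, "target_layer")))
    }
    e
  }
  gg <- chk(gg, "gg", "gene", "gene")
  pp <- chk(pp, "pp", "phenotype", "phenotype")
  mm <- chk(mm, "mm", "metabolite", "metabolite")
  gm <- chk(gm, "gm", "gene", "metabolite")
  pg <- chk(pg, "pg", "phenotype", "gene")
  pm <- chk(pm, "pm", "phenotype", "metabolite")

  genes <- .sort_ids(c(gg$source, gg$target, gm$source, pg$target))
  phenos <- .sort_ids(c(pp$source, pp$target, pg$source, pm$source))
  metabs <- .sort_ids(c(mm$source, mm$target, gm$target, pm$target))

  if (length(genes) + length(phenos) + length(metabs) == 0L) {
    warn("composite network is empty: all six edge lists are empty")
  }

  sym <- function(e, ids) {
    i <- match(e$source, ids); j <- match(e$target, ids)
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(e$weight, e$weight),
                         dims = c(length(ids), length(ids)),
                         dimnames = list(ids, ids))
  }
  bip <- function(e, rids, cids) {
    Matrix::sparseMatrix(i = match(e$source, rids), j = match(e$target, cids),
                         x = e$weight,
                         dims = c(length(rids), length(cids)),
                         dimnames = list(rids, cids))
  }

  structure(list(
    nodes = list(gene = genes, phenotype = phenos, metabolite = metabs),
    gg = sym(gg, genes), pp = sym(pp, phenos), mm = sym(mm, metabs),
    gm = bip(gm, genes, metabs), pg = bip(pg, phenos, genes),
    pm = bip(pm, phenos, metabs)
  ), class = "composite_network")
}

#' Read a composite network from a directory of six edge-list TSVs
#'
#' Expects files `gene_gene.tsv`, `phenotype_phenotype.tsv`,
#' `metabolite_metabolite.tsv`, `gene_metabolite.tsv`,
#' `phenotype_gene.tsv`, `phenotype_metabolite.tsv` (missing files are
#' treated as empty sub-networks). This plain-text directory layout is the
#' package's network bundle format; [write_composite()] adds a
#' `manifest.json`-style provenance file.
#'
#' @param dir Directory containing the TSVs.
#' @param quiet Passed to [read_edge_list()].
#' @return A `composite_network`.
#' @export
read_composite <- function(dir, quiet = TRUE) {
  rd <- function(file, sl, tl) {
    p <- file.path(dir, file)
    if (file.exists(p)) read_edge_list(p, sl, tl, quiet = quiet) else NULL
  }
  composite_network(
    gg = rd("gene_gene.tsv", "gene", "gene"),
    pp = rd("phenotype_phenotype.tsv", "phenotype", "phenotype"),
    mm = rd("metabolite_metabolite.tsv", "metabolite", "metabolite"),
    gm = rd("gene_metabolite.tsv", "gene", "metabolite"),
    pg = rd("phenotype_gene.tsv", "phenotype", "gene"),
    pm = rd("phenotype_metabolite.tsv", "phenotype", "metabolite"))
}

#' Write a composite network as a directory bundle
#'
#' Writes the six sub-networks as TSV edge lists plus a small JSON manifest
#' recording the bundle format version and node counts. The bundle is
#' plain text and round-trips through [read_composite()].
#'
#' @param net A `composite_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_composite <- function(net, dir) {
  stopifnot(inherits(net, "composite_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- network_edges(net)
  files <- c(`gene-gene` = "gene_gene.tsv",
             `phenotype-phenotype` = "phenotype_phenotype.tsv",
             `metabolite-metabolite` = "metabolite_metabolite.tsv",
             `gene-metabolite` = "gene_metabolite.tsv",
             `phenotype-gene` = "phenotype_gene.tsv",
             `phenotype-metabolite` = "phenotype_metabolite.tsv")
  for (sub in names(files)) {
    ei <- e[e$subnetwork == sub, ]
    writeLines(sprintf("%s\t%s\t%s", ei$source, ei$target,
                       format(ei$weight, digits = 17, scientific = FALSE,
                              trim = TRUE)),
               file.path(dir, files[[sub]]))
  }
  n <- vapply(net$nodes, length, integer(1))
  writeLines(sprintf(
    '{"format": "metprior-bundle", "version": 1, "n_gene": %d, "n_phenotype": %d, "n_metabolite": %d}',
    n[["gene"]], n[["phenotype"]], n[["metabolite"]]),
    file.path(dir, "manifest.json"))
  invisible(dir)
}

#' All edges of a composite network as one tidy table
#'
#' @param net A `composite_network`.
#' @return A tibble with columns `subnetwork` (e.g. `"gene-gene"`),
#'   `source`, `target`, `weight`. Within-layer edges appear once, with
#'   `source < target`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "composite_network"))
  up <- function(M, label) {
    if (nrow(M) == 0L) {
      return(tibble::tibble(subnetwork = character(), source = character(),
                            target = character(), weight = numeric()))
    }
    t <- as(Matrix::triu(M, k = 1L), "TsparseMatrix")
    tibble::tibble(subnetwork = rep(label, length(t@x)),
                   source = rownames(M)[t@i + 1L],
                   target = colnames(M)[t@j + 1L], weight = t@x)
  }
  bp <- function(M, label) {
    t <- as(M, "TsparseMatrix")
    tibble::tibble(subnetwork = rep(label, length(t@x)),
                   source = rownames(M)[t@i + 1L],
                   target = colnames(M)[t@j + 1L], weight = t@x)
  }
  out <- dplyr::bind_rows(
    up(net$gg, "gene-gene"), up(net$pp, "phenotype-phenotype"),
    up(net$mm, "metabolite-metabolite"), bp(net$gm, "gene-metabolite"),
    bp(net$pg, "phenotype-gene"), bp(net$pm, "phenotype-metabolite"))
  dplyr::arrange(out, .data$subnetwork, .data$source, .data$target)
}

#' Full block adjacency of the composite network
#'
#' Assembles the symmetric (n_gene + n_phenotype + n_metabolite)-square
#' sparse adjacency from the six sub-matrices and their transposes, with
#' node order genes, then phenotypes, then metabolites.
#'
#' @param net A `composite_network`.
#' @return A symmetric `dgCMatrix`.
#' @export
block_adjacency <- function(net) {
  stopifnot(inherits(net, "composite_network"))
  A <- rbind(
    cbind(net$gg, Matrix::t(net$pg), net$gm),
    cbind(net$pg, net$pp, net$pm),
    cbind(Matrix::t(net$gm), Matrix::t(net$pm), net$mm))
  rownames(A) <- colnames(A) <- node_names(net)
  methods::as(A, "CsparseMatrix")
}

# "layer:id" labels in composite node order
node_names <- function(net) {
  lab <- function(layer) {
    ids <- net$nodes[[layer]]
    if (length(ids) == 0L) character(0) else paste0(layer, ":", ids)
  }
  c(lab("gene"), lab("phenotype"), lab("metabolite"))
}

#' Summary counts per sub-network
#'
#' @param net A `composite_network`.
#' @return A tibble with one row per sub-network: node counts on each side
#'   and edge count, plus a total row across the composite.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "composite_network"))
  nz_up <- function(M) Matrix::nnzero(Matrix::triu(M, k = 1L))
  deg_nodes <- function(M, margin) sum(apply_margin_nnz(M, margin) > 0L)
  rows <- tibble::tibble(
    subnetwork = c("gene-gene", "phenotype-phenotype", "metabolite-metabolite",
                   "gene-metabolite", "phenotype-gene", "phenotype-metabolite"),
    n_source = c(length(net$nodes$gene), length(net$nodes$phenotype),
                 length(net$nodes$metabolite),
                 deg_nodes(net$gm, 1L), deg_nodes(net$pg, 1L), deg_nodes(net$pm, 1L)),
    n_target = c(length(net$nodes$gene), length(net$nodes$phenotype),
                 length(net$nodes$metabolite),
                 deg_nodes(net$gm, 2L), deg_nodes(net$pg, 2L), deg_nodes(net$pm, 2L)),
    n_edges = c(nz_up(net$gg), nz_up(net$pp), nz_up(net$mm),
                Matrix::nnzero(net$gm), Matrix::nnzero(net$pg),
                Matrix::nnzero(net$pm)))
  dplyr::bind_rows(rows, tibble::tibble(
    subnetwork = "composite",
    n_source = sum(vapply(net$nodes, length, integer(1))),
    n_target = sum(vapply(net$nodes, length, integer(1))),
    n_edges = sum(rows$n_edges)))
}

apply_margin_nnz <- function(M, margin) {
  if (margin == 1L) Matrix::rowSums(M != 0) else Matrix::colSums(M != 0)
}

#' @export
print.composite_network <- function(x, ...) {
  n <- vapply(x$nodes, length, integer(1))
  s <- network_summary(x)
  cat(sprintf("<composite_network> %d genes, %d phenotypes, %d metabolites, %d edges\n",
              n[["gene"]], n[["phenotype"]], n[["metabolite"]],
              s$n_edges[s$subnetwork == "composite"]))
  invisible(x)
}

#' Perturb edge weights with uniform noise
#'
#' Replaces every edge weight `w` by `(1 - sigma) * w + sigma * r` with `r`
#' drawn independently per edge from U(0, 1). `sigma` is the proportion of
#' noise in the combined score: `sigma = 0` returns the weights unchanged
#' and `sigma = 1` replaces them entirely by uniform noise. The topology is
#' untouched, and each undirected within-layer edge is perturbed once (the
#' same value lands on both triangle halves). Deterministic given
#' `rng_seed`.
#'
#' Weights are expected on a 0-1 confidence scale; a warning is issued if
#' any input weight exceeds 1, since the uniform admixture is then no
#' longer on the weights' own scale.
#'
#' @param net A `composite_network`.
#' @param sigma Noise proportion in `[0, 1]`.
#' @param rng_seed Integer seed for the noise draws.
#' @return A new `composite_network` with perturbed weights.
#' @export
perturb_weights <- function(net, sigma, rng_seed = 1L) {
  stopifnot(inherits(net, "composite_network"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
      sigma < 0 || sigma > 1) {
    abort("`sigma` must be a single number in [0, 1]")
  }
  e <- network_edges(net)
  if (any(e$weight > 1)) {
    warn("some edge weights exceed 1; the uniform noise mixture assumes weights on a 0-1 scale")
  }
  if (sigma > 0 && nrow(e) > 0) {
    r <- withr_seed(rng_seed, runif(nrow(e)))
    e$weight <- (1 - sigma) * e$weight + sigma * r
  }
  edges_to_network(e, nodes = net$nodes)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# rebuild a composite_network from a network_edges() table, preserving the
# node index even for nodes that lost all their edges
edges_to_network <- function(e, nodes = NULL) {
  pick <- function(label, sl, tl) {
    ei <- e[e$subnetwork == label, ]
    edge_list(ei$source, ei$target, ei$weight, sl, tl)
  }
  net <- composite_network(
    gg = pick("gene-gene", "gene", "gene"),
    pp = pick("phenotype-phenotype", "phenotype", "phenotype"),
    mm = pick("metabolite-metabolite", "metabolite", "metabolite"),
    gm = pick("gene-metabolite", "gene", "metabolite"),
    pg = pick("phenotype-gene", "phenotype", "gene"),
    pm = pick("phenotype-metabolite", "phenotype", "metabolite"))
  if (!is.null(nodes)) net <- .reindex(net, nodes)
  net
}

# expand a network's node index to `nodes` (a list gene/phenotype/metabolite),
# keeping isolated nodes registered
.reindex <- function(net, nodes) {
  grow_sym <- function(M, ids) {
    t <- as(M, "TsparseMatrix")
    Matrix::sparseMatrix(i = match(rownames(M)[t@i + 1L], ids),
                         j = match(colnames(M)[t@j + 1L], ids), x = t@x,
                         dims = c(length(ids), length(ids)),
                         dimnames = list(ids, ids))
  }
  grow_bip <- function(M, rids, cids) {
    t <- as(M, "TsparseMatrix")
    Matrix::sparseMatrix(i = match(rownames(M)[t@i + 1L], rids),
                         j = match(colnames(M)[t@j + 1L], cids), x = t@x,
                         dims = c(length(rids), length(cids)),
                         dimnames = list(rids, cids))
  }
  nodes <- lapply(nodes, .sort_ids)
  structure(list(
    nodes = nodes,
    gg = grow_sym(net$gg, nodes$gene), pp = grow_sym(net$pp, nodes$phenotype),
    mm = grow_sym(net$mm, nodes$metabolite),
    gm = grow_bip(net$gm, nodes$gene, nodes$metabolite),
    pg = grow_bip(net$pg, nodes$phenotype, nodes$gene),
    pm = grow_bip(net$pm, nodes$phenotype, nodes$metabolite)
  ), class = "composite_network")
}
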