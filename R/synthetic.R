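#' Configuration for the synthetic composite-network generator
#'
#' Describes a benchmark scenario: three Erdős–Rényi within-layer
#' association networks with Beta-distributed confidence weights, sparse
#' background cross-layer links, and a set of planted "diseases". Each
#' disease is a phenotype wired to a module of true genes (curated-style
#' links of weight 1), whose genes are densely interconnected and wired
#' to the disease's true metabolites with up-weighted edges; the true
#' metabolites are moderately interconnected among themselves. A fraction
#' of each disease's true metabolites is emitted as "known"
#' (phenotype-metabolite links of weight 1 plus annotation entries); the
#' rest are held-out discoveries recorded only in the ground truth.
#'
#' Defaults define the package's reference benchmark scenario: 300 genes,
#' 30 phenotypes, 200 metabolites, 10 diseases with 6 true genes and 6
#' true metabolites each, signal_strength 5.
#'
#' @param n_genes,n_phenotypes,n_metabolites Layer sizes.
#' @param gg_density,pp_density,mm_density Within-layer edge densities.
#' @param gm_density Background gene-metabolite link density.
#' @param background_attachment Background density of phenotype-gene and
#'   phenotype-metabolite links, in `[0, 1]`.
#' @param weight_shape1,weight_shape2 Beta parameters of the background
#'   confidence-weight distribution (default Beta(2, 5): skewed toward
#'   low confidence, as in database-derived association scores).
#' @param n_diseases Number of planted diseases (each gets one phenotype).
#' @param genes_per_disease,metabolites_per_disease Module sizes.
#' @param gg_module_density,gm_module_density Edge densities inside a
#'   disease module (gene-gene and gene-metabolite).
#' @param mm_module_density Density of metabolite-metabolite wiring among
#'   a disease's true metabolites (kept at base weights, so the
#'   metabolite layer alone carries weaker signal than the composite).
#' @param known_fraction Fraction of each disease's true metabolites
#'   emitted as known annotations (at least 2 per disease).
#' @param signal_strength Weight multiplier (>= 1) applied to module
#'   gene-gene and gene-metabolite edges, capped at 1 so weights stay on
#'   the 0-1 confidence scale.
#' @param rng_seed Integer seed; the whole scenario is a deterministic
#'   function of the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300L, n_phenotypes = 30L,
                             n_metabolites = 200L,
                             gg_density = 0.02, pp_density = 0.05,
                             mm_density = 0.05, gm_density = 0.03,
                             background_attachment = 0.08,
                             weight_shape1 = 2, weight_shape2 = 5,
                             n_diseases = 10L, genes_per_disease = 6L,
                             metabolites_per_disease = 6L,
                             gg_module_density = 0.8, gm_module_density = 0.8,
                             mm_module_density = 0.3,
                             known_fraction = 0.8, signal_strength = 5,
                             rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_phenotypes = as.integer(n_phenotypes),
              n_metabolites = as.integer(n_metabolites),
              gg_density = gg_density, pp_density = pp_density,
              mm_density = mm_density, gm_density = gm_density,
              background_attachment = background_attachment,
              weight_shape1 = weight_shape1, weight_shape2 = weight_shape2,
              n_diseases = as.integer(n_diseases),
              genes_per_disease = as.integer(genes_per_disease),
              metabolites_per_disease = as.integer(metabolites_per_disease),
              gg_module_density = gg_module_density,
              gm_module_density = gm_module_density,
              mm_module_density = mm_module_density,
              known_fraction = known_fraction,
              signal_strength = signal_strength,
              rng_seed = as.integer(rng_seed))
  dens <- c(cfg$gg_density, cfg$pp_density, cfg$mm_density, cfg$gm_density,
            cfg$background_attachment, cfg$gg_module_density,
            cfg$gm_module_density, cfg$mm_module_density, cfg$known_fraction)
  if (any(dens < 0 | dens > 1)) abort("all densities and fractions must lie in [0, 1]")
  if (cfg$signal_strength < 1) abort("`signal_strength` must be >= 1")
  if (cfg$n_diseases > cfg$n_phenotypes) {
    abort("infeasible config: more diseases than phenotype nodes")
  }
  if (cfg$genes_per_disease > cfg$n_genes ||
      cfg$metabolites_per_disease > cfg$n_metabolites) {
    abort("infeasible config: disease module larger than its layer")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic composite network with planted disease modules
#'
#' Draws the scenario described by a [synthetic_config()]: background
#' within-layer and cross-layer networks, plus one planted module per
#' disease with known ground truth. Fully reproducible: the same config
#' (including its `rng_seed`) yields byte-identical edge lists.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `metprior_simulation` with elements `network`
#'   (a `composite_network`), `annotations` (a [disease_annotations()]
#'   tibble: the known metabolites/genes per disease phenotype, with
#'   disease classes assigned cyclically), and `truth` (a tibble with the
#'   full planted modules, including held-out metabolites).
#' @export
simulate_composite <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  withr_seed(cfg$rng_seed, {
    genes <- sprintf("g%03d", seq_len(cfg$n_genes))
    phenos <- sprintf("p%03d", seq_len(cfg$n_phenotypes))
    metabs <- sprintf("m%03d", seq_len(cfg$n_metabolites))
    rw <- function(n) rbeta(n, cfg$weight_shape1, cfg$weight_shape2)
    boost <- function(w) pmin(1, w * cfg$signal_strength)

    er_edges <- function(ids, density) {
      n <- length(ids)
      pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
      keep <- runif(nrow(pairs)) < density
      pairs <- pairs[keep, , drop = FALSE]
      tibble::tibble(source = ids[pairs[, 1]], target = ids[pairs[, 2]],
                     weight = rw(nrow(pairs)))
    }
    bip_edges <- function(rids, cids, density) {
      n <- length(rids) * length(cids)
      keep <- which(runif(n) < density)
      tibble::tibble(source = rids[((keep - 1) %% length(rids)) + 1],
                     target = cids[((keep - 1) %/% length(rids)) + 1],
                     weight = rw(length(keep)))
    }

    gg <- er_edges(genes, cfg$gg_density)
    pp <- er_edges(phenos, cfg$pp_density)
    mm <- er_edges(metabs, cfg$mm_density)
    gm <- bip_edges(genes, metabs, cfg$gm_density)
    pg <- bip_edges(phenos, genes, cfg$background_attachment)
    pm <- bip_edges(phenos, metabs, cfg$background_attachment)

    disease_ph <- sample(phenos, cfg$n_diseases)
    truth_rows <- list()
    ann_rows <- list()
    classes <- paste0("class_", rep_len(seq_len(max(1L, cfg$n_diseases %/% 3L)),
                                        cfg$n_diseases))
    for (d in seq_len(cfg$n_diseases)) {
      p <- disease_ph[d]
      tg <- sample(genes, cfg$genes_per_disease)
      tm <- sample(metabs, cfg$metabolites_per_disease)

      # curated-style phenotype-gene links, weight 1
      pg <- dplyr::bind_rows(pg, tibble::tibble(source = p, target = tg, weight = 1))
      # dense up-weighted gene module
      mod_gg <- er_edges(tg, cfg$gg_module_density)
      mod_gg$weight <- boost(mod_gg$weight)
      gg <- dplyr::bind_rows(gg, mod_gg)
      # up-weighted gene-metabolite module wiring
      mod_gm <- bip_edges(tg, tm, cfg$gm_module_density)
      mod_gm$weight <- boost(mod_gm$weight)
      gm <- dplyr::bind_rows(gm, mod_gm)
      # moderate metabolite-metabolite wiring at base weights
      mm <- dplyr::bind_rows(mm, er_edges(tm, cfg$mm_module_density))

      n_known <- max(2L, min(length(tm),
                             as.integer(round(cfg$known_fraction * length(tm)))))
      known <- sort(sample(tm, n_known))
      pm <- dplyr::bind_rows(pm, tibble::tibble(source = p, target = known, weight = 1))

      truth_rows[[d]] <- tibble::tibble(
        phenotype = p, true_genes = list(sort(tg)),
        true_metabolites = list(sort(tm)), known_metabolites = list(known))
      ann_rows[[d]] <- tibble::tibble(
        phenotype = p, metabolites = list(known), genes = list(sort(tg)),
        class = classes[d])
    }

    net <- composite_network(
      gg = edge_list(gg$source, gg$target, gg$weight, "gene", "gene"),
      pp = edge_list(pp$source, pp$target, pp$weight, "phenotype", "phenotype"),
      mm = edge_list(mm$source, mm$target, mm$weight, "metabolite", "metabolite"),
      gm = edge_list(gm$source, gm$target, gm$weight, "gene", "metabolite"),
      pg = edge_list(pg$source, pg$target, pg$weight, "phenotype", "gene"),
      pm = edge_list(pm$source, pm$target, pm$weight, "phenotype", "metabolite"))
    # ensure every node is registered even if isolated
    net <- .reindex(net, list(gene = genes, phenotype = phenos, metabolite = metabs))

    structure(list(network = net,
                   annotations = dplyr::bind_rows(ann_rows),
                   truth = dplyr::bind_rows(truth_rows),
                   config = cfg),
              class = "metprior_simulation")
  })
}

#' @export
print.metprior_simulation <- function(x, ...) {
  cat(sprintf("<metprior_simulation> %d diseases planted; ", nrow(x$truth)))
  print(x$network)
  invisible(x)
}

#' Write a simulated scenario to a directory
#'
#' Writes the six edge-list TSVs (the bundle of [write_composite()]), the
#' annotations TSV and a ground-truth TSV, so a scenario can be consumed
#' by the file-based interfaces.
#'
#' @param sim A `metprior_simulation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "metprior_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_composite(sim$network, dir)
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  join <- function(x) vapply(x, paste, "", collapse = ",")
  writeLines(paste(sim$truth$phenotype, join(sim$truth$true_metabolites),
                   join(sim$truth$true_genes), join(sim$truth$known_metabolites),
                   sep = "\t"),
             file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
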