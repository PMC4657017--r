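#' Read a weighted edge list
#'
#' Reads a 3-column tab-separated file (`source_id`, `target_id`, `weight`)
#' describing one of the six sub-networks of a composite network, and
#' canonicalizes it: zero-weight edges are dropped, within-layer edges are
#' stored with source/target in a fixed order so that `(u, v)` and `(v, u)`
#' denote the same undirected edge, and duplicate node pairs are merged by
#' keeping the maximum weight (confidence-score semantics: the strongest
#' evidence wins).
#'
#' A header line is auto-detected: if the third field of the first line does
#' not parse as a number, the line is skipped.
#'
#' @param path Path to a TSV file.
#' @param source_layer,target_layer Layer of the source / target column; one
#'   of `"gene"`, `"phenotype"`, `"metabolite"`. Equal layers declare an
#'   undirected within-layer network.
#' @param quiet Suppress the message reporting dropped / merged edges.
#'
#' @return A tibble of class `metprior_edges` with columns `source`,
#'   `target`, `weight` and attributes `source_layer`, `target_layer`.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("g1\tg2\t0.9", "g2\tg1\t0.9"), f)
#' read_edge_list(f, "gene", "gene")  # one edge after canonicalization
#' @export
read_edge_list <- function(path, source_layer, target_layer, quiet = FALSE) {
  .check_layer(source_layer, "source_layer")
  .check_layer(target_layer, "target_layer")
  if (!file.exists(path)) abort(sprintf("edge-list file not found: %s", path))

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(edge_list(character(), character(), numeric(),
                     source_layer, target_layer))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed edge-list line %d in %s: expected 3 tab-separated fields, got %d",
                  bad[1], path, lengths(fields)[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  w <- suppressWarnings(as.numeric(m[, 3L]))

  offset <- 0L
  if (is.na(w[1L])) { # header line
    m <- m[-1L, , drop = FALSE]
    w <- w[-1L]
    offset <- 1L
  }
  if (anyNA(w)) {
    abort(sprintf("malformed edge-list line %d in %s: weight %s is not a number",
                  which(is.na(w))[1] + offset, path,
                  dQuote(m[which(is.na(w))[1], 3L])))
  }
  edge_list(m[, 1L], m[, 2L], w, source_layer, target_layer, quiet = quiet)
}

#' Construct a canonical weighted edge list from vectors
#'
#' The in-memory constructor behind [read_edge_list()]; applies the same
#' canonicalization rules (drop zero weights, undirected ordering within a
#' layer, max-weight merge of duplicates, no self-loops, no negative
#' weights).
#'
#' @param source,target Character vectors of node ids.
#' @param weight Numeric vector of non-negative weights.
#' @inheritParams read_edge_list
#' @return A `metprior_edges` tibble.
#' @export
edge_list <- function(source, target, weight, source_layer, target_layer,
                      quiet = TRUE) {
  .check_layer(source_layer, "source_layer")
  .check_layer(target_layer, "target_layer")
  source <- as.character(source)
  target <- as.character(target)
  weight <- as.numeric(weight)
  stopifnot(length(source) == length(target),
            length(source) == length(weight))
  if (any(!nzchar(source)) || any(!nzchar(target))) {
    abort("node ids must be non-empty strings")
  }
  if (anyNA(weight)) abort("edge weights must not be NA")
  if (any(weight < 0)) {
    i <- which(weight < 0)[1]
    abort(sprintf("negative edge weight %g on edge (%s, %s)",
                  weight[i], source[i], target[i]))
  }

  within <- identical(source_layer, target_layer)
  if (within && any(source == target)) {
    i <- which(source == target)[1]
    abort(sprintf("self-loop on node %s: within-layer networks are association networks without self-edges",
                  dQuote(source[i])))
  }

  n_zero <- sum(weight == 0)
  keep <- weight > 0
  source <- source[keep]; target <- target[keep]; weight <- weight[keep]

  if (within && length(source)) {
    flip <- source > target
    tmp <- source[flip]
    source[flip] <- target[flip]
    target[flip] <- tmp
  }

  n_dup <- 0L
  if (length(source)) {
    key <- paste(source, target, sep = "\r")
    if (anyDuplicated(key)) {
      n_dup <- sum(duplicated(key))
      w_max <- tapply(weight, key, max)
      first <- !duplicated(key)
      source <- source[first]; target <- target[first]
      weight <- as.numeric(w_max[key[first]])
    }
    ord <- order(source, target, method = "radix")
    source <- source[ord]; target <- target[ord]; weight <- weight[ord]
  }

  if (!quiet && (n_zero > 0L || n_dup > 0L)) {
    inform(sprintf("edge list (%s-%s): dropped %d zero-weight edge(s), merged %d duplicate pair(s) keeping max weight",
                   source_layer, target_layer, n_zero, n_dup))
  }

  out <- tibble::tibble(source = source, target = target, weight = weight)
  structure(out,
            class = c("metprior_edges", class(out)),
            source_layer = source_layer,
            target_layer = target_layer)
}

#' Write a weighted edge list to TSV
#'
#' Inverse of [read_edge_list()]: writes the canonicalized edges as a
#' 3-column tab-separated file without a header, so that a read/write round
#' trip reproduces the edge set and weights exactly.
#'
#' @param edges A `metprior_edges` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(inherits(edges, "metprior_edges"))
  writeLines(sprintf("%s\t%s\t%s", edges$source, edges$target,
                     format(edges$weight, digits = 17, scientific = FALSE,
                            trim = TRUE)),
             path)
  invisible(path)
}

#' @export
print.metprior_edges <- function(x, ...) {
  cat(sprintf("# %s-%s edge list (%d edges)\n",
              attr(x, "source_layer"), attr(x, "target_layer"), nrow(x)))
  NextMethod()
}
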