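# Disjoint-set union with path halving + union by size. Vertices are 1..n.
dsu_new <- function(n) {
  env <- new.env(parent = emptyenv())
  env$parent <- seq_len(n)
  env$size <- rep(1L, n)
  env$n_comp <- n
  env
}

dsu_find <- function(dsu, i) {
  p <- dsu$parent
  while (p[i] != i) {
    p[i] <- p[p[i]]
    i <- p[i]
  }
  dsu$parent <- p
  i
}

# returns TRUE if a merge happened
dsu_union <- function(dsu, i, j) {
  ri <- dsu_find(dsu, i)
  rj <- dsu_find(dsu, j)
  if (ri == rj) return(FALSE)
  if (dsu$size[ri] < dsu$size[rj]) { tmp <- ri; ri <- rj; rj <- tmp }
  dsu$parent[rj] <- ri
  dsu$size[ri] <- dsu$size[ri] + dsu$size[rj]
  dsu$n_comp <- dsu$n_comp - 1L
  TRUE
}

#' Minimum-bottleneck bipartition of a connected network
#'
#' Splits a connected (balanced) network into two sides so that the maximum
#' weight among the deleted (crossing) edges is minimised. Edges are sorted by
#' weight descending (ties broken on the canonical lexicographic edge key,
#' ascending, for determinism) and re-inserted into an empty disjoint-set
#' union; the first edge whose insertion would make the whole graph connected
#' is the bottleneck, and the two components present just before it is
#' inserted are the sides of the cut.
#'
#' @param x A connected PPIN with at least two vertices, typically with
#'   balanced weights (see [balance_weights()]).
#' @return A list of class `bops_split` with elements `side_a`, `side_b`
#'   (character vectors; `side_a` holds the lexicographically smallest
#'   vertex), `cost` (the bottleneck weight, i.e. the max weight among
#'   deleted edges) and `deleted_edges` (tibble of the crossing edges).
#' @examples
#' net <- ppin(data.frame(a = c("A", "B"), b = c("B", "C"), w = c(0.9, 0.4)))
#' bottleneck_split(net)
#' @export
bottleneck_split <- function(x) {
  x <- as_ppin(x)
  verts <- ppin_vertices(x)
  n <- length(verts)
  if (n < 2L) abort("bottleneck_split() needs at least two vertices.")
  ia <- match(x$protein_a, verts)
  ib <- match(x$protein_b, verts)
  key <- paste(x$protein_a, x$protein_b, sep = "|")
  ord <- order(-x$weight, xtfrm_c(key))
  dsu <- dsu_new(n)
  bottleneck <- NA_integer_
  for (e in ord) {
    ri <- dsu_find(dsu, ia[e])
    rj <- dsu_find(dsu, ib[e])
    if (ri == rj) next
    if (dsu$n_comp == 2L) {  # this union would connect the whole graph
      bottleneck <- e
      break
    }
    dsu_union(dsu, ia[e], ib[e])
  }
  if (is.na(bottleneck)) abort("bottleneck_split() requires a connected network.")
  roots <- vapply(seq_len(n), function(i) dsu_find(dsu, i), integer(1))
  root_a <- dsu_find(dsu, ia[bottleneck])
  side_a <- sort_c(verts[roots == root_a])
  side_b <- sort_c(verts[roots != root_a])
  if (cmp_gt(side_a[1L], side_b[1L])) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  crossing <- (x$protein_a %in% side_a) != (x$protein_b %in% side_a)
  deleted <- as_tibble(x[crossing, , drop = FALSE])[,
    c("protein_a", "protein_b", "weight")]
  structure(
    list(side_a = side_a, side_b = side_b,
         cost = x$weight[bottleneck],
         deleted_edges = deleted),
    class = "bops_split"
  )
}

#' @export
print.bops_split <- function(x, ...) {
  cat(sprintf(
    "# Bottleneck split: sides of %d and %d vertices, cost %.6g, %d deleted edge(s)\n",
    length(x$side_a), length(x$side_b), x$cost, nrow(x$deleted_edges)))
  invisible(x)
}

#' Segment a network into pieces of bounded size
#'
#' Recursively splits a (balanced) network into vertex-disjoint connected
#' subnetworks of at most `maxp` proteins. A FIFO queue is seeded with the
#' connected components of the input; each popped piece is emitted if it has
#' at most `maxp` vertices, otherwise it is bipartitioned by
#' [bottleneck_split()] and both sides are pushed to the back of the queue.
#'
#' @param x A PPIN, typically balanced (see [balance_weights()]).
#' @param maxp Maximum number of proteins per piece (default 20). Enumeration
#'   cost downstream grows as `2^maxp`, so values above 25 trigger a warning.
#' @return An object of class `bops_partition`: a list with `parts` (list of
#'   `bops_ppin` induced subnetworks), `trace` (tibble of the splits
#'   performed, in execution order, with list columns `side_a`, `side_b`,
#'   `deleted_edges` and the `cost` of each cut) and `maxp`.
#' @seealso [tidy.bops_partition()] for a protein-to-part table,
#'   [glance.bops_partition()] for a one-row summary.
#' @export
segment_ppin <- function(x, maxp = 20) {
  x <- as_ppin(x)
  stopifnot_scalar_number(maxp, "maxp", lower = 1)
  maxp <- as.integer(maxp)
  if (maxp > 25L) {
    warn(sprintf(
      "maxp = %d: candidate enumeration scales as 2^maxp; values > 25 get expensive.",
      maxp))
  }
  queue <- lapply(ppin_components(x), function(vs) ppin_induced(x, vs))
  parts <- list()
  trace <- list()
  while (length(queue) > 0L) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    if (length(ppin_vertices(g)) <= maxp) {
      parts[[length(parts) + 1L]] <- g
      next
    }
    sp <- bottleneck_split(g)
    trace[[length(trace) + 1L]] <- sp
    queue <- c(queue, list(ppin_induced(g, sp$side_a),
                           ppin_induced(g, sp$side_b)))
  }
  trace_tbl <- tibble(
    step = seq_along(trace),
    size_a = map_int(trace, ~ length(.x$side_a)),
    size_b = map_int(trace, ~ length(.x$side_b)),
    cost = map_dbl(trace, "cost"),
    n_deleted = map_int(trace, ~ nrow(.x$deleted_edges)),
    side_a = map(trace, "side_a"),
    side_b = map(trace, "side_b"),
    deleted_edges = map(trace, "deleted_edges")
  )
  structure(list(parts = parts, trace = trace_tbl, maxp = maxp),
            class = "bops_partition")
}

#' @export
print.bops_partition <- function(x, ...) {
  sizes <- map_int(x$parts, ~ length(ppin_vertices(.x)))
  cat(sprintf(
    "# PPIN segmentation: %d parts (sizes %d-%d) after %d cut(s), maxp = %d\n",
    length(x$parts), if (length(sizes)) min(sizes) else 0L,
    if (length(sizes)) max(sizes) else 0L, nrow(x$trace), x$maxp))
  invisible(x)
}

#' Tidy a segmentation into a protein-to-part table
#'
#' @param x A `bops_partition` from [segment_ppin()].
#' @param ... Unused.
#' @return A tibble with columns `protein` and `part` (integer part index).
#' @method tidy bops_partition
#' @export
tidy.bops_partition <- function(x, ...) {
  bind_rows(imap(x$parts, function(p, i) {
    tibble(protein = ppin_vertices(p), part = i)
  }))
}

#' Summarise a segmentation
#'
#' @param x A `bops_partition` from [segment_ppin()].
#' @param ... Unused.
#' @return A one-row tibble: number of parts, largest part, number of splits,
#'   number of deleted edges, and the maximum cut cost.
#' @method glance bops_partition
#' @export
glance.bops_partition <- function(x, ...) {
  sizes <- map_int(x$parts, ~ length(ppin_vertices(.x)))
  tibble(
    n_parts = length(x$parts),
    max_part_size = if (length(sizes)) max(sizes) else 0L,
    n_splits = nrow(x$trace),
    n_deleted_edges = sum(x$trace$n_deleted),
    max_cut_cost = if (nrow(x$trace)) max(x$trace$cost) else NA_real_,
    maxp = x$maxp
  )
}

#' Part vertex sets of a segmentation
#'
#' @param x A `bops_partition` (or a plain list of vertex-set character
#'   vectors).
#' @return List of character vectors, one per part.
#' @export
partition_members <- function(x) {
  if (inherits(x, "bops_partition")) {
    return(map(x$parts, ppin_vertices))
  }
  if (is.list(x)) return(map(x, as.character))
  abort("Cannot extract part membership from this object.")
}

#' Random equal-size segmentation (baseline)
#'
#' Shuffles the vertices and chops them into consecutive groups of at most
#' `maxp`, ignoring topology and weights. Used as the reference against which
#' the bottleneck segmentation's expected regression ratio is compared.
#'
#' @param x A PPIN.
#' @param maxp Maximum part size.
#' @param seed Integer seed for the shuffle (private RNG stream; the session
#'   RNG is left untouched).
#' @param sizes Optional integer vector of part sizes to realise instead of
#'   the equal `maxp` chop (must sum to the vertex count); use the sizes of
#'   an actual segmentation to compare against its exact part-size profile.
#' @return List of character vectors, one per part.
#' @export
random_segmentation <- function(x, maxp = 20, seed = 1, sizes = NULL) {
  x <- as_ppin(x)
  stopifnot_scalar_number(maxp, "maxp", lower = 1)
  verts <- ppin_vertices(x)
  if (!is.null(sizes)) {
    if (sum(sizes) != length(verts) || any(sizes < 1)) {
      abort("`sizes` must be positive and sum to the number of vertices.")
    }
  }
  with_private_seed(seed, {
    shuffled <- sample(verts)
    grp <- if (is.null(sizes)) {
      ceiling(seq_along(shuffled) / maxp)
    } else {
      rep(seq_along(sizes), sizes)
    }
    unname(split(shuffled, grp))
  })
}
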