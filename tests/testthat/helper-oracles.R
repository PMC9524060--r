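# Independent brute-force oracles and random fixtures. These deliberately use
# naive algorithms (power-set filters, exhaustive bipartitions, recursive
# matchings) so they share no code path with the package implementation.

# Random Erdos-Renyi-style weighted graph as a plain edge data frame.
rand_graph <- function(n, p = 0.5, seed = 1, connected = FALSE) {
  set.seed(seed)
  repeat {
    verts <- sprintf("v%02d", seq_len(n))
    pairs <- t(combn(verts, 2))
    keep <- runif(nrow(pairs)) < p
    df <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                     w = round(runif(sum(keep), 0.05, 1), 3))
    if (!connected) return(list(edges = df, vertices = verts))
    g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = verts))
    if (igraph::is_connected(g) && nrow(df) > 0) {
      return(list(edges = df, vertices = verts))
    }
  }
}

# Adjacency bitmasks for a vertex-name edge list.
adj_masks <- function(edges, verts) {
  n <- length(verts)
  nbr <- integer(n)
  ia <- match(edges$a, verts); ib <- match(edges$b, verts)
  for (e in seq_along(ia)) {
    nbr[ia[e]] <- bitwOr(nbr[ia[e]], bitwShiftL(1L, ib[e] - 1L))
    nbr[ib[e]] <- bitwOr(nbr[ib[e]], bitwShiftL(1L, ia[e] - 1L))
  }
  nbr
}

mask_connected <- function(mask, nbr) {
  start <- bitwAnd(mask, -mask)
  reach <- start
  repeat {
    grow <- reach
    m <- reach
    while (m != 0L) {
      bit <- bitwAnd(m, -m)
      m <- bitwXor(m, bit)
      v <- as.integer(round(log2(bit))) + 1L
      grow <- bitwOr(grow, bitwAnd(nbr[v], mask))
    }
    if (grow == reach) break
    reach <- grow
  }
  reach == mask
}

# Oracle 1: all connected subsets via power-set filter.
brute_connected_subsets <- function(edges, verts, min_size, max_size) {
  n <- length(verts)
  nbr <- adj_masks(edges, verts)
  out <- list()
  for (mask in seq_len(bitwShiftL(1L, n) - 1L)) {
    sz <- sum(bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) != 0L)
    if (sz < min_size || sz > max_size) next
    if (mask_connected(mask, nbr)) {
      out[[length(out) + 1L]] <-
        verts[bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) != 0L]
    }
  }
  out
}

# Oracle 2: minimum-bottleneck bipartition by exhaustive enumeration.
brute_bottleneck <- function(edges, verts) {
  n <- length(verts)
  ia <- match(edges$a, verts); ib <- match(edges$b, verts)
  best <- Inf
  for (mask in seq_len(bitwShiftL(1L, n - 1L) - 1L)) {
    # vertex n always on side B -> each bipartition counted once
    in_a <- bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) != 0L
    crossing <- in_a[ia] != in_a[ib]
    if (!any(crossing)) next  # disconnected bipartition of a connected graph impossible
    cost <- max(edges$w[crossing])
    if (cost < best) best <- cost
  }
  best
}

# Oracle 3: maximum-weight bipartite matching by recursion over predictions.
brute_matching <- function(w) {
  nb <- ncol(w)
  rec <- function(i, used) {
    if (i > nrow(w)) return(0)
    best <- rec(i + 1L, used)  # leave prediction i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && w[i, j] > 0) {
        used2 <- used; used2[j] <- TRUE
        best <- max(best, w[i, j] + rec(i + 1L, used2))
      }
    }
    best
  }
  rec(1L, rep(FALSE, nb))
}

# Oracle 4: hypergeometric upper tail by exhaustive draw enumeration.
brute_hyper_tail <- function(n_universe, n_group, n_draw, k) {
  draws <- combn(n_universe, n_draw)
  hits <- colSums(draws <= n_group)  # group = elements 1..n_group
  mean(hits >= k)
}

edges_df <- function(x) as.data.frame(x)[, c("protein_a", "protein_b", "weight")]

set_key <- function(s) paste(sort(s), collapse = "|")
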