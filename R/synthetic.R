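#' Generate a synthetic PPIN with planted small complexes
#'
#' Builds a reproducible weighted network that mimics the statistics of
#' experimentally derived yeast interaction maps: a few hundred to a few
#' thousand proteins, overall edge density in the few-per-thousand range, and
#' edge weights in (0, 1) with a high mean inside complexes and a low mean
#' elsewhere. Planted complexes are vertex-disjoint; intra-complex edges are
#' drawn at rate `p_in` with Beta-distributed weights of mean
#' `weight_in_mean`, every other vertex pair gets a background edge at rate
#' `p_background` with mean `weight_bg_mean`. With `core_attachment = TRUE`
#' each complex of size s instead gets a fully connected core of
#' `ceiling(s/2)` proteins; the remaining attachment proteins link to 1-2
#' random core members with background-strength weights.
#'
#' Each planted complex is resampled (up to 50 times) until its intra edges
#' connect it; if that fails, a random spanning chain is added and a warning
#' is emitted. All randomness comes from `seed` through a private RNG stream,
#' so identical parameters give identical output and the session RNG is not
#' disturbed.
#'
#' @param n_background Number of background proteins (default 400).
#' @param n_complexes Number of planted complexes (default 30).
#' @param size_low,size_high Complex size range (defaults 3 and 10).
#' @param p_in Intra-complex edge probability (default 0.9).
#' @param p_background Background edge probability (default 0.002; together
#'   with the intra-complex edges this lands
#'   the overall density in the 0.002-0.007 band at the default sizes).
#' @param weight_in_mean,weight_bg_mean Mean edge weights inside complexes
#'   and in the background (defaults 0.8 and 0.2; Beta draws with
#'   concentration 10).
#' @param core_attachment Plant core-attachment structure instead of uniform
#'   dense complexes (default `FALSE`).
#' @param seed Integer seed (default 1).
#' @return A list with `network` (a `bops_ppin`) and `complexes` (a
#'   `bops_complexes` gold standard of the planted complexes).
#' @examples
#' syn <- generate_planted_ppin(n_background = 50, n_complexes = 3, seed = 7)
#' syn$complexes
#' @export
generate_planted_ppin <- function(n_background = 400, n_complexes = 30,
                                  size_low = 3, size_high = 10,
                                  p_in = 0.9, p_background = 0.002,
                                  weight_in_mean = 0.8, weight_bg_mean = 0.2,
                                  core_attachment = FALSE, seed = 1) {
  stopifnot_scalar_number(n_background, "n_background", lower = 0)
  stopifnot_scalar_number(n_complexes, "n_complexes", lower = 0)
  stopifnot_scalar_number(size_low, "size_low", lower = 2)
  stopifnot_scalar_number(size_high, "size_high", lower = size_low)
  stopifnot_scalar_number(p_in, "p_in", lower = 1e-12, upper = 1)
  stopifnot_scalar_number(p_background, "p_background", lower = 0, upper = 1)
  if (p_background >= p_in) {
    abort("`p_background` must be smaller than `p_in`.")
  }
  stopifnot_scalar_number(weight_in_mean, "weight_in_mean", 1e-6, 1 - 1e-6)
  stopifnot_scalar_number(weight_bg_mean, "weight_bg_mean", 1e-6, 1 - 1e-6)
  with_private_seed(seed, {
    size_range <- seq(as.integer(size_low), as.integer(size_high))
    sizes <- if (n_complexes > 0) {
      size_range[sample.int(length(size_range), n_complexes, replace = TRUE)]
    } else integer()
    n_complex_prot <- sum(sizes)
    width <- max(4L, nchar(as.character(n_complex_prot + n_background)))
    all_names <- sprintf("P%0*d", width, seq_len(n_complex_prot + n_background))
    idx <- if (n_complex_prot) split(
      all_names[seq_len(n_complex_prot)],
      rep(seq_along(sizes), sizes)
    ) else list()
    planted <- map(idx, sort_c)

    edges_a <- character(); edges_b <- character(); edges_w <- double()
    add_edges <- function(a, b, mean_w) {
      w <- rbeta(length(a), mean_w * 10, (1 - mean_w) * 10)
      w <- pmin(pmax(w, 1e-6), 1)
      edges_a <<- c(edges_a, a); edges_b <<- c(edges_b, b)
      edges_w <<- c(edges_w, w)
    }

    for (cx in planted) {
      s <- length(cx)
      if (core_attachment) {
        n_core <- ceiling(s / 2)
        core <- cx[seq_len(n_core)]
        attach <- setdiff(cx, core)
        pr <- t(combn(core, 2))
        add_edges(pr[, 1L], pr[, 2L], weight_in_mean)
        for (a in attach) {
          anchors <- sample(core, min(sample(1:2, 1L), n_core))
          add_edges(rep(a, length(anchors)), anchors, weight_bg_mean)
        }
      } else {
        pairs <- t(combn(cx, 2))
        for (try in seq_len(50L)) {
          pick <- rbinom(nrow(pairs), 1L, p_in) == 1L
          if (intra_connected(cx, pairs[pick, , drop = FALSE])) break
        }
        if (!intra_connected(cx, pairs[pick, , drop = FALSE])) {
          warn("Planted complex still disconnected after 50 resamples; adding a spanning chain.")
          chain <- cbind(cx[-length(cx)], cx[-1L])
          extra <- !paste(chain[, 1L], chain[, 2L]) %in%
            paste(pairs[pick, 1L], pairs[pick, 2L])
          pick_pairs <- rbind(pairs[pick, , drop = FALSE],
                              chain[extra, , drop = FALSE])
        } else {
          pick_pairs <- pairs[pick, , drop = FALSE]
        }
        if (nrow(pick_pairs)) {
          add_edges(pick_pairs[, 1L], pick_pairs[, 2L], weight_in_mean)
        }
      }
    }

    # background edges: all pairs not inside the same planted complex
    if (p_background > 0 && length(all_names) > 1L) {
      member_of <- rep(NA_integer_, length(all_names))
      names(member_of) <- all_names
      for (i in seq_along(planted)) member_of[planted[[i]]] <- i
      n_all <- length(all_names)
      n_pairs_total <- n_all * (n_all - 1) / 2
      n_draw <- rbinom(1L, n_pairs_total, p_background)
      if (n_draw > 0) {
        pick <- sample(n_pairs_total, n_draw)
        # unrank pair index -> (i, j), i < j, row-major over the upper triangle
        cum <- cumsum(seq(n_all - 1L, 1L))
        i <- findInterval(pick - 0.5, cum) + 1L
        j <- as.integer(pick - c(0, cum)[i] + i)
        same <- !is.na(member_of[i]) & !is.na(member_of[j]) &
          member_of[i] == member_of[j]
        if (any(!same)) {
          add_edges(all_names[i[!same]], all_names[j[!same]], weight_bg_mean)
        }
      }
    }
    net <- ppin(data.frame(a = edges_a, b = edges_b, w = edges_w),
                vertices = all_names)
    list(network = net, complexes = complex_set(planted))
  })
}

intra_connected <- function(members, pair_mat) {
  if (length(members) <= 1L) return(TRUE)
  if (nrow(pair_mat) < length(members) - 1L) return(FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = pair_mat[, 1L], to = pair_mat[, 2L]),
    directed = FALSE, vertices = data.frame(name = members))
  igraph::is_connected(g)
}

#' Clique fixture: disjoint unit-weight cliques with optional weak bridges
#'
#' Builds unit-weight cliques of the given sizes; consecutive cliques are
#' joined by a single bridge edge of weight `bridge_weight` (0 means no
#' bridges). The planted gold standard is the cliques themselves. This is the
#' canonical exact-recovery fixture: with weak bridges the bottleneck
#' segmentation should cut only bridges, and the prediction pipeline should
#' return exactly the cliques.
#'
#' @param sizes Integer vector of clique sizes (each at least 2).
#' @param bridge_weight Bridge edge weight in `[0, 1)` (default 0).
#' @return A list with `network` (a `bops_ppin`) and `complexes` (the
#'   cliques as a `bops_complexes` gold standard).
#' @examples
#' generate_clique_fixture(c(3, 4), bridge_weight = 0.1)$network
#' @export
generate_clique_fixture <- function(sizes, bridge_weight = 0) {
  if (length(sizes) == 0L) {
    return(list(network = ppin(data.frame(a = character(), b = character(),
                                          w = double())),
                complexes = complex_set(list())))
  }
  if (any(sizes < 2)) abort("Clique sizes must be at least 2.")
  stopifnot_scalar_number(bridge_weight, "bridge_weight", lower = 0,
                          upper = 1 - 1e-12)
  names_by_clique <- imap(as.integer(sizes), function(s, i) {
    sprintf("C%02d_%02d", i, seq_len(s))
  })
  edges <- purrr::map_dfr(names_by_clique, function(nm) {
    pr <- t(combn(nm, 2))
    tibble(a = pr[, 1L], b = pr[, 2L], w = 1)
  })
  if (bridge_weight > 0 && length(sizes) > 1L) {
    bridges <- tibble(
      a = map_chr(names_by_clique[-length(sizes)], ~ .x[[length(.x)]]),
      b = map_chr(names_by_clique[-1L], 1L),
      w = bridge_weight
    )
    edges <- bind_rows(edges, bridges)
  }
  list(network = ppin(edges), complexes = complex_set(names_by_clique))
}
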