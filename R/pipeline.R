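#' Cohesion of a vertex set
#'
#' The cohesion of a protein set S in a (balanced) network averages, over the
#' members, the product of each member's within-set strength and the fraction
#' of the set it touches:
#' \deqn{Cohesion(S) = \frac{1}{|S|}\sum_{x \in S} s_x \frac{c_x + 1}{|S|}}
#' where `s_x` and `c_x` are strength and degree of `x` counting only edges
#' with both endpoints in S (the `+ 1` counts the protein itself). A complex
#' should score high on both terms: every member interacts with most other
#' members, and it does so strongly.
#'
#' @param x A PPIN (a segmentation part with balanced weights, normally).
#' @param members A character vector of vertex names, or a list of such
#'   vectors to score many sets at once.
#' @return A numeric vector of cohesion values (non-negative).
#' @examples
#' tri <- ppin(data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"), w = 1))
#' cohesion(tri, c("a", "b", "c"))
#' @export
cohesion <- function(x, members) {
  x <- as_ppin(x)
  if (is.character(members)) members <- list(members)
  verts <- ppin_vertices(x)
  bad <- purrr::detect_index(members, function(m) {
    length(m) == 0L || !all(m %in% verts)
  })
  if (bad > 0L) {
    abort("Every set must be non-empty and contained in the network's vertices.")
  }
  map_dbl(members, function(m) cohesion_one(x, m))
}

cohesion_one <- function(x, m) {
  k <- length(m)
  keep <- x$protein_a %in% m & x$protein_b %in% m
  if (!any(keep)) return(0)
  ends <- c(x$protein_a[keep], x$protein_b[keep])
  w <- rep(x$weight[keep], 2L)
  f <- factor(ends, levels = m)
  cnt <- tabulate(f, nbins = k)
  sm <- vapply(split(w, f), sum, double(1))
  sm[is.na(sm)] <- 0
  sum(sm * (cnt + 1) / k) / k
}

#' Rank candidate complexes and remove near-duplicates
#'
#' Candidates are sorted by cohesion (descending; ties broken on the
#' canonical member-set key, ascending). Scanning in that order, a candidate
#' is deleted when its neighbourhood affinity (see
#' [neighborhood_affinity()]) to any earlier — i.e. more cohesive —
#' candidate reaches `sim_threshold`; only candidates dissimilar to every
#' more cohesive candidate survive. The survivors are therefore pairwise
#' dissimilar as well.
#'
#' @param candidates A tibble with a `members` list column and a `cohesion`
#'   column (as produced inside [run_bops()]), or a `bops_complexes` set with
#'   scores.
#' @param sim_threshold Neighbourhood-affinity threshold in (0, 1]
#'   (default 0.25).
#' @return The surviving rows, ranked by cohesion descending.
#' @export
rank_and_dedup <- function(candidates, sim_threshold = 0.25) {
  stopifnot_scalar_number(sim_threshold, "sim_threshold", lower = 1e-12, upper = 1)
  if (inherits(candidates, "bops_complexes") && "score" %in% names(candidates)) {
    candidates <- tibble(members = candidates$members,
                         cohesion = candidates$score)
  }
  if (!"members" %in% names(candidates) || nrow(candidates) == 0L) {
    return(tibble(members = list(), cohesion = double(), size = integer()))
  }
  members <- map(candidates$members, ~ sort_c(unique(as.character(.x))))
  coh <- candidates$cohesion
  key <- map_chr(members, paste, collapse = "|")
  ord <- order(-coh, xtfrm_c(key))
  members <- members[ord]
  coh <- coh[ord]
  n <- length(members)
  if (n == 0L) {
    return(tibble(members = list(), cohesion = double(), size = integer()))
  }
  prots <- sort_c(unique(unlist(members)))
  idx_sets <- lapply(members, function(m) match(m, prots))  # sorted ascending
  keep <- dedup_sets_cpp(idx_sets, sim_threshold)
  tibble(members = members[keep], cohesion = coh[keep],
         size = lengths(members)[keep])
}

#' Keep the most cohesive fraction of ranked candidates
#'
#' @param ranked A tibble as returned by [rank_and_dedup()] (already ordered
#'   by cohesion descending).
#' @param keep_fraction Fraction in (0, 1] to retain; the first
#'   `ceiling(n * keep_fraction)` rows are kept, so a non-empty input never
#'   yields an empty result.
#' @return The retained rows, order preserved.
#' @export
select_top_fraction <- function(ranked, keep_fraction = 0.5) {
  stopifnot_scalar_number(keep_fraction, "keep_fraction",
                          lower = 1e-12, upper = 1)
  n <- nrow(ranked)
  if (n == 0L) return(ranked)
  head(ranked, ceiling(n * keep_fraction))
}

# Mask-space dedup for one segmentation part: identical in outcome to
# rank_and_dedup() on the materialised member sets (parts have <= 31
# vertices, so candidates are 31-bit masks and intersections are popcounts).
dedup_part_masks <- function(em, coh, sim_threshold) {
  ord <- order(-coh)  # stable, so tied runs keep enumeration order for now
  coh_s <- coh[ord]
  ties <- which(duplicated(coh_s) | duplicated(coh_s, fromLast = TRUE))
  if (length(ties)) {
    # resolve cohesion ties on the canonical member-name key
    key <- mask_keys(em, em$masks[ord[ties]])
    ord[ties] <- ord[ties][order(-coh_s[ties], xtfrm_c(key))]
  }
  masks <- em$masks[ord]
  keep <- dedup_masks_cpp(masks, sim_threshold)
  kept_masks <- masks[keep]
  n <- length(em$verts)
  bits <- bitwShiftL(1L, 0:(n - 1L))
  members <- lapply(kept_masks, function(m) em$verts[bitwAnd(bits, m) != 0L])
  tibble(members = members, cohesion = coh[ord][keep],
         size = lengths(members))
}

mask_keys <- function(em, masks) {
  n <- length(em$verts)
  bits <- bitwShiftL(1L, 0:(n - 1L))
  vapply(masks, function(m) {
    paste(em$verts[bitwAnd(bits, m) != 0L], collapse = "|")
  }, character(1))
}

#' Predict small protein complexes in a weighted PPI network
#'
#' The full prediction pipeline: (1) replace edge weights with balanced
#' weights ([balance_weights()]); (2) segment the network into connected
#' pieces of at most `maxp` proteins by recursive minimum-bottleneck cuts
#' ([segment_ppin()]); (3) enumerate every connected subset of each piece
#' within the size window, score it by cohesion, pool candidates across
#' pieces, drop candidates similar to a more cohesive one, and keep the most
#' cohesive `keep_fraction` of the survivors. The result is deterministic:
#' the same network and parameters always give the same complexes in the
#' same order.
#'
#' @param x A weighted PPIN (see [ppin()] / [read_ppin()]).
#' @param beta Balance exponent (default 1.5; see [balance_weights()]).
#' @param maxp Maximum proteins per segmentation piece (default 20).
#' @param min_size,max_size Candidate complex size window (defaults 2 and 10,
#'   the small-complex regime; `max_size` must not exceed `maxp`).
#' @param sim_threshold Neighbourhood-affinity threshold for deduplication
#'   (default 0.25).
#' @param keep_fraction Fraction of ranked survivors reported (default 0.5).
#' @return A `bops_result`: a `bops_complexes` tibble (columns `complex_id`,
#'   `members`, `size`, `score` = cohesion) with a `params` attribute.
#'   Write it with [write_complexes()]; summarise with [glance.bops_result()];
#'   plot with [autoplot.bops_result()].
#' @examples
#' fix <- generate_clique_fixture(c(3, 4, 5))
#' run_bops(fix$network, keep_fraction = 1)
#' @export
run_bops <- function(x, beta = 1.5, maxp = 20, min_size = 2, max_size = 10,
                     sim_threshold = 0.25, keep_fraction = 0.5) {
  x <- as_ppin(x)
  stopifnot_scalar_number(min_size, "min_size", lower = 2)
  stopifnot_scalar_number(max_size, "max_size", lower = min_size)
  if (max_size > maxp) abort("`max_size` must not exceed `maxp`.")
  balanced <- balance_weights(x, beta = beta)
  seg <- segment_ppin(balanced, maxp = maxp)
  n_cands <- 0L
  # Parts are vertex-disjoint, so neighbourhood affinity between candidates
  # of different parts is always 0: deduplication decomposes exactly into a
  # per-part pass, and the survivors only need one global re-ranking.
  survivors <- purrr::map_dfr(seg$parts, function(part) {
    em <- enumerate_masks(part, min_size = min_size, max_size = max_size)
    if (length(em$masks) == 0L) {
      return(tibble(members = list(), cohesion = double(), size = integer()))
    }
    n_cands <<- n_cands + length(em$masks)
    coh <- cohesion_masks(part, em$masks)
    dedup_part_masks(em, coh, sim_threshold)
  })
  if (!"members" %in% names(survivors)) {
    survivors <- tibble(members = list(), cohesion = double(),
                        size = integer())
  }
  ranked <- if (nrow(survivors) > 0L) {
    key <- map_chr(survivors$members, paste, collapse = "|")
    survivors[order(-survivors$cohesion, xtfrm_c(key)), , drop = FALSE]
  } else {
    survivors
  }
  kept <- select_top_fraction(ranked, keep_fraction = keep_fraction)
  out <- complex_set(kept$members, score = kept$cohesion)
  attr(out, "params") <- list(beta = beta, maxp = maxp, min_size = min_size,
                              max_size = max_size,
                              sim_threshold = sim_threshold,
                              keep_fraction = keep_fraction)
  attr(out, "n_parts") <- length(seg$parts)
  attr(out, "n_candidates") <- n_cands
  attr(out, "n_survivors") <- nrow(ranked)
  class(out) <- c("bops_result", class(out))
  out
}

#' @export
print.bops_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "# BOPS predictions: %d complexes (beta %g, maxp %d, sizes %d-%d)\n",
    nrow(x), p$beta, p$maxp, p$min_size, p$max_size))
  cat(sprintf("#   %d parts, %d candidates, %d after dedup\n",
              attr(x, "n_parts"), attr(x, "n_candidates"),
              attr(x, "n_survivors")))
  NextMethod()
}

#' Tidy BOPS predictions into one row per protein
#'
#' @param x A `bops_result` from [run_bops()].
#' @param ... Unused.
#' @return A tibble with columns `complex_id`, `protein`, `score`.
#' @method tidy bops_result
#' @export
tidy.bops_result <- function(x, ...) {
  tibble(complex_id = rep(x$complex_id, x$size),
         protein = unlist(x$members),
         score = rep(x$score, x$size))
}

#' One-row summary of a BOPS run
#'
#' @param x A `bops_result` from [run_bops()].
#' @param ... Unused.
#' @return A one-row tibble: complex count, size range, candidate and
#'   survivor counts, and the parameters used.
#' @method glance bops_result
#' @export
glance.bops_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_complexes = nrow(x),
    size_min = if (nrow(x)) min(x$size) else NA_integer_,
    size_max = if (nrow(x)) max(x$size) else NA_integer_,
    n_parts = attr(x, "n_parts"),
    n_candidates = attr(x, "n_candidates"),
    n_survivors = attr(x, "n_survivors"),
    beta = p$beta, maxp = p$maxp,
    sim_threshold = p$sim_threshold, keep_fraction = p$keep_fraction
  )
}

#' Plot the size/cohesion profile of a prediction set
#'
#' @param object A `bops_result` from [run_bops()].
#' @param ... Unused.
#' @return A ggplot: complex size against cohesion, one point per predicted
#'   complex (jittered horizontally).
#' @method autoplot bops_result
#' @export
autoplot.bops_result <- function(object, ...) {
  df <- tibble(size = object$size, cohesion = object$score)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$size), y = .data$cohesion)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "complex size (proteins)", y = "cohesion",
                  title = "Predicted complexes") +
    ggplot2::theme_minimal()
}
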