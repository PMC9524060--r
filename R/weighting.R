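#' Per-vertex degree statistics
#'
#' For every protein `v` of the network, `degree` is the number of incident
#' interactions (cnt_v) and `strength` the sum of their weights (sum_v).
#' Isolated vertices get (0, 0).
#'
#' @param x A PPIN (see [ppin()]).
#' @return A tibble with columns `protein`, `degree` (integer) and `strength`
#'   (double), one row per vertex, sorted by protein.
#' @examples
#' net <- ppin(data.frame(a = c("A", "B"), b = c("B", "C"), w = c(0.8, 0.4)))
#' vertex_stats(net)
#' @export
vertex_stats <- function(x) {
  x <- as_ppin(x)
  verts <- ppin_vertices(x)
  ends <- c(x$protein_a, x$protein_b)
  w <- c(x$weight, x$weight)
  cnt <- table(factor(ends, levels = verts))
  sm <- tapply(w, factor(ends, levels = verts), sum, default = 0)
  tibble(
    protein = verts,
    degree = as.integer(cnt),
    strength = as.double(sm)
  )
}

#' Balanced edge weights
#'
#' Rescales every edge weight by the weighted degrees (strengths) of its
#' endpoints to encode the core-attachment structure of protein complexes:
#' for an edge `e = (x, y, w)`,
#' \deqn{bw_e = \frac{1}{2}\left(\frac{w^\beta}{s_x^{\beta-1}} +
#'   \frac{w^\beta}{s_y^{\beta-1}}\right)}
#' where `s_x`, `s_y` are the endpoint strengths in the original network.
#' Edges attached to low-strength (peripheral) proteins are dampened least,
#' edges between promiscuous hubs most. `beta = 1` leaves all weights
#' unchanged; for `beta >= 1`, `bw_e <= w_e` always, since each endpoint
#' strength is at least `w_e`.
#'
#' @param x A PPIN.
#' @param beta Balance exponent, normally in `[1, 2]` (default 1.5). Values
#'   outside that range trigger a warning but are accepted.
#' @return A `bops_ppin` with the same topology, `weight` replaced by the
#'   balanced weight, and attribute `beta` recording the exponent.
#' @examples
#' net <- ppin(data.frame(a = c("A", "B"), b = c("B", "C"), w = c(0.8, 0.4)))
#' balance_weights(net, beta = 2)
#' @export
balance_weights <- function(x, beta = 1.5) {
  x <- as_ppin(x)
  stopifnot_scalar_number(beta, "beta")
  if (beta < 1 || beta > 2) {
    warn(sprintf("beta = %g is outside the recommended range [1, 2].", beta))
  }
  stats <- vertex_stats(x)
  s <- setNames(stats$strength, stats$protein)
  bw <- 0.5 * (x$weight^beta / s[x$protein_a]^(beta - 1) +
               x$weight^beta / s[x$protein_b]^(beta - 1))
  out <- x
  out$weight <- unname(as.double(bw))
  new_ppin(out, vertices = ppin_vertices(x), beta = beta)
}
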