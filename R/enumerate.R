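#' Enumerate all connected vertex subsets of a small network
#'
#' Yields every subset of vertices whose induced subgraph is connected and
#' whose size lies in `[min_size, max_size]`, each exactly once, in a
#' deterministic order. The enumeration is anchored: vertices are taken in
#' lexicographic order, and subsets containing vertex `v_i` but none of
#' `v_1..v_{i-1}` are grown by extending only with exclusive (never-seen)
#' neighbours — the classic duplicate-free connected-subgraph scheme, run in
#' compiled code over 31-bit subset masks. The mask representation caps the
#' part size at 31 vertices, far above the recommended `maxp` of 20.
#'
#' @param x A PPIN piece (at most 31 vertices).
#' @param min_size,max_size Inclusive size bounds (defaults 2 and 10).
#' @return A list of character vectors (sorted members), possibly empty.
#' @examples
#' tri <- ppin(data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"), w = 1))
#' enumerate_connected_subsets(tri, 2, 3)
#' @export
enumerate_connected_subsets <- function(x, min_size = 2, max_size = 10) {
  x <- as_ppin(x)
  em <- enumerate_masks(x, min_size, max_size)
  n <- length(em$verts)
  if (n == 0L) return(list())
  bits <- bitwShiftL(1L, 0:(n - 1L))
  lapply(em$masks, function(m) em$verts[bitwAnd(bits, m) != 0L])
}

# Mask-level enumeration shared by the public API and the pipeline fast path.
enumerate_masks <- function(x, min_size = 2, max_size = 10) {
  stopifnot_scalar_number(min_size, "min_size", lower = 1)
  stopifnot_scalar_number(max_size, "max_size", lower = min_size)
  verts <- ppin_vertices(x)
  n <- length(verts)
  if (n > 31L) {
    abort(sprintf(
      "Part has %d vertices; enumeration supports at most 31 (use a smaller maxp).",
      n))
  }
  if (n == 0L) return(list(masks = integer(), verts = verts))
  ia <- match(x$protein_a, verts)
  ib <- match(x$protein_b, verts)
  masks <- enum_connected_masks_cpp(n, ia, ib, as.integer(min_size),
                                    as.integer(min(max_size, n)))
  list(masks = masks, verts = verts)
}

# Cohesion for a batch of subset masks of one part (compiled loop).
cohesion_masks <- function(x, masks) {
  verts <- ppin_vertices(x)
  ia <- match(x$protein_a, verts)
  ib <- match(x$protein_b, verts)
  cohesion_masks_cpp(length(verts), ia, ib, x$weight, as.integer(masks))
}
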