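#' Regression degree of a reference complex within a subnetwork
#'
#' `RD(b, s) = |s intersect b| / |b|` — the fraction of a reference
#' complex's proteins found inside one subnetwork. A reference is considered
#' recallable from `s` when RD reaches the threshold (0.25 by convention).
#'
#' @param reference Non-empty character vector: the reference complex.
#' @param subset Character vector: the subnetwork's vertex set.
#' @return A number in `[0, 1]`.
#' @export
regression_degree <- function(reference, subset) {
  reference <- unique(as.character(reference))
  if (length(reference) == 0L) abort("`reference` must be non-empty.")
  length(intersect(unique(as.character(subset)), reference)) / length(reference)
}

#' Expected regression ratio of a segmentation
#'
#' Measures how many recallable reference complexes survive network
#' segmentation: the numerator counts references with regression degree at
#' least `delta` inside some part, the denominator counts references with
#' regression degree at least `delta` in the full network. A segmentation
#' that never separates a complex's proteins across parts scores 1.
#'
#' @param ref The gold-standard complex set.
#' @param parts A `bops_partition` from [segment_ppin()], or a list of
#'   vertex-set character vectors (e.g. from [random_segmentation()]).
#' @param network The original PPIN the parts came from.
#' @param delta Recall threshold in (0, 1] (default 0.25).
#' @return A number in `[0, 1]`.
#' @export
expected_regression_ratio <- function(ref, parts, network, delta = 0.25) {
  stopifnot_scalar_number(delta, "delta", lower = 1e-12, upper = 1)
  ref <- as_complex_set(ref)$members
  part_sets <- partition_members(parts)
  verts <- ppin_vertices(as_ppin(network))
  recallable <- map_lgl(ref, function(b) regression_degree(b, verts) >= delta)
  if (!any(recallable)) {
    abort("No reference complex is recallable from the network at this delta.")
  }
  recalled <- map_lgl(ref, function(b) {
    any(map_lgl(part_sets, function(s) regression_degree(b, s) >= delta))
  })
  sum(recalled) / sum(recallable)
}
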