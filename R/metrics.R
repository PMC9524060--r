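#' Neighbourhood affinity between two protein sets
#'
#' `NA(p, b) = |p intersect b|^2 / (|p| * |b|)` — the squared overlap
#' normalised by both set sizes. Symmetric, 1 for identical sets, 0 for
#' disjoint ones. Two complexes are conventionally called matched when the
#' score reaches 0.25.
#'
#' @param p,b Non-empty character vectors of protein identifiers.
#' @return A number in `[0, 1]`.
#' @examples
#' neighborhood_affinity(c("A", "B", "C"), c("B", "C", "D"))  # 4/9
#' @export
neighborhood_affinity <- function(p, b) {
  p <- unique(as.character(p)); b <- unique(as.character(b))
  if (length(p) == 0L || length(b) == 0L) {
    abort("neighborhood_affinity() needs two non-empty sets.")
  }
  length(intersect(p, b))^2 / (length(p) * length(b))
}

# n_pred x n_ref matrix of pairwise intersection counts
overlap_matrix <- function(pred, ref) {
  prots <- sort_c(unique(c(unlist(pred), unlist(ref))))
  mp <- matrix(0, length(pred), length(prots))
  for (i in seq_along(pred)) mp[i, match(unique(pred[[i]]), prots)] <- 1
  mb <- matrix(0, length(ref), length(prots))
  for (i in seq_along(ref)) mb[i, match(unique(ref[[i]]), prots)] <- 1
  mp %*% t(mb)
}

na_matrix <- function(pred, ref) {
  t_mat <- overlap_matrix(pred, ref)
  sp <- lengths(map(pred, unique))
  sb <- lengths(map(ref, unique))
  t_mat^2 / outer(sp, sb)
}

#' Matched-complex counts at a neighbourhood-affinity threshold
#'
#' `n_cp` counts predictions matching (NA at least `omega`) at least one
#' reference complex; `n_cb` counts reference complexes matched by at least
#' one prediction. The comparison is inclusive: NA exactly at `omega` counts
#' as a match.
#'
#' @param pred,ref Complex sets ([complex_set()] tibbles or lists of
#'   character vectors): predictions and gold standard.
#' @param omega Match threshold in (0, 1] (default 0.25).
#' @return A named list with integers `n_cp` and `n_cb`.
#' @export
match_counts <- function(pred, ref, omega = 0.25) {
  stopifnot_scalar_number(omega, "omega", lower = 1e-12, upper = 1)
  pred <- as_complex_set(pred)$members
  ref <- as_complex_set(ref)$members
  if (length(pred) == 0L || length(ref) == 0L) {
    return(list(n_cp = 0L, n_cb = 0L))
  }
  na_mat <- na_matrix(pred, ref)
  list(n_cp = sum(apply(na_mat, 1L, max) >= omega),
       n_cb = sum(apply(na_mat, 2L, max) >= omega))
}

#' Clustering-wise sensitivity, positive predictive value and accuracy
#'
#' Built on the protein overlap counts `T[p, b] = |V_p intersect V_b|`:
#' Sn sums, over references, the best per-reference overlap and divides by
#' total reference proteins; PPV sums, over predictions, the best
#' per-prediction overlap and divides by the total of all overlaps; ACC is
#' their geometric mean. Both are 0 when their denominator is 0.
#'
#' @inheritParams match_counts
#' @return A named list with `sn`, `ppv` and `acc`.
#' @export
sn_ppv_acc <- function(pred, ref) {
  pred <- as_complex_set(pred)$members
  ref <- as_complex_set(ref)$members
  if (length(pred) == 0L || length(ref) == 0L) {
    return(list(sn = 0, ppv = 0, acc = 0))
  }
  t_mat <- overlap_matrix(pred, ref)
  sn_den <- sum(lengths(map(ref, unique)))
  sn <- if (sn_den > 0) sum(apply(t_mat, 2L, max)) / sn_den else 0
  ppv_den <- sum(t_mat)
  ppv <- if (ppv_den > 0) sum(apply(t_mat, 1L, max)) / ppv_den else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum matching ratio
#'
#' Builds the bipartite graph with predictions on one side, references on the
#' other, and an edge weighted by neighbourhood affinity for every pair with
#' NA at least `omega`. The MMR is the total weight of a maximum-weight
#' matching divided by the number of reference complexes; because each
#' reference can be matched by at most one prediction, splitting a reference
#' across several predictions is penalised.
#'
#' @inheritParams match_counts
#' @param omega Edge-inclusion threshold (default 0.25). Set `omega = 0` to
#'   include every pair with positive overlap.
#' @return A number in `[0, 1]`.
#' @export
mmr <- function(pred, ref, omega = 0.25) {
  stopifnot_scalar_number(omega, "omega", lower = 0, upper = 1)
  pred <- as_complex_set(pred)$members
  ref <- as_complex_set(ref)$members
  if (length(pred) == 0L || length(ref) == 0L) return(0)
  na_mat <- na_matrix(pred, ref)
  thr <- if (omega > 0) na_mat >= omega else na_mat > 0
  edges <- which(thr, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(0)
  np <- length(pred); nb <- length(ref)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, nb)),
    edges = as.vector(t(cbind(edges[, 1L], np + edges[, 2L])))
  )
  m <- igraph::max_bipartite_match(
    g, weights = na_mat[edges]
  )
  m$matching_weight / nb
}

#' Evaluate a prediction set against a gold standard
#'
#' Computes the full metric suite for protein complex prediction: precision
#' (`n_cp / |P|`), recall (`n_cb / |B|`) and their harmonic mean F-score at
#' neighbourhood-affinity threshold `omega`; the protein-level Sn, PPV and
#' their geometric mean ACC; and the maximum matching ratio.
#'
#' @inheritParams match_counts
#' @param omega Match threshold in (0, 1] (default 0.25).
#' @param max_size Optional size cap applied to the predictions first (see
#'   [size_filter()]); `Inf` (default) evaluates all predictions.
#' @return A one-row tibble with columns `n_predicted`, `n_reference`,
#'   `n_cp`, `n_cb`, `precision`, `recall`, `f_score`, `sn`, `ppv`, `acc`,
#'   `mmr`.
#' @examples
#' pred <- complex_set(list(c("A", "B", "C")))
#' ref <- complex_set(list(c("B", "C", "D"), c("X", "Y")))
#' evaluate_complexes(pred, ref)
#' @export
evaluate_complexes <- function(pred, ref, omega = 0.25, max_size = Inf) {
  pred <- as_complex_set(pred)
  ref <- as_complex_set(ref)
  if (is.finite(max_size)) pred <- size_filter(pred, max_size)
  counts <- match_counts(pred, ref, omega = omega)
  np <- nrow(pred); nb <- nrow(ref)
  precision <- if (np > 0) counts$n_cp / np else 0
  recall <- if (nb > 0) counts$n_cb / nb else 0
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  spa <- sn_ppv_acc(pred, ref)
  tibble(
    n_predicted = np, n_reference = nb,
    n_cp = counts$n_cp, n_cb = counts$n_cb,
    precision = precision, recall = recall, f_score = f_score,
    sn = spa$sn, ppv = spa$ppv, acc = spa$acc,
    mmr = mmr(pred, ref, omega = omega)
  )
}

#' Keep only complexes up to a maximum size
#'
#' @param x A complex set.
#' @param max_size Largest complex size retained (default 10, the
#'   small-complex regime).
#' @return The filtered complex set, original order preserved.
#' @export
size_filter <- function(x, max_size = 10) {
  stopifnot_scalar_number(max_size, "max_size", lower = 1)
  x <- as_complex_set(x)
  out <- x[lengths(x$members) <= max_size, , drop = FALSE]
  out$complex_id <- seq_len(nrow(out))
  out
}
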