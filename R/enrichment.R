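#' Minimum hypergeometric enrichment p-value of a complex
#'
#' For a predicted complex C and each functional group F sharing at least one
#' protein with it, computes the hypergeometric upper-tail probability of
#' drawing at least `k = |C intersect F|` group members in `|C|` draws from a
#' universe of `universe_size` proteins containing `|F|` group members:
#' \deqn{P = 1 - \sum_{i=0}^{k-1} \binom{|F|}{i}\binom{|V|-|F|}{|C|-i} /
#'   \binom{|V|}{|C|}}
#' The smallest p-value over groups (the complex's functional homogeneity)
#' is returned. A low value means the complex is unlikely to collect that
#' many same-function proteins by chance. Tails are evaluated with
#' [stats::phyper()], which works in log space internally.
#'
#' @param members Non-empty character vector: the complex.
#' @param annotations A tibble with columns `protein` and `group` (see
#'   [read_annotations()]).
#' @param universe_size Total number of proteins in the network; must be at
#'   least `|C|` and at least every group size.
#' @return A one-row tibble with `group`, `k` (overlap), `group_size` and
#'   `p_value`. When no group overlaps the complex, `group` is `NA` and
#'   `p_value` is `NA` (an "unannotated" complex).
#' @examples
#' ann <- tibble::tibble(protein = c("A", "B", "C", "D", "E"), group = "G1")
#' min_p_value(c("A", "B"), ann, universe_size = 10)
#' @export
min_p_value <- function(members, annotations, universe_size) {
  members <- unique(as.character(members))
  if (length(members) == 0L) abort("`members` must be non-empty.")
  stopifnot_scalar_number(universe_size, "universe_size",
                          lower = length(members))
  stopifnot(all(c("protein", "group") %in% names(annotations)))
  ann <- dplyr::distinct(tibble(protein = as.character(annotations$protein),
                                group = as.character(annotations$group)))
  groups <- split(ann$protein, ann$group)
  k <- map_int(groups, ~ length(intersect(.x, members)))
  fsize <- lengths(groups)
  hit <- k >= 1L
  if (!any(hit)) {
    return(tibble(group = NA_character_, k = 0L, group_size = NA_integer_,
                  p_value = NA_real_))
  }
  if (any(fsize[hit] > universe_size)) {
    abort("`universe_size` is smaller than an annotated group.")
  }
  # upper tail P(X >= k) for X ~ Hypergeometric(|F|, |V|-|F|, |C|)
  p <- unname(phyper(k[hit] - 1L, fsize[hit], universe_size - fsize[hit],
                     length(members), lower.tail = FALSE))
  best <- order(p, xtfrm_c(names(groups)[hit]))[1L]
  tibble(group = names(groups)[hit][best], k = unname(k[hit][best]),
         group_size = unname(fsize[hit][best]), p_value = p[best])
}

#' Per-complex enrichment table
#'
#' Applies [min_p_value()] to every complex of a prediction set.
#'
#' @param pred A complex set.
#' @param annotations A tibble with columns `protein` and `group`.
#' @param universe_size Total number of proteins in the network.
#' @return A tibble with one row per complex: `complex_id`, `size`, `group`,
#'   `k`, `group_size`, `p_value`, plus an attribute `n_below_1e5` counting
#'   complexes with p-value below 1e-5.
#' @export
complex_enrichment <- function(pred, annotations, universe_size) {
  pred <- as_complex_set(pred)
  rows <- purrr::map_dfr(seq_len(nrow(pred)), function(i) {
    res <- min_p_value(pred$members[[i]], annotations, universe_size)
    dplyr::bind_cols(tibble(complex_id = pred$complex_id[i],
                            size = pred$size[i]), res)
  })
  attr(rows, "n_below_1e5") <- sum(!is.na(rows$p_value) & rows$p_value < 1e-5)
  rows
}
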