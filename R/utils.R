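#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows row_number n desc left_join
#' @importFrom tibble tibble as_tibble new_tibble
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2 imap
#' @importFrom stats rbinom rbeta setNames phyper
#' @importFrom utils head combn
#' @importFrom Rcpp evalCpp
#' @useDynLib bops, .registration = TRUE
NULL

# Run code with a private RNG stream: seeds from `seed`, restores the caller's
# .Random.seed on exit so generators do not perturb the session RNG.
with_private_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Canonical unordered edge key "a|b" with a < b lexicographically (C collation,
# so keys are locale-independent).
edge_key <- function(a, b) {
  swap <- cmp_gt(a, b)
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "|")
}

# Locale-independent elementwise a > b (C collation): rank over the pooled
# values so the two sides are comparable.
cmp_gt <- function(a, b) {
  n <- length(a)
  r <- xtfrm_c(c(a, b))
  r[seq_len(n)] > r[n + seq_len(n)]
}

xtfrm_c <- function(x) {
  # rank strings under C collation, stable across locales
  u <- unique(x)
  match(x, u[order(u, method = "radix")])
}

sort_c <- function(x) sort(x, method = "radix")

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
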