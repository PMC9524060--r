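#' Build a complex set
#'
#' A complex set (a prediction set or a gold standard) is a tibble with one
#' row per complex: `complex_id` (position in the set), `members` (list column
#' of character vectors) and optionally `score`. Order is meaningful and is
#' preserved through file round-trips; members are stored deduplicated and
#' sorted.
#'
#' @param members A list of character vectors of protein identifiers, or a
#'   single character vector (one complex).
#' @param score Optional numeric vector of per-complex scores.
#' @return A `bops_complexes` tibble.
#' @examples
#' complex_set(list(c("A", "B", "C"), c("D", "E")))
#' @export
complex_set <- function(members, score = NULL) {
  if (is.character(members)) members <- list(members)
  members <- lapply(members, function(m) {
    m <- as.character(m)
    if (length(m) == 0L) abort("Every complex must be non-empty.")
    sort_c(unique(m))
  })
  out <- tibble(
    complex_id = seq_along(members),
    members = members,
    size = lengths(members)
  )
  if (!is.null(score)) {
    stopifnot(length(score) == length(members))
    out$score <- as.double(score)
  }
  class(out) <- c("bops_complexes", class(out))
  out
}

#' @export
print.bops_complexes <- function(x, ...) {
  cat(sprintf("# A complex set: %d complexes, sizes %s\n", nrow(x),
              if (nrow(x)) paste0(min(x$size), "-", max(x$size)) else "-"))
  NextMethod()
}

#' Read a complex set (one complex per line)
#'
#' Each non-comment line holds the whitespace-separated protein identifiers of
#' one complex; duplicates within a line are merged. An optional leading
#' numeric score column (as written by [write_complexes()]) is detected when
#' every line starts with a number followed by at least one identifier.
#'
#' @param path Path to the file.
#' @param scores `"auto"` (detect a leading score column), `"none"` (all
#'   tokens are proteins) or `"first"` (first token is always the score).
#' @return A `bops_complexes` tibble (see [complex_set()]).
#' @export
read_complexes <- function(path, scores = c("auto", "none", "first")) {
  scores <- match.arg(scores)
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines)
  lines <- lines[keep]
  blank <- grepl("^\\s*$", lines)
  if (any(blank)) {
    warn(sprintf("Skipping %d empty line(s) in '%s'.", sum(blank), path))
    lines <- lines[!blank]
  }
  if (length(lines) == 0L) return(complex_set(list()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  has_score <- switch(
    scores,
    none = FALSE,
    first = TRUE,
    auto = all(lengths(fields) >= 2L) &&
      !anyNA(suppressWarnings(as.double(map_chr(fields, 1L))))
  )
  if (has_score) {
    sc <- as.double(map_chr(fields, 1L))
    if (anyNA(sc)) abort(sprintf("Non-numeric score column in '%s'.", path))
    complex_set(lapply(fields, `[`, -1L), score = sc)
  } else {
    complex_set(fields)
  }
}

#' Write a complex set, one complex per line
#'
#' Proteins are written tab-separated and sorted lexicographically within each
#' line so output is byte-reproducible; if a `score` column is present it is
#' written as the first field.
#'
#' @param x A `bops_complexes` tibble (or list of character vectors).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(x, path) {
  x <- as_complex_set(x)
  body <- map_chr(x$members, function(m) paste(sort_c(m), collapse = "\t"))
  if ("score" %in% names(x)) {
    body <- paste(format(x$score, digits = 15, nsmall = 1, scientific = FALSE,
                         trim = TRUE),
                  body, sep = "\t")
  }
  writeLines(body, path, useBytes = TRUE)
  invisible(path)
}

as_complex_set <- function(x) {
  if (inherits(x, "bops_complexes")) return(x)
  if (is.data.frame(x) && "members" %in% names(x)) {
    return(complex_set(x$members, score = x[["score"]]))
  }
  complex_set(x)
}

#' Read a protein-to-group annotation table
#'
#' Two tab- or space-separated columns per line: protein identifier then
#' functional-group label (for example a GO term). Duplicated pairs are
#' counted once.
#'
#' @param path Path to the file.
#' @return A tibble with columns `protein` and `group`, one row per distinct
#'   pair.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(protein = character(), group = character()))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- lengths(fields) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed annotation line %d in '%s': expected 2 fields.",
                  idx[which(bad)[1L]], path))
  }
  out <- tibble(protein = map_chr(fields, 1L), group = map_chr(fields, 2L))
  dplyr::distinct(out)
}
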