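#' Build a weighted PPI network from an edge table
#'
#' A PPIN (protein-protein interaction network) is represented as a tibble of
#' undirected weighted edges with columns `protein_a`, `protein_b` and
#' `weight`, carrying the full vertex set (including isolated proteins) in an
#' attribute so that vertices without interactions are not silently lost.
#' Input edges are canonicalised: endpoints are oriented lexicographically,
#' self-loops are dropped with a warning, duplicate pairs are merged keeping
#' the maximum weight, and rows are sorted by the canonical edge key so equal
#' networks have byte-identical representations.
#'
#' @param edges A data frame whose first three columns are the two endpoint
#'   protein identifiers and an edge weight; a missing weight column defaults
#'   to 1. Column names are not required, only position.
#' @param vertices Optional character vector of protein identifiers; vertices
#'   mentioned by edges are added automatically. Use this to keep isolated
#'   proteins in the network.
#' @return A `bops_ppin` tibble with columns `protein_a < protein_b`
#'   (character) and `weight` (positive double), and attribute `vertices`.
#' @examples
#' net <- ppin(data.frame(a = c("A", "B"), b = c("B", "C"), w = c(0.5, 0.4)))
#' ppin_vertices(net)
#' @export
ppin <- function(edges, vertices = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) == 2L) edges$weight <- 1
  if (ncol(edges) < 2L && nrow(edges) > 0L) {
    abort("`edges` needs at least two endpoint columns.")
  }
  if (nrow(edges) == 0L) {
    return(new_ppin(
      tibble(protein_a = character(), protein_b = character(),
             weight = double()),
      vertices = sort_c(unique(as.character(vertices %||% character())))
    ))
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  w <- as.double(edges[[3L]])
  if (anyNA(a) || anyNA(b) || any(!nzchar(a)) || any(!nzchar(b))) {
    abort("Protein identifiers must be non-empty and non-missing.")
  }
  if (any(grepl("[[:space:]]", a)) || any(grepl("[[:space:]]", b))) {
    abort("Protein identifiers must not contain whitespace.")
  }
  if (anyNA(w) || any(w <= 0)) {
    abort("Edge weights must be positive numbers.")
  }
  verts <- sort_c(unique(c(a, b, as.character(vertices %||% character()))))
  loop <- a == b
  if (any(loop)) {
    warn(sprintf("Dropping %d self-loop(s); their vertices are kept.",
                 sum(loop)))
    a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
  }
  swap <- cmp_gt(a, b)
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  key <- paste(lo, hi, sep = "|")
  if (anyDuplicated(key)) {
    inform(sprintf("Merging %d duplicate edge record(s), keeping max weight.",
                   sum(duplicated(key))))
    keep <- tapply(w, key, max)
    ord <- !duplicated(key)
    lo <- lo[ord]; hi <- hi[ord]; key <- key[ord]
    w <- as.double(keep[key])
  }
  ord <- order(xtfrm_c(key))
  new_ppin(tibble(protein_a = lo[ord], protein_b = hi[ord], weight = w[ord]),
           vertices = verts)
}

new_ppin <- function(edges, vertices, beta = NULL) {
  cols <- list(protein_a = as.character(edges$protein_a),
               protein_b = as.character(edges$protein_b),
               weight = as.double(edges$weight))
  structure(
    new_tibble(cols, nrow = length(cols$protein_a), class = "bops_ppin"),
    vertices = vertices,
    beta = beta
  )
}

#' @export
print.bops_ppin <- function(x, ...) {
  beta <- attr(x, "beta")
  cat(sprintf("# A weighted PPIN: %d proteins, %d interactions%s\n",
              length(ppin_vertices(x)), nrow(x),
              if (is.null(beta)) "" else sprintf(" (balanced, beta = %g)", beta)))
  NextMethod()
}

#' Vertex set of a PPIN
#'
#' @param x A PPIN (see [ppin()]).
#' @return Character vector of protein identifiers, sorted, including
#'   isolated vertices.
#' @export
ppin_vertices <- function(x) {
  x <- as_ppin(x)
  attr(x, "vertices")
}

#' Coerce to a PPIN
#'
#' Accepts a `bops_ppin`, a data frame of edges, or an igraph graph.
#'
#' @inheritParams ppin
#' @param x Object to coerce.
#' @return A `bops_ppin` tibble.
#' @export
as_ppin <- function(x, vertices = NULL) {
  if (inherits(x, "bops_ppin") && !is.null(attr(x, "vertices")) &&
      is.null(vertices)) {
    return(x)
  }
  if (inherits(x, "igraph")) {
    df <- igraph::as_data_frame(x, what = "edges")
    w <- if ("weight" %in% names(df)) df$weight else rep(1, nrow(df))
    return(ppin(data.frame(a = df$from, b = df$to, w = w),
                vertices = igraph::V(x)$name))
  }
  ppin(x, vertices = vertices)
}

# igraph view of a ppin (named vertices, weight attribute)
ppin_igraph <- function(x) {
  x <- as_ppin(x)
  igraph::graph_from_data_frame(
    data.frame(from = x$protein_a, to = x$protein_b, weight = x$weight),
    directed = FALSE,
    vertices = data.frame(name = ppin_vertices(x))
  )
}

# induced sub-ppin on a vertex subset, keeping the beta tag
ppin_induced <- function(x, members) {
  x <- as_ppin(x)
  keep <- x$protein_a %in% members & x$protein_b %in% members
  new_ppin(x[keep, , drop = FALSE], vertices = sort_c(unique(members)),
           beta = attr(x, "beta"))
}

# connected components as a list of vertex-name character vectors,
# deterministic order: by canonical smallest member
ppin_components <- function(x) {
  x <- as_ppin(x)
  g <- ppin_igraph(x)
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  groups <- lapply(groups, sort_c)
  groups[order(xtfrm_c(map_chr(groups, 1L)))]
}

#' Read a weighted edge list
#'
#' Parses the tab- or space-separated edge-list format
#' `proteinA proteinB [weight]`, one interaction per line. Lines starting with
#' `#` and blank lines are ignored. A missing weight defaults to 1. Self-loops
#' are dropped (their protein is kept as an isolated vertex) and duplicate
#' pairs are merged keeping the maximum weight.
#'
#' @param path Path to the edge-list file.
#' @return A `bops_ppin` tibble (see [ppin()]).
#' @export
read_ppin <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(ppin(data.frame(a = character(), b = character(), w = double())))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  bad <- nf < 2L | nf > 3L
  if (any(bad)) {
    abort(sprintf("Malformed edge line %d in '%s': expected 2 or 3 fields, got %d.",
                  idx[which(bad)[1L]], path, nf[which(bad)[1L]]))
  }
  a <- map_chr(fields, 1L)
  b <- map_chr(fields, 2L)
  wtxt <- map_chr(fields, function(f) if (length(f) == 3L) f[[3L]] else "1")
  w <- suppressWarnings(as.double(wtxt))
  if (anyNA(w)) {
    abort(sprintf("Malformed weight on line %d in '%s': '%s'.",
                  idx[which(is.na(w))[1L]], path, wtxt[which(is.na(w))[1L]]))
  }
  if (any(w <= 0)) {
    abort(sprintf("Non-positive weight on line %d in '%s'.",
                  idx[which(w <= 0)[1L]], path))
  }
  ppin(data.frame(a = a, b = b, w = w))
}

#' Write a PPIN as a tab-separated edge list
#'
#' @param x A PPIN.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppin <- function(x, path) {
  x <- as_ppin(x)
  lines <- sprintf("%s\t%s\t%s", x$protein_a, x$protein_b,
                   format(x$weight, digits = 15, scientific = FALSE,
                          trim = TRUE))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
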