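#' Read an undirected simple graph from a plain-text edge list
#'
#' Parses the edge-list dialect used by networkrepository.com and
#' sociopatterns.org downloads: one edge per line, the first two
#' whitespace- or comma-separated tokens naming the endpoints. Lines starting
#' with `%` or `#` are comments; an MTX-style numeric size header (a line of
#' two or three numbers directly after `%%MatrixMarket`-style comments that
#' does not recur as an edge) is skipped. Extra tokens on a line (weights,
#' timestamps) are ignored. The result is always a simple undirected graph:
#' self-loops are dropped and duplicate or reversed edges collapsed (counts
#' reported via [message()]).
#'
#' @param path Path to the edge-list file.
#' @param sep Token separator: `"auto"` (default; splits on any mix of
#'   whitespace and commas), `"whitespace"`, or `","`.
#' @return An [igraph][igraph::igraph-package] graph with vertex names equal
#'   to the labels in the file.
#' @examples
#' f <- tempfile(fileext = ".edges")
#' writeLines(c("% a comment", "1 2", "2 3", "3 1"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path, sep = c("auto", "whitespace", ",")) {
  sep <- match.arg(sep)
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  split_re <- switch(sep,
    auto = "[[:space:],]+",
    whitespace = "[[:space:]]+",
    "," = "[[:space:]]*,[[:space:]]*"
  )

  from <- character(0)
  to <- character(0)
  # MatrixMarket files announce themselves on line 1; only then is the first
  # data line a rows/cols/nnz size header rather than an edge.
  is_mtx <- length(lines) > 0 && grepl("^%%", trimws(lines[[1]]))
  mtx_header_skipped <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "%") || startsWith(ln, "#")) next
    tok <- strsplit(ln, split_re)[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 2) {
      stop("malformed edge-list line ", i, ": ", lines[[i]])
    }
    if (is_mtx && !mtx_header_skipped) {
      mtx_header_skipped <- TRUE
      next
    }
    from <- c(from, tok[[1]])
    to <- c(to, tok[[2]])
  }
  if (length(from) == 0) stop("no edges found in ", path)

  loops <- from == to
  if (any(loops)) message("dropped ", sum(loops), " self-loop(s)")
  from_k <- from[!loops]
  to_k <- to[!loops]
  a <- pmin(from_k, to_k)
  b <- pmax(from_k, to_k)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message("collapsed ", sum(dup), " duplicate/reversed edge(s)")
  a <- a[!dup]
  b <- b[!dup]
  if (length(a) == 0) stop("graph is empty after removing loops: ", path)

  labels <- unique(c(from, to)) # keep isolated loop-only labels out: from/to include loops
  labels <- labels[.label_order(labels)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = labels, stringsAsFactors = FALSE)
  )
  stopifnot(igraph::is_simple(g))
  g
}

#' Write a graph as a canonical edge list
#'
#' Emits one edge per line, endpoints in ascending label order within each
#' line and lines sorted, using the graph's original vertex names, so that
#' re-reading with [read_edge_list()] reproduces the graph exactly.
#'
#' @param g An undirected igraph graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    swap <- .label_rank(.node_labels(g))[match(el[, 1], .node_labels(g))] >
      .label_rank(.node_labels(g))[match(el[, 2], .node_labels(g))]
    tmp <- el[swap, 1]
    el[swap, 1] <- el[swap, 2]
    el[swap, 2] <- tmp
    ord <- order(
      .label_rank(.node_labels(g))[match(el[, 1], .node_labels(g))],
      .label_rank(.node_labels(g))[match(el[, 2], .node_labels(g))]
    )
    el <- el[ord, , drop = FALSE]
  }
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}
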