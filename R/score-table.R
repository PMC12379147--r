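#' Construct a score table
#'
#' A score table binds one finite real score to every node of a graph and
#' remembers which method (and parameters) produced it. It is an ordinary
#' `data.frame` with columns `node` and `score` plus `method`/`params`
#' attributes, so the usual data-frame tools apply.
#'
#' @param node Character vector of node labels.
#' @param score Numeric vector of finite scores, one per node.
#' @param method Identifier of the producing method (e.g. `"eddc"`).
#' @param params Named list of method parameters (possibly empty).
#' @return A `score_table` data frame.
#' @export
score_table <- function(node, score, method, params = list()) {
  node <- as.character(node)
  score <- as.numeric(score)
  stopifnot(length(node) == length(score), !anyDuplicated(node))
  if (any(!is.finite(score))) stop("scores must be finite reals")
  out <- data.frame(node = node, score = score, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "params") <- params
  class(out) <- c("score_table", "data.frame")
  out
}

#' @export
print.score_table <- function(x, ...) {
  p <- attr(x, "params")
  ptxt <- if (length(p)) {
    paste0(" (", paste(names(p), unlist(p), sep = "=", collapse = ", "), ")")
  } else ""
  cat("score_table: ", attr(x, "method"), ptxt, ", ", nrow(x), " nodes\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Rank nodes by score
#'
#' Produces the total order used throughout the evaluation: descending score,
#' ties broken by ascending node label (numeric when all labels are numeric),
#' so identical inputs always give identical rankings.
#'
#' @param scores A [score_table()].
#' @return A `rank_list` data frame with columns `rank`, `node`, `score`.
#' @export
rank_nodes <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  ord <- order(-scores$score, .label_rank(scores$node))
  out <- data.frame(
    rank = seq_len(nrow(scores)),
    node = scores$node[ord],
    score = scores$score[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- attr(scores, "method")
  class(out) <- c("rank_list", "data.frame")
  out
}

#' @export
print.rank_list <- function(x, ...) {
  cat("rank_list:", attr(x, "method"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Write a score table or rank list as TSV
#'
#' The header comment line records the producing method and its parameters so
#' written tables are self-describing.
#'
#' @param x A `score_table` or `rank_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(x, path) {
  p <- attr(x, "params")
  ptxt <- if (length(p)) {
    paste0(" ", paste(names(p), unlist(p), sep = "=", collapse = " "))
  } else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", attr(x, "method"), ptxt), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
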