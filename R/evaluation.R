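#' Kendall rank correlation between two score sequences
#'
#' The untied (tau-a) form
#' \deqn{\tau = \frac{N_c - N_d}{0.5\, n (n - 1)},}
#' where \eqn{N_c} and \eqn{N_d} count concordant and discordant pairs picked
#' from corresponding positions of `x` and `y`. Tied pairs count in neither,
#' so heavy ties pull \eqn{\tau} towards 0 — deliberate, since SIR mean
#' outbreak sizes tie often and the evaluation should reflect that. The
#' tie-corrected tau-b is available via `variant = "b"`.
#'
#' @param x,y Numeric vectors of equal length \eqn{n \ge 2}, aligned on node
#'   identity.
#' @param variant `"a"` (default, as defined above) or `"b"` (tie-corrected,
#'   via [stats::cor()]).
#' @return \eqn{\tau \in [-1, 1]}.
#' @export
kendall_tau <- function(x, y, variant = c("a", "b")) {
  variant <- match.arg(variant)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2) stop("need at least two observations")
  if (variant == "b") return(stats::cor(x, y, method = "kendall"))
  # Nc - Nd = sum over i<j of sign(x_j - x_i) * sign(y_j - y_i), accumulated
  # in blocks to keep memory linear in n per block.
  s <- 0
  block <- max(1L, floor(4e6 / n))
  for (start in seq(1L, n - 1L, by = block)) {
    rows <- start:min(start + block - 1L, n - 1L)
    for (i in rows) {
      j <- (i + 1L):n
      s <- s + sum(sign(x[j] - x[i]) * sign(y[j] - y[i]))
    }
  }
  s / (0.5 * n * (n - 1))
}

#' Grid-averaged Kendall tau
#'
#' Arithmetic mean of tau values computed across an infection-probability
#' grid; the summary used to compare methods over a range of spreading
#' intensities.
#'
#' @param taus Numeric vector of tau values (one per grid point).
#' @return Their mean.
#' @seealso [beta_grid()]
#' @export
sigma_tau <- function(taus) {
  if (length(taus) == 0) stop("empty tau grid")
  mean(taus)
}

#' Infection-probability grid anchored at the epidemic threshold
#'
#' \eqn{\beta_{th} + step \cdot i} for \eqn{i = 1, \dots, n_{steps}}: the grid
#' over which rankings are scored once spreading actually percolates.
#'
#' @param beta_th Epidemic threshold (see [epidemic_threshold()]).
#' @param n_steps Number of grid points (default 15).
#' @param step Grid increment (default 0.01).
#' @return Numeric vector of beta values.
#' @export
beta_grid <- function(beta_th, n_steps = 15, step = 0.01) {
  stopifnot(n_steps >= 1, step > 0)
  beta_th + step * seq_len(n_steps)
}

#' Monotonicity of a scoring
#'
#' How uniquely a method scores nodes:
#' \deqn{M = \Big(1 - \frac{\sum_i N_i (N_i - 1)}{N (N - 1)}\Big)^2,}
#' summing over distinct score values, \eqn{N_i} nodes sharing value
#' \eqn{i}. 1 means all scores distinct, 0 all equal. Scores are rounded to
#' `digits` decimals first so floating-point noise does not fake uniqueness.
#'
#' @param scores A [score_table()] or numeric vector, \eqn{N \ge 2} entries.
#' @param digits Rounding applied before counting ties (default 10).
#' @return \eqn{M \in [0, 1]}.
#' @export
monotonicity <- function(scores, digits = 10) {
  x <- if (inherits(scores, "score_table")) scores$score else as.numeric(scores)
  n <- length(x)
  stopifnot(n >= 2)
  ni <- table(round(x, digits))
  (1 - sum(ni * (ni - 1)) / (n * (n - 1)))^2
}

#' Percentage performance gain of one tau over another
#'
#' \deqn{\eta = \frac{\tau_C - \tau_\phi}{|\tau_\phi|} \times 100} for
#' \eqn{\tau_\phi \ne 0} (the positive- and negative-baseline branches both
#' reduce to division by the absolute value), and 0 when the baseline tau is
#' 0. Positive \eqn{\eta} means the candidate tracks the SIR ranking better
#' than the baseline.
#'
#' @param tau_c Candidate tau, in `[-1, 1]`.
#' @param tau_phi Baseline tau, in `[-1, 1]`. Vectorised over both.
#' @return \eqn{\eta} in percent.
#' @export
performance_gain <- function(tau_c, tau_phi) {
  stopifnot(all(abs(tau_c) <= 1), all(abs(tau_phi) <= 1))
  out <- ifelse(tau_phi == 0, 0, (tau_c - tau_phi) / abs(tau_phi) * 100)
  as.numeric(out)
}

#' Top-k nodes of a ranking, and overlap between node lists
#'
#' @param ranks A `rank_list` from [rank_nodes()].
#' @param k How many leading nodes to take, `1 <= k <= N`.
#' @return `top_k()`: character vector of the first `k` node labels.
#' @export
top_k <- function(ranks, k) {
  stopifnot(inherits(ranks, "rank_list"))
  if (k < 1 || k > nrow(ranks)) stop("k must be in [1, ", nrow(ranks), "]")
  ranks$node[seq_len(k)]
}

#' @rdname top_k
#' @param a,b Node-label vectors.
#' @return `overlap()`: size of the set intersection.
#' @export
overlap <- function(a, b) {
  length(intersect(unique(a), unique(b)))
}

#' Evaluate centrality methods against SIR ground truth
#'
#' Runs the full comparison pipeline on one graph: computes each method's
#' scores, simulates SIR spreading ability at every infection probability in
#' `grid` (each grid point gets its own substream of the master seed), and
#' reports per-method Kendall tau at each grid point, the grid mean
#' `sigma_tau`, monotonicity, the percentage gain of the `candidate` method
#' over every other method (computed on the grid means), and top-`k` node
#' lists.
#'
#' @param g An undirected igraph graph.
#' @param methods Character vector of method names from
#'   [centrality_methods()].
#' @param cfg A [sir_config()]; its `beta` field is overridden by each grid
#'   value.
#' @param grid Numeric vector of infection probabilities; default the
#'   15-point 0.01-step grid just above the epidemic threshold.
#' @param candidate Method whose gain over the others is reported (default
#'   `"eddc"`).
#' @param k Top-k table size (default `min(10, N)`).
#' @param delta Threshold passed to isolating centrality.
#' @param max_hops Hop cutoff passed to the distance-sum measures.
#' @return An `eval_report` list with elements `grid`, `tau` (grid x method
#'   matrix), `sigma_tau`, `monotonicity`, `gain`, `top_k`, `config`.
#' @export
evaluate_methods <- function(g, methods, cfg,
                             grid = beta_grid(epidemic_threshold(g)),
                             candidate = "eddc", k = NULL,
                             delta = 2, max_hops = Inf) {
  if (length(methods) == 0) stop("no methods given")
  if (length(grid) == 0) stop("empty beta grid")
  reg <- centrality_methods()
  bad <- setdiff(methods, names(reg))
  if (length(bad)) {
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; registered methods: ", paste(names(reg), collapse = ", "))
  }
  if (is.null(k)) k <- min(10L, igraph::vcount(g))

  scores <- lapply(methods, function(m) {
    reg[[m]](g, delta = delta, max_hops = max_hops)
  })
  names(scores) <- methods
  labels <- .node_labels(g)

  tau <- matrix(NA_real_, nrow = length(grid), ncol = length(methods),
                dimnames = list(format(grid, trim = TRUE), methods))
  for (i in seq_along(grid)) {
    cfg_i <- sir_config(beta = grid[[i]], lambda = cfg$lambda,
                        runs = cfg$runs, seed = cfg$seed + i - 1L)
    sir_scores <- spreading_ability(g, cfg_i)
    y <- sir_scores$score[match(labels, sir_scores$node)]
    for (m in methods) {
      x <- scores[[m]]$score[match(labels, scores[[m]]$node)]
      tau[i, m] <- kendall_tau(x, y)
    }
  }

  sig <- apply(tau, 2, sigma_tau)
  mono <- vapply(scores, monotonicity, numeric(1))
  gain <- if (candidate %in% methods) {
    vapply(setdiff(methods, candidate), function(m) {
      performance_gain(sig[[candidate]], sig[[m]])
    }, numeric(1))
  } else {
    numeric(0)
  }
  tops <- lapply(scores, function(s) top_k(rank_nodes(s), k))

  structure(
    list(
      grid = grid, tau = tau, sigma_tau = sig, monotonicity = mono,
      gain = gain, top_k = tops,
      config = list(methods = methods, candidate = candidate, k = k,
                    lambda = cfg$lambda, runs = cfg$runs, seed = cfg$seed,
                    delta = delta, max_hops = max_hops,
                    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", x$config$n_nodes, "nodes,", x$config$n_edges, "edges;",
      length(x$grid), "beta grid points;", x$config$runs, "SIR runs/node\n")
  cat("sigma(tau):\n")
  print(round(x$sigma_tau, 4))
  cat("monotonicity:\n")
  print(round(x$monotonicity, 4))
  if (length(x$gain)) {
    cat("gain of", x$config$candidate, "(%):\n")
    print(round(x$gain, 2))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (the full report) plus per-metric TSV tables with
#' methods as columns: `tau.tsv` (tau at each beta), `sigma_tau.tsv`,
#' `monotonicity.tsv`, `gain.tsv`, `top_k.tsv`.
#'
#' @param report An `eval_report` from [evaluate_methods()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      grid = report$grid,
      tau = as.data.frame(report$tau),
      sigma_tau = as.list(report$sigma_tau),
      monotonicity = as.list(report$monotonicity),
      gain = as.list(report$gain),
      top_k = report$top_k,
      config = report$config
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  tau_df <- data.frame(beta = report$grid, report$tau, check.names = FALSE)
  utils::write.table(tau_df, file.path(dir, "tau.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  one_row <- function(v) {
    data.frame(as.list(v), check.names = FALSE)
  }
  utils::write.table(one_row(report$sigma_tau),
                     file.path(dir, "sigma_tau.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(one_row(report$monotonicity),
                     file.path(dir, "monotonicity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(report$gain)) {
    utils::write.table(one_row(report$gain), file.path(dir, "gain.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  topk_df <- data.frame(rank = seq_len(report$config$k),
                        report$top_k, check.names = FALSE)
  utils::write.table(topk_df, file.path(dir, "top_k.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Minimal tau-versus-beta plot
#'
#' Base-graphics helper: one line per method across the beta grid.
#'
#' @param report An `eval_report`.
#' @param ... Passed to [graphics::matplot()].
#' @return The report, invisibly.
#' @export
plot_tau <- function(report, ...) {
  stopifnot(inherits(report, "eval_report"))
  graphics::matplot(report$grid, report$tau, type = "b", pch = 1,
                    xlab = expression(beta), ylab = expression(tau),
                    lty = 1, ...)
  graphics::legend("bottomright", legend = colnames(report$tau),
                   col = seq_len(ncol(report$tau)), lty = 1, cex = 0.8)
  invisible(report)
}
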