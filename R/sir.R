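#' SIR simulation configuration
#'
#' Bundles the parameters of the discrete-time SIR spreading process:
#' infection probability `beta` per infected-susceptible contact per step,
#' recovery probability `lambda` per step (1 means every infected node
#' transmits for exactly one step), the number of Monte-Carlo `runs` per seed
#' node, and the master RNG `seed`.
#'
#' @param beta Infection probability, in `[0, 1]`.
#' @param lambda Recovery probability, in `(0, 1]`; default 1.
#' @param runs Monte-Carlo repetitions per seed node; default 1000.
#' @param seed Master integer seed (default 1).
#' @return A `sir_config` list.
#' @export
sir_config <- function(beta, lambda = 1, runs = 1000, seed = 1L) {
  stopifnot(beta >= 0, beta <= 1, lambda > 0, lambda <= 1, runs >= 1)
  structure(
    list(beta = beta, lambda = lambda, runs = as.integer(runs),
         seed = as.integer(seed)),
    class = "sir_config"
  )
}

# Flattened adjacency (CSR-style): nbr holds the concatenated neighbour
# indices, ptr[i] the first position of node i's block, len[i] its length.
# Directed entry ids (positions in nbr) index the optional coupling uniforms.
.flat_adjacency <- function(g) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  len <- lengths(adj)
  list(
    nbr = if (sum(len) > 0) unlist(adj, use.names = FALSE) else integer(0),
    ptr = c(1L, 1L + cumsum(len)),
    len = len,
    n = igraph::vcount(g)
  )
}

# One synchronous SIR run. Infections are computed from the infected set at
# the start of the step, then recoveries are applied to that same set, so
# with lambda = 1 every infected node transmits for exactly one step.
# contact_uniforms (optional, lambda = 1 only): one uniform per directed
# adjacency entry, enabling coupled comparisons across beta values.
.sir_run <- function(fa, start, beta, lambda, contact_uniforms = NULL) {
  if (!is.null(contact_uniforms) && lambda != 1) {
    stop("contact_uniforms coupling requires lambda = 1")
  }
  status <- integer(fa$n) # 0 susceptible, 1 infected, 2 recovered
  status[start] <- 1L
  infected <- start
  n_ever <- 1L
  while (length(infected) > 0) {
    li <- fa$len[infected]
    active <- li > 0
    newly <- integer(0)
    if (any(active)) {
      idx <- sequence(li[active], from = fa$ptr[infected[active]])
      targets <- fa$nbr[idx]
      sus <- status[targets] == 0L
      if (any(sus)) {
        u <- if (is.null(contact_uniforms)) {
          runif(sum(sus))
        } else {
          contact_uniforms[idx[sus]]
        }
        hit <- targets[sus][u < beta]
        newly <- unique(hit)
      }
    }
    if (lambda >= 1) {
      status[infected] <- 2L
      infected <- integer(0)
    } else {
      rec <- runif(length(infected)) < lambda
      status[infected[rec]] <- 2L
      infected <- infected[!rec]
    }
    if (length(newly) > 0) {
      status[newly] <- 1L
      infected <- c(infected, newly)
      n_ever <- n_ever + length(newly)
    }
  }
  n_ever
}

#' Simulate one SIR outbreak
#'
#' Synchronous discrete-time dynamics: each step, every infected node
#' independently infects each susceptible neighbour with probability `beta`;
#' the step's infected nodes then recover with probability `lambda`. The run
#' ends when no infected nodes remain.
#'
#' @param g An undirected igraph graph.
#' @param seed_node Vertex name of the initially infected node.
#' @param cfg A [sir_config()]; its `runs` field is ignored here.
#' @param contact_uniforms Optional numeric vector of uniforms, one per
#'   directed adjacency entry (in [igraph::as_adj_list()] order), consumed
#'   instead of fresh draws; requires `lambda = 1`. This gives a monotone
#'   coupling across `beta` values: with the same uniforms, a larger `beta`
#'   can only enlarge the outbreak.
#' @return The outbreak size: the count of ever-infected nodes, in `[1, N]`.
#' @export
simulate_once <- function(g, seed_node, cfg, contact_uniforms = NULL) {
  stopifnot(inherits(cfg, "sir_config"))
  fa <- .flat_adjacency(g)
  .sir_run(fa, .resolve_vertex(g, seed_node), cfg$beta, cfg$lambda,
           contact_uniforms)
}

#' Spreading ability of every node under SIR
#'
#' The ground truth the centralities are scored against: for each node, the
#' mean final outbreak size over `cfg$runs` independent SIR simulations
#' seeded at that node. Each node gets its own RNG substream derived from the
#' master seed and the node's position, so results for a node do not change
#' when other nodes are added.
#'
#' @param g An undirected igraph graph.
#' @param cfg A [sir_config()].
#' @return A [score_table()] with method `"sir"`; scores lie in `[1, N]`.
#' @export
spreading_ability <- function(g, cfg) {
  stopifnot(inherits(cfg, "sir_config"))
  fa <- .flat_adjacency(g)
  set.seed(cfg$seed)
  node_seeds <- sample.int(.Machine$integer.max - 1L, fa$n)
  sc <- vapply(seq_len(fa$n), function(v) {
    set.seed(node_seeds[[v]])
    tot <- 0
    for (r in seq_len(cfg$runs)) tot <- tot + .sir_run(fa, v, cfg$beta, cfg$lambda)
    tot / cfg$runs
  }, numeric(1))
  score_table(.node_labels(g), sc, "sir",
              list(beta = cfg$beta, lambda = cfg$lambda, runs = cfg$runs,
                   seed = cfg$seed))
}

#' Heterogeneous mean-field epidemic threshold
#'
#' \deqn{\beta_{th} = \langle k \rangle / (\langle k^2 \rangle -
#'       \langle k \rangle)} from the graph's degree moments: the infection
#' probability above which outbreaks percolate through the network.
#'
#' @param g An undirected igraph graph with at least one edge.
#' @return The threshold estimate, a positive number.
#' @export
epidemic_threshold <- function(g) {
  deg <- igraph::degree(g)
  if (sum(deg) == 0) stop("graph has no edges")
  k1 <- mean(deg)
  k2 <- mean(deg^2)
  if (k2 - k1 <= 0) {
    stop("epidemic threshold undefined: <k^2> <= <k> (degree moments ",
         "give a non-positive denominator)")
  }
  k1 / (k2 - k1)
}
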