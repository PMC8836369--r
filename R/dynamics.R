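#' Fermi imitation probability
#'
#' Probability that a focal player with accumulated payoff `ui` adopts the
#' strategy of a neighbour with payoff `uj`:
#' `1 / (1 + exp((ui - uj) / a))`. The rationality `a` sets how sharply
#' payoff differences translate into imitation; the probability is strictly
#' decreasing in `ui - uj` and `p(ui, uj) + p(uj, ui) = 1`.
#'
#' @param ui,uj Payoffs of the focal player and the imitated neighbour.
#' @param a Rationality (noise) parameter, `> 0`. Default 0.1.
#' @return Imitation probability in `(0, 1)` (saturating at the floating
#'   point limits for extreme payoff gaps).
#' @examples
#' fermi_probability(1, 1)            # 0.5
#' fermi_probability(0.23, 0, 0.1)    # ~ 0.0911
#' @export
fermi_probability <- function(ui, uj, a = 0.1) {
  if (any(a <= 0)) stop("rationality a must be positive")
  z <- pmin(pmax((ui - uj) / a, -700), 700)
  1 / (1 + exp(z))
}

# payoffs of all nodes in one round, given integer strategies s and the
# edge list (e1, e2); P is the score matrix over strategy indices
round_payoffs <- function(s, e1, e2, P, n) {
  u <- numeric(n)
  if (length(e1)) {
    contrib <- rowsum(c(P[cbind(s[e1], s[e2])], P[cbind(s[e2], s[e1])]),
                      c(e1, e2))
    u[as.integer(rownames(contrib))] <- contrib[, 1]
  }
  u
}

#' Simulate an evolutionary game on a network
#'
#' Every round, each node plays one prisoner's dilemma round against every
#' neighbour and accumulates the payoffs; then all nodes synchronously pick
#' one random neighbour and adopt its strategy with the Fermi probability
#' ([fermi_probability()]). To keep the observed data diverse after the
#' dynamics freeze, all strategies are re-drawn uniformly at random every
#' `reshuffle_period` rounds (set `Inf` to disable; the initial round is
#' always a uniform draw).
#'
#' @param net An [igraph::igraph].
#' @param table A [payoff_table()]; its active strategies define the
#'   strategy pool.
#' @param rounds Number of observed rounds `M`.
#' @param a Rationality of the Fermi rule.
#' @param reshuffle_period Rounds between uniform strategy re-draws.
#' @param seed Optional integer seed; all randomness of the simulation
#'   flows from it.
#' @return A `game_trace`: list with the `N x M` integer strategy matrix
#'   `strategies` (levels in `strategy_levels`), the `N x M` payoff matrix
#'   `payoffs`, the game parameters, and the generating network.
#' @examples
#' g <- generate_network("scale_free", 50, 6, seed = 1)
#' tr <- simulate_game(g, payoff_table(c("C", "D")), rounds = 10, seed = 1)
#' dim(tr$payoffs)
#' @export
simulate_game <- function(net, table, rounds, a = 0.1, reshuffle_period = 3,
                          seed = NULL) {
  if (rounds < 1) stop("rounds must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  e1 <- el[, 1]; e2 <- el[, 2]
  adj <- lapply(igraph::adjacent_vertices(net, seq_len(n)), as.integer)
  levels <- rownames(table)
  k <- length(levels)
  P <- unclass(table)

  S <- matrix(0L, n, rounds)
  Y <- matrix(0, n, rounds)
  s <- sample.int(k, n, replace = TRUE)
  for (t in seq_len(rounds)) {
    if (t > 1) {
      if (is.finite(reshuffle_period) && (t - 1) %% reshuffle_period == 0) {
        s <- sample.int(k, n, replace = TRUE)
      }
    }
    S[, t] <- s
    u <- round_payoffs(s, e1, e2, P, n)
    Y[, t] <- u
    if (t < rounds) {
      # synchronous Fermi imitation of one random neighbour each
      pick <- vapply(adj, function(v) {
        if (length(v)) v[sample.int(length(v), 1L)] else NA_integer_
      }, integer(1))
      has <- !is.na(pick)
      adopt <- logical(n)
      if (any(has)) {
        p <- fermi_probability(u[has], u[pick[has]], a)
        adopt[has] <- runif(sum(has)) < p
      }
      s_new <- s
      s_new[adopt] <- s[pick[adopt]]
      s <- s_new
    }
  }
  structure(list(strategies = S, strategy_levels = levels, payoffs = Y,
                 table = table, a = a, reshuffle_period = reshuffle_period,
                 seed = seed, network = net),
            class = "game_trace")
}

#' @export
print.game_trace <- function(x, ...) {
  cat("Evolutionary game trace: ", nrow(x$payoffs), " nodes x ",
      ncol(x$payoffs), " rounds; strategies {",
      paste(x$strategy_levels, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Strategy labels of a game trace
#'
#' @param trace A `game_trace`.
#' @return Character `N x M` matrix of strategy labels.
#' @export
strategy_matrix <- function(trace) {
  matrix(trace$strategy_levels[trace$strategies],
         nrow(trace$strategies), ncol(trace$strategies))
}

#' Per-node linear recovery problem from a game trace
#'
#' For a focal node `i`, the observed payoff in round `t` is the sum of the
#' pairwise scores against its (unknown) neighbours, so
#' `y = F x` with `F[t, j] = u(s_i(t), s_j(t))` over the `N - 1` candidate
#' neighbours and the binary incidence vector `x`. This builds `(F, y)`
#' with the column-to-node map.
#'
#' @param trace A `game_trace`.
#' @param node Focal node id (1-based).
#' @param table Payoff table; defaults to the one stored in the trace.
#' @return A [node_problem()].
#' @export
build_node_problem <- function(trace, node, table = trace$table) {
  S <- trace$strategies
  n <- nrow(S)
  if (node < 1 || node > n) stop("node out of range")
  P <- unclass(table)
  others <- setdiff(seq_len(n), node)
  Sj <- S[others, , drop = FALSE]              # (N-1) x M
  si <- S[node, ]
  f <- t(matrix(P[cbind(si[col(Sj)], as.vector(Sj))],
                nrow = length(others)))
  node_problem(f, trace$payoffs[node, ], focal = node, column_map = others)
}

#' Contaminate a payoff series with observation noise
#'
#' Exactly `round(u/100 * length(y))` positions, chosen uniformly without
#' replacement, are perturbed by i.i.d. Gaussian noise with standard
#' deviation `sigma`. For a matrix, contamination is applied independently
#' to each row (each node's series).
#'
#' @param y Numeric vector or matrix of payoffs.
#' @param sigma Noise standard deviation (`>= 0`).
#' @param u Percentage of contaminated samples in `[0, 100]`.
#' @param seed Optional integer seed.
#' @return Object of the same shape as `y`.
#' @export
add_noise <- function(y, sigma, u, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (u < 0 || u > 100) stop("u must be a percentage in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(y)) {
    for (i in seq_len(nrow(y))) y[i, ] <- add_noise(y[i, ], sigma, u)
    return(y)
  }
  k <- round(u / 100 * length(y))
  if (k > 0) {
    pos <- sample.int(length(y), k)
    y[pos] <- y[pos] + rnorm(k, 0, sigma)
  }
  y
}
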