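# small deterministic fixtures shared across test files

cd_table <- function() payoff_table(c("C", "D"), b = 1.5, c = 1)

# a star graph: node 1 is the hub with `leaves` spokes
star_net <- function(leaves = 5) {
  igraph::graph_from_edgelist(cbind(1, 1 + seq_len(leaves)),
                              directed = FALSE)
}

# random binary recovery instance with a known planted solution
planted_instance <- function(n, m, values = c(-1, 0, 0.5, 1.5),
                             p_one = 0.4) {
  f <- matrix(sample(values, m * n, replace = TRUE), m, n)
  x <- rbinom(n, 1, p_one)
  list(p = node_problem(f, as.numeric(f %*% x)), x = x)
}

# exhaustive minimum-cardinality solver over all binary vectors
brute_force_l0 <- function(f, y, tol = 1e-6) {
  n <- ncol(f)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  feas <- apply(abs(f %*% t(grid) - y), 2, max) <= tol
  if (!any(feas)) return(NULL)
  sizes <- rowSums(grid)[feas]
  list(objective = min(sizes),
       x = grid[feas, , drop = FALSE][which.min(sizes), ])
}
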