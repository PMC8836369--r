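test_that("Fermi probability matches its closed form and symmetry", {
  expect_equal(fermi_probability(1, 1), 0.5)
  expect_equal(fermi_probability(0.23, 0, a = 0.1), 1 / (1 + exp(2.3)))
  expect_equal(fermi_probability(-10, 0, a = 0.1), 1, tolerance = 1e-12)
  expect_error(fermi_probability(1, 0, a = 0), "positive")

  set.seed(4)
  ui <- rnorm(50); uj <- rnorm(50)
  expect_equal(fermi_probability(ui, uj) + fermi_probability(uj, ui),
               rep(1, 50))
  # extreme gaps neither overflow nor leave [0, 1]
  p <- fermi_probability(c(-1e6, 1e6), 0, a = 0.1)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("per-round payoffs follow the pairwise score sum", {
  # hub playing D against 5 cooperating leaves earns 5 * b
  net <- star_net(5)
  tab <- cd_table()
  el <- igraph::as_edgelist(net, names = FALSE)
  s <- c(2L, rep(1L, 5))                  # levels are C = 1, D = 2
  u <- ccsnet:::round_payoffs(s, el[, 1], el[, 2], unclass(tab), 6)
  expect_equal(u[1], 5 * 1.5)
  expect_equal(u[-1], rep(-1, 5))         # each leaf loses c to the hub
})

test_that("simulated payoffs satisfy the linear observation identity", {
  for (s in 1:3) {
    net <- generate_network("scale_free", 40, 6, seed = s)
    tab <- payoff_table(c("C", "D", "WSLS", "ZD"), chi = 2)
    tr <- simulate_game(net, tab, rounds = 12, seed = s)
    a <- adjacency_matrix(net)
    for (i in c(1, 7, 40)) {
      p <- build_node_problem(tr, i)
      expect_equal(max(abs(p$f %*% a[i, -i] - p$y)), 0)
      expect_equal(dim(p$f), c(12L, 39L))
      expect_equal(p$column_map, setdiff(1:40, i))
    }
  }
})

test_that("two-strategy games freeze without reshuffling", {
  for (s in 1:3) {
    net <- generate_network("scale_free", 150, 6, seed = s)
    tr <- simulate_game(net, cd_table(), rounds = 12,
                        reshuffle_period = Inf, seed = s)
    changes <- colSums(tr$strategies[, -1, drop = FALSE] !=
                       tr$strategies[, -12, drop = FALSE])
    expect_true(all(changes[8:11] == 0))
  }
})

test_that("single-strategy populations give rank-one design matrices", {
  net <- generate_network("random", 20, 4, seed = 9)
  tr <- simulate_game(net, payoff_table("C"), rounds = 6, seed = 9)
  p <- build_node_problem(tr, 1)
  expect_true(all(p$f == p$f[1, 1]))
  expect_lte(qr(p$f)$rank, 1)
})

test_that("noise contamination hits exactly the requested count", {
  y <- rnorm(40)
  expect_identical(add_noise(y, sigma = 0.3, u = 0, seed = 1), y)
  expect_identical(add_noise(y, sigma = 0, u = 100, seed = 1), y)
  y2 <- add_noise(y, sigma = 0.3, u = 50, seed = 1)
  expect_equal(sum(y2 != y), 20)
  ym <- matrix(rnorm(80), 4)
  ym2 <- add_noise(ym, sigma = 0.5, u = 25, seed = 2)
  expect_equal(rowSums(ym2 != ym), rep(5, 4))
  expect_error(add_noise(y, -1, 10), "non-negative")
  expect_error(add_noise(y, 1, 150), "percentage")
})

test_that("uncoupled oscillators drift linearly at their natural rate", {
  g <- igraph::make_empty_graph(5, directed = FALSE)
  om <- c(-1, -0.5, 0, 0.5, 1)
  th0 <- rep(0, 5)
  tr <- simulate_kuramoto(g, omega = om, theta0 = th0, dt = 0.01,
                          n_samples = 20)
  expect_equal(tr$phases, outer(om, tr$sample_times), tolerance = 1e-10)
  expect_equal(tr$dtheta, matrix(om, 5, 20), tolerance = 1e-8)
})

test_that("two equal-frequency oscillators phase-lock", {
  g <- igraph::graph_from_edgelist(cbind(1, 2), directed = FALSE)
  tr <- simulate_kuramoto(g, omega = c(0.3, 0.3), theta0 = c(0, 1.5),
                          dt = 0.01, n_samples = 400)
  gap <- abs(tr$phases[1, ] - tr$phases[2, ])
  expect_lt(gap[400], 0.05)
  expect_true(all(diff(gap) < 1e-8))
})

test_that("Kuramoto regression system reproduces the coupling row", {
  g <- generate_network("random", 10, 4, seed = 5)
  a <- adjacency_matrix(g)
  tr <- simulate_kuramoto(g, dt = 0.001, n_samples = 60, seed = 5)
  worst <- max(vapply(1:10, function(i) {
    p <- build_kuramoto_problem(tr, i)
    max(abs(p$f %*% a[i, -i] - p$y))
  }, numeric(1)))
  expect_lt(worst, 1e-4)
  # exact model derivatives remove the finite-difference error entirely
  tre <- simulate_kuramoto(g, omega = tr$omega,
                           theta0 = NULL, dt = 0.001, n_samples = 60,
                           seed = 5, derivative = "exact")
  p <- build_kuramoto_problem(tre, 3)
  expect_lt(max(abs(p$f %*% a[3, -3] - p$y)), 1e-10)
})

test_that("game traces round-trip through delimited text", {
  net <- generate_network("random", 15, 4, seed = 2)
  tr <- simulate_game(net, payoff_table(c("C", "D", "TFT")), rounds = 5,
                      seed = 2)
  d <- tempfile()
  write_game_trace(tr, d)
  back <- read_game_trace(d)
  expect_equal(back$payoffs, tr$payoffs)
  expect_equal(strategy_matrix(back), strategy_matrix(tr))
  expect_equal(back$a, tr$a)
})
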