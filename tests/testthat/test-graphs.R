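test_that("generators hit the requested average degree", {
  g <- generate_network("scale_free", 500, 6, seed = 11)
  expect_true(abs(mean(igraph::degree(g)) - 6) < 0.3)
  expect_true(max(igraph::component_distribution(g) * 500) >= 475)

  g2 <- generate_network("random", 10, 9, seed = 1)
  expect_equal(igraph::ecount(g2), 45)        # complete graph forced

  g3 <- generate_network("small_world", 100, 6, seed = 2)
  expect_equal(mean(igraph::degree(g3)), 6, tolerance = 0.02)

  expect_error(generate_network("random", 20, 25), "infeasible")
  expect_error(generate_network("random", 5, 2), "at least 10")
})

test_that("hub structure separates scale-free from homogeneous models", {
  hub_ratio <- function(model, seed) {
    g <- generate_network(model, 300, 6, seed = seed)
    max(igraph::degree(g)) / mean(igraph::degree(g))
  }
  for (s in 1:5) {
    expect_gt(hub_ratio("scale_free", s), 3)
    expect_lt(hub_ratio("small_world", s), 3)
    expect_lt(hub_ratio("random", s), 3)
  }
})

test_that("small-world graphs stay connected at mild rewiring", {
  for (s in 1:20) {
    g <- generate_network("small_world", 100, 6, seed = s)
    expect_true(igraph::is_connected(g))
    expect_true(all(igraph::degree(g) >= 2))
  }
})

test_that("edge lists round-trip and normalize ids", {
  f <- tempfile()
  writeLines(c("0 1", "1 2"), f)
  g <- load_edgelist(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  # comma-delimited, 1-based
  writeLines(c("1,2", "2,3", "3,1"), f)
  g2 <- load_edgelist(f)
  expect_equal(igraph::ecount(g2), 3)

  g3 <- generate_network("scale_free", 100, 6, seed = 3)
  save_edgelist(g3, f)
  g4 <- load_edgelist(f)
  a3 <- adjacency_matrix(g3)
  expect_equal(adjacency_matrix(g4), a3)

  writeLines(c("1 2", "2 1", "3 3", "1 2"), f)
  expect_warning(expect_warning(g5 <- load_edgelist(f), "self-loop"),
                 "duplicate")
  expect_equal(igraph::ecount(g5), 1)

  writeLines(c("1 a"), f)
  expect_error(load_edgelist(f), "parse error")
})
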