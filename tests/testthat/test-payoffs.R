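test_that("payoff table reproduces the printed two-strategy scores", {
  tab <- payoff_table(c("C", "D"), b = 1.5, c = 1)
  expect_equal(tab["D", "C"], 1.5)
  expect_equal(tab["C", "D"], -1)
  expect_equal(tab["C", "C"], 0.5)
  expect_equal(tab["D", "D"], 0)

  single <- payoff_table("D", b = 2, c = 0.5)
  expect_equal(dim(single), c(1L, 1L))
  expect_equal(single["D", "D"], 0)

  cw <- payoff_table(c("C", "WSLS"), b = 1.5, c = 1)
  expect_equal(cw["WSLS", "C"], 1.0)      # (2b - c)/2
  expect_equal(cw["C", "WSLS"], -0.25)    # (b - 2c)/2
})

test_that("zero cells and parameter validation hold", {
  tab <- payoff_table(pd_strategies(), b = 1.5, c = 1, chi = 2)
  expect_equal(tab["D", "D"], 0)
  expect_equal(tab["D", "TFT"], 0)
  expect_equal(tab["D", "ZD"], 0)
  expect_equal(tab["ZD", "ZD"], 0)
  expect_equal(tab["TFT", "ZD"], 0)
  # reciprocal cooperation cells share b - c
  expect_equal(unname(tab["C", "C"]), unname(tab["C", "TFT"]))
  expect_equal(unname(tab["C", "C"]), unname(tab["TFT", "C"]))

  expect_error(payoff_table(c("C", "D"), b = 1, c = 1), "b > c")
  expect_error(payoff_table(c("C", "ZD"), chi = NULL), "chi")
  expect_error(payoff_table(c("C", "ZD"), chi = -1), "chi")
  expect_error(payoff_table(c("C", "Q")), "unknown")
})

test_that("ndp matches the printed distinct-value counts", {
  groups <- list(c("C", "TFT"), c("C", "D"), c("C", "WSLS"),
                 c("C", "D", "TFT"), c("C", "D", "WSLS"))
  expected <- c(2, 4, 3, 5, 8)
  got <- vapply(groups, function(g) ndp(payoff_table(g)), numeric(1))
  expect_equal(got, expected)
})

test_that("ndp is permutation invariant and monotone under set growth", {
  sets <- list(c("C", "D"), c("C", "D", "WSLS"), c("C", "TFT", "WSLS"),
               c("C", "D", "ZD", "WSLS"))
  for (s in sets) {
    perm <- sample(s)
    expect_equal(ndp(payoff_table(perm, chi = 2)),
                 ndp(payoff_table(s, chi = 2)))
  }
  supersets <- list(c("C", "D"), c("C", "D", "WSLS"),
                    c("C", "D", "WSLS", "TFT"),
                    c("C", "D", "WSLS", "TFT", "ZD"))
  nds <- vapply(supersets, function(s) ndp(payoff_table(s, chi = 2)),
                numeric(1))
  expect_true(all(diff(nds) >= 0))
})

test_that("modal element frequency behaves as a pooled percentage", {
  expect_equal(mf(matrix(0.5, 2, 2)), 100)
  expect_equal(mf(c(0.5, 0.5, 0.25, -1)), 50)
  expect_equal(mf(c(1, 2, 3, 4)), 25)
  # shape invariance for the same multiset
  v <- c(0.5, 0.5, 0.25, -1, 0, 0)
  expect_equal(mf(matrix(v, 2, 3)), mf(matrix(v, 3, 2)))
  expect_equal(mf(list(matrix(v[1:4], 2), v[5:6])), mf(v))
  expect_error(mf(numeric(0)), "at least one")
})

test_that("payoff tables export as readable delimited text", {
  tab <- payoff_table(c("C", "D", "WSLS"))
  path <- tempfile(fileext = ".csv")
  write_payoff_table(tab, path)
  back <- as.matrix(read.csv(path, row.names = 1))
  expect_equal(unname(back), unname(unclass(tab)[1:3, 1:3]),
               tolerance = 1e-12)
})
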