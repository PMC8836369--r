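test_that("confusion scoring follows the success-rate decomposition", {
  g <- generate_network("random", 20, 4, seed = 71)
  a <- adjacency_matrix(g)
  perfect <- score_reconstruction(a, g)
  expect_equal(perfect$sr, 1)
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$aupr, 1)

  # hand-built confusion: TP=3, FN=1, TN=5, FP=1 over 10 pairs (5 nodes)
  tru <- matrix(0, 5, 5)
  tru[1, 2] <- tru[1, 3] <- tru[1, 4] <- tru[2, 3] <- 1
  tru <- tru + t(tru)
  est <- matrix(0, 5, 5)
  est[1, 2] <- est[1, 3] <- est[2, 3] <- 1   # 3 true positives
  est[4, 5] <- 1                             # 1 false positive
  est <- est + t(est)
  sc <- score_reconstruction(est, tru)
  expect_equal(unlist(sc[c("tp", "fp", "tn", "fn")]),
               c(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(sc$srel, 0.75)
  expect_equal(sc$srnc, 5 / 6)
  expect_equal(sc$sr, 0.625)

  empty <- score_reconstruction(matrix(0, 5, 5), tru)
  expect_equal(empty$sr, 0)

  none <- score_reconstruction(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_true(is.na(none$srel))
})

test_that("sr factorizes exactly and is permutation invariant", {
  set.seed(72)
  for (rep in 1:10) {
    n <- 12
    tru <- matrix(rbinom(n^2, 1, 0.2), n); tru <- 1 * ((tru + t(tru)) > 0)
    diag(tru) <- 0
    est <- matrix(rbinom(n^2, 1, 0.2), n); est <- 1 * ((est + t(est)) > 0)
    diag(est) <- 0
    sc <- score_reconstruction(est, tru)
    if (!is.na(sc$sr)) expect_equal(sc$sr, sc$srel * sc$srnc)
    perm <- sample(n)
    sc2 <- score_reconstruction(est[perm, perm], tru[perm, perm])
    expect_equal(sc2$sr, sc$sr)
  }
})

test_that("ranking metrics behave on known toy cases", {
  # AP for labels (1,0,1,0) ranked by score: 0.5 * 1 + 0.5 * 2/3
  expect_equal(ccsnet:::average_precision(c(1, 0, 1, 0),
                                          c(0.9, 0.8, 0.7, 0.6)),
               0.5 + 0.5 * 2 / 3)
  expect_equal(ccsnet:::auroc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)),
               0.75)
  set.seed(73)
  lab <- rep(c(0, 1), 100)
  expect_equal(ccsnet:::auroc_score(lab, runif(200)), 0.5, tolerance = 0.12)
})

test_that("per-node success rates use each node's candidate row", {
  tru <- matrix(0, 4, 4)
  tru[1, 2] <- tru[2, 1] <- 1
  est <- matrix(0, 4, 4)                   # all-zero estimate
  pn <- per_node_success(est, tru)
  expect_equal(pn$sr, c(0, 0, 1, 1))       # isolated nodes score 1
})

test_that("completely-correct frequencies and the minimum failing degree", {
  runs <- rbind(rep(TRUE, 3), c(TRUE, TRUE, FALSE), rep(TRUE, 3),
                c(TRUE, FALSE, FALSE))
  nf <- node_frequencies(runs, degrees = c(2, 5, 16))
  expect_equal(nf$freq$fr, c(1, 0.75, 0.5))
  expect_equal(nf$md, 5)

  perfect <- node_frequencies(matrix(TRUE, 5, 3), degrees = c(1, 2, 3))
  expect_equal(perfect$md, Inf)

  # worked example: perfect in 9 of 10 runs
  one <- node_frequencies(matrix(c(rep(TRUE, 9), FALSE)), degrees = 4)
  expect_equal(one$freq$fr, 0.9)

  # adding a failed run can only lower fr; a perfect run can only raise it
  fr0 <- node_frequencies(runs, c(2, 5, 16))$freq$fr
  fr_bad <- node_frequencies(rbind(runs, FALSE), c(2, 5, 16))$freq$fr
  fr_good <- node_frequencies(rbind(runs, TRUE), c(2, 5, 16))$freq$fr
  expect_true(all(fr_bad <= fr0))
  expect_true(all(fr_good >= fr0))
})

test_that("diversity regression reproduces the reference coefficients", {
  fit <- diversity_analysis(diversity_benchmark())
  td <- tidy(fit)
  expect_equal(round(td$estimate[td$term == "(Intercept)"], 3), 0.995)
  expect_equal(round(td$estimate[td$term == "ndp"], 3), 0.030)
  expect_equal(round(td$estimate[td$term == "mf"], 3), -0.010)
  expect_equal(round(td$std_estimate[td$term == "ndp"], 3), 0.382)
  expect_equal(round(td$std_estimate[td$term == "mf"], 3), -0.711)
  expect_equal(round(glance(fit)$r.squared, 3), 0.933)
  expect_equal(round(td$statistic, 3), c(7.151, 2.815, -5.237))
})

test_that("standardized coefficients equal a z-scored refit", {
  df <- diversity_benchmark()
  fit <- diversity_analysis(df)
  zfit <- lm(scale(sr) ~ scale(ndp) + scale(mf), data = df)
  expect_equal(tidy(fit)$std_estimate[-1], unname(coef(zfit)[-1]),
               tolerance = 1e-10)
})

test_that("a response linear in one predictor yields a clean fit", {
  df <- tibble::tibble(ndp = c(2, 4, 6, 8, 10, 12),
                       mf = c(30, 70, 45, 60, 25, 50),
                       sr = 0.05 + 0.07 * c(2, 4, 6, 8, 10, 12))
  # lm's summary warns about an essentially perfect fit, by construction
  fit <- suppressWarnings(diversity_analysis(df))
  expect_equal(glance(fit)$r.squared, 1)
  expect_equal(unname(coef(fit$fit)["mf"]), 0, tolerance = 1e-12)
  expect_error(diversity_analysis(df[1:2, ]), "at least 3")
})
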