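test_that("node problems validate their shapes", {
  f <- matrix(1, 3, 4)
  expect_error(node_problem(f, 1:2), "nrow")
  expect_error(node_problem(f, 1:3, column_map = 1:3), "column_map")
  p <- node_problem(f, c(4, 4, 4))
  expect_s3_class(p, "node_problem")
})

test_that("exact 0-1 recovery solves the worked examples", {
  f <- diag(3)
  r <- solve_ics(node_problem(f, c(1, 0, 1)))
  expect_equal(r$estimate, c(1, 0, 1))
  expect_equal(r$status, "optimal")
  expect_true(r$binary)

  # zero observations with positive achievable payoffs: empty neighborhood
  f2 <- matrix(c(1, 0.5, 0, 1.5, 1, 1), 2, 3)
  r2 <- solve_ics(node_problem(f2, c(0, 0)))
  expect_equal(r2$estimate, c(0, 0, 0))
  expect_equal(r2$objective, 0)
})

test_that("exact 0-1 recovery equals exhaustive search on small problems", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    inst <- planted_instance(n, sample(3:6, 1))
    r <- solve_ics(inst$p)
    bf <- brute_force_l0(inst$p$f, inst$p$y)
    expect_equal(r$status, "optimal")
    expect_equal(sum(r$estimate), bf$objective)
    expect_lte(max(abs(inst$p$f %*% r$estimate - inst$p$y)), 1e-6)
  }
})

test_that("infeasible 0-1 systems are reported as such", {
  f <- matrix(c(1, 1), 1, 2)          # max achievable is 2
  r <- solve_ics(node_problem(f, 5))
  expect_equal(r$status, "infeasible")
  expect_length(r$estimate, 0)
})

test_that("concave-quadratic recovery lands on binary vertices", {
  set.seed(31)
  for (rep in 1:10) {
    inst <- planted_instance(8, 12)    # overdetermined, full rank a.s.
    r <- solve_qcs(inst$p, seed = rep)
    expect_equal(r$status, "optimal")
    expect_lt(r$objective, 1e-9)
    expect_equal(r$estimate, inst$x, tolerance = 1e-6)
  }
})

test_that("the concave objective is monotone along the linearization path", {
  set.seed(12)
  inst <- planted_instance(10, 6)
  r <- solve_qcs(inst$p, restarts = 1, start = rep(0.5, 10), seed = 1)
  expect_true(all(diff(r$objective_trace) <= 1e-12))
})

test_that("zero QCS objective certifies a binary feasible point", {
  set.seed(55)
  for (rep in 1:15) {
    inst <- planted_instance(sample(6:12, 1), sample(4:10, 1))
    r <- solve_qcs(inst$p, seed = rep)
    if (r$status == "optimal") {
      expect_true(all(abs(r$estimate - round(r$estimate)) < 1e-6))
      expect_lte(max(abs(inst$p$f %*% r$estimate - inst$p$y)), 2e-6)
    }
  }
})

test_that("L1 recovery matches an independent LP oracle", {
  set.seed(21)
  checked <- 0
  for (rep in 1:10) {
    m <- sample(3:5, 1); n <- sample(4:7, 1)
    f <- matrix(rnorm(m * n), m)
    x0 <- rbinom(n, 1, 0.3)
    y <- as.numeric(f %*% x0)
    ours <- solve_cs(node_problem(f, y), tol = 1e-9)
    # pracma solves min 1'x s.t. equality constraints, x >= 0
    orc <- pracma::linprog(rep(1, n), Aeq = f, beq = y, maxiter = 500)
    if (orc$errno == 1 && is.finite(orc$fval)) {
      checked <- checked + 1
      expect_equal(sum(ours$estimate), orc$fval, tolerance = 1e-5)
    }
  }
  expect_gte(checked, 5)
})

test_that("L1 recovery is exact for 1-sparse truths and fails densely", {
  set.seed(8)
  f <- matrix(rnorm(8), 2, 4)
  x1 <- c(0, 1, 0, 0)
  r <- solve_cs(node_problem(f, as.numeric(f %*% x1)), tol = 1e-9)
  expect_equal(r$estimate, x1, tolerance = 1e-5)

  r0 <- solve_cs(node_problem(f, c(0, 0)))
  expect_equal(r0$estimate, rep(0, 4))

  # dense truth from 2 equations: the L1 minimizer is sparser than truth
  x3 <- c(1, 1, 1, 0)
  f2 <- matrix(rnorm(8), 2, 4)
  r3 <- solve_cs(node_problem(f2, as.numeric(f2 %*% x3)))
  expect_lt(sum(r3$estimate), 3 - 1e-6)
})

test_that("non-negative LASSO tracks its penalty limits", {
  set.seed(10)
  f <- matrix(rnorm(200), 20, 10)
  x0 <- c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0)
  y <- as.numeric(f %*% x0)
  lo <- solve_lasso(node_problem(f, y), lambda_grid = 1e-6)
  expect_equal(lo$estimate, x0, tolerance = 1e-3)
  hi <- solve_lasso(node_problem(f, y), lambda_grid = 1e4)
  expect_equal(hi$estimate, rep(0, 10))
  expect_equal(solve_lasso(node_problem(matrix(0, 4, 3), rep(0, 4)))$status,
               "infeasible")
})

test_that("LASSO at a fixed penalty matches a proximal-gradient oracle", {
  set.seed(14)
  m <- 15; n <- 8
  f <- matrix(rnorm(m * n), m)
  y <- as.numeric(f %*% rbinom(n, 1, 0.4) + rnorm(m, 0, 0.05))
  lam <- 0.05
  # independent solver: projected proximal gradient on the glmnet objective
  # (1/(2m)) ||y - f x||^2 + lam * sum(x), x >= 0
  x <- rep(0, n)
  step <- 1 / (2 * max(eigen(crossprod(f) / m)$values))
  for (it in 1:20000) {
    grad <- -crossprod(f, y - f %*% x) / m
    x <- pmax(x - step * (as.numeric(grad) + lam), 0)
  }
  ours <- solve_lasso(node_problem(f, y), lambda_grid = lam)
  expect_equal(ours$estimate, x, tolerance = 1e-4)
})

test_that("gap-rule binarization cuts at the largest relative drop", {
  expect_equal(threshold_cut(c(0.98, 0.95, 0.03, 0.01)), c(1, 1, 0, 0))
  # idempotent on binary vectors
  expect_equal(threshold_cut(c(1, 0, 1)), c(1, 0, 1))
  expect_equal(threshold_cut(c(0, 1, 0, 0)), c(0, 1, 0, 0))
  # direct evaluation of the gap scores: g1 = 1.5 * 0.3, g2 = 2 * 0.3
  expect_equal(threshold_cut(c(0.9, 0.6, 0.3)), c(1, 1, 0))
  # product form prefers the cut between large values
  expect_equal(threshold_cut(c(0.9, 0.6, 0.3), form = "product"),
               c(1, 0, 0))
  # degenerate all-equal rules
  expect_equal(threshold_cut(c(0.8, 0.8, 0.8)), c(1, 1, 1))
  expect_equal(threshold_cut(c(0.2, 0.2)), c(0, 0))
  expect_error(threshold_cut(0.5), "at least 2")
})

test_that("binarization keeps order: selected values dominate rejected", {
  set.seed(3)
  for (rep in 1:20) {
    v <- runif(sample(3:12, 1))
    b <- threshold_cut(v)
    if (any(b == 1) && any(b == 0))
      expect_gte(min(v[b == 1]), max(v[b == 0]))
  }
})
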