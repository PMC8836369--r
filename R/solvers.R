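#' Per-node linear recovery problem
#'
#' Container for the linear system `y = F x` of one focal node: `F` holds
#' the pairwise scores against every candidate neighbour in each observed
#' round, `y` the focal node's accumulated payoffs, and `column_map` the
#' node id behind each column.
#'
#' @param f Numeric `M x p` score matrix.
#' @param y Numeric payoff vector of length `M`.
#' @param focal Focal node id (informational).
#' @param column_map Integer vector mapping columns of `f` to node ids.
#' @return A `node_problem` object.
#' @export
node_problem <- function(f, y, focal = NA_integer_,
                         column_map = seq_len(ncol(f))) {
  f <- as.matrix(f)
  y <- as.numeric(y)
  if (nrow(f) != length(y)) stop("nrow(f) must equal length(y)")
  if (ncol(f) != length(column_map))
    stop("column_map must have one entry per column of f")
  structure(list(f = f, y = y, focal = focal,
                 column_map = as.integer(column_map)),
            class = "node_problem")
}

#' @export
print.node_problem <- function(x, ...) {
  cat("Node problem: ", nrow(x$f), " observations x ", ncol(x$f),
      " candidate neighbours (focal node ", x$focal, ")\n", sep = "")
  invisible(x)
}

solver_result <- function(estimate, binary, status, iterations,
                          objective = NA_real_, solver,
                          objective_trace = NULL) {
  structure(list(estimate = estimate, binary = binary, status = status,
                 iterations = iterations, objective = objective,
                 solver = solver, objective_trace = objective_trace),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(x$solver, " result: status ", x$status, ", ",
      length(x$estimate), " estimates",
      if (!is.na(x$objective)) paste0(", objective ",
                                      signif(x$objective, 6)) else "",
      "\n", sep = "")
  invisible(x)
}

# equality-form data of the feasibility band |F x - y|_inf <= tol:
# [F | I] [x; s] = y + tol, 0 <= s <= 2 tol, with x bounds supplied
band_polytope <- function(p, tol, x_ub) {
  m <- nrow(p$f); n <- ncol(p$f)
  list(A = cbind(p$f, diag(m)),
       b = p$y + tol,
       lb = rep(0, n + m),
       ub = c(rep(x_ub, n), rep(2 * tol, m)),
       n = n, m = m)
}

lp_over_band <- function(pol, cost_x, max_iter = 20000) {
  lp_bounded_cpp(c(cost_x, rep(0, pol$m)), pol$A, pol$b, pol$lb, pol$ub,
                 max_iter)
}

#' Exact 0-1 sparse recovery (integer program)
#'
#' Solves `min sum(x)` over binary `x` subject to
#' `|F x - y|_inf <= tol` by branch-and-bound on the LP relaxation (for
#' binary `x` the cardinality equals the L0 norm, so the 0-1 program is an
#' exact minimum-link formulation). Needs no decision threshold: the output
#' is already binary. Exploration is capped; a node whose search exceeds
#' `iteration_cap` explored branch-and-bound nodes is reported with status
#' `"iteration_cap"` and an empty estimate, and downstream scoring treats
#' it as a reconstruction failure.
#'
#' On large instances the search proceeds by increasing candidate
#' cardinality; when a feasible binary solution is found but some smaller
#' cardinality could not be exhaustively refuted within its search budget,
#' the solution is returned with status `"local"` (a certified-feasible,
#' possibly non-minimal recovery). Small instances are always fully
#' certified.
#'
#' @param p A [node_problem()].
#' @param iteration_cap Maximum explored branch-and-bound nodes.
#' @param tol Feasibility tolerance on the residual (infinity norm). Use
#'   roughly `3 * sigma` for noisy observations.
#' @return A `solver_result` with a binary `estimate` and status one of
#'   `"optimal"`, `"infeasible"`, `"iteration_cap"`.
#' @examples
#' f <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3)
#' solve_ics(node_problem(f, c(1, 0, 1)))$estimate
#' @export
solve_ics <- function(p, iteration_cap = 1e6, tol = 1e-6) {
  r <- ics_branch_bound_cpp(p$f, p$y, tol, node_cap = iteration_cap)
  status <- c("optimal", "infeasible", "iteration_cap", "local")[r$status + 1]
  est <- if (status %in% c("optimal", "local")) as.numeric(r$x) else
    numeric(0)
  solver_result(est, binary = TRUE, status = status,
                iterations = r$nodes,
                objective = if (length(est)) r$objective else NA_real_,
                solver = "ICS")
}

#' Concave-quadratic sparse recovery
#'
#' Minimizes `sum(x * (1 - x))` over the polytope
#' `{|F x - y|_inf <= tol, 0 <= x <= 1}`. The objective is concave, so its
#' minima sit at polytope vertices; it is driven there by successive
#' linearization (Frank-Wolfe style): from the current point, the linear
#' objective `(1 - 2 x)` is minimized over the polytope with the simplex
#' method, which yields a vertex that can only improve the concave
#' objective, until the vertex stabilizes. Several randomized starts are
#' taken and the best vertex kept. A zero objective certifies a binary
#' feasible point.
#'
#' @param p A [node_problem()].
#' @param restarts Number of random linearization starts.
#' @param tol Feasibility tolerance on the residual.
#' @param start Optional explicit first linearization point in `[0, 1]^p`.
#' @param max_steps Cap on linearization steps per start.
#' @param seed Optional integer seed for the random starts.
#' @return A `solver_result` with a fractional `estimate` in `[0, 1]`,
#'   `objective` (the concavity gap), and the per-step `objective_trace`
#'   of the best start. Status is `"optimal"` when the objective is
#'   numerically zero, `"local"` otherwise.
#' @export
solve_qcs <- function(p, restarts = 5, tol = 1e-6, start = NULL,
                      max_steps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pol <- band_polytope(p, tol, x_ub = 1)
  n <- pol$n
  feas <- lp_over_band(pol, rep(0, n))
  if (feas$status == 1)
    return(solver_result(numeric(0), FALSE, "infeasible", 0L,
                         solver = "QCS"))
  qobj <- function(x) sum(x * (1 - x))

  best <- NULL
  total_steps <- 0L
  for (r in seq_len(restarts)) {
    x <- if (r == 1 && !is.null(start)) start else runif(n)
    trace <- c()
    cur_obj <- Inf
    for (step in seq_len(max_steps)) {
      total_steps <- total_steps + 1L
      lp <- lp_over_band(pol, 1 - 2 * x)
      if (lp$status != 0) break
      v <- lp$x[seq_len(n)]
      ov <- qobj(v)
      trace <- c(trace, ov)
      if (ov < cur_obj - 1e-12) {
        x <- v
        cur_obj <- ov
      } else break
      if (cur_obj <= 1e-12) break
    }
    if (is.finite(cur_obj) &&
        (is.null(best) || cur_obj < best$objective - 1e-12)) {
      best <- list(x = x, objective = cur_obj, trace = trace)
    }
    if (!is.null(best) && best$objective <= 1e-12) break
  }
  if (is.null(best))
    return(solver_result(numeric(0), FALSE, "infeasible", total_steps,
                         solver = "QCS"))
  est <- pmin(pmax(best$x, 0), 1)
  solver_result(est, binary = FALSE,
                status = if (best$objective <= 1e-9) "optimal" else "local",
                iterations = total_steps, objective = best$objective,
                solver = "QCS", objective_trace = best$trace)
}

#' L1 sparse recovery (basis pursuit)
#'
#' Minimizes `sum(x)` over `x >= 0` subject to `|F x - y|_inf <= tol`
#' (with non-negative `x` the L1 norm is the plain sum), solved as a
#' linear program. Non-negativity reflects the 0/1 ground truth. The
#' output is fractional and is typically binarized with
#' [threshold_cut()].
#'
#' @param p A [node_problem()].
#' @param tol Feasibility tolerance on the residual.
#' @return A `solver_result` with fractional `estimate`.
#' @export
solve_cs <- function(p, tol = 1e-6) {
  pol <- band_polytope(p, tol, x_ub = 1e6)
  lp <- lp_over_band(pol, rep(1, pol$n))
  status <- switch(as.character(lp$status), "0" = "optimal",
                   "1" = "infeasible", "2" = "infeasible", "iteration_cap")
  est <- if (status == "optimal") pmax(lp$x[seq_len(pol$n)], 0) else
    numeric(0)
  solver_result(est, binary = FALSE, status = status,
                iterations = lp$iterations,
                objective = if (status == "optimal") lp$objective else
                  NA_real_,
                solver = "CS")
}

#' Non-negative LASSO recovery
#'
#' Minimizes `||y - F x||^2 / (2 M) + lambda * sum(x)` over `x >= 0`, with
#' `lambda` chosen by k-fold cross-validation over `lambda_grid`
#' (via [glmnet::cv.glmnet()], no intercept, no standardization).
#'
#' @param p A [node_problem()].
#' @param lambda_grid Candidate penalty values.
#' @param nfolds Cross-validation folds (reduced automatically for very
#'   short series).
#' @param seed Optional integer seed for the fold assignment.
#' @return A `solver_result` with fractional `estimate`.
#' @export
solve_lasso <- function(p, lambda_grid = 10^seq(0, -4, length.out = 30),
                        nfolds = 5, seed = NULL) {
  if (all(p$f == 0))
    return(solver_result(numeric(0), FALSE, "infeasible", 0L,
                         solver = "LASSO"))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(p$f)
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  if (length(lambda_grid) == 1) {
    # glmnet wants a path: pad above, then read off the requested penalty
    fit <- glmnet::glmnet(p$f, p$y,
                          lambda = c(lambda_grid * c(100, 10), lambda_grid),
                          lower.limits = 0, intercept = FALSE,
                          standardize = FALSE)
    est <- as.numeric(coef(fit, s = lambda_grid, exact = TRUE, x = p$f,
                           y = p$y))[-1]
    return(solver_result(pmax(est, 0), binary = FALSE, status = "optimal",
                         iterations = as.integer(fit$npasses),
                         objective = lambda_grid, solver = "LASSO"))
  }
  if (m >= 6) {
    cv <- glmnet::cv.glmnet(p$f, p$y, lambda = lambda_grid,
                            lower.limits = 0, intercept = FALSE,
                            standardize = FALSE,
                            nfolds = min(nfolds, floor(m / 2)),
                            grouped = FALSE)
    lam <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # too few rows to cross-validate: take the weakest penalty on the grid
    fit <- glmnet::glmnet(p$f, p$y, lambda = lambda_grid, lower.limits = 0,
                          intercept = FALSE, standardize = FALSE)
    lam <- min(lambda_grid)
  }
  est <- as.numeric(coef(fit, s = lam))[-1]
  solver_result(pmax(est, 0), binary = FALSE, status = "optimal",
                iterations = as.integer(fit$npasses),
                objective = lam, solver = "LASSO")
}

#' Binarize fractional link estimates by the largest relative gap
#'
#' Sorts the estimates in decreasing order `k_1 >= k_2 >= ...` and cuts the
#' ranking where the gap score `g_j = (k_j / k_(j+1)) * (k_j - k_(j+1))`
#' (ratio form, the default) or `g_j = k_j * k_(j+1) * (k_j - k_(j+1))`
#' (product form) is maximal; entries ranked at or above the cut become 1.
#' Values at or below `eps` end the ranked list, and the break from the
#' positive prefix into numerical zero counts as an infinitely large gap,
#' which makes the rule idempotent on binary input. When all values are
#' equal the degenerate rule applies: all ones if the common value exceeds
#' 0.5, all zeros otherwise.
#'
#' @param values Numeric vector of fractional estimates (length `>= 2`).
#' @param eps Numerical-zero threshold.
#' @param form `"ratio"` (default) or `"product"` gap score.
#' @return Binary vector in the original order.
#' @examples
#' threshold_cut(c(0.98, 0.95, 0.03, 0.01))   # 1 1 0 0
#' @export
threshold_cut <- function(values, eps = 1e-8, form = c("ratio", "product")) {
  form <- match.arg(form)
  if (length(values) < 2) stop("at least 2 values are required")
  v <- pmax(values, 0)
  if (diff(range(v)) <= 1e-12)
    return(rep(if (v[1] > 0.5) 1 else 0, length(v)))
  o <- order(v, decreasing = TRUE)
  k <- v[o]
  L <- sum(k > eps)
  if (L == 0) return(rep(0, length(v)))
  cand <- seq_len(min(L, length(v) - 1))
  g <- vapply(cand, function(j) {
    if (j == L && L < length(v)) return(Inf)  # clean break to zero
    if (form == "ratio") (k[j] / k[j + 1]) * (k[j] - k[j + 1])
    else k[j] * k[j + 1] * (k[j] - k[j + 1])
  }, numeric(1))
  cut <- cand[which.max(g)]
  out <- numeric(length(v))
  out[o[seq_len(cut)]] <- 1
  out
}
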