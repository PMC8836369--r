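#' Simulate coupled Kuramoto oscillators on a network
#'
#' Integrates the phase dynamics
#' `dtheta_i/dt = omega_i + sum_j a_ij sin(theta_j - theta_i)`
#' with a fixed-step 4th-order Runge-Kutta scheme and records phases at the
#' sampling interval `dt`. Phase derivatives at the sample times are
#' estimated by central finite differences (error `O(dt^2)`), or taken from
#' the model right-hand side exactly when `derivative = "exact"` (useful as
#' an integration-accuracy oracle).
#'
#' Natural frequencies default to i.i.d. uniform draws on `[-1, 1]` and
#' initial phases to uniform on `[0, 2*pi)`.
#'
#' @param net An [igraph::igraph].
#' @param omega Optional numeric vector of natural frequencies.
#' @param theta0 Optional numeric vector of initial phases.
#' @param dt Sampling (and integration) step, `> 0`.
#' @param n_samples Number of recorded sample times.
#' @param seed Optional integer seed.
#' @param derivative `"central"` (default) or `"exact"`.
#' @return A `kuramoto_trace`: phases (`N x n_samples`), derivative
#'   estimates `dtheta`, `omega`, `sample_times`, `dt` and the network.
#' @examples
#' g <- generate_network("random", 10, 4, seed = 1)
#' tr <- simulate_kuramoto(g, dt = 0.01, n_samples = 50, seed = 1)
#' @export
simulate_kuramoto <- function(net, omega = NULL, theta0 = NULL, dt = 0.01,
                              n_samples = 100, seed = NULL,
                              derivative = c("central", "exact")) {
  derivative <- match.arg(derivative)
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net)
  if (is.null(omega)) omega <- runif(n, -1, 1)
  if (is.null(theta0)) theta0 <- runif(n, 0, 2 * pi)
  A <- adjacency_matrix(net)

  rhs <- function(t, th, parms) {
    st <- sin(th); ct <- cos(th)
    list(omega + ct * as.vector(A %*% st) - st * as.vector(A %*% ct))
  }
  times <- seq(0, by = dt, length.out = n_samples + 2)
  out <- deSolve::rk4(theta0, times, rhs, parms = NULL)
  theta <- unname(t(out[, -1, drop = FALSE]))  # N x (n_samples + 2)

  keep <- 2:(n_samples + 1)
  phases <- theta[, keep, drop = FALSE]
  dth <- if (derivative == "central") {
    (theta[, keep + 1, drop = FALSE] - theta[, keep - 1, drop = FALSE]) /
      (2 * dt)
  } else {
    vapply(keep, function(k) unlist(rhs(0, theta[, k], NULL)), numeric(n))
  }
  structure(list(phases = phases, dtheta = dth, omega = omega,
                 sample_times = times[keep], dt = dt, network = net,
                 derivative = derivative),
            class = "kuramoto_trace")
}

#' @export
print.kuramoto_trace <- function(x, ...) {
  cat("Kuramoto trace: ", nrow(x$phases), " oscillators x ",
      ncol(x$phases), " samples (dt = ", x$dt, ")\n", sep = "")
  invisible(x)
}

#' Per-node recovery problem from a Kuramoto trace
#'
#' With the natural frequency known, `y_i(t) = dtheta_i(t) - omega_i` is
#' linear in the incidence row of node `i`:
#' `y_i = F x` with `F[t, j] = sin(theta_j(t) - theta_i(t))`.
#'
#' @param trace A `kuramoto_trace`.
#' @param node Focal node id.
#' @return A [node_problem()].
#' @export
build_kuramoto_problem <- function(trace, node) {
  n <- nrow(trace$phases)
  if (node < 1 || node > n) stop("node out of range")
  others <- setdiff(seq_len(n), node)
  f <- t(sin(trace$phases[others, , drop = FALSE] -
             matrix(trace$phases[node, ], length(others),
                    ncol(trace$phases), byrow = TRUE)))
  node_problem(f, trace$dtheta[node, ] - trace$omega[node],
               focal = node, column_map = others)
}
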