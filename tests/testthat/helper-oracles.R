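# Independent oracles used across the test suite.  These deliberately do
# not reuse the package's integrators or filters.

# Plain fixed-step RK4 integration of a single trajectory, written directly
# against the system's rhs.
oracle_rk4 <- function(system, x0, lambda, t0, t_end, h = 1e-3) {
  x <- as.numeric(x0)
  t <- t0
  nstep <- round((t_end - t0) / h)
  for (i in seq_len(nstep)) {
    k1 <- system$rhs(t, x, lambda)
    k2 <- system$rhs(t + h / 2, x + h / 2 * k1, lambda)
    k3 <- system$rhs(t + h / 2, x + h / 2 * k2, lambda)
    k4 <- system$rhs(t + h, x + h * k3, lambda)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  x
}

# Brute-force Bayesian filter for the scalar random-walk state model on a
# dense state grid.  Returns the filtered posterior mean at each time.
oracle_grid_filter <- function(obs, R, Q, init_mean, init_var,
                               lo, hi, ngrid = 2001) {
  xs <- seq(lo, hi, length.out = ngrid)
  dx <- xs[2] - xs[1]
  dens <- stats::dnorm(xs, init_mean, sqrt(init_var))
  K <- NULL
  if (Q > 0) {
    K <- outer(xs, xs, function(a, b) stats::dnorm(a - b, 0, sqrt(Q)))
  }
  means <- numeric(length(obs))
  for (t in seq_along(obs)) {
    if (t > 1 && !is.null(K)) dens <- as.vector(K %*% dens) * dx
    dens <- dens * stats::dnorm(obs[t], xs, sqrt(R[t]))
    dens <- dens / (sum(dens) * dx)
    means[t] <- sum(xs * dens) * dx
  }
  means
}

# Small cached fixtures (computed once per test run)
ts_env <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$sys)) {
      cache$sys <- toggle_switch(env = TRUE)
      cache$grid <- time_grid(0, 50, 1)
      cache$sens <- sensitivities_variational(cache$sys, c(0, 0),
                                              c(0, 0, 0), cache$grid)
    }
    cache
  }
})
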