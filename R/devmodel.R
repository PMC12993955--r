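#' Define a developmental dynamical system
#'
#' A developmental model is an autonomous-in-form ODE system
#' \eqn{\dot x = f(t, x, \lambda)} whose state \eqn{x \in R^n} collects the
#' phenotypic variables (e.g. gene expression levels) and whose parameter
#' vector \eqn{\lambda \in R^p} collects the developmental parameters of
#' genetic or environmental origin.
#'
#' @param n_states number of state variables (traits).
#' @param n_params number of developmental parameters.
#' @param rhs function `(t, x, lambda)` returning the derivative vector of
#'   length `n_states`.
#' @param jac_x optional function `(t, x, lambda)` returning the
#'   `n_states x n_states` Jacobian of `rhs` with respect to the state.
#'   When `NULL`, central finite differences of `rhs` are used.
#' @param jac_lambda optional function `(t, x, lambda)` returning the
#'   `n_states x n_params` matrix of partial derivatives of `rhs` with
#'   respect to each parameter (column k is the forcing vector of the
#'   variational equation for parameter k).  When `NULL`, central finite
#'   differences are used.
#' @param rhs_pop optional vectorised version of `rhs` taking an
#'   `M x n_states` state matrix and an `M x n_params` parameter matrix and
#'   returning an `M x n_states` derivative matrix; used by the fast
#'   population integrator.  When `NULL`, populations fall back to a
#'   row-by-row loop over `rhs`.
#' @param name identifier for the model.
#'
#' @return An object of class `ode_system`.
#' @export
ode_system <- function(n_states, n_params, rhs, jac_x = NULL,
                       jac_lambda = NULL, rhs_pop = NULL,
                       name = "ode_system") {
  stopifnot(n_states >= 1, n_params >= 1, is.function(rhs))
  structure(list(n_states = as.integer(n_states),
                 n_params = as.integer(n_params),
                 rhs = rhs, jac_x = jac_x, jac_lambda = jac_lambda,
                 rhs_pop = rhs_pop, name = name),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system> ", x$name, ": ", x$n_states, " states, ",
      x$n_params, " parameters\n", sep = "")
  invisible(x)
}

#' Evaluate the state Jacobian of a system
#'
#' Returns the analytic Jacobian when the system provides one, otherwise a
#' central finite-difference approximation.
#'
#' @param system an [ode_system()].
#' @param t,x,lambda evaluation point.
#' @param h finite-difference step (used only for the numeric fallback).
#' @return `n x n` matrix.
#' @export
system_jac_x <- function(system, t, x, lambda, h = 1e-6) {
  if (!is.null(system$jac_x)) return(system$jac_x(t, x, lambda))
  n <- system$n_states
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- xp[j] + hj; xm[j] <- xm[j] - hj
    J[, j] <- (system$rhs(t, xp, lambda) - system$rhs(t, xm, lambda)) / (2 * hj)
  }
  J
}

#' Evaluate the parameter Jacobian of a system
#'
#' Column k is the direct dependence of the right-hand side on parameter k,
#' i.e. the forcing term of the variational (sensitivity) equation.
#'
#' @inheritParams system_jac_x
#' @return `n x p` matrix.
#' @export
system_jac_lambda <- function(system, t, x, lambda, h = 1e-6) {
  if (!is.null(system$jac_lambda)) return(system$jac_lambda(t, x, lambda))
  p <- system$n_params
  B <- matrix(0, system$n_states, p)
  for (k in seq_len(p)) {
    hk <- h * max(1, abs(lambda[k]))
    lp <- lambda; lm <- lambda
    lp[k] <- lp[k] + hk; lm[k] <- lm[k] - hk
    B[, k] <- (system$rhs(t, x, lp) - system$rhs(t, x, lm)) / (2 * hk)
  }
  B
}

#' Two-gene toggle-switch developmental model
#'
#' Mutually repressive two-gene circuit, a minimal model of cell-fate
#' determination.  Gene 1 expression \eqn{x_1} and gene 2 expression
#' \eqn{x_2} obey
#' \deqn{\dot x_1 = (2+\lambda_1)/(1+x_2^2)^2 - 0.4\,x_1}
#' \deqn{\dot x_2 = (2+\lambda_2)/(1+x_1^3 + \lambda_3)^2 - 0.4\,x_2}
#' where \eqn{\lambda_1,\lambda_2} modulate the regulatory input each gene
#' receives (genetically determined in the population scenarios) and
#' \eqn{\lambda_3} shifts the repression of gene 2 (environmentally
#' determined; the two-parameter variant omits it, i.e. fixes
#' \eqn{\lambda_3 = 0}).  The circuit is bistable at the reference
#' parameters: either gene can win the mutual repression.
#'
#' The exact algebraic form of the Hill terms is confined to this factory so
#' that it can be revised in one place.
#'
#' @param env logical; include the environmental parameter \eqn{\lambda_3}
#'   as a third parameter dimension (default `TRUE`).
#' @return An [ode_system()] with `n_states = 2`, analytic Jacobians, and a
#'   vectorised population right-hand side.
#' @export
toggle_switch <- function(env = TRUE) {
  n_par <- if (env) 3L else 2L
  getl3 <- if (env) function(l) l[3] else function(l) 0
  rhs <- function(t, x, lambda) {
    den1 <- (1 + x[2]^2)^2
    den2 <- (1 + x[1]^3 + getl3(lambda))^2
    c((2 + lambda[1]) / den1 - 0.4 * x[1],
      (2 + lambda[2]) / den2 - 0.4 * x[2])
  }
  jac_x <- function(t, x, lambda) {
    u2 <- 1 + x[2]^2
    u1 <- 1 + x[1]^3 + getl3(lambda)
    matrix(c(-0.4,
             (2 + lambda[2]) * (-2) * u1^(-3) * 3 * x[1]^2,
             (2 + lambda[1]) * (-2) * u2^(-3) * 2 * x[2],
             -0.4),
           2, 2)
  }
  jac_lambda <- function(t, x, lambda) {
    u2 <- 1 + x[2]^2
    u1 <- 1 + x[1]^3 + getl3(lambda)
    B <- matrix(0, 2, n_par)
    B[1, 1] <- 1 / u2^2
    B[2, 2] <- 1 / u1^2
    if (n_par == 3L) B[2, 3] <- (2 + lambda[2]) * (-2) * u1^(-3)
    B
  }
  rhs_pop <- function(t, X, L) {
    l3 <- if (n_par == 3L) L[, 3] else 0
    den1 <- (1 + X[, 2]^2)^2
    den2 <- (1 + X[, 1]^3 + l3)^2
    cbind((2 + L[, 1]) / den1 - 0.4 * X[, 1],
          (2 + L[, 2]) / den2 - 0.4 * X[, 2])
  }
  ode_system(2L, n_par, rhs, jac_x, jac_lambda, rhs_pop,
             name = if (env) "toggle_switch_env" else "toggle_switch")
}

#' Retrieve a built-in developmental model by name
#'
#' @param name `"toggle_switch"` (two parameters) or `"toggle_switch_env"`
#'   (adds the environmental parameter).
#' @return An [ode_system()].
#' @export
model_registry <- function(name) {
  switch(name,
         toggle_switch = toggle_switch(env = FALSE),
         toggle_switch_env = toggle_switch(env = TRUE),
         stop("unknown model name: ", name))
}

#' Developmental time grid
#'
#' Unit-step grids (`h = 1`) match the discrete-time estimators; other steps
#' are allowed.
#'
#' @param t0,t_end start and end of development, `t_end > t0`.
#' @param h step size, `> 0`.
#' @return Object of class `time_grid` with a `$times` vector.
#' @export
time_grid <- function(t0 = 0, t_end = 50, h = 1) {
  stopifnot(t_end > t0, h > 0)
  structure(list(t0 = t0, t_end = t_end, h = h,
                 times = seq(t0, t_end, by = h)),
            class = "time_grid")
}

#' Integrate a developmental trajectory
#'
#' Solves \eqn{\dot x = f(t,x,\lambda)} from `x0` and samples the solution
#' exactly on the grid.  The default solver is adaptive (`lsoda`) with tight
#' tolerances because downstream sensitivity computations amplify solver
#' error; the fixed-step `"rk4"` method uses the same arithmetic as the
#' population integrator (useful when bit-identical agreement with
#' population runs is required).
#'
#' @param system an [ode_system()].
#' @param x0 initial state, length `n_states`.
#' @param lambda parameter vector, length `n_params`.
#' @param grid a [time_grid()].
#' @param method `"lsoda"` (adaptive, default) or `"rk4"` (fixed step).
#' @param rtol,atol solver tolerances for the adaptive method.
#' @param h_int internal fixed step for `"rk4"`.
#' @return Object of class `trajectory`: list with `times` (length `T`) and
#'   `states` (`T x n` matrix).
#' @export
integrate_system <- function(system, x0, lambda, grid,
                             method = c("lsoda", "rk4"),
                             rtol = 1e-8, atol = 1e-10, h_int = 0.02) {
  method <- match.arg(method)
  stopifnot(length(x0) == system$n_states,
            length(lambda) == system$n_params)
  times <- grid$times
  if (length(times) == 1L) {
    return(new_trajectory(times, matrix(x0, 1, system$n_states)))
  }
  if (method == "rk4") {
    states <- rk4_population(system, matrix(x0, 1), matrix(lambda, 1),
                             times, h_int)
    st <- t(vapply(states, function(S) S[1, ], numeric(system$n_states)))
    return(new_trajectory(times, st))
  }
  fun <- function(t, y, parms) list(system$rhs(t, y, parms))
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = fun,
                      parms = as.numeric(lambda), method = "lsoda",
                      rtol = rtol, atol = atol)
  st <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (any(!is.finite(st))) {
    bad <- which(rowSums(!is.finite(st)) > 0)[1]
    stop("integration produced non-finite state at time ", times[bad])
  }
  if (nrow(st) < length(times)) {
    stop("integration failed at time ", times[nrow(st) + 1])
  }
  new_trajectory(times, st)
}

new_trajectory <- function(times, states) {
  stopifnot(all(diff(times) > 0) || length(times) == 1L,
            nrow(states) == length(times))
  structure(list(times = times, states = states), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points, ",
      ncol(x$states), " states; t in [", x$times[1], ", ",
      x$times[length(x$times)], "]\n", sep = "")
  invisible(x)
}

# One classical RK4 sweep of a whole population between consecutive grid
# times.  X: M x n states, L: M x p parameters.  Returns the list of state
# matrices at each grid time (including the first).  Used both by
# integrate_system(method = "rk4") with M = 1 and by the population
# simulator, so single individuals and populations agree bit-for-bit.
rk4_population <- function(system, X, L, times, h_int = 0.02,
                           perturb = NULL) {
  f <- system$rhs_pop
  if (is.null(f)) {
    f <- function(t, X, L) {
      t(vapply(seq_len(nrow(X)),
               function(m) system$rhs(t, X[m, ], L[m, ]),
               numeric(system$n_states)))
    }
  }
  out <- vector("list", length(times))
  out[[1]] <- X
  for (j in seq_along(times)[-1]) {
    t0 <- times[j - 1]; t1 <- times[j]
    nstep <- max(1L, ceiling((t1 - t0) / h_int - 1e-9))
    h <- (t1 - t0) / nstep
    t <- t0
    for (s in seq_len(nstep)) {
      k1 <- f(t, X, L)
      k2 <- f(t + h / 2, X + (h / 2) * k1, L)
      k3 <- f(t + h / 2, X + (h / 2) * k2, L)
      k4 <- f(t + h, X + h * k3, L)
      X <- X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    if (!is.null(perturb)) X <- perturb(j, X)
    if (any(!is.finite(X))) {
      stop("population integration produced non-finite state at time ", t1,
           " (individual ", which(!is.finite(rowSums(X)))[1], ")")
    }
    out[[j]] <- X
  }
  out
}

#' Locate equilibria of a developmental system
#'
#' Damped Newton root-finding on the right-hand side from each start;
#' converged roots (residual below `tol`) are deduplicated.
#'
#' @param system an [ode_system()].
#' @param lambda parameter vector.
#' @param starts list (or matrix rows) of initial state guesses.
#' @param tol residual norm below which a root is accepted.
#' @param max_iter Newton iteration cap per start.
#' @return Matrix with one equilibrium per row (possibly zero rows).
#' @export
find_equilibria <- function(system, lambda, starts, tol = 1e-8,
                            max_iter = 100) {
  if (is.matrix(starts)) starts <- split(starts, row(starts))
  stopifnot(length(starts) >= 1)
  roots <- list()
  for (x in starts) {
    x <- as.numeric(x)
    ok <- FALSE
    for (i in seq_len(max_iter)) {
      fx <- system$rhs(0, x, lambda)
      if (sqrt(sum(fx^2)) < tol) { ok <- TRUE; break }
      J <- system_jac_x(system, 0, x, lambda)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      # backtracking keeps the residual decreasing
      lam <- 1
      repeat {
        xn <- x + lam * step
        fn <- system$rhs(0, xn, lambda)
        if (all(is.finite(fn)) &&
            sum(fn^2) < sum(fx^2) || lam < 1e-6) break
        lam <- lam / 2
      }
      if (lam < 1e-6) break
      x <- x + lam * step
    }
    if (ok && all(is.finite(x))) {
      dup <- any(vapply(roots, function(r) max(abs(r - x)) < 1e-6, logical(1)))
      if (!dup) roots[[length(roots) + 1]] <- x
    }
  }
  if (length(roots) == 0) {
    return(matrix(numeric(0), 0, system$n_states))
  }
  do.call(rbind, roots)
}

#' Export a trajectory (or set of trajectories) as tidy data
#'
#' @param traj a `trajectory`.
#' @param individual_id id recorded in the `individual_id` column.
#' @return data.frame with columns `individual_id`, `time`, `state_index`
#'   (0-based), `value`.
#' @export
trajectory_to_df <- function(traj, individual_id = 1L) {
  n <- ncol(traj$states)
  data.frame(individual_id = individual_id,
             time = rep(traj$times, times = n),
             state_index = rep(seq_len(n) - 1L, each = length(traj$times)),
             value = as.vector(traj$states))
}
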