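#' Sensitivity vectors by integrating the variational equations
#'
#' The sensitivity vector of parameter k,
#' \eqn{s_k(t) = \partial x(t,\lambda)/\partial \lambda_k} evaluated at the
#' reference \eqn{\lambda^*}, obeys the variational (forward sensitivity)
#' equation \eqn{\dot s_k = A(t) s_k + b_k(t)}, \eqn{s_k(t_0) = 0}, where
#' `A` is the state Jacobian and `b_k` the direct parameter dependence of
#' the right-hand side, both evaluated along the reference trajectory.  The
#' reference state and all `n x p` sensitivities are integrated jointly as
#' one augmented system.
#'
#' @param system an [ode_system()].
#' @param x0 initial state.
#' @param lambda_ref reference parameter vector \eqn{\lambda^*}.
#' @param grid a [time_grid()].
#' @param rtol,atol solver tolerances.
#' @return Object of class `sensitivity_set`: list with `times` (length `T`),
#'   `s` (`T x n x p` array, `s[t, , k]` is \eqn{s_k(t)}), `method`,
#'   `lambda_ref`, and the reference `trajectory`.
#' @export
sensitivities_variational <- function(system, x0, lambda_ref, grid,
                                      rtol = 1e-8, atol = 1e-10) {
  n <- system$n_states; p <- system$n_params
  stopifnot(length(x0) == n, length(lambda_ref) == p)
  fun <- function(t, y, parms) {
    x <- y[seq_len(n)]
    S <- matrix(y[-seq_len(n)], n, p)
    A <- system_jac_x(system, t, x, parms)
    B <- system_jac_lambda(system, t, x, parms)
    list(c(system$rhs(t, x, parms), as.vector(A %*% S + B)))
  }
  y0 <- c(as.numeric(x0), rep(0, n * p))
  sol <- deSolve::ode(y = y0, times = grid$times, func = fun,
                      parms = as.numeric(lambda_ref), method = "lsoda",
                      rtol = rtol, atol = atol)
  mat <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (any(!is.finite(mat))) {
    stop("variational integration produced non-finite values")
  }
  Tn <- length(grid$times)
  s <- array(mat[, -seq_len(n), drop = FALSE], dim = c(Tn, n, p))
  new_sensitivity_set(grid$times, s, "variational", lambda_ref,
                      reference = new_trajectory(grid$times,
                                                 mat[, seq_len(n),
                                                     drop = FALSE]))
}

new_sensitivity_set <- function(times, s, method, lambda_ref,
                                reference = NULL) {
  structure(list(times = times, s = s, method = method,
                 lambda_ref = lambda_ref, reference = reference),
            class = "sensitivity_set")
}

#' @export
print.sensitivity_set <- function(x, ...) {
  d <- dim(x$s)
  cat("<sensitivity_set> method=", x$method, "; ", d[1], " times x ",
      d[2], " states x ", d[3], " parameters\n", sep = "")
  invisible(x)
}

#' Sensitivity vectors by central finite differences
#'
#' Re-integrates the system at \eqn{\lambda^* \pm \Delta\lambda\, e_k} and
#' forms the symmetric difference quotient per parameter.  A numerical
#' route that requires no Jacobians; tighter-than-default solver tolerances
#' are used because the differences are small.
#'
#' @inheritParams sensitivities_variational
#' @param delta perturbation size \eqn{\Delta\lambda} (default `1e-4`,
#'   chosen by a step-halving convergence check).
#' @param rtol,atol solver tolerances.
#' @return A `sensitivity_set` with `method = "finite_difference"`.
#' @export
sensitivities_fd <- function(system, x0, lambda_ref, grid, delta = 1e-4,
                             rtol = 1e-10, atol = 1e-12) {
  stopifnot(delta > 0)
  if (delta < 1e3 * rtol) {
    warning("delta is close to solver tolerance; differences may be noise")
  }
  n <- system$n_states; p <- system$n_params
  Tn <- length(grid$times)
  s <- array(0, dim = c(Tn, n, p))
  for (k in seq_len(p)) {
    lp <- lambda_ref; lm <- lambda_ref
    lp[k] <- lp[k] + delta; lm[k] <- lm[k] - delta
    xp <- integrate_system(system, x0, lp, grid, rtol = rtol, atol = atol)
    xm <- integrate_system(system, x0, lm, grid, rtol = rtol, atol = atol)
    s[, , k] <- (xp$states - xm$states) / (2 * delta)
  }
  s[1, , ] <- 0  # exact: the initial state does not depend on lambda
  new_sensitivity_set(grid$times, s, "finite_difference", lambda_ref)
}

#' Second-order sensitivities by central second differences
#'
#' Estimates \eqn{s^{(1)}_k(t) = \partial^2 x(t,\lambda)/\partial\lambda_k^2}
#' at the reference, the curvature term that generates dominance in the
#' genotypic-value expansion.
#'
#' @inheritParams sensitivities_fd
#' @param delta perturbation size (default `1e-3`; the second difference
#'   loses more precision than the first, so a larger step is appropriate).
#' @return List of class `second_order_set` with `times` and `s1`
#'   (`T x n x p` array), zero at `t0`.
#' @export
second_order_fd <- function(system, x0, lambda_ref, grid, delta = 1e-3,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(delta > 0)
  n <- system$n_states; p <- system$n_params
  Tn <- length(grid$times)
  x_ref <- integrate_system(system, x0, lambda_ref, grid,
                            rtol = rtol, atol = atol)
  s1 <- array(0, dim = c(Tn, n, p))
  for (k in seq_len(p)) {
    lp <- lambda_ref; lm <- lambda_ref
    lp[k] <- lp[k] + delta; lm[k] <- lm[k] - delta
    xp <- integrate_system(system, x0, lp, grid, rtol = rtol, atol = atol)
    xm <- integrate_system(system, x0, lm, grid, rtol = rtol, atol = atol)
    s1[, , k] <- (xp$states - 2 * x_ref$states + xm$states) / delta^2
  }
  s1[1, , ] <- 0
  structure(list(times = grid$times, s1 = s1, lambda_ref = lambda_ref),
            class = "second_order_set")
}

#' Sensitivity vectors by regression on perturbed simulations
#'
#' For black-box simulators with no accessible right-hand side: run the
#' model at parameter draws near the reference, then regress each trait at
#' each time on the parameter deviations \eqn{\lambda - \lambda^*}.  The
#' slope matrix at each time is the sensitivity estimate.
#'
#' @param trajectories list of `trajectory` objects (or `T x n` state
#'   matrices), one per run, all on the same time grid.
#' @param param_draws matrix with one row of parameters per run.
#' @param lambda_ref reference parameter vector.
#' @param times time vector shared by the runs.
#' @return A `sensitivity_set` with `method = "regression"`.
#' @export
sensitivities_regression <- function(trajectories, param_draws, lambda_ref,
                                     times) {
  states <- lapply(trajectories, function(tr) {
    if (inherits(tr, "trajectory")) tr$states else tr
  })
  R <- length(states)
  p <- length(lambda_ref)
  stopifnot(R >= p + 2, nrow(param_draws) == R)
  n <- ncol(states[[1]])
  Tn <- length(times)
  D <- sweep(param_draws, 2, lambda_ref)  # centered design
  X <- cbind(1, D)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient design; collinear parameter columns: ",
         paste(drop - 1L, collapse = ", "))
  }
  s <- array(0, dim = c(Tn, n, p))
  # flatten: responses are R x (Tn * n)
  Y <- matrix(0, R, Tn * n)
  for (r in seq_len(R)) Y[r, ] <- as.vector(states[[r]])
  coefs <- qr.coef(qrX, Y)           # (p+1) x (Tn*n)
  for (k in seq_len(p)) {
    s[, , k] <- matrix(coefs[k + 1, ], Tn, n)
  }
  new_sensitivity_set(times, s, "regression", lambda_ref)
}

#' Angle between two vectors, in degrees
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @param convention `"directed"` gives the raw angle in `[0, 180]`;
#'   `"axial"` folds sign-ambiguous directions to `[0, 90]` via the
#'   absolute cosine (appropriate for eigenvector comparisons).
#' @return Angle in degrees.
#' @export
vec_angle <- function(u, v, convention = c("directed", "axial")) {
  convention <- match.arg(convention)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("angle undefined for a zero vector")
  ct <- sum(u * v) / (nu * nv)
  if (convention == "axial") ct <- abs(ct)
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

#' Pairwise angles between sensitivity vectors over time
#'
#' @param sens a `sensitivity_set`.
#' @param pairs optional 2-column matrix of parameter index pairs; default
#'   all unordered pairs.
#' @param convention see [vec_angle()].
#' @return data.frame with columns `time`, `param_i`, `param_j`,
#'   `angle_deg` (rows with a zero vector, e.g. at `t0`, are `NA`).
#' @export
angle_report <- function(sens, pairs = NULL,
                         convention = c("directed", "axial")) {
  convention <- match.arg(convention)
  p <- dim(sens$s)[3]
  if (is.null(pairs)) pairs <- t(utils::combn(p, 2))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ang <- vapply(seq_along(sens$times), function(t) {
      u <- sens$s[t, , i]; v <- sens$s[t, , j]
      if (all(u == 0) || all(v == 0)) return(NA_real_)
      vec_angle(u, v, convention)
    }, numeric(1))
    data.frame(time = sens$times, param_i = i, param_j = j,
               angle_deg = ang)
  }))
  attr(out, "convention") <- convention
  out
}

#' Null distribution of angles between random directions
#'
#' Samples angles between pairs of independent isotropic Gaussian vectors
#' in `dim` dimensions.  The closed-form density is proportional to
#' \eqn{\sin^{d-2}\theta} on \eqn{[0, 180]} degrees; in two dimensions the
#' distribution is uniform.
#'
#' @param dim trait-space dimension, at least 2.
#' @param n_samples number of angle draws.
#' @param seed optional integer seed.
#' @return List with `angles_deg` (samples), `density` (function of angle
#'   in degrees) and `cdf` (function of angle in degrees).
#' @export
random_angle_null <- function(dim, n_samples = 1e5, seed = NULL) {
  stopifnot(dim >= 2)
  if (!is.null(seed)) set.seed(seed)
  U <- matrix(stats::rnorm(n_samples * dim), n_samples, dim)
  V <- matrix(stats::rnorm(n_samples * dim), n_samples, dim)
  ct <- rowSums(U * V) /
    (sqrt(rowSums(U^2)) * sqrt(rowSums(V^2)))
  angles <- acos(pmax(-1, pmin(1, ct))) * 180 / pi
  # density of theta (radians) is sin^(d-2)(theta) / B((d-1)/2, 1/2)
  lognorm <- lbeta((dim - 1) / 2, 1 / 2)
  density <- function(theta_deg) {
    th <- theta_deg * pi / 180
    out <- ifelse(th >= 0 & th <= pi,
                  exp((dim - 2) * log(pmax(sin(th), 0)) - lognorm), 0)
    out * pi / 180  # per-degree density
  }
  # closed form: (1 - cos(theta))/2 ~ Beta((d-1)/2, (d-1)/2)
  cdf <- function(theta_deg) {
    th <- pmin(pmax(theta_deg, 0), 180) * pi / 180
    stats::pbeta((1 - cos(th)) / 2, (dim - 1) / 2, (dim - 1) / 2)
  }
  list(angles_deg = angles, density = density, cdf = cdf, dim = dim)
}

#' Export a sensitivity set as tidy data
#'
#' @param sens a `sensitivity_set`.
#' @return data.frame with columns `time`, `state_index` (0-based),
#'   `param_index` (0-based), `value`.
#' @export
sensitivity_to_df <- function(sens) {
  d <- dim(sens$s)
  data.frame(time = rep(sens$times, times = d[2] * d[3]),
             state_index = rep(rep(seq_len(d[2]) - 1L, each = d[1]),
                               times = d[3]),
             param_index = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
             value = as.vector(sens$s))
}
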