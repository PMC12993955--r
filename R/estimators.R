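#' Static (per-time) regression estimates of average effects
#'
#' At each developmental time the observed trait values are regressed on
#' the genotype codes of all loci with an intercept,
#' \eqn{y(t) = \mu(t) 1 + Z \alpha(t) + \epsilon(t)}; the slope vector is
#' the static estimate \eqn{\hat\alpha^s(t)} of the average effects.  The
#' design matrix is shared across times, so a single QR factorisation
#' serves the whole series.
#'
#' @param series a `phenotype_series`.
#' @param trait_index which trait (state) to analyse, 1-based.
#' @param use `"observed"` (default) or `"true"` states.
#' @return Object of class `static_estimate`: list with `times`,
#'   `alpha_s` (`T x N` slopes), `se` (`T x N` standard errors), `mu`
#'   (intercepts), `sigma2_eps` (residual variances), `n_ind`.
#' @export
static_average_effects <- function(series, trait_index = 1,
                                   use = c("observed", "true")) {
  use <- match.arg(use)
  Z <- series$genotypes$codes
  M <- nrow(Z); N <- ncol(Z)
  if (M <= N + 1) {
    stop("population size (", M, ") must exceed number of loci + 1 (",
         N + 1, ")")
  }
  Y <- if (use == "observed") series$observed[, , trait_index]
       else series$true_states[, , trait_index]
  Y <- matrix(Y, M)  # M x T
  X <- cbind(1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(seq_len(ncol(X)), keep) - 1L
    stop("rank-deficient genotype design; collinear loci: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrX, Y)            # (N+1) x T
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  dfree <- M - N - 1
  sigma2 <- rss / dfree
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))
  se <- sqrt(outer(sigma2, xtx_inv_diag[-1]))   # T x N
  structure(list(times = series$times,
                 alpha_s = t(coefs[-1, , drop = FALSE]),
                 se = se,
                 mu = coefs[1, ],
                 sigma2_eps = sigma2,
                 n_ind = M),
            class = "static_estimate")
}

#' Dynamic (Kalman-filtered) estimates of average effects
#'
#' Treats the static per-time estimates as noisy observations of average
#' effects that evolve as a random walk,
#' \eqn{\alpha_i(t) = \alpha_i(t-1) + \eta(t)},
#' \eqn{\eta(t) \sim N(0, Q)}, and runs an independent scalar Kalman filter
#' per locus.  Each filtered value integrates the full history of
#' observations up to that time.  The filter is initialised at the first
#' time point with mean 0 and a very small variance, because sensitivity
#' vectors (and hence average effects) vanish at the start of development.
#'
#' @param static a `static_estimate`.
#' @param Q process-noise variance: a scalar, a per-locus vector, or
#'   `NULL` (default) for a per-locus method-of-moments plug-in: since
#'   \eqn{E[(\Delta \hat\alpha^s)^2] = Q + R_t + R_{t-1}} under the model,
#'   Q is estimated as the mean squared first difference of the static
#'   estimates minus the mean adjacent observation-variance sum, floored at
#'   a small positive fraction of the former.
#' @param R_mode `"from_ols_se"` (observation variance = squared OLS
#'   standard error, default) or `"fixed"` (supply `R`).
#' @param R fixed observation variance (scalar or `T x N` matrix) when
#'   `R_mode = "fixed"`.
#' @param init_mean,init_var prior at the first time point.
#' @param smooth logical; additionally run a backward (RTS) smoothing pass.
#' @return Object of class `dynamic_estimate`: list with `times`,
#'   `alpha_d`, `var_d` (`T x N`), and when `smooth = TRUE` also
#'   `alpha_smooth`, `var_smooth`.
#' @export
kalman_average_effects <- function(static, Q = NULL,
                                   R_mode = c("from_ols_se", "fixed"),
                                   R = NULL, init_mean = 0,
                                   init_var = 1e-12, smooth = FALSE) {
  R_mode <- match.arg(R_mode)
  obs <- static$alpha_s
  if (any(!is.finite(obs))) stop("non-finite static estimates")
  Tn <- nrow(obs); N <- ncol(obs)
  stopifnot(Tn >= 2)
  Robs <- switch(R_mode,
                 from_ols_se = static$se^2,
                 fixed = {
                   stopifnot(!is.null(R))
                   if (length(R) == 1) matrix(R, Tn, N) else as.matrix(R)
                 })
  if (is.null(Q)) {
    Q <- vapply(seq_len(N), function(i) {
      m2 <- mean(diff(obs[, i])^2)
      rsum <- mean(Robs[-1, i] + Robs[-Tn, i])
      max(m2 - rsum, 1e-3 * m2)
    }, numeric(1))
  }
  Q <- rep_len(Q, N)
  alpha_d <- var_d <- matrix(0, Tn, N)
  pred_m <- pred_v <- matrix(0, Tn, N)
  for (i in seq_len(N)) {
    m <- init_mean; v <- init_var
    for (t in seq_len(Tn)) {
      if (t > 1) v <- v + Q[i]
      pred_m[t, i] <- m; pred_v[t, i] <- v
      denom <- v + Robs[t, i]
      K <- if (denom > 0) v / denom else 1
      m <- m + K * (obs[t, i] - m)
      v <- (1 - K) * v
      alpha_d[t, i] <- m; var_d[t, i] <- v
    }
  }
  out <- list(times = static$times, alpha_d = alpha_d, var_d = var_d,
              Q = Q)
  if (smooth) {
    alpha_sm <- alpha_d; var_sm <- var_d
    for (i in seq_len(N)) {
      for (t in (Tn - 1):1) {
        C <- if (pred_v[t + 1, i] > 0) var_d[t, i] / pred_v[t + 1, i] else 0
        alpha_sm[t, i] <- alpha_d[t, i] +
          C * (alpha_sm[t + 1, i] - pred_m[t + 1, i])
        var_sm[t, i] <- var_d[t, i] +
          C^2 * (var_sm[t + 1, i] - pred_v[t + 1, i])
      }
    }
    out$alpha_smooth <- alpha_sm
    out$var_smooth <- var_sm
  }
  structure(out, class = "dynamic_estimate")
}

#' Relative estimation error against a known truth
#'
#' Elementwise \eqn{|\hat\alpha_i(t) - \alpha_i(t)| / |\alpha_i(t)|},
#' aggregated over loci and over all time points after the first (where the
#' truth vanishes and the ratio is undefined).
#'
#' @param estimate `T x N` matrix of estimates.
#' @param truth `T x N` matrix of true values.
#' @param exclude_first drop the first time point (default `TRUE`).
#' @return List with `elementwise` (matrix), `by_time`, `by_locus`, and the
#'   aggregate `mean`.
#' @export
relative_error <- function(estimate, truth, exclude_first = TRUE) {
  estimate <- as.matrix(estimate); truth <- as.matrix(truth)
  stopifnot(all(dim(estimate) == dim(truth)))
  if (exclude_first) {
    estimate <- estimate[-1, , drop = FALSE]
    truth <- truth[-1, , drop = FALSE]
  }
  if (all(truth == 0)) stop("truth is identically zero")
  err <- abs(estimate - truth) / abs(truth)
  err[truth == 0] <- NA
  list(elementwise = err,
       by_time = rowMeans(err, na.rm = TRUE),
       by_locus = colMeans(err, na.rm = TRUE),
       mean = mean(err, na.rm = TRUE))
}
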