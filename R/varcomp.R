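#' Additive-genetic covariance matrix from sensitivity vectors
#'
#' Under Hardy-Weinberg equilibrium and small per-locus effects, the
#' contribution of locus i at time t is the rank-1 matrix
#' \eqn{G_i(t) = 2 p_i q_i \gamma_i^2\, s_{w(i)}(t) s_{w(i)}(t)^T}
#' and the G-matrix is the sum over polymorphic loci.
#'
#' @param sens a `sensitivity_set`.
#' @param loci a [loci_table()].
#' @param t developmental time at which to evaluate (must be on the grid).
#' @return List with `G` (`n x n`), `per_locus` (list of rank-1
#'   contributions), `sigma2_by_locus` (parameter variances
#'   \eqn{2 p_i q_i \gamma_i^2}) and `time`.
#' @export
build_G <- function(sens, loci, t) {
  ti <- match_time(sens$times, t)
  p_dim <- dim(sens$s)[3]
  if (any(loci$target_param > p_dim)) {
    stop("loci target parameters exceed available sensitivities")
  }
  n <- dim(sens$s)[2]
  sigma2 <- 2 * (1 - loci$freq_B) * loci$freq_B * loci$gamma^2
  per_locus <- lapply(seq_len(nrow(loci)), function(i) {
    s <- sens$s[ti, , loci$target_param[i]]
    sigma2[i] * tcrossprod(s)
  })
  G <- Reduce(`+`, per_locus, matrix(0, n, n))
  list(G = G, per_locus = per_locus, sigma2_by_locus = sigma2, time = t)
}

#' Environmental covariance matrix from sensitivity vectors
#'
#' First-order approximation: an environmental factor j perturbing
#' parameter v(j) with variance \eqn{\sigma_j^2} contributes
#' \eqn{E_j(t) = \sigma_j^2\, s_{v(j)}(t) s_{v(j)}(t)^T}; factors sum.
#'
#' @param sens a `sensitivity_set`.
#' @param env_factors data.frame with columns `target_param` and `sd`
#'   (e.g. an [env_spec()]).
#' @param t developmental time.
#' @return List with `E`, `per_env`, `sigma2_by_env`, `time`.
#' @export
build_E <- function(sens, env_factors, t) {
  ti <- match_time(sens$times, t)
  n <- dim(sens$s)[2]
  if (is.null(env_factors) || nrow(env_factors) == 0) {
    return(list(E = matrix(0, n, n), per_env = list(),
                sigma2_by_env = numeric(0), time = t))
  }
  if (any(env_factors$target_param > dim(sens$s)[3])) {
    stop("environmental target parameters exceed available sensitivities")
  }
  sigma2 <- env_factors$sd^2
  per_env <- lapply(seq_len(nrow(env_factors)), function(j) {
    s <- sens$s[ti, , env_factors$target_param[j]]
    sigma2[j] * tcrossprod(s)
  })
  list(E = Reduce(`+`, per_env, matrix(0, n, n)), per_env = per_env,
       sigma2_by_env = sigma2, time = t)
}

#' Phenotypic covariance matrix
#'
#' To first order, `P = G + E`.
#'
#' @param G,E `n x n` matrices (or the lists returned by [build_G()] /
#'   [build_E()]).
#' @return `n x n` matrix.
#' @export
build_P <- function(G, E) {
  if (is.list(G)) G <- G$G
  if (is.list(E)) E <- E$E
  stopifnot(all(dim(G) == dim(E)))
  G + E
}

#' Empirical additive-genetic covariance from realized frequencies
#'
#' \eqn{2 \sum_i \hat p_i \hat q_i\, \alpha_i \alpha_i^T} with allele
#' frequencies realized in the genotype sample rather than the nominal
#' architecture values.
#'
#' @param geno a [genotype_matrix()].
#' @param alpha `n x N` matrix of per-locus average-effect vectors at the
#'   chosen time (e.g. a slice of [average_effect_linear()]).
#' @return `n x n` matrix.
#' @export
empirical_G <- function(geno, alpha) {
  alpha <- as.matrix(alpha)
  codes <- geno$codes
  stopifnot(ncol(alpha) == ncol(codes))
  qhat <- colMeans(codes + 1) / 2
  w <- 2 * qhat * (1 - qhat)
  G <- matrix(0, nrow(alpha), nrow(alpha))
  for (i in seq_len(ncol(alpha))) {
    G <- G + w[i] * tcrossprod(alpha[, i])
  }
  G
}

#' Angle between the leading eigenvectors of G and P
#'
#' A scalar proportionality diagnostic for two-trait systems: the axial
#' angle (in `[0, 90]` degrees) between Gmax and Pmax.  Eigenvector signs
#' are fixed by making the largest-magnitude component positive so reports
#' are deterministic.  A tie between the two leading eigenvalues leaves the
#' leading axis undefined and raises an error.
#'
#' @param G,P symmetric covariance matrices (or [build_G()]-style lists).
#' @param tie_tol relative eigenvalue-gap threshold treated as a tie.
#' @return List with `angle_deg`, `gmax`, `pmax`, `eig_G`, `eig_P`.
#' @export
gmax_pmax_angle <- function(G, P, tie_tol = 1e-10) {
  if (is.list(G)) G <- G$G
  if (is.list(P)) P <- P$P
  lead <- function(M, label) {
    if (all(M == 0)) stop(label, " matrix is zero")
    e <- eigen(M, symmetric = TRUE)
    gap <- e$values[1] - e$values[2]
    if (gap <= tie_tol * max(abs(e$values))) {
      stop("leading eigenvalues of ", label,
           " are tied; leading axis undefined")
    }
    v <- e$values
    u <- e$vectors[, 1]
    if (u[which.max(abs(u))] < 0) u <- -u
    list(vec = u, values = v)
  }
  g <- lead(G, "G"); p <- lead(P, "P")
  list(angle_deg = vec_angle(g$vec, p$vec, "axial"),
       gmax = g$vec, pmax = p$vec,
       eig_G = g$values, eig_P = p$values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

match_time <- function(times, t) {
  ti <- which(abs(times - t) < 1e-9)
  if (length(ti) != 1) stop("time ", t, " is not on the grid")
  ti
}
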