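#' Define a genetic architecture (loci table)
#'
#' Each biallelic locus targets one developmental parameter; its per-allele
#' substitution effect is \eqn{\gamma_i} (the shift in the parameter caused
#' by replacing a b allele with a B allele), and `freq_B` is the frequency
#' q of the B allele (so p = 1 - q for b).
#'
#' Genotypes are coded internally as the B-allele count minus one: +1 for
#' BB, 0 for Bb, -1 for bb.  Under this coding the regression slope of
#' phenotype on genotype code equals the average effect with its
#' conventional sign, so that \eqn{\alpha(t) \approx +s(t)\gamma} for small
#' effects.
#'
#' @param target_param integer vector, parameter index affected by each
#'   locus.
#' @param gamma per-allele effect on the parameter, one per locus.
#' @param freq_B frequency of the B allele, in `[0, 1]`, one per locus.
#' @return data.frame of class `loci_table` with columns `locus`,
#'   `target_param`, `gamma`, `freq_B`.
#' @export
loci_table <- function(target_param, gamma, freq_B) {
  stopifnot(length(target_param) == length(gamma),
            length(gamma) == length(freq_B),
            all(freq_B >= 0 & freq_B <= 1))
  structure(data.frame(locus = seq_along(gamma),
                       target_param = as.integer(target_param),
                       gamma = gamma, freq_B = freq_B),
            class = c("loci_table", "data.frame"))
}

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' Draws the two alleles at each locus independently (no linkage, unrelated
#' individuals).  Allele matrices are retained so that Mendelian
#' segregation from heterozygotes is exact in downstream breeding.
#'
#' @param loci a [loci_table()].
#' @param M population size.
#' @param seed optional integer seed.
#' @return Object of class `genotype_matrix`: list with `codes`
#'   (`M x N` matrix in \{-1, 0, 1\}) and allele indicator matrices
#'   `hap_a`, `hap_b` (`M x N`, 1 = B allele).
#' @export
sample_genotypes <- function(loci, M, seed = NULL) {
  stopifnot(M >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(loci)
  q <- matrix(loci$freq_B, M, N, byrow = TRUE)
  hap_a <- matrix(as.numeric(stats::runif(M * N) < q), M, N)
  hap_b <- matrix(as.numeric(stats::runif(M * N) < q), M, N)
  genotype_matrix(hap_a = hap_a, hap_b = hap_b)
}

#' Construct a genotype matrix
#'
#' Either from two allele indicator matrices or from a code matrix (in the
#' latter case heterozygote phase is immaterial and alleles are assigned
#' deterministically).
#'
#' @param codes `M x N` matrix with entries in \{-1, 0, 1\} (+1 = BB,
#'   0 = Bb, -1 = bb).
#' @param hap_a,hap_b `M x N` 0/1 allele indicators (1 = B).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes = NULL, hap_a = NULL, hap_b = NULL) {
  if (is.null(codes)) {
    stopifnot(!is.null(hap_a), !is.null(hap_b),
              all(hap_a %in% c(0, 1)), all(hap_b %in% c(0, 1)))
    codes <- hap_a + hap_b - 1
  } else {
    stopifnot(all(codes %in% c(-1, 0, 1)))
    codes <- as.matrix(codes)
    if (is.null(hap_a)) {
      hap_a <- (codes >= 0) * 1
      hap_b <- (codes > 0) * 1
    }
  }
  structure(list(codes = unname(codes), hap_a = unname(hap_a),
                 hap_b = unname(hap_b)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$codes), " individuals x ",
      ncol(x$codes), " loci\n", sep = "")
  invisible(x)
}

#' Map genotypes to developmental parameters
#'
#' Additive genotype-to-parameter map: individual m receives
#' \eqn{\lambda^{(m)} = \lambda^* + \sum_i z_{mi}\,\gamma_i\, e_{w(i)}}
#' where \eqn{z_{mi}} is the genotype code.  An all-heterozygote individual
#' maps exactly to the reference \eqn{\lambda^*}, which is therefore the
#' natural reference for population work.
#'
#' @param geno a [genotype_matrix()] or a plain code matrix.
#' @param loci a [loci_table()] whose rows match the genotype columns.
#' @param lambda_ref reference parameter vector.
#' @return `M x p` matrix of per-individual parameters.
#' @export
genotype_to_parameters <- function(geno, loci, lambda_ref) {
  codes <- if (inherits(geno, "genotype_matrix")) geno$codes else
    as.matrix(geno)
  stopifnot(ncol(codes) == nrow(loci))
  p <- length(lambda_ref)
  stopifnot(all(loci$target_param >= 1), all(loci$target_param <= p))
  # effect design: N x p, locus i contributes gamma_i to column w(i)
  W <- matrix(0, nrow(loci), p)
  W[cbind(seq_len(nrow(loci)), loci$target_param)] <- loci$gamma
  sweep(codes %*% W, 2, lambda_ref, "+")
}

#' Genotypic-value trajectories for a focal locus
#'
#' Integrates the developmental model at the three parameter values implied
#' by genotypes bb, Bb and BB at one locus (background loci held at the
#' heterozygote, i.e. at the reference).  The heterozygote trajectory is the
#' reference trajectory.
#'
#' @param system an [ode_system()].
#' @param x0 initial state.
#' @param grid a [time_grid()].
#' @param gamma per-allele effect of the focal locus.
#' @param target_param parameter index affected by the locus.
#' @param lambda_ref reference parameter vector.
#' @param ... passed to [integrate_system()].
#' @return List with `trajectory` elements `x_bb`, `x_Bb`, `x_BB`.
#' @export
genotypic_values <- function(system, x0, grid, gamma, target_param,
                             lambda_ref, ...) {
  lam <- function(code) {
    l <- lambda_ref; l[target_param] <- l[target_param] + code * gamma; l
  }
  list(x_bb = integrate_system(system, x0, lam(-1), grid, ...),
       x_Bb = integrate_system(system, x0, lam(0), grid, ...),
       x_BB = integrate_system(system, x0, lam(+1), grid, ...))
}

#' Additive, dominance and average-effect curves from genotypic values
#'
#' Classical single-locus decomposition at each developmental time:
#' additive value \eqn{a(t) = (x_{BB} - x_{bb})/2}, dominance value
#' \eqn{d(t) = x_{Bb} - (x_{BB}+x_{bb})/2}, and, under random mating, the
#' average effect of substituting a b allele with a B allele,
#' \eqn{\alpha(t) = a(t) + d(t)(p - q)} with q the frequency of B.  With
#' this sign convention \eqn{\alpha(t)} equals the slope of the regression
#' of phenotype on B-allele count for a population at exact Hardy-Weinberg
#' proportions, and \eqn{\alpha(t) \approx s(t)\gamma} for small effects.
#'
#' @param x_bb,x_Bb,x_BB `trajectory` objects on a shared grid.
#' @param q frequency of the B allele.
#' @return Object of class `effect_curves`: list with `times` and `T x n`
#'   matrices `a`, `d`, `alpha`.
#' @export
effect_curves <- function(x_bb, x_Bb, x_BB, q) {
  stopifnot(isTRUE(all.equal(x_bb$times, x_BB$times)),
            isTRUE(all.equal(x_bb$times, x_Bb$times)),
            q >= 0, q <= 1)
  a <- (x_BB$states - x_bb$states) / 2
  d <- x_Bb$states - (x_BB$states + x_bb$states) / 2
  p <- 1 - q
  structure(list(times = x_bb$times, a = a, d = d,
                 alpha = a + d * (p - q), q = q),
            class = "effect_curves")
}

#' Small-effect (linear) average effects from sensitivities
#'
#' Infinitesimal-model approximation: the average-effect vector of locus i
#' on all traits is \eqn{\alpha_i(t) = \gamma_i\, s_{w(i)}(t)}.  Used as
#' the analytic ground truth when scoring estimators.
#'
#' @param sens a `sensitivity_set` at the reference parameters.
#' @param loci a [loci_table()].
#' @return `T x n x N` array; `[, , i]` is \eqn{\alpha_i(t)} over time.
#' @export
average_effect_linear <- function(sens, loci) {
  d <- dim(sens$s)
  stopifnot(all(loci$target_param <= d[3]))
  out <- array(0, dim = c(d[1], d[2], nrow(loci)))
  for (i in seq_len(nrow(loci))) {
    out[, , i] <- loci$gamma[i] * sens$s[, , loci$target_param[i]]
  }
  out
}
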