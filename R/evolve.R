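#' Selection configuration for one generation of evolution
#'
#' Truncation selection toward a fixed trait optimum: the fraction of the
#' population whose final-time phenotypes lie closest (Euclidean distance)
#' to the optimum is retained, paired monogamously at random, and each pair
#' produces a fixed number of offspring by Mendelian recombination.
#'
#' @param optimum trait-space optimum (default `c(4, 4)`).
#' @param fraction_selected fraction of the population retained
#'   (default 0.5).
#' @param offspring_per_pair offspring per mated pair (default 4).
#' @param seed optional integer seed for pairing and segregation.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(optimum = c(4, 4), fraction_selected = 0.5,
                             offspring_per_pair = 4, seed = NULL) {
  stopifnot(fraction_selected > 0, fraction_selected <= 1,
            offspring_per_pair >= 1)
  structure(list(optimum = optimum,
                 fraction_selected = fraction_selected,
                 offspring_per_pair = offspring_per_pair, seed = seed),
            class = "selection_config")
}

# Draw one gamete per (individual, locus): each allele comes from the
# parent's two haplotypes with equal probability.  Exact Mendelian
# segregation because haplotypes are stored explicitly.
draw_gametes <- function(geno, idx) {
  ha <- geno$hap_a[idx, , drop = FALSE]
  hb <- geno$hap_b[idx, , drop = FALSE]
  pick <- matrix(stats::runif(length(ha)) < 0.5, nrow(ha))
  ha * pick + hb * (1 - pick)
}

#' One generation of truncation selection and random mating
#'
#' Ranks individuals by distance of their final-time phenotype to the
#' optimum, retains the closest fraction, pairs them monogamously at
#' random, generates offspring genotypes by unlinked Mendelian segregation,
#' and develops the offspring with fresh environmental draws.
#'
#' @param series parental `phenotype_series` (phenotypes are taken from the
#'   final time of `true_states`).
#' @param config a [selection_config()].
#' @param system,x0,grid,env,lambda_ref,h_int developmental setup used to
#'   grow the offspring (defaults match the parental series where they can
#'   be inferred).
#' @param noise a [noise_config()] applied to offspring development.
#' @return List with `offspring` (a `phenotype_series`), `selected_idx`,
#'   `pairs` (2-column matrix of parental indices), `parental_mean`,
#'   `selected_mean`, `offspring_mean`, `S` (selection differential) and
#'   `observed_delta_z` (offspring mean minus pre-selection parental mean).
#' @export
select_and_breed <- function(series, config, system, x0, grid, env = NULL,
                             lambda_ref = rep(0, system$n_params),
                             noise = noise_config(), h_int = 0.05) {
  if (!is.null(config$seed)) set.seed(config$seed)
  Tn <- length(series$times)
  pheno <- series$true_states[, Tn, ]    # M x n final phenotypes
  M <- nrow(pheno)
  n_keep <- floor(M * config$fraction_selected)
  if (n_keep %% 2 == 1) n_keep <- n_keep - 1  # need whole pairs
  if (n_keep < 2) stop("fewer than 2 individuals selected")
  d2 <- rowSums(sweep(pheno, 2, config$optimum)^2)
  sel <- order(d2)[seq_len(n_keep)]
  perm <- sample(sel)
  pairs <- cbind(perm[seq(1, n_keep, by = 2)],
                 perm[seq(2, n_keep, by = 2)])
  k <- config$offspring_per_pair
  ia <- rep(pairs[, 1], each = k)
  ib <- rep(pairs[, 2], each = k)
  off_geno <- genotype_matrix(hap_a = draw_gametes(series$genotypes, ia),
                              hap_b = draw_gametes(series$genotypes, ib))
  offspring <- simulate_population(system, x0, grid, off_geno,
                                   series$loci, env = env, noise = noise,
                                   lambda_ref = lambda_ref, h_int = h_int)
  parental_mean <- colMeans(pheno)
  selected_mean <- colMeans(pheno[sel, , drop = FALSE])
  offspring_mean <- colMeans(offspring$true_states[, Tn, , drop = FALSE][, 1, ])
  list(offspring = offspring, selected_idx = sel, pairs = pairs,
       parental_mean = parental_mean, selected_mean = selected_mean,
       offspring_mean = offspring_mean,
       S = selected_mean - parental_mean,
       observed_delta_z = offspring_mean - parental_mean)
}

#' Multivariate breeder's-equation predictions
#'
#' Given a selection differential `S`, the predicted one-generation change
#' in trait means is \eqn{\Delta\bar z = G\beta} with selection gradient
#' \eqn{\beta = P^{-1} S}.  When P is used as a proxy for G the prediction
#' collapses to \eqn{P P^{-1} S = S}.
#'
#' @param S selection differential vector.
#' @param G additive-genetic covariance matrix (or [build_G()] list).
#' @param P phenotypic covariance matrix.
#' @return List with `beta`, `pred_G` (\eqn{G\beta}) and `pred_P` (= `S`).
#' @export
breeders_prediction <- function(S, G, P) {
  if (is.list(G)) G <- G$G
  beta <- tryCatch(solve(P, S),
                   error = function(e) stop("P is singular: ",
                                            conditionMessage(e)))
  list(beta = beta, pred_G = as.numeric(G %*% beta), pred_P = as.numeric(S))
}

#' Assemble a selection-response report
#'
#' Combines the realized response of one generation of selection with
#' breeder's-equation predictions based on the true G and on P as a proxy,
#' and their (axial) angles with the observed change.
#'
#' @param breeding result of [select_and_breed()].
#' @param G additive-genetic covariance matrix at the final time.
#' @param P phenotypic covariance matrix used for the selection gradient
#'   (e.g. the empirical phenotypic covariance of the full parental
#'   generation).
#' @return List of class `response_report` with the means, `S`,
#'   `observed_delta_z`, `predicted_delta_z_G`, `predicted_delta_z_P`,
#'   `angle_G_obs`, `angle_P_obs` (degrees, axial; `NA` with a flag when
#'   the selection differential is zero).
#' @export
response_report <- function(breeding, G, P) {
  pred <- breeders_prediction(breeding$S, G, P)
  obs <- breeding$observed_delta_z
  zero_S <- sqrt(sum(breeding$S^2)) == 0
  ang <- function(u) {
    if (zero_S || sqrt(sum(u^2)) == 0 || sqrt(sum(obs^2)) == 0) {
      return(NA_real_)
    }
    vec_angle(u, obs, "axial")
  }
  structure(list(parental_mean = breeding$parental_mean,
                 selected_mean = breeding$selected_mean,
                 offspring_mean = breeding$offspring_mean,
                 S = breeding$S,
                 observed_delta_z = obs,
                 predicted_delta_z_G = pred$pred_G,
                 predicted_delta_z_P = pred$pred_P,
                 beta = pred$beta,
                 angle_G_obs = ang(pred$pred_G),
                 angle_P_obs = ang(pred$pred_P),
                 zero_selection = zero_S),
            class = "response_report")
}
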