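#' Noise configuration for population simulations
#'
#' Both noise sources scale with the current absolute trait value:
#' developmental noise is an independent Gaussian perturbation added to each
#' state at each unit step of development (SD `dev_sd_rel * |state|`),
#' measurement noise is added once to the recorded values
#' (SD `meas_sd_rel * |state|`).
#'
#' @param dev_sd_rel developmental-noise SD as a fraction of the current
#'   state value (typical range 0.01-0.20).
#' @param meas_sd_rel measurement-noise SD as a fraction of the state value
#'   (typical range 0.01-0.08).
#' @param seed optional integer seed drawn on at simulation time.
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(dev_sd_rel = 0, meas_sd_rel = 0, seed = NULL) {
  stopifnot(dev_sd_rel >= 0, meas_sd_rel >= 0)
  structure(list(dev_sd_rel = dev_sd_rel, meas_sd_rel = meas_sd_rel,
                 seed = seed),
            class = "noise_config")
}

#' Environmental specification
#'
#' One environmentally determined developmental parameter, drawn
#' independently per individual from a zero-mean Gaussian.
#'
#' @param target_param parameter index perturbed by the environment.
#' @param sd standard deviation of the per-individual draw.
#' @return Object of class `env_spec` (a one-row data.frame usable as an
#'   environmental-factor table for covariance construction).
#' @export
env_spec <- function(target_param, sd) {
  structure(data.frame(target_param = as.integer(target_param), sd = sd),
            class = c("env_spec", "data.frame"))
}

#' Simulate a population of developmental trajectories
#'
#' Maps each genotype (plus an optional environmental draw) to its
#' developmental parameters, integrates development on unit steps with the
#' fixed-step population integrator, applies developmental noise at each
#' step boundary, and finally adds measurement noise to produce the
#' observed series.  Within-step integration is deterministic; with all
#' noise off, a single all-heterozygote individual reproduces
#' [integrate_system()] with `method = "rk4"` bit-for-bit.
#'
#' Negative states after a perturbation are allowed (the model dynamics are
#' defined for them); a message is logged if any state drops below -1.
#'
#' @param system an [ode_system()].
#' @param x0 initial state shared by all individuals.
#' @param grid a [time_grid()]; unit steps match the estimators.
#' @param geno a [genotype_matrix()].
#' @param loci a [loci_table()].
#' @param env an [env_spec()] or `NULL`.
#' @param noise a [noise_config()].
#' @param lambda_ref reference parameter vector.
#' @param h_int internal integrator step.
#' @return Object of class `phenotype_series`: list with `times`,
#'   `observed` and `true_states` (`M x T x n` arrays), `genotypes`,
#'   `env_params` (`M x 1` matrix or `NULL`), `loci`, `lambda`.
#' @export
simulate_population <- function(system, x0, grid, geno, loci, env = NULL,
                                noise = noise_config(),
                                lambda_ref = rep(0, system$n_params),
                                h_int = 0.02) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  M <- nrow(geno$codes)
  n <- system$n_states
  Tn <- length(grid$times)
  L <- genotype_to_parameters(geno, loci, lambda_ref)
  env_params <- NULL
  if (!is.null(env)) {
    draws <- stats::rnorm(M, 0, env$sd)
    L[, env$target_param] <- L[, env$target_param] + draws
    env_params <- matrix(draws, M, 1)
  }
  X0 <- matrix(x0, M, n, byrow = TRUE)
  perturb <- NULL
  if (noise$dev_sd_rel > 0) {
    perturb <- function(j, X) {
      X + matrix(stats::rnorm(length(X)), nrow(X)) *
        (noise$dev_sd_rel * abs(X))
    }
  }
  states <- rk4_population(system, X0, L, grid$times, h_int, perturb)
  true_states <- array(0, dim = c(M, Tn, n))
  for (j in seq_len(Tn)) true_states[, j, ] <- states[[j]]
  if (min(true_states) < -1) {
    message("simulate_population: some states fell below -1 after ",
            "perturbation")
  }
  observed <- true_states
  if (noise$meas_sd_rel > 0) {
    observed <- true_states +
      array(stats::rnorm(length(true_states)), dim = dim(true_states)) *
      (noise$meas_sd_rel * abs(true_states))
  }
  structure(list(times = grid$times, observed = observed,
                 true_states = true_states, genotypes = geno,
                 env_params = env_params, loci = loci, lambda = L),
            class = "phenotype_series")
}

#' @export
print.phenotype_series <- function(x, ...) {
  d <- dim(x$observed)
  cat("<phenotype_series> ", d[1], " individuals x ", d[2], " times x ",
      d[3], " traits\n", sep = "")
  invisible(x)
}

#' Export a phenotype series as tidy data
#'
#' @param series a `phenotype_series`.
#' @return data.frame with columns `individual`, `time`, `trait` (0-based),
#'   `observed`, `true`.
#' @export
phenotype_to_df <- function(series) {
  d <- dim(series$observed)
  data.frame(individual = rep(seq_len(d[1]), times = d[2] * d[3]),
             time = rep(rep(series$times, each = d[1]), times = d[3]),
             trait = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
             observed = as.vector(series$observed),
             true = as.vector(series$true_states))
}

#' Single-locus demonstration population
#'
#' A noise-free population segregating one biallelic locus that targets the
#' first regulatory parameter of the toggle switch, with allele frequencies
#' p = q = 0.5.  By default the genotype composition is fixed at the exact
#' Hardy-Weinberg proportions (M/4 bb, M/2 Bb, M/4 BB) so that the
#' regression estimate of the average effect coincides with the additive
#' value without genotype-sampling error; set `exact_hw = FALSE` for
#' binomial sampling instead.
#'
#' @param seed integer seed (used only when `exact_hw = FALSE`).
#' @param gamma per-allele effect on the parameter.
#' @param M population size (a multiple of 4 when `exact_hw = TRUE`).
#' @param t_end end of development.
#' @param exact_hw use the fixed exact Hardy-Weinberg genotype composition
#'   (default `TRUE`); otherwise sample genotypes binomially.
#' @return List with the `series`, the `loci` table, the variational
#'   `sens`itivity set, the `truth` array of linear average effects, the
#'   `system`, `grid`, `x0` and `lambda_ref`.
#' @export
scenario_single_locus <- function(seed = 1, gamma = 1e-2, M = 20,
                                  t_end = 50, exact_hw = TRUE) {
  system <- toggle_switch(env = FALSE)
  grid <- time_grid(0, t_end, 1)
  x0 <- c(0, 0)
  lambda_ref <- c(0, 0)
  loci <- loci_table(target_param = 1, gamma = gamma, freq_B = 0.5)
  if (exact_hw) {
    stopifnot(M %% 4 == 0)
    codes <- matrix(rep(c(-1, 0, 1), times = c(M / 4, M / 2, M / 4)),
                    ncol = 1)
    geno <- genotype_matrix(codes = codes)
  } else {
    geno <- sample_genotypes(loci, M, seed = seed)
  }
  series <- simulate_population(system, x0, grid, geno, loci,
                                lambda_ref = lambda_ref)
  sens <- sensitivities_variational(system, x0, lambda_ref, grid)
  list(series = series, loci = loci, sens = sens,
       truth = average_effect_linear(sens, loci),
       system = system, grid = grid, x0 = x0, lambda_ref = lambda_ref)
}

#' Replicated populations across a noise / sample-size grid
#'
#' Generates replicate populations of the two-parameter toggle switch with
#' 10 loci per developmental parameter (all at allele frequency 0.5),
#' per-replicate allelic effects drawn from a zero-mean Gaussian, and the
#' requested developmental and measurement noise.  Used to score the static
#' and dynamic average-effect estimators.
#'
#' @param M population size.
#' @param dev_sd_rel,meas_sd_rel relative noise levels.
#' @param n_replicates number of replicate populations.
#' @param seed integer seed for the whole batch.
#' @param gamma_sd SD of the per-locus allelic effects (default 0.01).
#' @param n_loci_per_param loci per developmental parameter (default 10).
#' @param t_end end of development.
#' @return List of bundles; each has `series`, `loci`, `truth` (linear
#'   average effects for trait arrays), and shares `sens`, `system`,
#'   `grid`.
#' @export
scenario_noise_grid <- function(M, dev_sd_rel, meas_sd_rel,
                                n_replicates = 100, seed = 1,
                                gamma_sd = 0.01, n_loci_per_param = 10,
                                t_end = 50) {
  system <- toggle_switch(env = FALSE)
  grid <- time_grid(0, t_end, 1)
  x0 <- c(0, 0)
  lambda_ref <- c(0, 0)
  sens <- sensitivities_variational(system, x0, lambda_ref, grid)
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    loci <- loci_table(
      target_param = rep(1:2, each = n_loci_per_param),
      gamma = stats::rnorm(2 * n_loci_per_param, 0, gamma_sd),
      freq_B = rep(0.5, 2 * n_loci_per_param))
    geno <- sample_genotypes(loci, M)
    series <- simulate_population(
      system, x0, grid, geno, loci,
      noise = noise_config(dev_sd_rel, meas_sd_rel),
      lambda_ref = lambda_ref)
    list(series = series, loci = loci,
         truth = average_effect_linear(sens, loci))
  })
  list(replicates = reps, sens = sens, system = system, grid = grid,
       x0 = x0, lambda_ref = lambda_ref)
}

#' Population for the covariance-alignment and selection scenarios
#'
#' A population of the environmentally extended toggle switch: 10 loci on
#' each genetic parameter, the first at allele frequency 0.5 and the second
#' at `maf_lambda2`; per-locus effects drawn from a zero-mean Gaussian
#' (SD `1e-4`); the environmental parameter drawn per individual from a
#' zero-mean Gaussian (SD `1.5e-3`); development integrated noise-free to
#' `t_end = 50`.
#'
#' @param maf_lambda2 minor allele frequency of the loci targeting the
#'   second regulatory parameter (e.g. 0.001, 0.016, 0.5).
#' @param seed integer seed.
#' @param M population size (default 5000).
#' @param gamma_sd SD of per-locus allelic effects.
#' @param env_sd SD of the environmental parameter.
#' @param n_loci_per_param loci per genetic parameter.
#' @param t_end end of development.
#' @param h_int internal integrator step.
#' @param simulate integrate the population (`TRUE`, default); set `FALSE`
#'   to draw only the architecture, e.g. for analytic covariance work.
#' @return List with `series` (`NULL` when `simulate = FALSE`), `loci`,
#'   `env`, `sens` (variational, at the reference), `system`, `grid`,
#'   `x0`, `lambda_ref`.
#' @export
scenario_maf_alignment <- function(maf_lambda2, seed = 1, M = 5000,
                                   gamma_sd = 1e-4, env_sd = 1.5e-3,
                                   n_loci_per_param = 10, t_end = 50,
                                   h_int = 0.05, simulate = TRUE) {
  system <- toggle_switch(env = TRUE)
  grid <- time_grid(0, t_end, 1)
  x0 <- c(0, 0)
  lambda_ref <- c(0, 0, 0)
  set.seed(seed)
  loci <- loci_table(
    target_param = rep(1:2, each = n_loci_per_param),
    gamma = stats::rnorm(2 * n_loci_per_param, 0, gamma_sd),
    freq_B = rep(c(0.5, maf_lambda2), each = n_loci_per_param))
  env <- env_spec(target_param = 3, sd = env_sd)
  series <- NULL
  if (simulate) {
    geno <- sample_genotypes(loci, M)
    series <- simulate_population(system, x0, grid, geno, loci, env = env,
                                  lambda_ref = lambda_ref, h_int = h_int)
  }
  sens <- sensitivities_variational(system, x0, lambda_ref, grid)
  list(series = series, loci = loci, env = env, sens = sens,
       system = system, grid = grid, x0 = x0, lambda_ref = lambda_ref)
}
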