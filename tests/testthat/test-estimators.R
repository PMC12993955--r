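test_that("static regression recovers exact and small-effect truths", {
  sc <- scenario_single_locus(seed = 1)
  est <- static_average_effects(sc$series, trait_index = 1)
  # noise-free balanced population: slope equals the additive value
  idx <- function(code) which(sc$series$genotypes$codes[, 1] == code)[1]
  a_t <- (sc$series$true_states[idx(1), , 1] -
            sc$series$true_states[idx(-1), , 1]) / 2
  expect_lt(max(abs(est$alpha_s[, 1] - a_t)), 1e-10)
  # permuting individuals leaves the estimate unchanged
  perm <- sample(nrow(sc$series$genotypes$codes))
  series2 <- sc$series
  series2$observed <- sc$series$observed[perm, , , drop = FALSE]
  series2$true_states <- sc$series$true_states[perm, , , drop = FALSE]
  series2$genotypes <- genotype_matrix(
    codes = sc$series$genotypes$codes[perm, , drop = FALSE])
  est2 <- static_average_effects(series2, trait_index = 1)
  expect_equal(est2$alpha_s, est$alpha_s)
  # multi-locus small effects match the sensitivity truth closely
  sys <- toggle_switch(env = FALSE)
  grid <- time_grid(0, 20, 1)
  loci <- loci_table(target_param = c(1, 1, 2), gamma = c(1e-3, -2e-3, 1e-3),
                     freq_B = c(0.5, 0.5, 0.5))
  geno <- sample_genotypes(loci, 200, seed = 6)
  series <- simulate_population(sys, c(0, 0), grid, geno, loci)
  est3 <- static_average_effects(series, trait_index = 2)
  sv <- sensitivities_variational(sys, c(0, 0), c(0, 0), grid)
  truth <- average_effect_linear(sv, loci)[, 2, ]
  expect_lt(max(abs(est3$alpha_s[-1, ] - truth[-1, ])),
            50 * max(abs(loci$gamma))^2)
})

test_that("degenerate designs are rejected with informative errors", {
  sc <- scenario_single_locus(seed = 1)
  small <- sc$series
  keep <- 1:2
  small$observed <- sc$series$observed[keep, , , drop = FALSE]
  small$true_states <- sc$series$true_states[keep, , , drop = FALSE]
  small$genotypes <- genotype_matrix(
    codes = sc$series$genotypes$codes[keep, , drop = FALSE])
  expect_error(static_average_effects(small), "population size")
  dup <- sc$series
  dup$genotypes <- genotype_matrix(
    codes = cbind(sc$series$genotypes$codes, sc$series$genotypes$codes))
  expect_error(static_average_effects(dup), "collinear")
})

test_that("the Kalman filter has the correct limiting behaviour", {
  sc <- scenario_single_locus(seed = 1, gamma = 1e-2, exact_hw = FALSE)
  noisy <- sc$series
  set.seed(8)
  noisy$observed <- noisy$true_states +
    array(rnorm(length(noisy$true_states)), dim = dim(noisy$true_states)) *
    (0.05 * abs(noisy$true_states))
  st <- static_average_effects(noisy, trait_index = 1)
  # infinite process noise: the filter reduces to the observations
  dyn <- kalman_average_effects(st, Q = 1e12)
  expect_lt(max(abs(dyn$alpha_d - st$alpha_s)), 1e-6 * max(abs(st$alpha_s)))
  # Q = 0 with a diffuse prior: running inverse-variance-weighted mean
  Tn <- length(st$times)
  obs <- rnorm(Tn, 1, 0.3)
  R <- runif(Tn, 0.2, 2)
  fake <- list(times = st$times, alpha_s = matrix(obs),
               se = matrix(sqrt(R)))
  class(fake) <- "static_estimate"
  dyn0 <- kalman_average_effects(fake, Q = 0, init_var = 1e9)
  ivw <- cumsum(obs / R) / cumsum(1 / R)
  expect_lt(max(abs(dyn0$alpha_d[Tn, 1] - ivw[Tn])), 1e-6)
  # filtered variance never increases when Q = 0 and R is constant
  fake2 <- fake
  fake2$se <- matrix(0.5, Tn, 1)
  dynv <- kalman_average_effects(fake2, Q = 0, init_var = 10)
  expect_true(all(diff(dynv$var_d[, 1]) <= 1e-15))
})

test_that("the scalar filter agrees with a brute-force grid filter", {
  set.seed(13)
  Tn <- 30
  truth <- cumsum(c(0, rnorm(Tn - 1, 0, 0.1)))
  R <- runif(Tn, 0.02, 0.08)
  obs <- truth + rnorm(Tn, 0, sqrt(R))
  fake <- list(times = seq_len(Tn) - 1, alpha_s = matrix(obs),
               se = matrix(sqrt(R)))
  class(fake) <- "static_estimate"
  dyn <- kalman_average_effects(fake, Q = 0.01, init_mean = 0,
                                init_var = 0.04)
  oracle <- oracle_grid_filter(obs, R, Q = 0.01, init_mean = 0,
                               init_var = 0.04, lo = -4, hi = 4,
                               ngrid = 4001)
  expect_lt(max(abs(dyn$alpha_d[, 1] - oracle)), 1e-6)
})

test_that("the smoothing pass reduces to the filter at the final time", {
  sc <- scenario_single_locus(seed = 1, exact_hw = FALSE)
  st <- static_average_effects(sc$series)
  dyn <- kalman_average_effects(st, Q = 1e-8, smooth = TRUE)
  Tn <- length(st$times)
  expect_equal(dyn$alpha_smooth[Tn, ], dyn$alpha_d[Tn, ])
})

test_that("relative error summarises elementwise deviation", {
  truth <- matrix(1:12, 4, 3)
  expect_equal(relative_error(truth, truth)$mean, 0)
  expect_equal(relative_error(2 * truth, truth)$mean, 1)
  expect_error(relative_error(truth * 0, truth * 0), "identically zero")
  # first row (t0) is excluded
  est <- truth; est[1, ] <- 99
  expect_equal(relative_error(est, truth)$mean, 0)
})

test_that("dynamic estimates beat static ones on a noisy replicate set", {
  gr <- driver_estimator_grid(seed = 5, M_values = 64,
                              meas_values = 0.08, dev_values = 0.01,
                              n_replicates = 12)
  cells <- gr$cells
  expect_lt(cells$err_dynamic, cells$err_static)
  expect_gte(cells$n_dynamic_better, 9)
})
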