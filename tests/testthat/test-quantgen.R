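test_that("the additive genotype-to-parameter map anchors at the reference", {
  loci <- loci_table(target_param = c(1, 1, 2), gamma = c(0.1, 0.2, 0.3),
                     freq_B = c(0.5, 0.5, 0.5))
  lref <- c(1, -1)
  codes <- rbind(c(0, 0, 0),    # all heterozygote
                 c(1, 0, 0),    # BB at locus 1
                 c(-1, 0, 0),   # bb at locus 1
                 c(1, 1, 0))    # two loci on the same parameter
  L <- genotype_to_parameters(codes, loci, lref)
  expect_equal(L[1, ], lref)
  expect_equal(L[2, ], lref + c(0.1, 0))
  expect_equal(L[3, ], lref - c(0.1, 0))
  expect_equal(L[4, ], lref + c(0.1 + 0.2, 0))
})

test_that("genotypic values collapse and expand with the allelic effect", {
  sys <- toggle_switch(env = FALSE)
  grid <- time_grid(0, 20, 1)
  gv0 <- genotypic_values(sys, c(0, 0), grid, 0, 1, c(0, 0))
  expect_equal(gv0$x_bb$states, gv0$x_BB$states)
  expect_equal(gv0$x_bb$states, gv0$x_Bb$states)
  # x_BB - x_Bb tracks gamma * s to second order (halving gamma -> ~4x)
  sv <- sensitivities_variational(sys, c(0, 0), c(0, 0), grid)
  err <- vapply(c(2e-3, 1e-3), function(g) {
    gv <- genotypic_values(sys, c(0, 0), grid, g, 1, c(0, 0))
    max(abs(gv$x_BB$states - gv$x_Bb$states - g * sv$s[, , 1]))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.3)
  # homozygote midpoint deviation matches the curvature term
  g <- 1e-2
  gv <- genotypic_values(sys, c(0, 0), grid, g, 1, c(0, 0))
  so <- second_order_fd(sys, c(0, 0), c(0, 0), grid)
  mid <- (gv$x_BB$states + gv$x_bb$states) / 2 - gv$x_Bb$states
  pred <- so$s1[, , 1] * g^2 / 2
  keep <- abs(pred) > 1e-8
  expect_lt(max(abs(mid[keep] - pred[keep]) / abs(pred[keep])), 0.05)
})

test_that("effect curves implement the classical decomposition", {
  sys <- toggle_switch(env = FALSE)
  grid <- time_grid(0, 30, 1)
  gv <- genotypic_values(sys, c(0, 0), grid, 1e-2, 1, c(0, 0))
  ec <- effect_curves(gv$x_bb, gv$x_Bb, gv$x_BB, q = 0.5)
  # q = p: average effect equals the additive value
  expect_equal(ec$alpha, ec$a)
  # identical trajectories give zero effects
  ec0 <- effect_curves(gv$x_Bb, gv$x_Bb, gv$x_Bb, q = 0.3)
  expect_equal(max(abs(ec0$a)), 0)
  expect_equal(max(abs(ec0$d)), 0)
  expect_equal(max(abs(ec0$alpha)), 0)
  # alpha tracks s * gamma within 2% late in development
  sv <- sensitivities_variational(sys, c(0, 0), c(0, 0), grid)
  win <- grid$times >= 5
  rel <- abs(ec$alpha[win, 1] - sv$s[win, 1, 1] * 1e-2) /
    abs(sv$s[win, 1, 1] * 1e-2)
  expect_lt(max(rel), 0.02)
})

test_that("regression slope equals a + d(q - p) on exact HW populations", {
  # frequency-weighted OLS identity, checked on populations whose genotype
  # counts sit exactly at Hardy-Weinberg proportions
  sys <- toggle_switch(env = FALSE)
  grid <- time_grid(0, 20, 1)
  gv <- genotypic_values(sys, c(0, 0), grid, 0.5, 1, c(0, 0))
  for (q in c(0.3, 0.5, 0.9)) {
    p <- 1 - q
    counts <- round(100 * c(p^2, 2 * p * q, q^2))
    stopifnot(sum(counts) == 100)
    codes <- matrix(rep(c(-1, 0, 1), counts), ncol = 1)
    Tn <- length(grid$times)
    states <- array(0, dim = c(100, Tn, 2))
    states[codes == -1, , ] <- rep(gv$x_bb$states, each = sum(codes == -1))
    states[codes == 0, , ] <- rep(gv$x_Bb$states, each = sum(codes == 0))
    states[codes == 1, , ] <- rep(gv$x_BB$states, each = sum(codes == 1))
    series <- structure(list(times = grid$times, observed = states,
                             true_states = states,
                             genotypes = genotype_matrix(codes = codes)),
                        class = "phenotype_series")
    est <- static_average_effects(series, trait_index = 1)
    ec <- effect_curves(gv$x_bb, gv$x_Bb, gv$x_BB, q = q)
    expect_lt(max(abs(est$alpha_s[, 1] - ec$alpha[, 1])), 1e-10)
  }
})

test_that("linear average effects scale with gamma and vanish at t0", {
  cache <- ts_env()
  loci <- loci_table(target_param = c(1, 1, 2), gamma = c(0, 1e-3, 2e-3),
                     freq_B = c(0.5, 0.5, 0.5))
  al <- average_effect_linear(cache$sens, loci)
  expect_equal(max(abs(al[, , 1])), 0)            # gamma = 0
  expect_equal(al[1, , ], matrix(0, 2, 3))        # t0
  loci2 <- loci_table(target_param = c(1, 1), gamma = c(1e-3, 2e-3),
                      freq_B = c(0.5, 0.5))
  al2 <- average_effect_linear(cache$sens, loci2)
  expect_equal(al2[, , 2], 2 * al2[, , 1])        # linearity in gamma
})

test_that("genotype sampling respects frequencies and seeds", {
  loci <- loci_table(target_param = c(1, 1), gamma = c(1, 1),
                     freq_B = c(1, 0.5))
  g1 <- sample_genotypes(loci, 1e5, seed = 3)
  expect_true(all(g1$codes[, 1] == 1))            # q = 1: all BB
  freq <- table(factor(g1$codes[, 2], levels = -1:1)) / 1e5
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.01)
  g2 <- sample_genotypes(loci, 1e5, seed = 3)
  expect_identical(g1$codes, g2$codes)
  # codes are consistent with the stored haplotypes
  expect_equal(g1$codes, g1$hap_a + g1$hap_b - 1)
})
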