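test_that("variational sensitivities start at zero and match closed forms", {
  # 1-D linear system xdot = lambda - x: s(t) = 1 - exp(-t)
  lin <- ode_system(1, 1, function(t, x, l) l - x,
                    jac_x = function(t, x, l) matrix(-1),
                    jac_lambda = function(t, x, l) matrix(1),
                    name = "linear")
  grid <- time_grid(0, 10, 0.5)
  sv <- sensitivities_variational(lin, 0, 0, grid)
  expect_equal(sv$s[1, , ], 0)
  expect_lt(max(abs(sv$s[, 1, 1] - (1 - exp(-grid$times)))), 1e-6)
})

test_that("variational and finite-difference routes agree on the switch", {
  cache <- ts_env()
  sv <- cache$sens
  sf <- sensitivities_fd(cache$sys, c(0, 0), c(0, 0, 0), cache$grid,
                         delta = 1e-5)
  expect_equal(sf$s[1, , ], matrix(0, 2, 3))
  rel <- abs(sv$s[-1, , ] - sf$s[-1, , ]) / abs(sf$s[-1, , ])
  expect_lt(max(rel), 1e-3)
})

test_that("numeric-Jacobian fallback reproduces analytic variational output", {
  cache <- ts_env()
  nojac <- ode_system(2, 3, cache$sys$rhs, name = "numeric")
  sv_num <- sensitivities_variational(nojac, c(0, 0), c(0, 0, 0),
                                      time_grid(0, 20, 1))
  expect_lt(max(abs(sv_num$s - cache$sens$s[1:21, , ])) /
              max(abs(cache$sens$s[1:21, , ])), 1e-5)
})

test_that("finite differences vanish for parameter-free dynamics and converge", {
  free <- ode_system(1, 1, function(t, x, l) -0.5 * x, name = "free")
  sf <- sensitivities_fd(free, 1, 0, time_grid(0, 5, 1), delta = 1e-4)
  expect_lt(max(abs(sf$s)), 1e-8)
  cache <- ts_env()
  a <- sensitivities_fd(cache$sys, c(0, 0), c(0, 0, 0), cache$grid,
                        delta = 1e-4)
  b <- sensitivities_fd(cache$sys, c(0, 0), c(0, 0, 0), cache$grid,
                        delta = 5e-5)
  expect_lt(max(abs(a$s[-1, , ] - b$s[-1, , ])) / max(abs(b$s)), 1e-4)
})

test_that("second-order sensitivities match closed form and vanish for linear maps", {
  lin <- ode_system(1, 1, function(t, x, l) l - x, name = "linear")
  so <- second_order_fd(lin, 0, 0, time_grid(0, 5, 1), delta = 1e-3)
  expect_lt(max(abs(so$s1)), 1e-4)
  # xdot = lambda^2 - x at lambda*=1: d2x/dlambda2 = 2(1-exp(-t))
  quad <- ode_system(1, 1, function(t, x, l) l^2 - x, name = "quad")
  grid <- time_grid(0, 5, 1)
  so2 <- second_order_fd(quad, 0, 1, grid, delta = 1e-2)
  expect_lt(max(abs(so2$s1[, 1, 1] - 2 * (1 - exp(-grid$times)))), 1e-5)
})

test_that("linearity in the perturbation holds to second order", {
  cache <- ts_env()
  grid <- cache$grid
  errs <- vapply(c(2e-3, 1e-3), function(g) {
    lam <- c(g, 0, 0)
    tr <- integrate_system(cache$sys, c(0, 0), lam, grid)
    ref <- cache$sens$reference$states
    max(abs(tr$states - ref - g * cache$sens$s[, , 1]))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.4)
  expect_lt(errs[1] / errs[2], 4.6)
})

test_that("regression sensitivities recover linear maps and black-box systems", {
  set.seed(42)
  # exact linear map x(t) = S(t) lambda
  times <- 0:5
  S_true <- lapply(times, function(t) matrix(c(t, 2 * t, -t, 0.5 * t), 2))
  draws <- matrix(rnorm(20, 0, 1e-2), 10, 2)
  trajs <- lapply(seq_len(nrow(draws)), function(r) {
    st <- t(vapply(seq_along(times),
                   function(j) as.numeric(S_true[[j]] %*% draws[r, ]),
                   numeric(2)))
    st
  })
  sr <- sensitivities_regression(trajs, draws, c(0, 0), times)
  for (j in seq_along(times)) {
    expect_lt(max(abs(sr$s[j, , ] - S_true[[j]])), 1e-10)
  }
  # duplicated runs leave the estimate unchanged
  sr2 <- sensitivities_regression(c(trajs, trajs), rbind(draws, draws),
                                  c(0, 0), times)
  expect_equal(sr2$s, sr$s)
  # rank-deficient design is reported
  bad <- cbind(draws[, 1], draws[, 1])
  expect_error(sensitivities_regression(trajs, bad, c(0, 0), times),
               "collinear")
})

test_that("regression route matches variational sensitivities on the switch", {
  cache <- ts_env()
  set.seed(7)
  R <- 200
  draws <- matrix(rnorm(R * 3, 0, 1e-3), R, 3)
  trajs <- lapply(seq_len(R), function(r) {
    integrate_system(cache$sys, c(0, 0), draws[r, ], cache$grid,
                     method = "rk4", h_int = 0.05)$states
  })
  sr <- sensitivities_regression(trajs, draws, c(0, 0, 0),
                                 cache$grid$times)
  at50 <- function(s) s[51, , ]
  rel <- abs(at50(sr$s) - at50(cache$sens$s)) / max(abs(at50(cache$sens$s)))
  expect_lt(max(rel), 0.02)
})

test_that("angles follow the directed and axial conventions", {
  expect_equal(vec_angle(c(1, 1), c(2, 2)), 0, tolerance = 1e-5)
  expect_equal(vec_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(vec_angle(c(1, 0), c(-1, 0)), 180)
  expect_equal(vec_angle(c(1, 0), c(-1, 0), "axial"), 0, tolerance = 1e-5)
  expect_error(vec_angle(c(0, 0), c(1, 0)), "zero")
  # invariant to positive rescaling
  set.seed(1)
  for (i in 1:10) {
    u <- rnorm(3); v <- rnorm(3)
    expect_equal(vec_angle(u, v), vec_angle(10 * u, 0.01 * v),
                 tolerance = 1e-9)
  }
})

test_that("random-angle null has the sin^(d-2) law", {
  null4 <- random_angle_null(4, 2e4, seed = 11)
  expect_lt(abs(mean(null4$angles_deg) - 90), 1)
  # density integrates to one
  expect_lt(abs(stats::integrate(null4$density, 0, 180)$value - 1), 1e-6)
  # dim 2 is uniform on [0, 180]
  null2 <- random_angle_null(2, 2e4, seed = 12)
  ks <- max(abs(seq_along(null2$angles_deg) / length(null2$angles_deg) -
                  sort(null2$angles_deg) / 180))
  expect_lt(ks, 0.015)
})
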