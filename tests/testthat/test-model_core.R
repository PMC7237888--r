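test_that("per-capita growth matches the growth law on hand-computed cases", {
  k <- killing_spec(0.25, 5)
  # wild type at its set-point has zero growth (to rounding), for any gamma, n
  for (g in c(0, 0.1, 0.25, 1, 2)) {
    for (n in c(1, 2, 5, 8)) {
      expect_lt(abs(per_capita_growth(1, 1 + g, 1, killing_spec(g, n))),
                1e-15)
    }
  }
  # hypersecretor in wild-type tissue: 2*1.25 - 1 - 0.25*2^5
  expect_equal(per_capita_growth(2, 1.25, 1, k), -6.5)
  # mutant-only tissue: killing normalized away, 2*1.25 - 1 - 0.25
  expect_equal(per_capita_growth(2, 1.25, 2, k), 1.25)
  expect_error(per_capita_growth(2, 1.25, 0, k),
               class = "ashm_degenerate_tissue")
})

test_that("QSS signal is p_hat over perceived abundance and degrades safely", {
  g <- 0.25
  expect_equal(qss_signal(clones(u = 1, x = 1), p_hat = 1 + g), 1 + g)
  expect_equal(qss_signal(clones(u = 2, x = 1), p_hat = 2), 1)
  expect_equal(qss_signal(clones(u = c(1, 2), x = c(0.5, 0.25)), p_hat = 1), 1)
  # homogeneity of degree -1 in total abundance
  cl <- clones(u = c(1, 2, 0.7), x = c(0.3, 0.1, 0.9))
  cl2 <- clones(u = cl$u, x = 2 * cl$x)
  expect_equal(qss_signal(cl2, 1.3), qss_signal(cl, 1.3) / 2)
  expect_error(qss_signal(clones(u = 1, x = 0), 1),
               class = "ashm_degenerate_tissue")
})

test_that("mean distortion is the abundance-weighted mean and is bracketed", {
  expect_equal(mean_distortion(clones(u = 1, x = 1)), 1)
  expect_equal(mean_distortion(clones(u = c(1, 2), x = c(1, 1))), 1.5)
  expect_equal(mean_distortion(clones(u = c(1, 2), x = c(3, 1))), 1.25)
  set.seed(7)
  for (i in 1:20) {
    cl <- clones(u = runif(4, 0.2, 3), x = runif(4, 0, 2) + 0.01)
    ub <- mean_distortion(cl)
    expect_gte(ub, min(cl$u))
    expect_lte(ub, max(cl$u))
  }
  expect_error(mean_distortion(clones(u = c(1, 2), x = c(0, 0))),
               class = "ashm_degenerate_tissue")
})

test_that("closed-form wild-type steady state matches the dimensional ODE", {
  up <- unscaled_params(mu0 = 1, s0 = 1, g0 = 1, a = 0.25, p = 1, r = 1,
                        b = 1, alpha = 1)
  ss <- wild_type_steady_state(up, killing_spec(0.25, 5))
  expect_equal(ss$s_star, 1.25)
  expect_equal(ss$x_star, 1 / 1.25^2)
  expect_equal(ss$y_star, 1 / 1.25)

  # no-surveillance limit
  up0 <- unscaled_params(mu0 = 2, s0 = 1.5, g0 = 1, a = 1e-12, p = 3, r = 0.8,
                         b = 1.2, alpha = 0.9)
  ss0 <- wild_type_steady_state(up0, killing_spec(0, 5))
  expect_equal(ss0$s_star, up0$s0, tolerance = 1e-9)
  expect_equal(ss0$x_star, up0$p * up0$alpha / (up0$r * up0$b * up0$s0^2),
               tolerance = 1e-9)

  # signal set-point depends only on s0 and gamma, not on p, r, b, alpha
  up_alt <- unscaled_params(mu0 = 1, s0 = 1, g0 = 1, a = 0.25, p = 7, r = 3,
                            b = 0.4, alpha = 2.2)
  expect_equal(wild_type_steady_state(up_alt, killing_spec(0.25, 5))$s_star,
               ss$s_star)

  # integrating the full three-variable system from a perturbed start
  # converges to the closed-form set-points
  set.seed(11)
  for (i in 1:3) {
    upr <- unscaled_params(mu0 = runif(1, 0.5, 2), s0 = runif(1, 0.5, 2),
                           g0 = 1, a = runif(1, 0.05, 0.5),
                           p = runif(1, 0.5, 2), r = runif(1, 0.5, 2),
                           b = runif(1, 0.5, 2), alpha = runif(1, 0.5, 2))
    ssr <- wild_type_steady_state(upr, killing_spec(1, 5))
    orc <- unscaled_oracle(u = 1, x0 = ssr$x_star * 1.3, up = upr, n_hill = 5,
                           s_init = ssr$s_star * 0.8, y_init = ssr$y_star * 1.2,
                           t_end = 3000, n_steps = 150)
    last <- length(orc$times)
    expect_equal(orc$s[last], ssr$s_star, tolerance = 1e-6)
    expect_equal(orc$y[last], ssr$y_star, tolerance = 1e-6)
    expect_equal(unname(orc$x[last, 1]), ssr$x_star, tolerance = 1e-6)
  }
})

test_that("rescaling reproduces gamma and p_hat and commutes with simulation", {
  up <- unscaled_params(mu0 = 1, s0 = 1, g0 = 1, a = 0.25, p = 1.25, r = 100,
                        b = 1, alpha = 100)
  sp <- rescale(up, n = 5)
  expect_equal(sp$killing$gamma, 0.25)
  expect_equal(sp$p_hat, 1.25)
  expect_equal(attr(sp, "time_unit"), 1)

  ones <- unscaled_params(mu0 = 1, s0 = 1, g0 = 1, a = 1, p = 1, r = 1,
                          b = 1, alpha = 1)
  sp1 <- rescale(ones, n = 2)
  expect_equal(sp1$killing$gamma, 1)
  expect_equal(sp1$p_hat, 1)

  # time rescaling commutes with simulation: integrating in dimensional time
  # with (mu0, s0, a) and sampling at t = mu0*s0*tau matches the rescaled
  # model, on random parameter draws
  set.seed(23)
  for (i in 1:3) {
    mu0 <- runif(1, 0.5, 2); s0 <- runif(1, 0.5, 2); a <- runif(1, 0.05, 0.6)
    spr <- rescale(unscaled_params(mu0 = mu0, s0 = s0, g0 = 1, a = a,
                                   p = (1 + a / (mu0 * s0)) * s0^2,
                                   r = 1, b = 1, alpha = 1), n = 5)
    cl0 <- clones(u = c(1, 2, 0.5), x = c(1, 0.4, 0.3))
    t_scaled <- 8
    tr <- simulate_clones(cl0, spr, t_end = t_scaled, n_steps = 80)
    orc <- dimensional_qss_oracle(u = cl0$u, x0 = cl0$x, mu0 = mu0, s0 = s0,
                                  a = a, p_hat = spr$p_hat, n_hill = 5,
                                  t_end = t_scaled / (mu0 * s0), n_steps = 80)
    expect_lt(max(abs(t(tr$abundances) - orc$x)), 1e-6)
  }

  # the full three-variable model reaches the same verdicts as the reduced
  # model: mutant eliminated at the ESS strength, signal back at s0*(1+gamma)
  cl0 <- clones(u = c(1, 2), x = c(1, 0.5))
  tr <- simulate_clones(cl0, sp, t_end = 60, n_steps = 100)
  ss <- wild_type_steady_state(up, killing_spec(0.25, 5))
  orc <- unscaled_oracle(u = cl0$u, x0 = cl0$x * ss$x_star, up = up,
                         n_hill = 5, s_init = ss$s_star, y_init = ss$y_star,
                         t_end = 60, n_steps = 100)
  last <- 101
  expect_identical(tr$outcome, c("persists", "extinct"))
  expect_lt(orc$x[last, 2] / ss$x_star, 1e-6)            # mutant eliminated
  expect_equal(unname(orc$x[last, 1]) / ss$x_star, 1, tolerance = 1e-4)
  expect_equal(orc$s[last], ss$s_star, tolerance = 1e-4)
  expect_equal(tr$s_rel[last] * up$s0, ss$s_star, tolerance = 1e-4)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(killing_spec(-0.1, 5), "gamma")
  expect_error(killing_spec(0.25, 0.5), "n")
  expect_error(unscaled_params(mu0 = 0, s0 = 1, g0 = 1, a = 1, p = 1, r = 1,
                               b = 1, alpha = 1), "positive")
  expect_error(scaled_params(killing_spec(0.25, 5), p_hat = -1), "p_hat")
  expect_error(clones(u = c(1, -2), x = 1))
  expect_error(clones(u = 101, x = 1))
  # default p_hat puts the wild-type steady state at x = 1
  sp <- scaled_params(killing_spec(0.4, 5))
  expect_equal(qss_signal(clones(u = 1, x = 1), sp$p_hat), 1.4)
})
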