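test_that("the wave ODE rest point has the splitting the pulse construction needs", {
  lp <- local_params()
  rp <- std_rate()
  sp7 <- rest_point_and_splitting(tw_system(lp, rp, 1, 0.5), 0.65)
  expect_equal(sp7$n_unstable, 2L)
  expect_equal(sp7$n_stable, 5L)
  sp5 <- rest_point_and_splitting(tw_system(lp, rp, 1, 0), 0.65)
  expect_equal(sp5$n_unstable, 1L)
  expect_equal(sp5$n_stable, 4L)
  # the fast pair comes from inverting the inhibitory convolution:
  # eigenvalues close to +-1/sigma_i
  ev <- Re(sp7$values)
  expect_lt(min(abs(ev - 2)), 0.05)
  expect_lt(min(abs(ev + 2)), 0.05)
  # rest point embeds the local rest state with zero kernel slopes
  r <- rest_state(lp, rp)
  expect_equal(sp7$P_bar, c(r, r[1], 0, r[2], 0), tolerance = 1e-12)
})

test_that("the wave ODE reduces to quadrature-consistent derivatives", {
  sys <- tw_system(local_params(), std_rate(), 1, 0.5)
  u <- c(0.03, 0.01, 0.1, 0.025, 0.004, 0.012, -0.002)
  f <- unname(tw_rhs(u, 0.6, sys))
  lp <- sys$lp
  Ge <- lp$g_ee * lp$gamma_e * u[4] - lp$g_ei * lp$gamma_i * u[6] -
    lp$g_ad * lp$gamma_z * u[3]
  expect_equal(f[1], (-u[1] / lp$tau_e + firing_rate(Ge, 1e-4)) / 0.6,
               tolerance = 1e-12)
  expect_equal(f[4], u[5])
  expect_equal(f[5], (u[4] - u[1]) / 1^2)
  expect_equal(f[7], (u[6] - u[2]) / 0.5^2)
})

test_that("reduced-system shooting brackets a pulse with a positive speed", {
  s5 <- fixture("shoot5", function()
    shoot_5d(tw_system(local_params(), std_rate(), 1, 0), tol = 1e-7))
  expect_gt(s5$c, 0.1)
  rest <- s5$splitting$P_bar[1]
  expect_gt(max(s5$traj[, 1]), rest + 10 * max(rest, 1e-4))
})

test_that("the collocation pulse solves the wave equations to tolerance and is robust to truncation", {
  s5 <- fixture("shoot5", function()
    shoot_5d(tw_system(local_params(), std_rate(), 1, 0), tol = 1e-7))
  sys <- tw_system(local_params(), std_rate(), 1, 0.15)
  p1 <- tw_bvp_refine(sys, s5, L_xi = 50, N = 700)
  expect_lt(p1$residual, 1e-9)
  expect_gt(p1$c, 0)
  # interior mesh points satisfy the ODE (independent finite-difference check)
  i <- seq(50, p1$N - 50, by = 13)
  fd <- (t(p1$traj)[, i + 1] - t(p1$traj)[, i - 1]) / (2 * p1$h)
  fmid <- tw_rhs_mat(t(p1$traj)[, i], p1$c, sys)
  expect_lt(max(abs(fd - fmid)), 5e-3)
  # lengthening the truncation interval barely moves the speed
  p2 <- tw_bvp_refine(sys, s5, L_xi = 60, N = 840)
  expect_equal(p1$c, p2$c, tolerance = 2e-4)
})

test_that("the continued pulse speed matches the direct field simulation", {
  p <- baseline_tw_pulse()
  expect_lt(p$residual, 1e-8)
  c_field <- classify_outcome(baseline_field())$speed
  expect_equal(p$c, c_field, tolerance = 0.02)
  # profile ends at the rest state on both sides
  expect_equal(unname(p$traj[1, 1]), p$P_bar[1], tolerance = 1e-3)
  expect_lt(abs(p$traj[nrow(p$traj), 4] - p$P_bar[4]), 0.05)
})

test_that("branch continuation in sigma_i reports monotone slowing", {
  p <- baseline_tw_pulse()
  br <- continue_branch(p, "sigma_i", to = 0.9, ds = 0.1)
  expect_gte(nrow(br$points), 3)
  expect_true(all(diff(br$points$c) < 0))
})
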