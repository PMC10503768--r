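test_that("discrete convolution reproduces the defining identities of the kernels", {
  x <- seq(0, 40, by = 0.1)
  for (fam in c("exponential", "gaussian")) {
    # unit-mass kernel maps a constant to (nearly) the same constant,
    # away from the free boundaries
    u <- rep(0.7, length(x))
    v <- field_convolve(u, x, 1.3, fam)
    interior <- x > 10 & x < 30
    expect_equal(v[interior], u[interior], tolerance = 1e-3)
    # symmetric response to a single hot cell, peaked at the source
    u2 <- numeric(length(x)); u2[201] <- 1
    v2 <- field_convolve(u2, x, 1, fam)
    expect_equal(which.max(v2), 201L)
    expect_equal(v2[201 - 30], v2[201 + 30], tolerance = 1e-10)
  }
})

test_that("the exponential-kernel convolution satisfies sigma^2 S'' = S - u", {
  x <- seq(0, 40, by = 0.05)
  u <- 0.05 * exp(-((x - 20) / 3)^2) + 0.01 * sin(x / 4)^2
  sig <- 0.8
  S <- field_convolve(u, x, sig, "exponential")
  dx <- x[2] - x[1]
  i <- 100:(length(x) - 100)
  Spp <- (S[i + 1] - 2 * S[i] + S[i - 1]) / dx^2
  resid <- sig^2 * Spp - (S[i] - u[i])
  expect_lt(max(abs(resid)), 5e-4 * max(abs(u)))
})

test_that("the rest state is stationary and linearly stable under the field flow", {
  fp <- field_params(L = 20, dx = 0.2)
  r <- rest_state(fp$local, fp$rate)
  x <- seq(0, fp$L, by = fp$dx)
  n <- length(x)
  interior <- x > 5 & x < 15  # the free boundaries relax to their own level
  init <- list(s_e = rep(r[1], n), s_i = rep(r[2], n), z = rep(r[3], n))
  tr <- simulate_field(fp, init = init, T_total = 60)
  settled <- tr$s_e[nrow(tr$s_e), ]
  expect_equal(max(abs(settled[interior] - r[1])), 0, tolerance = 1e-5)
  # small random perturbations of the settled profile decay
  set.seed(1)
  base <- list(s_e = settled, s_i = tr$s_i[nrow(tr$s_i), ],
               z = tr$z[nrow(tr$z), ])
  base$s_e <- base$s_e + runif(n, 0, 5e-4)
  tr2 <- simulate_field(fp, init = base, T_total = 80)
  d0 <- max(abs(tr2$s_e[1, ] - settled))
  d1 <- max(abs(tr2$s_e[nrow(tr2$s_e), ] - settled))
  expect_lt(d1, 0.5 * d0)
})

test_that("the default initial block evokes a steady rightward pulse at baseline", {
  tr <- baseline_field()
  oc <- classify_outcome(tr)
  expect_equal(oc$class, "steady_pulse")
  expect_true(oc$reached_end)
  expect_gt(oc$speed, 0.3)
  expect_lt(oc$speed, 1.2)
  cs <- crest_series(tr)
  expect_true(all(diff(cs$pos[cs$time > 20 & cs$time < 100]) >= 0))
})

test_that("the exponential-kernel wave is faster than the Gaussian one", {
  tr_exp <- baseline_field()
  fp_g <- field_params(kernel = "gaussian")
  tr_g <- simulate_field(fp_g, T_total = 150)
  oc_g <- classify_outcome(tr_g)
  expect_equal(oc_g$class, "steady_pulse")
  expect_gt(classify_outcome(tr_exp)$speed, oc_g$speed)
})

test_that("step-function gates saturate below their kinetic bound", {
  fp <- field_params(nonlinearity = "heaviside", L = 40)
  tr <- simulate_field(fp, T_total = 60)
  lp <- fp$local
  expect_lt(max(tr$s_e[tr$times > 10, ]), fp$a1 * lp$tau_e + 1e-6)
  expect_lt(max(tr$s_i), fp$a1 * lp$tau_i + 1e-6)
  expect_lt(max(tr$z), fp$a1 * lp$tau_z + 1e-6)
})

test_that("measured speed is insensitive to grid refinement", {
  fp1 <- field_params(L = 40, dx = 0.2)
  fp2 <- field_params(L = 40, dx = 0.1)
  c1 <- measure_speed(simulate_field(fp1, T_total = 70))
  c2 <- measure_speed(simulate_field(fp2, T_total = 70))
  expect_equal(c1, c2, tolerance = 0.01)
})

test_that("speed declines as the inhibitory footprint widens", {
  c1 <- classify_outcome(baseline_field())$speed
  fp2 <- field_params(sigma_i = 1.5)
  c2 <- classify_outcome(simulate_field(fp2, T_total = 150))$speed
  expect_gt(c1, c2)
})
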