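test_that("closed-form kernel convolutions match adaptive quadrature", {
  set.seed(7)
  worst <- 0
  for (k in 1:40) {
    x0 <- runif(1, -2, 2); sig <- runif(1, 0.3, 2); xi <- runif(1, -4, 6)
    # real decay constants
    zr <- runif(1, 0.2, 3)
    # split the quadrature at the kernel kink y = xi
    quad <- function(f) {
      if (xi > x0)
        stats::integrate(f, x0, xi, rel.tol = 1e-12)$value +
          stats::integrate(f, xi, Inf, rel.tol = 1e-12)$value
      else stats::integrate(f, x0, Inf, rel.tol = 1e-12)$value
    }
    q <- quad(function(y)
      exp(-abs(xi - y) / sig) / (2 * sig) * exp(-(y - x0) / zr))
    worst <- max(worst, abs(q - conv_expstep(xi, x0, zr, sig)))
    qs <- quad(function(y)
      exp(-abs(xi - y) / sig) / (2 * sig) * rep(1, length(y)))
    worst <- max(worst, abs(qs - conv_step(xi, x0, sig)))
  }
  expect_lt(worst, 1e-8)
})

test_that("complex-decay convolutions match quadrature inside the validity region", {
  set.seed(8)
  worst <- 0
  for (k in 1:30) {
    x0 <- runif(1, -1, 1); sig <- runif(1, 0.4, 1.5); xi <- runif(1, -3, 5)
    lam <- complex(real = runif(1, -0.005, 0.3),
                   imaginary = runif(1, -1, 1))
    tau <- sample(c(3, 4, 50), 1); cc <- runif(1, 0.3, 1)
    zeta <- cc * tau / (lam * tau + 1)
    fre <- function(y) exp(-abs(xi - y) / sig) / (2 * sig) *
      Re(exp(-(y - x0) / zeta))
    fim <- function(y) exp(-abs(xi - y) / sig) / (2 * sig) *
      Im(exp(-(y - x0) / zeta))
    quad <- function(f) {
      if (xi > x0)
        stats::integrate(f, x0, xi, rel.tol = 1e-12)$value +
          stats::integrate(f, xi, Inf, rel.tol = 1e-12)$value
      else stats::integrate(f, x0, Inf, rel.tol = 1e-12)$value
    }
    q <- quad(fre) + 1i * quad(fim)
    worst <- max(worst, abs(q - conv_expstep(xi, x0, zeta, sig)))
  }
  expect_lt(worst, 1e-8)
})

test_that("convolution derivatives match finite differences", {
  h <- 1e-6
  for (xi in c(-1, 0.5, 3)) {
    fd <- (conv_step(xi + h, 0.2, 0.7) - conv_step(xi - h, 0.2, 0.7)) /
      (2 * h)
    expect_equal(conv_step_deriv(xi, 0.2, 0.7), fd, tolerance = 1e-5)
    z <- 1.4 + 0.3i
    fd2 <- (conv_expstep(xi + h, 0.2, z, 0.7) -
              conv_expstep(xi - h, 0.2, z, 0.7)) / (2 * h)
    expect_lt(abs(conv_expstep_deriv(xi, 0.2, z, 0.7) - fd2), 1e-5)
  }
})

test_that("the gate profile matches its defining ODE and boundary values", {
  b <- 1.2; d <- 4.5; ctau <- 2.3
  xi <- seq(-2, 25, by = 0.001)
  u <- pulse_profile(xi, b, d, ctau)
  expect_equal(u[xi <= b], rep(0, sum(xi <= b)))
  # continuous at d with the saturation peak value
  expect_equal(pulse_profile(d - 1e-9, b, d, ctau),
               1 - exp(-(d - b) / ctau), tolerance = 1e-6)
  expect_equal(pulse_profile(d + 1e-9, b, d, ctau),
               1 - exp(-(d - b) / ctau), tolerance = 1e-6)
  # RK4 oracle for c*tau*u' = -u + H(I)
  f <- function(x, u) (-u + as.numeric(x > b & x < d)) / ctau
  uo <- 0; h <- 0.001; err <- 0
  for (i in 2:length(xi)) {
    k1 <- f(xi[i - 1], uo); k2 <- f(xi[i - 1] + h / 2, uo + h / 2 * k1)
    k3 <- f(xi[i - 1] + h / 2, uo + h / 2 * k2); k4 <- f(xi[i], uo + h * k3)
    uo <- uo + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    err <- max(err, abs(uo - u[i]))
  }
  # the oracle's one-sided sampling of the jump at d limits it to O(h)
  expect_lt(err, 1e-4)
  # finite integral
  expect_lt(sum(u) * 0.001, (d - b) + ctau + 1)
})

test_that("the four threshold equations have the baseline pulse as a transversal root", {
  p <- baseline_hs_pulse()
  x <- c(p$c, p$a, p$b, p$d)
  expect_lt(max(abs(c(hs_inputs(c(0, p$a), x, p$par)$I_e,
                      hs_inputs(c(p$b, p$d), x, p$par)$I_i))), 1e-9)
  expect_gt(min(abs(p$dI)), 1e-3)
  expect_gt(p$a, 0)
  expect_lt(p$b, p$d)
  # the root reproduces the step-function field-simulation speed
  fp <- field_params(nonlinearity = "heaviside")
  cs <- measure_speed(simulate_field(fp, T_total = 120))
  expect_equal(p$c, cs, tolerance = 0.02)
})

test_that("pulse speed falls and width grows as the feedback parameters demand", {
  p0 <- baseline_hs_pulse()
  g0 <- c(p0$c, p0$a, p0$b, p0$d)
  up_gei <- hs_solve_pulse(step_params(g_ei = 2.5), g0)
  up_gad <- hs_solve_pulse(step_params(g_ad = 0.35), g0)
  up_sig <- hs_solve_pulse(step_params(sigma_i = 0.9), g0)
  expect_lt(up_gei$c, p0$c)
  expect_lt(up_gad$c, p0$c)
  expect_lt(up_sig$c, p0$c)
  dn_gei <- hs_solve_pulse(step_params(g_ei = 1.5), g0)
  dn_gad <- hs_solve_pulse(step_params(g_ad = 0.15), g0)
  expect_gt(dn_gei$a, p0$a)
  expect_gt(dn_gad$a, p0$a)
})

test_that("normalization gains and round-trip rescaling are exact", {
  k <- kappa_gains()
  expect_equal(unname(k), c(0.92, 0.37333333, 7.3333333), tolerance = 1e-7)
  s <- c(0.05, 0.02, 0.4)
  expect_equal(rescale_state(rescale_state(s, direction = "to_normalized"),
                             direction = "to_raw"), s)
  m <- matrix(runif(9), 3)
  expect_equal(rescale_state(rescale_state(m, direction = "to_raw"),
                             direction = "to_normalized"), m)
})

test_that("the Evans function vanishes at the translation mode for every pulse", {
  p0 <- baseline_hs_pulse()
  g0 <- c(p0$c, p0$a, p0$b, p0$d)
  for (par in list(step_params(), step_params(sigma_i = 1.5),
                   step_params(g_ei = 2.5), step_params(g_ad = 0.15))) {
    p <- hs_solve_pulse(par, g0)
    expect_lt(abs(evans_fun(0, p)), 1e-10)
  }
})

test_that("the Evans function respects conjugation symmetry and the matrix form", {
  p <- baseline_hs_pulse()
  for (l in c(0.05 + 0.4i, -0.1 + 0.7i, -0.3 - 0.2i)) {
    expect_equal(evans_fun(Conj(l), p), Conj(evans_fun(l, p)),
                 tolerance = 1e-12)
    # vectorized determinant agrees with the assembled matrix determinant
    M <- evans_matrix(l, p) - diag(4)
    # cofactor expansion of the 4x4 complex determinant
    det4 <- function(A) {
      s <- 0
      for (perm in list(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2),
                        c(1,4,2,3), c(1,4,3,2), c(2,1,3,4), c(2,1,4,3),
                        c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
                        c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1),
                        c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                        c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))) {
        sgn <- 1
        for (i in 1:3) for (j in (i + 1):4)
          if (perm[i] > perm[j]) sgn <- -sgn
        s <- s + sgn * A[1, perm[1]] * A[2, perm[2]] * A[3, perm[3]] *
          A[4, perm[4]]
      }
      s
    }
    expect_lt(abs(evans_fun(l, p) - det4(M)), 1e-10)
  }
})

test_that("eigenvalues come in conjugate pairs and are genuine roots", {
  par <- step_params(sigma_i = 2.0)
  p <- hs_solve_pulse(par, c(0.7, 5.7, 1.5, 5.5))
  ev <- find_eigenvalues(p, re_range = c(-0.5, 0.25), im_range = c(-1, 1),
                         n = 121)
  expect_gt(length(ev$eigenvalues), 0)
  for (l in ev$eigenvalues) {
    expect_lt(abs(evans_fun(l, p)), 1e-9)
    if (abs(Im(l)) > 1e-6)
      expect_lt(min(abs(ev$eigenvalues - Conj(l))), 1e-6)
  }
  expect_lt(ev$translation_residual, 1e-10)
})
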