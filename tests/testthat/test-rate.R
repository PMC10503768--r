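test_that("deterministic rate vanishes below threshold and matches the QIF passage time above it", {
  rp <- std_rate()
  Gstar <- rp$g_L / 2  # deterministic threshold in conductance units
  expect_equal(firing_rate(c(-1, 0, Gstar - 1e-6), 0, rp), c(0, 0, 0))
  for (G in c(0.1, 0.3, 1, 3)) {
    expect_equal(firing_rate(G, 0, rp), 1 / qif_period(G, rp),
                 tolerance = 1e-7)
  }
})

test_that("noise smoothing behaves as a regularization of the rate", {
  rp <- std_rate()
  Gstar <- rp$g_L / 2
  # exactly at threshold: F = sqrt(zeta/2)/pi
  for (z in c(1e-4, 1e-2))
    expect_equal(firing_rate(Gstar, z, rp), sqrt(z / 2) / pi,
                 tolerance = 1e-12)
  # strictly positive everywhere for zeta > 0, strictly increasing in G
  G <- seq(-2, 2, by = 0.05)
  Fz <- firing_rate(G, 1e-3, rp)
  expect_true(all(Fz > 0))
  expect_true(all(diff(Fz) > 0))
  # pointwise convergence to the deterministic rate as zeta -> 0
  for (G0 in c(-0.5, 0.2, 1.5)) {
    lim <- firing_rate(G0, 1e-10, rp)
    expect_equal(lim, firing_rate(G0, 0, rp), tolerance = 1e-4)
  }
})

test_that("rate derivative matches finite differences away from the kink", {
  rp <- std_rate()
  for (G in c(-0.8, 0.2, 0.9)) {
    fd <- (firing_rate(G + 1e-6, 1e-3, rp) -
             firing_rate(G - 1e-6, 1e-3, rp)) / 2e-6
    expect_equal(firing_rate_deriv(G, 1e-3, rp), fd, tolerance = 1e-5)
  }
})
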