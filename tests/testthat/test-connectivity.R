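test_that("connection kernels have the stated peaks and ranges", {
  expect_equal(connection_prob(0.3, 0.3, "ee"), 0.35)
  expect_equal(connection_prob(0.3, 0.3, "ei"), 1)
  expect_equal(connection_prob(0.5, 0.4, "ie"), exp(-2))
  expect_equal(connection_prob(0.5, 0.4, "ee"), 0.35 * exp(-1))
})

test_that("connectivity is binary, correctly shaped and seed-reproducible", {
  sp <- spiking_params()
  W1 <- build_connectivity(sp, seed = 7)
  W2 <- build_connectivity(sp, seed = 7)
  W3 <- build_connectivity(sp, seed = 8)
  expect_identical(W1$W_ee, W2$W_ee)
  expect_identical(W1$W_ii, W2$W_ii)
  expect_false(identical(W1$W_ee, W3$W_ee))
  expect_equal(dim(W1$W_ee), c(400L, 400L))
  expect_equal(dim(W1$W_ei), c(400L, 80L))
  expect_equal(dim(W1$W_ie), c(80L, 400L))
  expect_equal(dim(W1$W_ii), c(80L, 80L))
  expect_true(all(W1$W_ee %in% c(0, 1)))
  expect_equal(W1$x_e[1], 0)
  expect_equal(W1$x_i[2], 1 / 80)
})

test_that("connectivity draws do not disturb the caller's RNG stream", {
  set.seed(42)
  a <- runif(1)
  set.seed(42)
  invisible(build_connectivity(spiking_params(), seed = 3))
  expect_identical(runif(1), a)
})

test_that("empirical mean in-degrees match the analytic Bernoulli sums", {
  sp <- spiking_params()
  exp_deg <- expected_indegree(sp)
  st <- indegree_stats(sp, seeds = 1:15)
  for (proj in c("ee", "ei", "ie", "ii")) {
    se <- stats::sd(st[[proj]]) / sqrt(nrow(st))
    expect_lt(abs(mean(st[[proj]]) - exp_deg[[paste0("mean_", proj)]]),
              3 * se + 1e-9)
  }
  # headline numbers for cells away from the domain ends: ~27 E and ~8 I
  # inputs per E cell; ~80 E and ~8 I inputs per I cell (the domain edges
  # pull the grand means below these typical-cell values)
  expect_equal(exp_deg$ee[200], 27, tolerance = 0.06)
  expect_equal(exp_deg$ei[200], 8, tolerance = 0.10)
  expect_equal(exp_deg$ie[40], 80, tolerance = 0.06)
  expect_equal(exp_deg$ii[40], 8, tolerance = 0.10)
})
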