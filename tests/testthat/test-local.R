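test_that("the rest state is a quiescent equilibrium of the local kinetics", {
  lp <- local_params()
  rp <- std_rate()
  r <- rest_state(lp, rp)
  expect_lt(max(abs(local_rhs(r, lp, rp))), 1e-10)
  expect_lt(r[1], 0.01)  # quiescent: well below pulse amplitudes
  expect_true(all(r >= 0))
})

test_that("baseline kinetics are excitable: perturbation makes an excursion and returns", {
  lp <- local_params()
  rp <- std_rate()
  r <- rest_state(lp, rp)
  out <- simulate_local(c(0.015, r[2], r[3]), lp, rp, T_total = 400)
  expect_gt(max(out[, "s_e"]), 5 * r[1])
  expect_equal(unname(out[nrow(out), "s_e"]), r[1], tolerance = 0.2)
  expect_true(all(out[, c("s_e", "s_i", "z")] > -1e-9))
})

test_that("equilibrium structure changes with the two feedback gains as expected", {
  rp <- std_rate()
  # inhibition only: three equilibria, one a saddle at small activity
  eq_i <- find_equilibria(local_params(g_ad = 0, g_ei = 2), rp)
  expect_gte(nrow(eq_i), 3)
  expect_true("saddle" %in% eq_i$class)
  sad <- eq_i[eq_i$class == "saddle", ][1, ]
  expect_lt(sad$s_e, 0.02)
  expect_lt(abs(sad$s_i - 0.005), 0.01)
  # adaptation only: a unique stable equilibrium
  eq_a <- find_equilibria(local_params(g_ad = 0.25, g_ei = 0), rp)
  expect_equal(nrow(eq_a), 1L)
  expect_match(eq_a$class, "stable")
  # negligible recurrent excitation: unique trivial rest, no excitability
  eq_0 <- find_equilibria(local_params(g_ee = 0.05), rp)
  expect_equal(nrow(eq_0), 1L)
  expect_match(eq_0$class, "stable")
  expect_lt(eq_0$s_e, 0.01)
})

test_that("low inhibition with no adaptation makes the kinetics bistable", {
  rp <- std_rate()
  eq <- find_equilibria(local_params(g_ad = 0, g_ei = 1), rp)
  up <- eq[eq$s_e > 0.1 & grepl("stable", eq$class), ]
  expect_gte(nrow(up), 1)
})

test_that("Jacobian classification agrees with forward simulation", {
  rp <- std_rate()
  lp <- local_params(g_ad = 0, g_ei = 1)
  eq <- find_equilibria(lp, rp)
  up <- eq[which.max(eq$s_e), ]
  out <- simulate_local(c(up$s_e, up$s_i, up$z) * 1.02, lp, rp,
                        T_total = 400)
  expect_equal(unname(out[nrow(out), "s_e"]), up$s_e, tolerance = 0.05)
})
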