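test_that("seed splitting is deterministic and collision-free across streams", {
  expect_identical(split_seed(1, "noise", 3), split_seed(1, "noise", 3))
  s <- c(split_seed(5, "connectivity", 1:20), split_seed(5, "noise", 1:20),
         split_seed(5, "trial", 1:20))
  expect_equal(length(unique(s)), length(s))
  expect_true(all(s < 2^31))
})

test_that("an empty parameter grid yields an empty bundle without error", {
  b <- run_experiment(list(kind = "hs_pulse",
                           grid = data.frame(g_ei = numeric(0)),
                           seed = 1))
  expect_s3_class(b, "experiment_bundle")
  expect_length(b$results, 0)
})

test_that("rerunning a spec reproduces its metrics bit-identically", {
  spec <- list(kind = "spiking_wave",
               grid = data.frame(g_ee = 0.2, g_ei = 2,
                                 N_e = 120L, N_i = 24L),
               T_total = 40, seed = 9L)
  b1 <- run_experiment(spec)
  b2 <- run_experiment(spec)
  expect_identical(b1$results, b2$results)
})

test_that("the step-pulse experiment reports existence and wave descriptors", {
  b <- run_experiment(list(kind = "hs_pulse",
                           grid = data.frame(g_ei = c(2, 2.5)),
                           seed = 1))
  expect_true(all(vapply(b$results, `[[`, logical(1), "exists")))
  expect_gt(b$results[[1]]$c, b$results[[2]]$c)
})
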