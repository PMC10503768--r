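test_that("quiet noiseless network stays at rest with phases at the stable fixed point", {
  sp <- small_net(zeta_e = 0, zeta_i = 0)
  W <- build_connectivity(sp, seed = 1)
  tr <- simulate_network(sp, W,
                         stimuli = list(stimulus_protocol(amplitude = 0)),
                         T_total = 50, seed_noise = 1, record = "full")
  expect_equal(nrow(tr$raster), 0L)
  # theta = -pi/2 maps to V = E_L, the resting potential
  expect_equal(unname(tr$theta_e[nrow(tr$theta_e), ]),
               rep(-pi / 2, sp$N_e), tolerance = 1e-6)
})

test_that("identical seeds replay bit-identical trajectories", {
  sp <- small_net()
  W <- build_connectivity(sp, seed = 5)
  tr1 <- simulate_network(sp, W, T_total = 40, seed_noise = 11)
  tr2 <- simulate_network(sp, W, T_total = 40, seed_noise = 11)
  expect_identical(tr1$raster, tr2$raster)
  expect_identical(tr1$s_e, tr2$s_e)
  tr3 <- simulate_network(sp, W, T_total = 40, seed_noise = 12)
  expect_false(identical(tr1$raster, tr3$raster))
})

test_that("an isolated neuron driven above threshold fires at the deterministic QIF rate", {
  sp <- spiking_params(N_e = 1L, N_i = 1L, g_ee = 0, g_ei = 0, g_ie = 0,
                       g_ii = 0, g_ad = 0, zeta_e = 0, zeta_i = 0)
  W <- build_connectivity(sp, seed = 1)
  I0 <- 3  # current units; G = 2 I / (E_T - E_L)
  tr <- simulate_network(sp, W,
                         stimuli = list(stimulus_protocol(onset = 0,
                                                          duration = 500,
                                                          amplitude = I0,
                                                          cells = 1L)),
                         T_total = 500, seed_noise = 1, record = "raster")
  sp_times <- tr$raster$time[tr$raster$pop == "e"]
  expect_gt(length(sp_times), 10)
  isi <- mean(diff(sp_times))
  G0 <- 2 * I0 / (sp$E_T - sp$E_L)
  expect_equal(isi, 1 / firing_rate(G0, 0), tolerance = 0.02)
})

test_that("gates and adaptation stay non-negative and decay between spikes", {
  sp <- small_net()
  W <- build_connectivity(sp, seed = 2)
  tr <- simulate_network(sp, W, T_total = 60, seed_noise = 3)
  expect_true(all(tr$s_e >= 0) && all(tr$s_i >= 0) && all(tr$z >= 0))
  # pick a cell with exactly one spike: after it, s decays monotonically
  re <- tr$raster[tr$raster$pop == "e", ]
  counts <- table(re$neuron)
  one <- as.integer(names(counts)[counts == 1][1])
  if (!is.na(one)) {
    t1 <- re$time[re$neuron == one]
    post <- tr$s_e[tr$times > t1 + 0.1, one]
    expect_true(all(diff(post) <= 1e-12))
  }
})

test_that("participation and transit behave at the extremes", {
  expect_equal(participation_fraction(
    structure(list(raster = data.frame(neuron = integer(0),
                                       pop = character(0),
                                       time = numeric(0)),
                   params = spiking_params(), stimuli = list()),
              class = "network_trajectory")), 0)
  # full-size network, no stimulus: the default noise cannot ignite a wave
  sp <- spiking_params(g_ee = 0.2, g_ei = 2)
  W <- build_connectivity(sp, seed = 31)
  tr0 <- simulate_network(sp, W,
                          stimuli = list(stimulus_protocol(amplitude = 0)),
                          T_total = 100, seed_noise = 41, record = "raster")
  expect_lt(nrow(tr0$raster), 5)
  expect_equal(participation_fraction(tr0), 0, tolerance = 0.01)
})

test_that("an evoked wave propagates, and the two speed estimators agree", {
  sp <- spiking_params(g_ee = 0.2, g_ei = 2)
  W <- build_connectivity(sp, seed = 103)
  tr <- evoke_wave(sp, W, seed_noise = 203, record = "raster")
  pf <- participation_fraction(tr)
  expect_gt(pf, 0.03)
  expect_lt(pf, 0.3)
  tt <- transit_time(tr, x_end = 0.95, band_cells = 40L)
  expect_gt(tt$transit, 5)
  expect_lt(tt$transit, 60)
  v_fit <- raster_front_speed(tr)
  expect_equal(v_fit, tt$velocity, tolerance = 0.35)
  # transit from a point to itself is zero
  expect_equal(transit_time(tr, 0.1, 0.1, band_cells = 40L)$transit, 0,
               tolerance = 1e-9)
})

test_that("participation rises steeply as recurrent inhibition is removed", {
  part <- sapply(c(2, 0), function(g) {
    sp <- spiking_params(g_ee = 0.2, g_ei = g)
    W <- build_connectivity(sp, seed = 51)
    participation_fraction(evoke_wave(sp, W, seed_noise = 61,
                                      record = "raster"))
  })
  expect_lt(part[1], 0.25)
  expect_gt(part[2], 0.9)
})

test_that("a probe below the saddle-node current cannot fire a resting cell", {
  sp <- spiking_params(g_ee = 0.2, g_ei = 1)
  W <- build_connectivity(sp, seed = 71)
  # probe alone (no wave): the target must stay silent
  quiet <- simulate_network(sp, W,
                            stimuli = list(stimulus_protocol(onset = 25,
                                                             duration = 5,
                                                             amplitude = 0.3,
                                                             cells = 296:305)),
                            T_total = 60, seed_noise = 81,
                            record = "raster")
  expect_false(300 %in% quiet$raster$neuron[quiet$raster$pop == "e"])
  expect_error(priming_probe(sp, W, target_cell = 1000L),
               "outside the excitatory population")
})

test_that("trial-averaged population activity has the stated structure", {
  sp <- small_net()
  trs <- lapply(1:3, function(k) {
    W <- build_connectivity(sp, seed = 90 + k)
    simulate_network(sp, W, T_total = 40, seed_noise = 95 + k)
  })
  pa <- population_average(trs, e_band = 20:40, i_band = 3:8)
  expect_equal(dim(pa$s_e), c(length(trs[[1]]$times), 2L))
  expect_true(all(pa$s_e[, "se"] >= 0))
  expect_error(population_average(trs[1]), "fewer than 2 trials")
  # averaging identical trials reproduces the single trial
  pa2 <- population_average(list(trs[[1]], trs[[1]]), e_band = 20:40,
                            i_band = 3:8)
  expect_equal(pa2$s_e[, "mean"],
               rowMeans(trs[[1]]$s_e[, 20:40]))
  expect_equal(max(pa2$s_e[, "se"]), 0)
})
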