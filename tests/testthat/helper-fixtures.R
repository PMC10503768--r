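# Shared fixtures, built lazily and cached for the whole suite so the more
# expensive objects (baseline pulses, field runs) are computed once.
.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

std_rate <- function() rate_params()

# Small spiking network for fast structural tests.
small_net <- function(...) spiking_params(N_e = 60L, N_i = 12L, ...)

baseline_field <- function() {
  fixture("baseline_field", function() {
    simulate_field(field_params(), T_total = 150)
  })
}

baseline_hs_pulse <- function() {
  fixture("baseline_hs_pulse", function() hs_solve_pulse(step_params()))
}

baseline_tw_pulse <- function() {
  fixture("baseline_tw_pulse", function() {
    lift_and_refine(tw_system(local_params(), rate_params(), 1, 0.5))
  })
}

# Numerical QIF passage time: time for V to run from -Inf to +Inf under
# constant input conductance G (deterministic, zeta = 0).  Uses the phase
# substitution V = Vbar + (E_T - E_L)/2 * tan(theta/2).
qif_period <- function(G, rp = rate_params()) {
  dET <- rp$E_T - rp$E_L
  half <- dET / 2
  I <- G * half
  integrand <- function(theta) {
    V <- half * tan(theta / 2)  # V - Vbar
    dVdtheta <- half / 2 / cos(theta / 2)^2
    f <- rp$g_L * (V + half) * (V - half) / dET + I
    rp$C_m * dVdtheta / f
  }
  stats::integrate(integrand, -pi, pi, rel.tol = 1e-10)$value
}
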