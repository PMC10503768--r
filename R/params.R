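#' Parameters of the spiking theta-neuron network
#'
#' Constructs the full parameter set of the 400E/80I theta-neuron network:
#' membrane constants, synaptic/adaptation conductances and time constants,
#' reversal potentials, noise amplitudes and the integration step.
#'
#' Synapses are current-based with driving forces frozen at the midpoint
#' potential \eqn{\bar V = (E_L + E_T)/2}, which is what later permits the
#' mean-field reduction.  The default recurrent excitation is
#' \code{g_ee = 0.15}, the value used for the network simulations (the raw
#' parameter table also quotes 0.2; pass it explicitly if wanted).
#'
#' @param C_m membrane capacitance (uF/cm^2).
#' @param g_L leak conductance (mS/cm^2).
#' @param E_L,E_T leak and threshold potentials (mV); the quadratic
#'   nonlinearity has fixed points at both.
#' @param E_syn,I_syn,E_K excitatory, inhibitory and adaptation (potassium)
#'   reversal potentials (mV).
#' @param g_ee,g_ei,g_ie,g_ii synaptic gains (mS/cm^2); first index is the
#'   target population, second the source (\code{g_ei} = inhibition onto E).
#' @param g_ad adaptation gain on excitatory cells (mS/cm^2).
#' @param tau_e,tau_i,tau_z synaptic and adaptation decay times (msec).
#' @param zeta_e,zeta_i current-noise amplitudes for the two populations.
#' @param N_e,N_i population sizes.
#' @param dt Euler--Maruyama step (msec).
#' @return An object of class \code{"spiking_params"} (a validated list).
#' @export
spiking_params <- function(C_m = 1, g_L = 0.1,
                           E_L = -65, E_T = -50, E_syn = 0, I_syn = -75,
                           E_K = -85,
                           g_ee = 0.15, g_ei = 1, g_ie = 0.2, g_ii = 0.1,
                           g_ad = 1,
                           tau_e = 3, tau_i = 4, tau_z = 50,
                           zeta_e = 0.05, zeta_i = 0.5,
                           N_e = 400L, N_i = 80L, dt = 0.05) {
  p <- list(C_m = C_m, g_L = g_L, E_L = E_L, E_T = E_T, E_syn = E_syn,
            I_syn = I_syn, E_K = E_K,
            g_ee = g_ee, g_ei = g_ei, g_ie = g_ie, g_ii = g_ii, g_ad = g_ad,
            tau_e = tau_e, tau_i = tau_i, tau_z = tau_z,
            zeta_e = zeta_e, zeta_i = zeta_i,
            N_e = as.integer(N_e), N_i = as.integer(N_i), dt = dt)
  gs <- c(g_L, g_ee, g_ei, g_ie, g_ii, g_ad)
  stopifnot(all(gs >= 0), dt > 0, p$N_e >= 1L, p$N_i >= 1L,
            E_K < I_syn, I_syn < E_L, E_L < E_T, E_T < E_syn,
            C_m > 0, tau_e > 0, tau_i > 0, tau_z > 0)
  structure(p, class = "spiking_params")
}

#' Parameters of the mean-field firing-rate function
#'
#' Membrane constants entering the quadratic integrate-and-fire rate function
#' \code{\link{firing_rate}}, plus the noise-smoothing parameters of the two
#' populations.
#'
#' The rate function takes its input in "input conductance" units
#' \eqn{G = 2I/(E_T - E_L)}; \code{d_e}, \code{d_i} smooth it below threshold
#' and carry the units of \eqn{\mu} (1/msec^2).  They are not fixed by the
#' membrane constants; the defaults are chosen so the rest state of the local
#' kinetics is quiescent (see the methods vignette).
#'
#' @param g_L,C_m,E_L,E_T as in \code{\link{spiking_params}}.
#' @param d_e,d_i noise smoothing for the excitatory / inhibitory rate.
#' @return An object of class \code{"rate_params"}.
#' @export
rate_params <- function(g_L = 0.1, C_m = 1, E_L = -65, E_T = -50,
                        d_e = 1e-4, d_i = 1e-4) {
  stopifnot(g_L > 0, C_m > 0, E_T > E_L, d_e >= 0, d_i >= 0)
  structure(list(g_L = g_L, C_m = C_m, E_L = E_L, E_T = E_T,
                 d_e = d_e, d_i = d_i),
            class = "rate_params")
}

#' Driving-force factors of the mean-field model
#'
#' Returns \eqn{\gamma_e, \gamma_i, \gamma_z}: the synaptic/adaptation driving
#' forces at the midpoint potential \eqn{(E_T + E_L)/2}, measured in units of
#' \eqn{(E_T - E_L)/2}, so that products \eqn{g \gamma s} are in the same
#' input-conductance units the rate function expects.  All three are defined
#' positive; the sign of each current is carried explicitly in the model
#' equations.
#'
#' @param sp a \code{\link{spiking_params}} object (only the potentials are
#'   used).
#' @return Named numeric vector \code{c(gamma_e, gamma_i, gamma_z)}.
#' @export
gamma_factors <- function(sp = spiking_params()) {
  vbar <- (sp$E_T + sp$E_L) / 2
  half <- (sp$E_T - sp$E_L) / 2
  c(gamma_e = (sp$E_syn - vbar) / half,
    gamma_i = (vbar - sp$I_syn) / half,
    gamma_z = (vbar - sp$E_K) / half)
}

#' Local (space-clamped) mean-field parameters
#'
#' Couplings and time constants of the three-variable \eqn{(s_e, s_i, z)}
#' kinetics.  Relative to the spiking network, the mean-field model uses
#' \code{g_ee = 1} and \code{g_ad = 0.25} (recurrent excitation must be
#' strong enough for the cubic excitatory nullcline, and adaptation weaker
#' so inhibition dominates the feedback).
#'
#' @param g_ee,g_ei,g_ie,g_ii,g_ad coupling gains.
#' @param gamma numeric(3), driving-force factors; see
#'   \code{\link{gamma_factors}}.
#' @param tau_e,tau_i,tau_z decay times (msec).
#' @param z_input either \code{"same_as_se"} (default: the adaptation is
#'   driven by exactly the excitatory input) or \code{"literal"}
#'   (\eqn{\gamma_i} multiplying \eqn{s_e}, an alternative reading of the
#'   printed equations).
#' @return An object of class \code{"local_params"}.
#' @export
local_params <- function(g_ee = 1, g_ei = 2, g_ie = 0.2, g_ii = 0.1,
                         g_ad = 0.25,
                         gamma = gamma_factors(),
                         tau_e = 3, tau_i = 4, tau_z = 50,
                         z_input = c("same_as_se", "literal")) {
  z_input <- match.arg(z_input)
  stopifnot(length(gamma) == 3, all(gamma > 0),
            tau_e > 0, tau_i > 0, tau_z > 0,
            g_ee >= 0, g_ei >= 0, g_ie >= 0, g_ii >= 0, g_ad >= 0)
  structure(list(g_ee = g_ee, g_ei = g_ei, g_ie = g_ie, g_ii = g_ii,
                 g_ad = g_ad,
                 gamma_e = unname(gamma[1]), gamma_i = unname(gamma[2]),
                 gamma_z = unname(gamma[3]),
                 tau_e = tau_e, tau_i = tau_i, tau_z = tau_z,
                 z_input = z_input),
            class = "local_params")
}

#' Parameters of the 1-D neural-field model
#'
#' Spatial domain, grid, kernel family and footprints on top of the local
#' kinetics.  The excitatory footprint \code{sigma_e} sets the space unit;
#' the inhibitory footprint \code{sigma_i} is the main bifurcation parameter
#' of the wave-stability analysis.
#'
#' @param L domain length (space units); the domain is \code{[0, L]}.
#' @param dx grid step; must divide \code{L}.
#' @param sigma_e,sigma_i,sigma_z kernel length scales.
#' @param kernel \code{"exponential"} (\eqn{W(x) = e^{-|x|}/2}) or
#'   \code{"gaussian"} (\eqn{W(x) = e^{-x^2}/\sqrt{\pi}}).
#' @param nonlinearity \code{"smooth"} for the noisy-QIF rate function or
#'   \code{"heaviside"} for the calibrated step function
#'   \eqn{a_1 H(G - a_2)}.
#' @param a1,a2 plateau rate and threshold of the step nonlinearity.
#' @param local a \code{\link{local_params}} object.
#' @param rate a \code{\link{rate_params}} object.
#' @param dt integration step of the field solver (msec).
#' @return An object of class \code{"field_params"}.
#' @export
field_params <- function(L = 80, dx = 0.2,
                         sigma_e = 1, sigma_i = 0.5, sigma_z = 0.001,
                         kernel = c("exponential", "gaussian"),
                         nonlinearity = c("smooth", "heaviside"),
                         a1 = 0.04, a2 = 0.12,
                         local = local_params(), rate = rate_params(),
                         dt = 0.05) {
  kernel <- match.arg(kernel)
  nonlinearity <- match.arg(nonlinearity)
  n <- L / dx
  stopifnot(abs(n - round(n)) < 1e-8, sigma_e > 0, sigma_i > 0, sigma_z > 0,
            dx < min(sigma_e, sigma_i) / 2, dt > 0, a1 > 0, a2 > 0)
  structure(list(L = L, dx = dx, n = as.integer(round(n)) + 1L,
                 sigma_e = sigma_e, sigma_i = sigma_i, sigma_z = sigma_z,
                 kernel = kernel, nonlinearity = nonlinearity,
                 a1 = a1, a2 = a2, local = local, rate = rate, dt = dt),
            class = "field_params")
}

#' Parameters of the normalized step-function (Heaviside) model
#'
#' The normalized model replaces the smooth rate by \eqn{a_1 H(G - a_2)} and
#' rescales \eqn{s_\beta \to a_1 \tau_\beta \hat s_\beta} so all variables lie
#' in \eqn{[0,1]}; the couplings collapse into the composite gains
#' \eqn{\kappa_\beta = a_1 \tau_\beta \gamma_\beta}.  With the standard
#' membrane constants \eqn{\kappa_e = 0.92}, \eqn{\kappa_i = 0.37333},
#' \eqn{\kappa_z = 7.333333}.
#'
#' @param g_ee,g_ei,g_ie,g_ii,g_ad coupling gains (mean-field values).
#' @param tau_e,tau_i,tau_z decay times (msec).
#' @param sigma_e,sigma_i kernel footprints; \code{sigma_z} is the narrow
#'   regularizing footprint of the adaptation drive used by the stability
#'   analysis.
#' @param a1,a2 plateau rate (spikes/msec) and threshold (input-conductance
#'   units) of the step nonlinearity.
#' @param gamma driving-force factors, see \code{\link{gamma_factors}}.
#' @return An object of class \code{"step_params"} carrying the
#'   \code{kappa_e}, \code{kappa_i}, \code{kappa_z} composite gains.
#' @export
step_params <- function(g_ee = 1, g_ei = 2, g_ie = 0.2, g_ii = 0.1,
                        g_ad = 0.25,
                        tau_e = 3, tau_i = 4, tau_z = 50,
                        sigma_e = 1, sigma_i = 0.5, sigma_z = 0.001,
                        a1 = 0.04, a2 = 0.12,
                        gamma = gamma_factors()) {
  stopifnot(a1 > 0, a2 > 0, sigma_e > 0, sigma_i > 0, sigma_z > 0,
            sigma_z < sigma_e, all(gamma > 0))
  kap <- kappa_gains(a1 = a1, tau = c(tau_e, tau_i, tau_z), gamma = gamma)
  structure(list(g_ee = g_ee, g_ei = g_ei, g_ie = g_ie, g_ii = g_ii,
                 g_ad = g_ad,
                 tau_e = tau_e, tau_i = tau_i, tau_z = tau_z,
                 sigma_e = sigma_e, sigma_i = sigma_i, sigma_z = sigma_z,
                 a1 = a1, a2 = a2,
                 kappa_e = unname(kap[1]), kappa_i = unname(kap[2]),
                 kappa_z = unname(kap[3])),
            class = "step_params")
}

#' Composite gains of the normalized step-function model
#'
#' \eqn{\kappa_\beta = a_1 \tau_\beta \gamma_\beta} for
#' \eqn{\beta \in \{e, i, z\}}.
#'
#' @param a1 plateau rate of the step nonlinearity (spikes/msec).
#' @param tau numeric(3), decay times \code{c(tau_e, tau_i, tau_z)} (msec).
#' @param gamma numeric(3), driving-force factors.
#' @return Named numeric vector \code{c(kappa_e, kappa_i, kappa_z)}.
#' @export
kappa_gains <- function(a1 = 0.04, tau = c(3, 4, 50),
                        gamma = gamma_factors()) {
  stopifnot(length(tau) == 3, length(gamma) == 3)
  k <- a1 * tau * unname(gamma)
  names(k) <- c("kappa_e", "kappa_i", "kappa_z")
  k
}

#' Rescale raw mean-field state to the normalized step-function variables
#'
#' The normalization \eqn{s_\beta = a_1 \tau_\beta \hat s_\beta} maps the raw
#' synaptic gates onto \eqn{[0,1]}.  \code{direction = "to_normalized"}
#' divides by \eqn{a_1 \tau_\beta}; \code{"to_raw"} multiplies.
#'
#' @param state numeric vector or 3-column matrix with components
#'   (s_e, s_i, z).
#' @param a1 plateau rate.
#' @param tau numeric(3) decay times.
#' @param direction which way to map.
#' @return Rescaled state of the same shape.
#' @export
rescale_state <- function(state, a1 = 0.04, tau = c(3, 4, 50),
                          direction = c("to_normalized", "to_raw")) {
  direction <- match.arg(direction)
  fac <- a1 * tau
  if (direction == "to_raw") {
    scl <- fac
  } else {
    scl <- 1 / fac
  }
  if (is.matrix(state)) {
    stopifnot(ncol(state) == 3)
    sweep(state, 2, scl, `*`)
  } else {
    stopifnot(length(state) == 3)
    state * scl
  }
}
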