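#' Noisy quadratic integrate-and-fire firing-rate function
#'
#' The population rate of a QIF/theta neuron driven by input conductance
#' \code{G} (units of \eqn{2/(E_T - E_L)} times current) with noise smoothing
#' \code{zeta}:
#' \deqn{F(G, \zeta) = \frac{1}{\pi}\left[\tfrac12\left(\mu +
#'   \sqrt{\mu^2 + \zeta^2}\right)\right]^{1/2},}
#' where \eqn{\mu(G) = g_L\,(G (E_T-E_L)/2 - I^*) / (C_m^2 (E_T - E_L))} and
#' \eqn{I^* = g_L (E_T - E_L)/4} is the saddle-node current.  With
#' \code{zeta = 0} this reduces to the deterministic rate
#' \eqn{\sqrt{\mu_+}/\pi} (zero below threshold); with \code{zeta > 0} the
#' rate is strictly positive everywhere (noise-induced firing).
#'
#' @param G input in conductance units (may be a vector).
#' @param zeta noise smoothing (units of \eqn{\mu}, 1/msec^2).
#' @param rp a \code{\link{rate_params}} object (membrane constants).
#' @return Firing rate in spikes/msec, same shape as \code{G}.
#' @export
firing_rate <- function(G, zeta = 0, rp = rate_params()) {
  mu <- rate_mu(G, rp)
  inner <- 0.5 * (mu + sqrt(mu^2 + zeta^2))
  sqrt(pmax(inner, 0)) / pi
}

#' @rdname firing_rate
#' @details \code{rate_mu} exposes the intermediate quantity \eqn{\mu(G)};
#'   with the standard constants it is \eqn{\mu = (g_L/2 C_m^2)(G - g_L/2)},
#'   so the deterministic threshold sits at \eqn{G^* = g_L/2}.
#' @export
rate_mu <- function(G, rp = rate_params()) {
  dET <- rp$E_T - rp$E_L
  Istar <- rp$g_L * dET / 4
  rp$g_L * (G * dET / 2 - Istar) / (rp$C_m^2 * dET)
}

#' Derivative of the firing-rate function with respect to its input
#'
#' Used by Jacobian-based equilibrium classification and by the linearization
#' of the traveling-wave equations.  For \code{zeta > 0} the function is
#' differentiable everywhere.
#'
#' @inheritParams firing_rate
#' @return dF/dG, same shape as \code{G}.
#' @export
firing_rate_deriv <- function(G, zeta = 0, rp = rate_params()) {
  mu <- rate_mu(G, rp)
  dET <- rp$E_T - rp$E_L
  dmu <- rp$g_L * (dET / 2) / (rp$C_m^2 * dET)
  root <- sqrt(mu^2 + zeta^2)
  inner <- 0.5 * (mu + root)
  dinner <- 0.5 * (1 + ifelse(root > 0, mu / root, 0)) * dmu
  out <- ifelse(inner > 0, dinner / (2 * pi * sqrt(inner)), 0)
  out
}
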