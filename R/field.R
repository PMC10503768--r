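#' Normalized coupling kernels
#'
#' \code{kernel_fun} evaluates the unit-mass kernel \eqn{W(x)}:
#' exponential \eqn{e^{-|x|}/2} or Gaussian \eqn{e^{-x^2}/\sqrt{\pi}}.
#'
#' @param x evaluation points.
#' @param family \code{"exponential"} or \code{"gaussian"}.
#' @return Kernel values.
#' @export
kernel_fun <- function(x, family = c("exponential", "gaussian")) {
  family <- match.arg(family)
  switch(family,
         exponential = exp(-abs(x)) / 2,
         gaussian = exp(-x^2) / sqrt(pi))
}

#' Discretized convolution operator on the grid
#'
#' Builds the dense matrix of the truncated (free-boundary) convolution
#' \eqn{(1/\sigma)\int_0^L W((x-y)/\sigma) u(y) dy} on a uniform grid.
#' The domain is deliberately not wrapped: waves interact with the domain
#' ends, which is what produces the boundary-reflected (zigzag) regimes.
#'
#' @param x grid points.
#' @param sigma kernel footprint (> 0).
#' @param family kernel family.
#' @return A matrix \code{K} such that \code{K \%*\% u} is the gridded
#'   convolution (trapezoid weights).
#' @export
kernel_matrix <- function(x, sigma, family = c("exponential", "gaussian")) {
  family <- match.arg(family)
  if (sigma <= 0) stop("sigma must be positive")
  dx <- x[2] - x[1]
  K <- outer(x, x, function(a, b) kernel_fun((a - b) / sigma, family)) *
    (dx / sigma)
  K[, 1L] <- K[, 1L] / 2
  K[, length(x)] <- K[, length(x)] / 2
  K
}

#' Convolve a grid function with a coupling kernel
#'
#' @param u grid function.
#' @param x grid points (uniform).
#' @param sigma footprint.
#' @param family kernel family.
#' @return Convolved grid function.
#' @export
field_convolve <- function(u, x, sigma,
                           family = c("exponential", "gaussian")) {
  drop(kernel_matrix(x, sigma, family) %*% u)
}

field_nonlin <- function(G, zeta, fp) {
  if (fp$nonlinearity == "smooth") firing_rate(G, zeta, fp$rate)
  else fp$a1 * (G > fp$a2)
}

#' Simulate the 1-D neural-field model
#'
#' Integrates the spatially extended mean-field system with a classical
#' 4th-order Runge--Kutta scheme.  The excitatory and inhibitory gates are
#' convolved with their kernels; the adaptation acts locally (its
#' regularizing convolution is far narrower than the grid).
#'
#' @param fp a \code{\link{field_params}} object.
#' @param init optional list with vectors \code{s_e, s_i, z} on the grid;
#'   default is the rest state with \code{s_e = 0.2} clamped on
#'   \code{[0, 4]} (the standard wave-evoking initial condition).
#' @param T_total simulated time (msec).
#' @param save_every store the state every this many msec.
#' @return An object of class \code{"field_trajectory"}: grid \code{x},
#'   saved \code{times}, arrays \code{s_e}, \code{s_i}, \code{z}
#'   (time x space), the parameters and the rest state.
#' @export
simulate_field <- function(fp = field_params(), init = NULL, T_total = 200,
                           save_every = 1) {
  x <- seq(0, fp$L, by = fp$dx)
  n <- length(x)
  Ke <- kernel_matrix(x, fp$sigma_e, fp$kernel)
  Ki <- kernel_matrix(x, fp$sigma_i, fp$kernel)
  lp <- fp$local; rp <- fp$rate
  rest <- rest_state_for(fp)
  if (is.null(init)) {
    s_e <- rep(rest[1], n); s_i <- rep(rest[2], n); z <- rep(rest[3], n)
    s_e[x <= 4] <- 0.2
  } else {
    s_e <- init$s_e; s_i <- init$s_i; z <- init$z
    stopifnot(length(s_e) == n, length(s_i) == n, length(z) == n)
  }
  rhs <- function(se, si, zz) {
    Se <- Ke %*% se; Si <- Ki %*% si
    Ge <- lp$g_ee * lp$gamma_e * Se - lp$g_ei * lp$gamma_i * Si -
      lp$g_ad * lp$gamma_z * zz
    Gi <- lp$g_ie * lp$gamma_e * Se - lp$g_ii * lp$gamma_i * Si
    list(drop(-se / lp$tau_e + field_nonlin(Ge, rp$d_e, fp)),
         drop(-si / lp$tau_i + field_nonlin(Gi, rp$d_i, fp)),
         drop(-zz / lp$tau_z + field_nonlin(Ge, rp$d_e, fp)))
  }
  dt <- fp$dt
  nstep <- ceiling(T_total / dt)
  stride <- max(1L, round(save_every / dt))
  nsave <- floor(nstep / stride) + 1L
  S_e <- matrix(0, nsave, n); S_i <- matrix(0, nsave, n)
  Z <- matrix(0, nsave, n)
  times <- numeric(nsave)
  S_e[1L, ] <- s_e; S_i[1L, ] <- s_i; Z[1L, ] <- z
  isave <- 1L
  for (k in seq_len(nstep)) {
    k1 <- rhs(s_e, s_i, z)
    k2 <- rhs(s_e + dt / 2 * k1[[1]], s_i + dt / 2 * k1[[2]],
              z + dt / 2 * k1[[3]])
    k3 <- rhs(s_e + dt / 2 * k2[[1]], s_i + dt / 2 * k2[[2]],
              z + dt / 2 * k2[[3]])
    k4 <- rhs(s_e + dt * k3[[1]], s_i + dt * k3[[2]], z + dt * k3[[3]])
    s_e <- s_e + dt / 6 * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]])
    s_i <- s_i + dt / 6 * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]])
    z <- z + dt / 6 * (k1[[3]] + 2 * k2[[3]] + 2 * k3[[3]] + k4[[3]])
    if (!all(is.finite(s_e)))
      stop("field blow-up at t = ", k * dt, " msec")
    if (k %% stride == 0L) {
      isave <- isave + 1L
      S_e[isave, ] <- s_e; S_i[isave, ] <- s_i; Z[isave, ] <- z
      times[isave] <- k * dt
    }
  }
  structure(list(x = x, times = times[seq_len(isave)],
                 s_e = S_e[seq_len(isave), , drop = FALSE],
                 s_i = S_i[seq_len(isave), , drop = FALSE],
                 z = Z[seq_len(isave), , drop = FALSE],
                 params = fp, rest = rest),
            class = "field_trajectory")
}

# Rest state of the field's local kinetics (smooth model) or of the step
# model (quiescent state is exactly 0 since H(-a2) = 0).
rest_state_for <- function(fp) {
  if (fp$nonlinearity == "heaviside") c(0, 0, 0)
  else rest_state(fp$local, fp$rate)
}

crest_series <- function(traj) {
  amp <- apply(traj$s_e, 1L, max)
  pos <- traj$x[apply(traj$s_e, 1L, which.max)]
  data.frame(time = traj$times, amp = amp, pos = pos)
}

#' Classify the outcome of a field simulation
#'
#' Tracks the crest (spatial maximum of \code{s_e} above 3x the rest level)
#' and classifies the run as a steady pulse, a periodically modulated pulse,
#' propagation failure, a front (persistent plateau behind the crest), a
#' zigzag (boundary-reflected) wave, or stationary stripes.
#'
#' @param traj a \code{"field_trajectory"}.
#' @param settle_frac fraction of the run treated as transient.
#' @return An object of class \code{"wave_outcome"}: the \code{class}
#'   string plus crest metrics (speed, modulation depth and period where
#'   defined) and whether the crest traversed the domain.
#' @export
classify_outcome <- function(traj, settle_frac = 0.25) {
  cs <- crest_series(traj)
  fp <- traj$params
  rest_amp <- max(traj$rest[1], 1e-6)
  thresh <- 3 * rest_amp
  alive <- cs$amp > thresh
  L <- fp$L
  reached_end <- any(alive & cs$pos >= L - 5)
  out <- list(crest = cs, reached_end = reached_end, speed = NA_real_,
              modulation_depth = NA_real_, modulation_period = NA_real_)
  died <- !alive[length(alive)] ||
    all(!alive[cs$time > max(cs$time) * 0.9])
  # direction reversals of the smoothed crest path while alive
  al <- which(alive)
  zig <- FALSE
  if (length(al) > 20) {
    p <- stats::filter(cs$pos[al], rep(1 / 9, 9), sides = 2)
    dp <- diff(p[!is.na(p)])
    sg <- sign(dp[abs(dp) > fp$dx / 2])
    zig <- sum(diff(sg) != 0) >= 2
  }
  # stationary periodic pattern at the end of the run?
  nt <- nrow(traj$s_e)
  last <- traj$s_e[nt, ]
  prev <- traj$s_e[max(1L, nt - 10L), ]
  stationary <- max(abs(last - prev)) < 0.02 * max(abs(last), 1e-12)
  peaks <- sum(diff(sign(diff(last))) == -2 & last[2:(length(last) - 1)] > thresh)
  # persistent active plateau over most of the domain -> front
  interior <- traj$x > 0.1 * L & traj$x < 0.9 * L
  plateau <- stats::median(last[interior]) > 10 * rest_amp &&
    stats::sd(last[interior]) < 0.2 * stats::median(last[interior])
  if (plateau) {
    out$class <- "front"
  } else if (stationary && peaks >= 3) {
    out$class <- "stripes"
  } else if (zig && !died) {
    out$class <- "zigzag"
  } else if (died && !reached_end) {
    out$class <- "failure"
  } else {
    # plateau behind the crest -> front
    ilast_alive <- max(which(alive))
    behind_x <- cs$pos[ilast_alive] - 10 * fp$sigma_e
    front <- FALSE
    if (behind_x > 0) {
      jx <- which.min(abs(traj$x - behind_x))
      front <- traj$s_e[ilast_alive, jx] > 0.5 * cs$amp[ilast_alive]
    }
    if (front) {
      out$class <- "front"
    } else {
      win <- which(alive & cs$time >= settle_frac * max(cs$time) &
                     cs$pos < L - 5)
      if (length(win) > 10) {
        a <- cs$amp[win]
        depth <- (max(a) - min(a)) / mean(a)
        out$modulation_depth <- depth
        if (depth > 0.05) {
          out$class <- "modulated_pulse"
          pk <- which(diff(sign(diff(a))) == -2) + 1L
          if (length(pk) >= 2)
            out$modulation_period <- mean(diff(cs$time[win][pk]))
        } else out$class <- "steady_pulse"
      } else {
        out$class <- if (died) "failure" else "unclassified"
      }
    }
  }
  if (out$class %in% c("steady_pulse", "modulated_pulse", "front"))
    out$speed <- tryCatch(measure_speed(traj), error = function(e) NA_real_)
  structure(out, class = "wave_outcome")
}

#' Measure the wave speed from crest positions
#'
#' Least-squares slope of the crest position against time over the interior
#' of the domain (transients and boundary effects excluded).  For modulated
#' waves this is the mean speed over the fitting window.
#'
#' @param traj a \code{"field_trajectory"}.
#' @param interior positions used for the fit, as fractions of the domain.
#' @return Speed c in space units/msec.
#' @export
measure_speed <- function(traj, interior = c(0.25, 0.85)) {
  cs <- crest_series(traj)
  rest_amp <- max(traj$rest[1], 1e-6)
  L <- traj$params$L
  win <- cs$amp > 3 * rest_amp & cs$pos > interior[1] * L &
    cs$pos < interior[2] * L
  if (sum(win) < 5) stop("no propagating crest to measure")
  unname(stats::coef(stats::lm(pos ~ time, data = cs[win, ]))[2L])
}

#' Did the pulse propagate across the domain?
#'
#' Convenience predicate used by the breakdown scans: TRUE when the crest
#' reaches the far end of the domain with its amplitude still above the
#' crest threshold.
#'
#' @param traj a \code{"field_trajectory"}.
#' @return Logical.
#' @export
propagated <- function(traj) {
  classify_outcome(traj)$reached_end
}

#' Locate the pulse-to-front transition by simulation
#'
#' Bisects the coupling value at which the evoked wave stops returning to
#' rest behind its crest and instead leaves the whole medium active (a
#' front): the signature of the underlying kinetics having become bistable.
#'
#' @param param parameter varied (currently \code{"g_ei"}).
#' @param bracket numeric(2): values bracketing the transition (front at
#'   the lower end, pulse at the upper).
#' @param g_ad adaptation gain (the transition is a low-adaptation
#'   phenomenon).
#' @param sigma_i inhibitory footprint.
#' @param rate rate-function parameters.
#' @param tol bisection tolerance on the parameter.
#' @param T_total simulated time per probe (msec).
#' @return List: \code{value} (the transition point), \code{front_at},
#'   \code{pulse_at} (the final bracket).
#' @export
front_transition_sim <- function(param = "g_ei", bracket = c(1.6, 3.2),
                                 g_ad = 0, sigma_i = 0.5,
                                 rate = rate_params(), tol = 0.02,
                                 T_total = 160) {
  stopifnot(param == "g_ei")
  is_front <- function(g) {
    fp <- field_params(sigma_i = sigma_i,
                       local = local_params(g_ei = g, g_ad = g_ad),
                       rate = rate)
    tr <- simulate_field(fp, T_total = T_total)
    last <- tr$s_e[nrow(tr$s_e), ]
    interior <- tr$x > 0.1 * fp$L & tr$x < 0.9 * fp$L
    stats::median(last[interior]) > 10 * max(tr$rest[1], 1e-6)
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!is_front(lo) || is_front(hi))
    stop("bracket does not straddle the pulse-to-front transition")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_front(mid)) lo <- mid else hi <- mid
  }
  list(value = (lo + hi) / 2, front_at = lo, pulse_at = hi)
}
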