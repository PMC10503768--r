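#' Stimulus protocol
#'
#' A square current pulse delivered to a contiguous window of cells.
#'
#' @param onset stimulus onset (msec).
#' @param duration pulse duration (msec), > 0.
#' @param amplitude current amplitude (same units as the other currents of
#'   the voltage equation).
#' @param population \code{"e"} or \code{"i"}.
#' @param cells integer vector of 1-based target indices within the
#'   population.
#' @return An object of class \code{"stimulus"}.
#' @export
stimulus_protocol <- function(onset = 5, duration = 3, amplitude = 20,
                              population = c("e", "i"), cells = 1:20) {
  population <- match.arg(population)
  stopifnot(duration > 0, length(cells) >= 1, all(cells >= 1))
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 population = population, cells = as.integer(cells)),
            class = "stimulus")
}

raw_gamma <- function(params) {
  vbar <- (params$E_T + params$E_L) / 2
  c(e = params$E_syn - vbar, i = vbar - params$I_syn, z = vbar - params$E_K)
}

#' Simulate the spiking theta-neuron network
#'
#' Integrates the full E/I network with the Euler--Maruyama method.  Each
#' neuron is a theta neuron (phase form of the quadratic
#' integrate-and-fire model); a phase crossing \eqn{\pi} from below is
#' recorded as a spike, the phase is reset to \eqn{-\pi} and the neuron's
#' outgoing synaptic gate (and adaptation for E cells) is incremented by 1 at
#' the end of the step.  Between spikes the gates and adaptation decay
#' exponentially with their time constants.  Current noise enters the voltage
#' equation before the conductance conversion and is scaled by
#' \eqn{\sqrt{dt}}.
#'
#' @param params a \code{\link{spiking_params}} object.
#' @param W a \code{\link{build_connectivity}} ensemble.
#' @param stimuli a single \code{\link{stimulus_protocol}} or a list of them.
#' @param T_total simulated time (msec).
#' @param seed_noise integer seed for the noise stream (independent of the
#'   connectivity seed).
#' @param record which state to keep: \code{"gates"} stores the
#'   \code{s_e}, \code{s_i}, \code{z} time series, \code{"full"} additionally
#'   the phases, \code{"raster"} only spikes.
#' @return An object of class \code{"network_trajectory"}: \code{times},
#'   spike \code{raster} (data frame \code{neuron}, \code{pop},
#'   \code{time}), recorded state matrices (time x neuron), the parameters
#'   and stimuli.
#' @export
simulate_network <- function(params = spiking_params(),
                             W = build_connectivity(params),
                             stimuli = list(stimulus_protocol()),
                             T_total = 110, seed_noise = 1L,
                             record = c("gates", "full", "raster")) {
  record <- match.arg(record)
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed_noise)

  Ne <- params$N_e; Ni <- params$N_i
  dt <- params$dt
  nstep <- ceiling(T_total / dt)
  times <- seq(0, by = dt, length.out = nstep + 1L)
  gam <- raw_gamma(params)
  g2 <- 2 / (params$E_T - params$E_L)  # current -> conductance conversion

  theta_e <- rep(-pi / 2, Ne); theta_i <- rep(-pi / 2, Ni)
  s_e <- numeric(Ne); s_i <- numeric(Ni); z <- numeric(Ne)
  dec_e <- exp(-dt / params$tau_e)
  dec_i <- exp(-dt / params$tau_i)
  dec_z <- exp(-dt / params$tau_z)

  keep_gates <- record != "raster"
  if (keep_gates) {
    S_e <- matrix(0, nstep + 1L, Ne); S_i <- matrix(0, nstep + 1L, Ni)
    Z <- matrix(0, nstep + 1L, Ne)
  }
  keep_theta <- record == "full"
  if (keep_theta) {
    TH <- matrix(0, nstep + 1L, Ne)
    TH[1L, ] <- theta_e
  }

  sp_n <- integer(0); sp_p <- character(0); sp_t <- numeric(0)
  noise_e <- params$zeta_e * g2 * sqrt(dt)
  noise_i <- params$zeta_i * g2 * sqrt(dt)

  for (k in seq_len(nstep)) {
    t_now <- times[k]
    Istim_e <- numeric(Ne); Istim_i <- numeric(Ni)
    for (st in stimuli) {
      if (t_now >= st$onset && t_now < st$onset + st$duration) {
        if (st$population == "e") Istim_e[st$cells] <- Istim_e[st$cells] + st$amplitude
        else Istim_i[st$cells] <- Istim_i[st$cells] + st$amplitude
      }
    }
    # current-based synaptic drive at frozen driving forces
    Ie <- params$g_ee * gam["e"] * drop(W$W_ee %*% s_e) -
      params$g_ei * gam["i"] * drop(W$W_ei %*% s_i) -
      params$g_ad * gam["z"] * z + Istim_e
    Ii <- params$g_ie * gam["e"] * drop(W$W_ie %*% s_e) -
      params$g_ii * gam["i"] * drop(W$W_ii %*% s_i) + Istim_i
    Ge <- g2 * Ie; Gi <- g2 * Ii
    one_ce <- 1 + cos(theta_e); one_ci <- 1 + cos(theta_i)
    theta_e <- theta_e + dt / params$C_m *
      (-params$g_L * cos(theta_e) + one_ce * Ge) +
      one_ce * noise_e * stats::rnorm(Ne)
    theta_i <- theta_i + dt / params$C_m *
      (-params$g_L * cos(theta_i) + one_ci * Gi) +
      one_ci * noise_i * stats::rnorm(Ni)
    if (!all(is.finite(theta_e)) || !all(is.finite(theta_i)))
      stop("non-finite phase at t = ", t_now, " msec; integration aborted")

    fired_e <- theta_e >= pi
    fired_i <- theta_i >= pi
    # decay first, then apply the delta-function increments of this step
    s_e <- s_e * dec_e
    s_i <- s_i * dec_i
    z <- z * dec_z
    if (any(fired_e)) {
      idx <- which(fired_e)
      theta_e[idx] <- -pi
      s_e[idx] <- s_e[idx] + 1
      z[idx] <- z[idx] + 1
      sp_n <- c(sp_n, idx); sp_p <- c(sp_p, rep("e", length(idx)))
      sp_t <- c(sp_t, rep(times[k + 1L], length(idx)))
    }
    if (any(fired_i)) {
      idx <- which(fired_i)
      theta_i[idx] <- -pi
      s_i[idx] <- s_i[idx] + 1
      sp_n <- c(sp_n, idx); sp_p <- c(sp_p, rep("i", length(idx)))
      sp_t <- c(sp_t, rep(times[k + 1L], length(idx)))
    }
    if (keep_gates) {
      S_e[k + 1L, ] <- s_e; S_i[k + 1L, ] <- s_i; Z[k + 1L, ] <- z
    }
    if (keep_theta) TH[k + 1L, ] <- theta_e
  }

  out <- list(times = times,
              raster = data.frame(neuron = sp_n, pop = sp_p, time = sp_t),
              params = params, stimuli = stimuli,
              seed_connectivity = W$seed, seed_noise = as.integer(seed_noise))
  if (keep_gates) {
    out$s_e <- S_e; out$s_i <- S_i; out$z <- Z
  }
  if (keep_theta) out$theta_e <- TH
  structure(out, class = "network_trajectory")
}

#' Evoke a traveling wave in the spiking network
#'
#' Convenience wrapper around \code{\link{simulate_network}} with the standard
#' wave-evoking stimulus: a brief current pulse at t = 5 msec to the first 20
#' excitatory cells.
#'
#' @inheritParams simulate_network
#' @param stim the evoking stimulus.
#' @return A \code{"network_trajectory"}.
#' @export
evoke_wave <- function(params = spiking_params(),
                       W = build_connectivity(params),
                       stim = stimulus_protocol(),
                       T_total = 110, seed_noise = 1L,
                       record = "gates") {
  simulate_network(params, W, list(stim), T_total = T_total,
                   seed_noise = seed_noise, record = record)
}

#' Fraction of excitatory cells participating in a wave
#'
#' The share of E cells that fire at least once inside the wave window
#' (stimulus onset to onset + 100 msec by default).
#'
#' @param traj a \code{"network_trajectory"}.
#' @param window numeric(2) time window (msec); defaults to the first
#'   stimulus onset plus 100 msec.
#' @return Fraction in \code{[0, 1]}.
#' @export
participation_fraction <- function(traj, window = NULL) {
  if (is.null(window)) {
    onset <- if (length(traj$stimuli)) traj$stimuli[[1L]]$onset else 0
    window <- c(onset, onset + 100)
  }
  r <- traj$raster
  r <- r[r$pop == "e" & r$time >= window[1] & r$time <= window[2], ]
  if (nrow(r) == 0L) return(0)
  length(unique(r$neuron)) / traj$params$N_e
}

first_spike_band <- function(traj, cells) {
  r <- traj$raster
  r <- r[r$pop == "e" & r$neuron %in% cells, ]
  if (nrow(r) == 0L) return(NA_real_)
  firsts <- tapply(r$time, r$neuron, min)
  stats::median(firsts)
}

#' Wave transit time across the spiking-network domain
#'
#' Arrival time is the median first-spike time of E cells in a 10-cell band
#' around each landmark; transit time is the difference between the two
#' landmarks, and velocity the position difference over it.
#'
#' @param traj a \code{"network_trajectory"} containing an evoked wave.
#' @param x_start,x_end landmark positions in \code{[0, 1)}.
#' @param band_cells width of the landmark band (cells).
#' @return A list with \code{t_start}, \code{t_end}, \code{transit}
#'   (msec) and \code{velocity} (space units/msec).  Signals an error when
#'   the wave never reaches the end band.
#' @export
transit_time <- function(traj, x_start = 0, x_end = 1 - 1 / traj$params$N_e,
                         band_cells = 10L) {
  Ne <- traj$params$N_e
  cell_of <- function(x) pmin(pmax(1L, round(x * Ne) + 1L), Ne)
  band <- function(x) {
    c0 <- cell_of(x)
    lo <- min(max(1L, c0 - band_cells %/% 2L), Ne - band_cells + 1L)
    lo:(lo + band_cells - 1L)
  }
  t0 <- first_spike_band(traj, band(x_start))
  t1 <- first_spike_band(traj, band(x_end))
  if (is.na(t1)) stop("propagation failure: wave never reached x_end")
  if (is.na(t0)) stop("no spikes in the start band")
  tr <- t1 - t0
  vel <- if (abs(x_end - x_start) > 0) (x_end - x_start) / tr else 0
  list(t_start = t0, t_end = t1, transit = tr, velocity = vel)
}

#' Least-squares wave-front speed from the raster
#'
#' Fits arrival position against first-spike time of every participating E
#' cell; an independent cross-check on \code{\link{transit_time}}.
#'
#' @param traj a \code{"network_trajectory"}.
#' @return Velocity in space units/msec (slope of the regression).
#' @export
raster_front_speed <- function(traj) {
  r <- traj$raster
  r <- r[r$pop == "e", ]
  if (nrow(r) < 3L) stop("too few spikes to fit a front")
  firsts <- tapply(r$time, r$neuron, min)
  x <- (as.integer(names(firsts)) - 1L) / traj$params$N_e
  unname(stats::coef(stats::lm(x ~ as.numeric(firsts)))[2L])
}

#' Probe the network after an evoked wave (priming)
#'
#' Evokes a wave and then delivers a weak, spatially localized square pulse
#' (subthreshold for a resting network) to a band of cells; reports whether
#' the target cell fires within a response window after probe onset.
#'
#' @param params,W,seed_noise as in \code{\link{simulate_network}}.
#' @param wave_stim stimulus evoking the wave (default: 10-cell band centered
#'   on E cell 100 at t = 5 msec).
#' @param probe the probe stimulus; its amplitude should be below the
#'   saddle-node current \eqn{I^* = g_L (E_T - E_L)/4} so it can never fire a
#'   resting cell by itself.
#' @param target_cell E-cell index whose response is scored.
#' @param response_window msec after probe onset within which a spike counts.
#' @param T_total simulated time (msec).
#' @return A list: \code{spiked} (logical), \code{latency} (msec after probe
#'   onset, NA when silent) and the trajectory.
#' @export
priming_probe <- function(params = spiking_params(),
                          W = build_connectivity(params),
                          wave_stim = stimulus_protocol(cells = 96:105),
                          probe = stimulus_protocol(onset = 25, duration = 5,
                                                    amplitude = 0.3,
                                                    cells = 296:305),
                          target_cell = 300L, seed_noise = 1L,
                          response_window = 15, T_total = 80) {
  if (target_cell < 1L || target_cell > params$N_e)
    stop("target cell outside the excitatory population")
  traj <- simulate_network(params, W, list(wave_stim, probe),
                           T_total = T_total, seed_noise = seed_noise,
                           record = "raster")
  r <- traj$raster
  r <- r[r$pop == "e" & r$neuron == target_cell &
           r$time >= probe$onset &
           r$time <= probe$onset + response_window, ]
  list(spiked = nrow(r) > 0L,
       latency = if (nrow(r) > 0L) min(r$time) - probe$onset else NA_real_,
       trajectory = traj)
}

#' Trial-averaged population synaptic activity
#'
#' Averages the band-mean gate variables over repeated simulations, each with
#' a freshly regenerated connectivity matrix (same statistics) and noise.
#'
#' @param trajs list of \code{"network_trajectory"} objects recorded with
#'   gates.
#' @param e_band,i_band 1-based index bands over which cells are averaged
#'   within each trial.
#' @return A list of matrices \code{s_e}, \code{z}, \code{s_i}, each with
#'   columns \code{mean} and \code{se} (standard error across trials), plus
#'   \code{times}.
#' @export
population_average <- function(trajs, e_band = 180:220, i_band = 35:45) {
  if (length(trajs) < 2L) stop("standard error undefined with fewer than 2 trials")
  stopifnot(all(vapply(trajs, function(x) !is.null(x$s_e), logical(1))))
  band_series <- function(tr, field, band)
    rowMeans(tr[[field]][, band, drop = FALSE])
  agg <- function(field, band) {
    M <- vapply(trajs, band_series, numeric(length(trajs[[1]]$times)),
                field = field, band = band)
    cbind(mean = rowMeans(M),
          se = apply(M, 1L, stats::sd) / sqrt(ncol(M)))
  }
  list(times = trajs[[1]]$times,
       s_e = agg("s_e", e_band),
       z = agg("z", e_band),
       s_i = agg("s_i", i_band),
       n_trials = length(trajs))
}

#' Run repeated wave trials with regenerated connectivity
#'
#' @param params a \code{\link{spiking_params}}.
#' @param n_trials number of repetitions.
#' @param stim evoking stimulus.
#' @param base_seed integer; trial k uses connectivity seed
#'   \code{base_seed + 1000 + k} and noise seed \code{base_seed + 2000 + k},
#'   so adding trials never perturbs earlier ones.
#' @param T_total simulated time (msec).
#' @param record passed to \code{\link{simulate_network}}.
#' @return List of \code{"network_trajectory"} objects.
#' @export
run_wave_trials <- function(params = spiking_params(), n_trials = 10L,
                            stim = stimulus_protocol(), base_seed = 1L,
                            T_total = 110, record = "gates") {
  lapply(seq_len(n_trials), function(k) {
    W <- build_connectivity(params, seed = base_seed + 1000L + k)
    simulate_network(params, W, list(stim), T_total = T_total,
                     seed_noise = base_seed + 2000L + k, record = record)
  })
}
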