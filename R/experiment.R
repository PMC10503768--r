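#' Split a master seed into independent component streams
#'
#' Deterministic counter-based scheme: component \code{k} of stream
#' \code{name} gets seed \code{base + 1000 * index(name) + k}, so adding
#' trials or components never perturbs earlier ones.  All derived seeds stay
#' far below the 32-bit limit for master seeds below ~2e9 / 1e4.
#'
#' @param base integer master seed.
#' @param stream one of \code{"connectivity"}, \code{"noise"},
#'   \code{"trial"}, \code{"misc"}.
#' @param k counter within the stream (1-based).
#' @return Integer seed.
#' @export
split_seed <- function(base, stream = c("connectivity", "noise", "trial",
                                        "misc"), k = 1L) {
  stream <- match.arg(stream)
  idx <- match(stream, c("connectivity", "noise", "trial", "misc"))
  as.integer(base %% 100000L + 1000L * idx + k)
}

#' Run a declarative experiment specification
#'
#' Small driver tying the modules together: a spec names an experiment
#' family and a parameter grid; every run is fully reproducible from the
#' spec plus its seed.
#'
#' @param spec a list with fields \code{kind} (one of
#'   \code{"spiking_wave"}, \code{"field_run"}, \code{"local_equilibria"},
#'   \code{"hs_pulse"}), \code{grid} (data frame of parameter values, one
#'   row per run; may have zero rows), \code{seed} (integer), and optional
#'   kind-specific settings (\code{T_total}, ...).
#' @return A list of class \code{"experiment_bundle"}: \code{spec} and one
#'   \code{results} entry per grid row with the run's metrics.
#' @export
run_experiment <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind), !is.null(spec$grid),
            !is.null(spec$seed))
  kinds <- c("spiking_wave", "field_run", "local_equilibria", "hs_pulse")
  if (!spec$kind %in% kinds)
    stop("unknown experiment kind: ", spec$kind)
  grid <- spec$grid
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- as.list(grid[i, , drop = FALSE])
    results[[i]] <- switch(spec$kind,
      spiking_wave = {
        sp <- do.call(spiking_params, row[names(row) %in%
                                            names(formals(spiking_params))])
        W <- build_connectivity(sp, seed = split_seed(spec$seed,
                                                      "connectivity", i))
        tr <- evoke_wave(sp, W,
                         T_total = spec$T_total %||% 110,
                         seed_noise = split_seed(spec$seed, "noise", i),
                         record = "raster")
        list(params = row,
             participation = participation_fraction(tr),
             transit = tryCatch(
               transit_time(tr, x_end = 0.95, band_cells = 40L)$transit,
               error = function(e) NA_real_),
             n_spikes = nrow(tr$raster))
      },
      field_run = {
        lp <- do.call(local_params, row[names(row) %in%
                                          c("g_ee", "g_ei", "g_ie",
                                            "g_ii", "g_ad")])
        fp <- field_params(sigma_i = row$sigma_i %||% 0.5, local = lp,
                           rate = spec$rate %||% rate_params(),
                           kernel = spec$kernel %||% "exponential",
                           nonlinearity = spec$nonlinearity %||% "smooth")
        tr <- simulate_field(fp, T_total = spec$T_total %||% 200)
        oc <- classify_outcome(tr)
        list(params = row, class = oc$class, speed = oc$speed,
             modulation_depth = oc$modulation_depth,
             reached_end = oc$reached_end)
      },
      local_equilibria = {
        lp <- do.call(local_params, row[names(row) %in%
                                          c("g_ee", "g_ei", "g_ie",
                                            "g_ii", "g_ad")])
        eq <- find_equilibria(lp, spec$rate %||% rate_params())
        list(params = row, equilibria = eq)
      },
      hs_pulse = {
        par <- do.call(step_params, row[names(row) %in%
                                          c("g_ee", "g_ei", "g_ie",
                                            "g_ii", "g_ad", "sigma_i")])
        p <- tryCatch(hs_solve_pulse(par, guess = spec$guess %||%
                                       c(0.94, 6.1, 0.6, 5.2)),
                      error = function(e) NULL)
        if (is.null(p)) list(params = row, exists = FALSE)
        else list(params = row, exists = TRUE, c = p$c, a = p$a,
                  b = p$b, d = p$d)
      })
  }
  structure(list(spec = spec, results = results),
            class = "experiment_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
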