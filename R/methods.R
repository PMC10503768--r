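#' @export
print.network_trajectory <- function(x, ...) {
  cat("Spiking network trajectory:", x$params$N_e, "E /", x$params$N_i,
      "I theta neurons,", round(max(x$times), 1), "msec\n")
  cat("  spikes:", nrow(x$raster),
      sprintf("(E: %d, I: %d)", sum(x$raster$pop == "e"),
              sum(x$raster$pop == "i")), "\n")
  cat("  g_ei =", x$params$g_ei, ", g_ad =", x$params$g_ad,
      ", seeds (connectivity, noise) = (", x$seed_connectivity, ",",
      x$seed_noise, ")\n")
  invisible(x)
}

#' Raster plot of a spiking-network trajectory
#'
#' @param x a \code{"network_trajectory"}.
#' @param ... passed to \code{plot}.
#' @export
plot.network_trajectory <- function(x, ...) {
  r <- x$raster
  plot(r$time, ifelse(r$pop == "e", r$neuron,
                      x$params$N_e + r$neuron * 5),
       pch = 20, cex = 0.4, col = ifelse(r$pop == "e", "black", "red"),
       xlab = "time (msec)", ylab = "cell index (I cells above, red)", ...)
  invisible(x)
}

#' @export
print.field_trajectory <- function(x, ...) {
  cat("Neural-field trajectory on [0,", x$params$L, "], dx =",
      x$params$dx, ",", round(max(x$times), 1), "msec\n")
  cat("  kernel:", x$params$kernel, "; nonlinearity:",
      x$params$nonlinearity, "\n")
  cat("  (g_ei, g_ad, sigma_i) = (", x$params$local$g_ei, ",",
      x$params$local$g_ad, ",", x$params$sigma_i, ")\n")
  invisible(x)
}

#' Space-time image of the excitatory field
#'
#' @param x a \code{"field_trajectory"}.
#' @param ... passed to \code{image}.
#' @export
plot.field_trajectory <- function(x, ...) {
  graphics::image(x$times, x$x, x$s_e, xlab = "time (msec)",
                  ylab = "space", col = grDevices::hcl.colors(64, "Inferno"),
                  ...)
  invisible(x)
}

#' @export
print.wave_outcome <- function(x, ...) {
  cat("Wave outcome:", x$class, "\n")
  if (is.finite(x$speed)) cat("  speed:", signif(x$speed, 4),
                              "space units/msec\n")
  if (is.finite(x$modulation_depth))
    cat("  crest modulation depth:", signif(x$modulation_depth, 3), "\n")
  if (is.finite(x$modulation_period))
    cat("  modulation period:", signif(x$modulation_period, 4), "msec\n")
  invisible(x)
}

#' @export
print.tw_pulse <- function(x, ...) {
  cat("Traveling-pulse solution (collocation BVP):\n")
  cat("  c =", signif(x$c, 6), "space units/msec;  amplitude =",
      signif(max(x$traj[, 1]), 4), "\n")
  cat("  mesh: N =", x$N, "on [0,", x$L_xi, "]; residual =",
      format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Profile plot of a traveling-pulse solution
#'
#' @param x a \code{"tw_pulse"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.tw_pulse <- function(x, ...) {
  graphics::matplot(x$xi, x$traj[, 1:3], type = "l", lty = 1,
                    col = c("black", "red", "blue"),
                    xlab = expression(xi), ylab = "activity", ...)
  graphics::legend("topright", c("s_e", "s_i", "z"), lty = 1,
                   col = c("black", "red", "blue"), bty = "n")
  invisible(x)
}

#' @export
print.tw_branch <- function(x, ...) {
  cat("Pulse branch in", x$param, ":", nrow(x$points), "points;",
      x$reason, "\n")
  if (is.finite(x$fold)) cat("  fold at", x$param, "=",
                             signif(x$fold, 5), "\n")
  if (is.finite(x$front_transition))
    cat("  pulse-to-front transition at", x$param, "=",
        signif(x$front_transition, 5), "\n")
  invisible(x)
}

#' Speed-vs-parameter plot of a pulse branch
#'
#' @param x a \code{"tw_branch"}.
#' @param ... passed to \code{plot}.
#' @export
plot.tw_branch <- function(x, ...) {
  plot(x$points$param, x$points$c, type = "b", pch = 20,
       xlab = x$param, ylab = "wave speed c", ...)
  if (is.finite(x$fold)) graphics::abline(v = x$fold, lty = 2)
  invisible(x)
}

#' @export
print.hs_pulse <- function(x, ...) {
  cat("Step-function traveling pulse:\n")
  cat(sprintf("  c = %.5f, a = %.4f, b = %.4f, d = %.4f\n",
              x$c, x$a, x$b, x$d))
  cat("  (g_ei, g_ad, sigma_i) = (", x$par$g_ei, ",", x$par$g_ad, ",",
      x$par$sigma_i, ")\n")
  invisible(x)
}

#' @export
print.evans_eval <- function(x, ...) {
  cat("Evans-function evaluation on [",
      signif(x$rectangle$re[1], 3), ",", signif(x$rectangle$re[2], 3),
      "] x i[", signif(x$rectangle$im[1], 3), ",",
      signif(x$rectangle$im[2], 3), "]\n")
  cat("  |E(0)| =", format(x$translation_residual, digits = 3),
      "(translation mode)\n")
  if (length(x$eigenvalues)) {
    cat("  eigenvalues:\n")
    for (l in x$eigenvalues)
      cat(sprintf("    %+.5f %+.5fi\n", Re(l), Im(l)))
  } else cat("  no non-translation eigenvalues in the rectangle\n")
  invisible(x)
}

#' Zero contours of the Evans function
#'
#' Plots the zero level sets of the real (blue) and imaginary (red) parts;
#' their intersections are the eigenvalues.
#'
#' @param x an \code{"evans_eval"}.
#' @param ... passed to \code{contour}.
#' @export
plot.evans_eval <- function(x, ...) {
  graphics::contour(x$re_grid, x$im_grid, Re(x$E), levels = 0,
                    col = "blue", drawlabels = FALSE,
                    xlab = expression(Re(lambda)),
                    ylab = expression(Im(lambda)), ...)
  graphics::contour(x$re_grid, x$im_grid, Im(x$E), levels = 0,
                    col = "red", drawlabels = FALSE, add = TRUE)
  if (length(x$eigenvalues))
    graphics::points(Re(x$eigenvalues), Im(x$eigenvalues), pch = 19)
  graphics::points(0, 0, pch = 1, cex = 1.4)
  invisible(x)
}

#' @export
print.eigen_path <- function(x, ...) {
  n <- nrow(x$path)
  cat("Tracked Evans eigenvalue along", x$param, ":", n, "points from",
      signif(x$path$param[1], 4), "to", signif(x$path$param[n], 4), "\n")
  cat(sprintf("  last: %+.5f %+.5fi\n", x$path$re[n], x$path$im[n]))
  invisible(x)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("Experiment bundle:", x$spec$kind, "with", length(x$results),
      "runs (seed", x$spec$seed, ")\n")
  invisible(x)
}
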