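#' Closed-form convolutions with the exponential kernel
#'
#' Building blocks of the step-function pulse analysis.  For the unit-mass
#' kernel \eqn{W_\sigma(x) = e^{-|x|/\sigma}/(2\sigma)}:
#' \code{conv_step} is \eqn{(W_\sigma * H(\cdot - x_0))(\xi)} and
#' \code{conv_expstep} is
#' \eqn{(W_\sigma * e^{-(\cdot - x_0)/\zeta} H(\cdot - x_0))(\xi)}.
#' The decay constant \code{zeta} may be complex; the integral converges for
#' \eqn{Re(1/\zeta) > -1/\sigma}.  The resonant case \eqn{\zeta = \sigma}
#' is handled by its limit formula.
#'
#' @param xi evaluation points (vector).
#' @param x0 onset of the step.
#' @param zeta decay constant (possibly complex scalar).
#' @param sigma kernel footprint.
#' @return Convolution values at \code{xi} (complex when \code{zeta} is).
#' @export
conv_step <- function(xi, x0, sigma) {
  s <- xi - x0
  ifelse(s <= 0, 0.5 * exp(s / sigma), 1 - 0.5 * exp(-s / sigma))
}

#' @rdname conv_step
#' @export
conv_expstep <- function(xi, x0, zeta, sigma) {
  s <- xi - x0
  n <- max(length(s), length(zeta))
  s <- rep_len(s, n); zeta <- rep_len(zeta, n)
  left <- zeta / (2 * (zeta + sigma)) * exp(s / sigma)
  res <- abs(zeta - sigma) < 1e-10 * sigma
  interior <- zeta / (2 * (zeta - sigma)) * (exp(-s / zeta) - exp(-s / sigma))
  if (any(res))  # resonant limit of the interior term
    interior[res] <- exp(-s[res] / sigma) * s[res] / (2 * sigma)
  right <- interior + zeta / (2 * (zeta + sigma)) * exp(-s / zeta)
  out <- right
  out[s <= 0] <- left[s <= 0]
  out
}

#' @rdname conv_step
#' @details \code{conv_step_deriv} and \code{conv_expstep_deriv} are the
#'   derivatives with respect to \code{xi}; the latter uses
#'   \eqn{d/d\xi\,C = W_\sigma(\xi - x_0) - C/\zeta}.
#' @export
conv_step_deriv <- function(xi, x0, sigma) {
  exp(-abs(xi - x0) / sigma) / (2 * sigma)
}

#' @rdname conv_step
#' @export
conv_expstep_deriv <- function(xi, x0, zeta, sigma) {
  exp(-abs(xi - x0) / sigma) / (2 * sigma) -
    conv_expstep(xi, x0, zeta, sigma) / zeta
}

#' Piecewise-exponential profile of the step-function pulse
#'
#' The steady profile of a gate with decay time \code{tau} that is driven by
#' a Heaviside input active on \eqn{(x_1, x_2)} in the comoving frame:
#' zero ahead of the pulse, saturating rise inside, exponential decay
#' behind.  In normalized variables the profile takes values in [0, 1).
#'
#' @param xi evaluation points.
#' @param x1,x2 onset and offset of the suprathreshold input.
#' @param ctau product of wave speed and decay time (the spatial decay
#'   scale).
#' @return Profile values.
#' @export
pulse_profile <- function(xi, x1, x2, ctau) {
  (xi > x1) - (xi > x2) -
    exp(-pmax(xi - x1, 0) / ctau) * (xi > x1) +
    exp(-pmax(xi - x2, 0) / ctau) * (xi > x2)
}

# Convolution of pulse_profile with the exponential kernel, closed form.
profile_conv <- function(xi, x1, x2, ctau, sigma) {
  conv_step(xi, x1, sigma) - conv_step(xi, x2, sigma) -
    conv_expstep(xi, x1, ctau, sigma) + conv_expstep(xi, x2, ctau, sigma)
}

profile_conv_deriv <- function(xi, x1, x2, ctau, sigma) {
  conv_step_deriv(xi, x1, sigma) - conv_step_deriv(xi, x2, sigma) -
    conv_expstep_deriv(xi, x1, ctau, sigma) +
    conv_expstep_deriv(xi, x2, ctau, sigma)
}

#' Threshold inputs of the step-function pulse
#'
#' \code{hs_inputs} evaluates the inputs to the excitatory and inhibitory
#' thresholds, \eqn{I_e(\xi)} and \eqn{I_i(\xi)}, for a candidate
#' \code{(c, a, b, d)}; \code{hs_inputs_deriv} their \eqn{\xi}-derivatives.
#'
#' @param xi evaluation points.
#' @param cabd numeric(4): speed \code{c}, excitatory offset \code{a},
#'   inhibitory onset \code{b} and offset \code{d}.
#' @param par a \code{\link{step_params}} object.
#' @return List with components \code{I_e} and \code{I_i}.
#' @export
hs_inputs <- function(xi, cabd, par) {
  cc <- cabd[1]; a <- cabd[2]; b <- cabd[3]; d <- cabd[4]
  Re_ <- profile_conv(xi, 0, a, cc * par$tau_e, par$sigma_e)
  Ri <- profile_conv(xi, b, d, cc * par$tau_i, par$sigma_i)
  Rz <- profile_conv(xi, 0, a, cc * par$tau_z, par$sigma_z)
  list(I_e = par$g_ee * par$kappa_e * Re_ - par$g_ei * par$kappa_i * Ri -
         par$g_ad * par$kappa_z * Rz - par$a2,
       I_i = par$g_ie * par$kappa_e * Re_ - par$g_ii * par$kappa_i * Ri -
         par$a2)
}

#' @rdname hs_inputs
#' @export
hs_inputs_deriv <- function(xi, cabd, par) {
  cc <- cabd[1]; a <- cabd[2]; b <- cabd[3]; d <- cabd[4]
  dRe <- profile_conv_deriv(xi, 0, a, cc * par$tau_e, par$sigma_e)
  dRi <- profile_conv_deriv(xi, b, d, cc * par$tau_i, par$sigma_i)
  dRz <- profile_conv_deriv(xi, 0, a, cc * par$tau_z, par$sigma_z)
  list(I_e = par$g_ee * par$kappa_e * dRe - par$g_ei * par$kappa_i * dRi -
         par$g_ad * par$kappa_z * dRz,
       I_i = par$g_ie * par$kappa_e * dRe - par$g_ii * par$kappa_i * dRi)
}

#' Solve the four threshold equations of the step-function pulse
#'
#' Finds \code{(c, a, b, d)} such that \eqn{I_e(0) = I_e(a) = I_i(b) =
#' I_i(d) = 0}, verifies the transversality of the four crossings and the
#' sign pattern of the inputs inside the active intervals.
#'
#' @param par a \code{\link{step_params}} object.
#' @param guess numeric(4) starting point; the default is the approximate
#'   baseline solution at (g_ei, g_ad, sigma_i) = (2, 0.25, 0.5).
#' @param tol Newton tolerance on the residual norm.
#' @return An object of class \code{"hs_pulse"}: \code{c}, \code{a},
#'   \code{b}, \code{d}, the slopes \code{dI} at the crossings, and the
#'   parameters; error when the root finder diverges or the solution is
#'   degenerate.
#' @export
hs_solve_pulse <- function(par = step_params(),
                           guess = c(0.94, 6.1, 0.6, 5.2), tol = 1e-11) {
  fn <- function(x) {
    if (x[1] <= 0 || x[2] <= 0 || x[4] <= x[3]) return(rep(1e3, 4))
    Ie <- hs_inputs(c(0, x[2]), x, par)$I_e
    Ii <- hs_inputs(c(x[3], x[4]), x, par)$I_i
    c(Ie, Ii)
  }
  res <- newton_fd(fn, guess, tol = tol, maxit = 60)
  if (!res$converged)
    stop("no pulse at these parameters: threshold equations did not ",
         "converge (residual ", format(sqrt(sum(res$f^2))), ")")
  x <- res$x
  dIe <- hs_inputs_deriv(c(0, x[2]), x, par)$I_e
  dIi <- hs_inputs_deriv(c(x[3], x[4]), x, par)$I_i
  if (min(abs(c(dIe, dIi))) < 1e-8)
    stop("degenerate pulse: transversality fails at a threshold crossing")
  # sign pattern inside the active intervals
  xe <- seq(0, x[2], length.out = 41)[-c(1, 41)]
  xi_ <- seq(x[3], x[4], length.out = 41)[-c(1, 41)]
  if (any(hs_inputs(xe, x, par)$I_e < 0) ||
      any(hs_inputs(xi_, x, par)$I_i < 0))
    stop("inconsistent pulse: threshold input not positive inside the ",
         "active interval")
  structure(list(c = x[1], a = x[2], b = x[3], d = x[4],
                 dI = c(Ie0 = dIe[1], Iea = dIe[2], Iib = dIi[1],
                        Iid = dIi[2]),
                 par = par),
            class = "hs_pulse")
}

#' Evans-function jump matrix of the step-function pulse
#'
#' Assembles the 4x4 matrix \eqn{M(\lambda)} relating the jump amplitudes
#' \eqn{(A_0, A_a, A_b, A_d)} of the linearized perturbation modes at the
#' four threshold crossings.  The modes decay with complex constants
#' \eqn{\zeta_\beta = c\tau_\beta/(\lambda\tau_\beta + 1)}; their kernel
#' convolutions are evaluated in closed form and scaled by the crossing
#' slopes.  Eigenvalues of the wave are the roots of
#' \eqn{E(\lambda) = \det(M(\lambda) - I)}.
#'
#' @param lambda complex number.
#' @param pulse an \code{"hs_pulse"}.
#' @return Complex 4x4 matrix.
#' @export
evans_matrix <- function(lambda, pulse) {
  par <- pulse$par
  cc <- pulse$c; a <- pulse$a; b <- pulse$b; d <- pulse$d
  ze <- cc * par$tau_e / (lambda * par$tau_e + 1)
  zi <- cc * par$tau_i / (lambda * par$tau_i + 1)
  zz <- cc * par$tau_z / (lambda * par$tau_z + 1)
  pts <- c(0, a, b, d)
  # convolved modes evaluated at the four crossings (columns = A0,Aa,Ab,Ad)
  Qe <- cbind(conv_expstep(pts, 0, ze, par$sigma_e),
              conv_expstep(pts, a, ze, par$sigma_e), 0, 0)
  Qz <- cbind(conv_expstep(pts, 0, zz, par$sigma_z),
              conv_expstep(pts, a, zz, par$sigma_z), 0, 0) *
    (par$tau_e / par$tau_z)
  Qi <- cbind(0, 0, conv_expstep(pts, b, zi, par$sigma_i),
              conv_expstep(pts, d, zi, par$sigma_i))
  Ge <- par$g_ee * par$kappa_e * Qe - par$g_ei * par$kappa_i * Qi -
    par$g_ad * par$kappa_z * Qz
  Gi <- par$g_ie * par$kappa_e * Qe - par$g_ii * par$kappa_i * Qi
  M <- rbind(Ge[1, ] / (cc * par$tau_e * abs(pulse$dI["Ie0"])),
             Ge[2, ] / (cc * par$tau_e * abs(pulse$dI["Iea"])),
             Gi[3, ] / (cc * par$tau_i * abs(pulse$dI["Iib"])),
             Gi[4, ] / (cc * par$tau_i * abs(pulse$dI["Iid"])))
  unname(M)
}

# Vectorized determinant of (M(lambda) - I) over a vector of lambdas.
# Entries of M are computed as vectors; the 4x4 determinant is expanded by
# Laplace over the first two rows (sums of products of 2x2 minors).
evans_det_vec <- function(lambda, pulse) {
  par <- pulse$par
  cc <- pulse$c; a <- pulse$a; b <- pulse$b; d <- pulse$d
  ze <- cc * par$tau_e / (lambda * par$tau_e + 1)
  zi <- cc * par$tau_i / (lambda * par$tau_i + 1)
  zz <- cc * par$tau_z / (lambda * par$tau_z + 1)
  pts <- c(0, a, b, d)
  E <- array(0i, c(length(lambda), 4, 4))
  for (r in 1:4) {
    Qe0 <- conv_expstep(pts[r], 0, ze, par$sigma_e)
    Qea <- conv_expstep(pts[r], a, ze, par$sigma_e)
    Qz0 <- conv_expstep(pts[r], 0, zz, par$sigma_z) * par$tau_e / par$tau_z
    Qza <- conv_expstep(pts[r], a, zz, par$sigma_z) * par$tau_e / par$tau_z
    Qib <- conv_expstep(pts[r], b, zi, par$sigma_i)
    Qid <- conv_expstep(pts[r], d, zi, par$sigma_i)
    if (r <= 2) {
      den <- cc * par$tau_e * abs(pulse$dI[r])
      E[, r, 1] <- (par$g_ee * par$kappa_e * Qe0 -
                      par$g_ad * par$kappa_z * Qz0) / den
      E[, r, 2] <- (par$g_ee * par$kappa_e * Qea -
                      par$g_ad * par$kappa_z * Qza) / den
      E[, r, 3] <- -par$g_ei * par$kappa_i * Qib / den
      E[, r, 4] <- -par$g_ei * par$kappa_i * Qid / den
    } else {
      den <- cc * par$tau_i * abs(pulse$dI[r])
      E[, r, 1] <- par$g_ie * par$kappa_e * Qe0 / den
      E[, r, 2] <- par$g_ie * par$kappa_e * Qea / den
      E[, r, 3] <- -par$g_ii * par$kappa_i * Qib / den
      E[, r, 4] <- -par$g_ii * par$kappa_i * Qid / den
    }
    E[, r, r] <- E[, r, r] - 1
  }
  m2 <- function(i1, i2, j1, j2)
    E[, i1, j1] * E[, i2, j2] - E[, i1, j2] * E[, i2, j1]
  m2(1, 2, 1, 2) * m2(3, 4, 3, 4) -
    m2(1, 2, 1, 3) * m2(3, 4, 2, 4) +
    m2(1, 2, 1, 4) * m2(3, 4, 2, 3) +
    m2(1, 2, 2, 3) * m2(3, 4, 1, 4) -
    m2(1, 2, 2, 4) * m2(3, 4, 1, 3) +
    m2(1, 2, 3, 4) * m2(3, 4, 1, 2)
}

#' Evaluate the Evans function
#'
#' \eqn{E(\lambda) = \det(M(\lambda) - I)}; its roots are the point-spectrum
#' eigenvalues of the linearization about the pulse.  \eqn{E(0) = 0} always
#' (translation invariance).  The closed forms require every mode
#' convolution to converge, i.e.
#' \eqn{Re(\lambda) > -1/\tau_\beta - c/\sigma_\beta} for each population;
#' see \code{\link{evans_valid_re}}.
#'
#' @param lambda complex vector.
#' @param pulse an \code{"hs_pulse"}.
#' @return Complex vector of Evans-function values.
#' @export
evans_fun <- function(lambda, pulse) {
  evans_det_vec(as.complex(lambda), pulse)
}

#' @rdname evans_fun
#' @export
evans_valid_re <- function(pulse) {
  par <- pulse$par
  max(-1 / par$tau_e - pulse$c / par$sigma_e,
      -1 / par$tau_i - pulse$c / par$sigma_i,
      -1 / par$tau_z - pulse$c / par$sigma_z)
}

polish_eigenvalue <- function(lambda0, pulse, tol = 1e-12, maxit = 60) {
  l <- as.complex(lambda0)
  h <- 1e-7
  for (it in seq_len(maxit)) {
    f <- evans_fun(l, pulse)
    if (abs(f) < tol) break
    df <- (evans_fun(l + h, pulse) - evans_fun(l - h, pulse)) / (2 * h)
    if (abs(df) < 1e-300) break
    step <- f / df
    l <- l - step
    if (abs(step) < 1e-14) break
  }
  l
}

#' Locate eigenvalues of the pulse in a rectangle of the complex plane
#'
#' Grids the rectangle, finds cells crossed by both the real and imaginary
#' zero contours of \eqn{E(\lambda)}, polishes each candidate by a complex
#' Newton iteration, and de-duplicates.  The translation eigenvalue at 0 is
#' always reported separately.
#'
#' @param pulse an \code{"hs_pulse"}.
#' @param re_range,im_range rectangle bounds; the real lower bound is
#'   clipped to the validity region of the closed forms.
#' @param n grid resolution per axis.
#' @return An object of class \code{"evans_eval"}: \code{eigenvalues}
#'   (complex, translation root excluded), \code{translation_residual}
#'   |E(0)|, the grid and gridded \code{E} values, and the rectangle.
#' @export
find_eigenvalues <- function(pulse, re_range = c(-1, 0.2),
                             im_range = c(-1, 1), n = 201) {
  lo <- evans_valid_re(pulse) + 0.02
  re_range[1] <- max(re_range[1], lo)
  xs <- seq(re_range[1], re_range[2], length.out = n)
  ys <- seq(im_range[1], im_range[2], length.out = n)
  L <- outer(xs, ys, function(a, b) complex(real = a, imaginary = b))
  Ev <- matrix(evans_det_vec(as.vector(L), pulse), n, n)
  sR <- Re(Ev) > 0; sI <- Im(Ev) > 0
  cand <- c()
  cross <- function(s) {
    (s[-n, -n] != s[-1, -n]) | (s[-n, -n] != s[-n, -1]) |
      (s[-n, -n] != s[-1, -1])
  }
  hit <- cross(sR) & cross(sI)
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx)) {
    cand <- complex(real = (xs[idx[, 1]] + xs[idx[, 1] + 1]) / 2,
                    imaginary = (ys[idx[, 2]] + ys[idx[, 2] + 1]) / 2)
  }
  roots <- c()
  for (l0 in cand) {
    l <- polish_eigenvalue(l0, pulse)
    if (!is.finite(Re(l)) || abs(evans_fun(l, pulse)) > 1e-8) next
    if (Re(l) < re_range[1] - 0.05 || Re(l) > re_range[2] + 0.05) next
    if (abs(Im(l)) > max(abs(im_range)) + 0.05) next
    if (abs(l) < 1e-6) next  # translation root
    if (!length(roots) || min(abs(roots - l)) > 1e-6)
      roots <- c(roots, l)
  }
  if (length(roots)) roots <- roots[order(-Re(roots), abs(Im(roots)))]
  else roots <- complex(0)
  structure(list(eigenvalues = roots,
                 translation_residual = abs(evans_fun(0, pulse)),
                 re_grid = xs, im_grid = ys, E = Ev,
                 rectangle = list(re = re_range, im = im_range)),
            class = "evans_eval")
}

#' Leading oscillatory eigenvalue of an Evans evaluation
#'
#' The complex eigenvalue with largest real part among those with positive
#' imaginary part (one member of each conjugate pair), or NULL when the
#' rectangle holds none.
#'
#' @param ev an \code{"evans_eval"}.
#' @return A complex scalar or NULL.
#' @export
leading_complex_eigenvalue <- function(ev) {
  cplx <- ev$eigenvalues[Im(ev$eigenvalues) > 1e-6]
  if (!length(cplx)) return(NULL)
  cplx[which.max(Re(cplx))]
}

#' Track the leading oscillatory eigenvalue along a parameter path
#'
#' Re-solves the pulse and follows the leading complex-conjugate eigenvalue
#' of the Evans function as one parameter varies, by warm-started Newton
#' polishing with automatic step halving when the eigenvalue or pulse moves
#' too abruptly.
#'
#' @param par a \code{\link{step_params}} at the start of the path.
#' @param param one of \code{"sigma_i"}, \code{"g_ei"}, \code{"g_ad"}.
#' @param to final parameter value.
#' @param step initial parameter step.
#' @param guess pulse guess at the start (passed to
#'   \code{\link{hs_solve_pulse}}).
#' @param lambda0 starting eigenvalue; located by a rectangle scan when
#'   missing.
#' @param jump_tol largest accepted eigenvalue move per step.
#' @return An object of class \code{"eigen_path"}: data frame \code{path}
#'   (param, re, im, c, a, b, d) and the final pulse.
#' @export
track_eigenvalue <- function(par = step_params(),
                             param = c("sigma_i", "g_ei", "g_ad"),
                             to, step = 0.05,
                             guess = c(0.94, 6.1, 0.6, 5.2),
                             lambda0 = NULL, jump_tol = 0.15) {
  param <- match.arg(param)
  pulse <- hs_solve_pulse(par, guess)
  if (is.null(lambda0)) {
    ev <- find_eigenvalues(pulse, re_range = c(-0.6, 0.25),
                           im_range = c(-1, 1), n = 151)
    l <- leading_complex_eigenvalue(ev)
    if (is.null(l)) stop("no oscillatory eigenvalue found at the path start")
  } else l <- as.complex(lambda0)
  p <- par[[param]]
  path <- data.frame(param = p, re = Re(l), im = Im(l), c = pulse$c,
                     a = pulse$a, b = pulse$b, d = pulse$d)
  dirn <- sign(to - p)
  g <- c(pulse$c, pulse$a, pulse$b, pulse$d)
  h <- step
  while (dirn * (to - p) > 1e-12) {
    h_try <- min(h, abs(to - p))
    p_new <- p + dirn * h_try
    par_new <- par
    par_new[[param]] <- p_new
    par_new <- do.call(step_params, par_new[c("g_ee", "g_ei", "g_ie",
                                              "g_ii", "g_ad", "tau_e",
                                              "tau_i", "tau_z", "sigma_e",
                                              "sigma_i", "sigma_z", "a1",
                                              "a2")])
    ok <- TRUE
    pulse_new <- tryCatch(hs_solve_pulse(par_new, g),
                          error = function(e) NULL)
    if (is.null(pulse_new)) ok <- FALSE
    if (ok) {
      l_new <- polish_eigenvalue(l, pulse_new)
      if (!is.finite(Re(l_new)) || abs(l_new - l) > jump_tol ||
          Im(l_new) < 0) ok <- FALSE
    }
    if (!ok) {
      h <- h / 2
      if (h < 1e-5) stop("eigenvalue path broke near ", param, " = ", p)
      next
    }
    p <- p_new; pulse <- pulse_new; l <- l_new
    g <- c(pulse$c, pulse$a, pulse$b, pulse$d)
    path <- rbind(path, data.frame(param = p, re = Re(l), im = Im(l),
                                   c = pulse$c, a = pulse$a, b = pulse$b,
                                   d = pulse$d))
    h <- min(step, h * 2)
  }
  structure(list(path = path, pulse = pulse, param = param,
                 lambda = l), class = "eigen_path")
}

#' Hopf destabilization point of the pulse
#'
#' Tracks the leading oscillatory eigenvalue in \code{param} and bisects the
#' zero crossing of its real part (the Hopf bifurcation of the traveling
#' pulse).
#'
#' @inheritParams track_eigenvalue
#' @param range numeric(2) parameter interval searched (the real part must
#'   change sign across it).
#' @param tol bisection tolerance on the parameter.
#' @return List: \code{param_at_crossing}, \code{im_at_crossing} (the Hopf
#'   frequency), and the tracked \code{path}.
#' @export
hopf_crossing <- function(par = step_params(),
                          param = c("sigma_i", "g_ei", "g_ad"),
                          range = c(1.0, 2.2), step = 0.05,
                          guess = c(0.94, 6.1, 0.6, 5.2), tol = 1e-4) {
  param <- match.arg(param)
  par0 <- par
  par0[[param]] <- range[1]
  par0 <- do.call(step_params, par0[c("g_ee", "g_ei", "g_ie", "g_ii",
                                      "g_ad", "tau_e", "tau_i", "tau_z",
                                      "sigma_e", "sigma_i", "sigma_z",
                                      "a1", "a2")])
  tp <- track_eigenvalue(par0, param, to = range[2], step = step,
                         guess = guess)
  path <- tp$path
  cross <- which(diff(sign(path$re)) != 0)
  if (!length(cross))
    stop("real part does not change sign over the tracked range")
  i <- cross[1]
  lo <- path$param[i]; hi <- path$param[i + 1]
  g <- c(path$c[i], path$a[i], path$b[i], path$d[i])
  l <- complex(real = path$re[i], imaginary = path$im[i])
  re_lo <- path$re[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    par_m <- par
    par_m[[param]] <- mid
    par_m <- do.call(step_params, par_m[c("g_ee", "g_ei", "g_ie", "g_ii",
                                          "g_ad", "tau_e", "tau_i",
                                          "tau_z", "sigma_e", "sigma_i",
                                          "sigma_z", "a1", "a2")])
    pm <- hs_solve_pulse(par_m, g)
    lm <- polish_eigenvalue(l, pm)
    if (sign(Re(lm)) == sign(re_lo)) {
      lo <- mid; g <- c(pm$c, pm$a, pm$b, pm$d); l <- lm
    } else hi <- mid
  }
  par_m <- par
  par_m[[param]] <- (lo + hi) / 2
  par_m <- do.call(step_params, par_m[c("g_ee", "g_ei", "g_ie", "g_ii",
                                        "g_ad", "tau_e", "tau_i", "tau_z",
                                        "sigma_e", "sigma_i", "sigma_z",
                                        "a1", "a2")])
  pm <- hs_solve_pulse(par_m, g)
  lm <- polish_eigenvalue(l, pm)
  list(param_at_crossing = (lo + hi) / 2, im_at_crossing = Im(lm),
       lambda = lm, path = path, param = param)
}

#' Trace the Hopf curve in a two-parameter plane
#'
#' For each value of a second parameter, bisects the \code{sigma_i} at which
#' the leading oscillatory eigenvalue crosses the imaginary axis.
#'
#' @param par base \code{\link{step_params}}.
#' @param vary \code{"g_ei"} or \code{"g_ad"}.
#' @param values vector of values for the varied parameter.
#' @param sigma_range \code{sigma_i} search interval.
#' @param ... passed to \code{\link{hopf_crossing}}.
#' @return Data frame with columns \code{value}, \code{sigma_i_hopf},
#'   \code{im} (NA rows where the calculation failed).
#' @export
hopf_curve <- function(par = step_params(), vary = c("g_ei", "g_ad"),
                       values, sigma_range = c(1.0, 2.4), ...) {
  vary <- match.arg(vary)
  rows <- lapply(values, function(v) {
    par_v <- par
    par_v[[vary]] <- v
    par_v <- do.call(step_params, par_v[c("g_ee", "g_ei", "g_ie", "g_ii",
                                          "g_ad", "tau_e", "tau_i",
                                          "tau_z", "sigma_e", "sigma_i",
                                          "sigma_z", "a1", "a2")])
    res <- tryCatch(hopf_crossing(par_v, "sigma_i", range = sigma_range,
                                  ...),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(value = v, sigma_i_hopf = NA_real_, im = NA_real_)
    else
      data.frame(value = v, sigma_i_hopf = res$param_at_crossing,
                 im = res$im_at_crossing)
  })
  do.call(rbind, rows)
}
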