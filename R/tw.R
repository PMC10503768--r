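#' Traveling-wave ODE system of the exponential-kernel field model
#'
#' In the comoving coordinate \eqn{\xi = x + ct} the exponential-kernel field
#' equations reduce to a 7-dimensional ODE: the three kinetic variables plus
#' the two convolutions \eqn{S_e, S_i}, each satisfying
#' \eqn{\sigma^2 S'' = S - s}.  A traveling pulse is a homoclinic orbit to
#' the rest point
#' \eqn{\bar P = (\bar s_e, \bar s_i, \bar z, \bar s_e, 0, \bar s_i, 0)}.
#' With \code{sigma_i = 0} the \eqn{S_i} pair drops out and the system is
#' 5-dimensional.
#'
#' @param u state vector (length 7, or 5 when \code{sigma_i == 0}); for
#'   \code{tw_rhs_mat} a matrix with one state per column.
#' @param c_speed wave speed.
#' @param sys a \code{tw_system} list as returned by \code{\link{tw_system}}.
#' @return Derivative of \code{u} with respect to \eqn{\xi}.
#' @export
tw_rhs <- function(u, c_speed, sys) {
  drop(tw_rhs_mat(matrix(u, ncol = 1L), c_speed, sys))
}

#' @rdname tw_rhs
#' @export
tw_rhs_mat <- function(u, c_speed, sys) {
  lp <- sys$lp; rp <- sys$rp
  se <- u[1, ]; si <- u[2, ]; z <- u[3, ]
  Se <- u[4, ]; Pe <- u[5, ]
  Si <- if (sys$dim == 7L) u[6, ] else si
  Ge <- lp$g_ee * lp$gamma_e * Se - lp$g_ei * lp$gamma_i * Si -
    lp$g_ad * lp$gamma_z * z
  Gi <- lp$g_ie * lp$gamma_e * Se - lp$g_ii * lp$gamma_i * Si
  Fe <- firing_rate(Ge, rp$d_e, rp)
  Fi <- firing_rate(Gi, rp$d_i, rp)
  out <- rbind((-se / lp$tau_e + Fe) / c_speed,
               (-si / lp$tau_i + Fi) / c_speed,
               (-z / lp$tau_z + Fe) / c_speed,
               Pe,
               (Se - se) / sys$sigma_e^2)
  if (sys$dim == 7L)
    out <- rbind(out, u[7, ], (Si - si) / sys$sigma_i^2)
  out
}

#' Construct a traveling-wave system descriptor
#'
#' @param lp local kinetics parameters.
#' @param rp rate-function parameters.
#' @param sigma_e,sigma_i kernel footprints; \code{sigma_i = 0} selects the
#'   reduced 5-dimensional system (pointwise inhibition).
#' @return A list of class \code{"tw_system"}.
#' @export
tw_system <- function(lp = local_params(), rp = rate_params(),
                      sigma_e = 1, sigma_i = 0.5) {
  stopifnot(sigma_e > 0, sigma_i >= 0)
  structure(list(lp = lp, rp = rp, sigma_e = sigma_e, sigma_i = sigma_i,
                 dim = if (sigma_i > 0) 7L else 5L),
            class = "tw_system")
}

tw_jacobian <- function(u, c_speed, sys, h = 1e-7) {
  n <- length(u)
  J <- matrix(0, n, n)
  f0 <- tw_rhs(u, c_speed, sys)
  for (j in seq_len(n)) {
    e <- u; e[j] <- e[j] + h
    J[, j] <- (tw_rhs(e, c_speed, sys) - f0) / h
  }
  J
}

#' Rest point of the wave ODE and its stable/unstable splitting
#'
#' Computes the rest equilibrium of the traveling-wave system and the
#' eigen-decomposition of its linearization.  For the full 7-dimensional
#' system a pulse requires a (2 unstable, 5 stable) splitting; the reduced
#' \code{sigma_i = 0} system has (1, 4).
#'
#' @param sys a \code{\link{tw_system}}.
#' @param c_speed wave speed at which the linearization is evaluated.
#' @return List: \code{P_bar}, eigenvalues \code{values}, right eigenvectors
#'   \code{vectors}, left eigenvectors \code{left} (rows), index sets
#'   \code{unstable}, \code{stable}, and \code{n_unstable}, \code{n_stable}.
#' @export
rest_point_and_splitting <- function(sys, c_speed = 0.5) {
  r <- rest_state(sys$lp, sys$rp)
  P <- if (sys$dim == 7L) c(r, r[1], 0, r[2], 0) else c(r, r[1], 0)
  J <- tw_jacobian(P, c_speed, sys)
  ei <- eigen(J)
  unst <- which(Re(ei$values) > 1e-8)
  stab <- which(Re(ei$values) < -1e-8)
  L <- solve(ei$vectors)
  list(P_bar = P, values = ei$values, vectors = ei$vectors, left = L,
       unstable = unst, stable = stab,
       n_unstable = length(unst), n_stable = length(stab))
}

# Real basis of the unstable right-eigenspace (columns) and real unstable
# left-projector rows; handles a complex-conjugate unstable pair.
unstable_frames <- function(sp) {
  iu <- sp$unstable
  # order by increasing real part so the "slow" direction is column 1
  iu <- iu[order(Re(sp$values[iu]))]
  if (length(iu) == 2L && abs(Im(sp$values[iu[1]])) > 1e-10) {
    v <- sp$vectors[, iu[1]]
    # rotate the complex phase so the largest component is real positive
    v <- v / (v[which.max(abs(v))] / abs(v[which.max(abs(v))]))
    V <- cbind(Re(v), Im(v))
    l <- sp$left[iu[1], ]
    l <- l / (l[which.max(abs(l))] / abs(l[which.max(abs(l))]))
    L <- rbind(Re(l), Im(l))
  } else {
    V <- Re(sp$vectors[, iu, drop = FALSE])
    L <- Re(sp$left[iu, , drop = FALSE])
  }
  # deterministic orientation: largest-magnitude component positive, so the
  # frame varies continuously along a parameter branch
  V <- apply(V, 2L, function(x) {
    x <- x / sqrt(sum(x^2))
    if (x[which.max(abs(x))] < 0) -x else x
  })
  L <- L / sqrt(rowSums(L^2))
  for (r in seq_len(nrow(L)))
    if (L[r, which.max(abs(L[r, ]))] < 0) L[r, ] <- -L[r, ]
  list(V = as.matrix(V), L = matrix(L, nrow = length(iu)))
}

# Fixed-step RK4 integration of the wave ODE.
tw_integrate <- function(u0, c_speed, sys, xi_max, dxi = 0.02,
                         blow_up = 5) {
  n <- ceiling(xi_max / dxi)
  u <- u0
  traj <- matrix(0, n + 1L, length(u0))
  traj[1L, ] <- u
  for (k in seq_len(n)) {
    k1 <- tw_rhs(u, c_speed, sys)
    k2 <- tw_rhs(u + dxi / 2 * k1, c_speed, sys)
    k3 <- tw_rhs(u + dxi / 2 * k2, c_speed, sys)
    k4 <- tw_rhs(u + dxi * k3, c_speed, sys)
    u <- u + dxi / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(u)) || max(abs(u)) > blow_up) {
      return(list(xi = (0:(k - 1)) * dxi,
                  traj = traj[seq_len(k), , drop = FALSE], blew_up = TRUE))
    }
    traj[k + 1L, ] <- u
  }
  list(xi = (0:n) * dxi, traj = traj, blew_up = FALSE)
}

# Outcome of a shot from the unstable manifold.  After the excursion the
# residual unstable content grows again and the orbit finally departs
# upward (a second excursion; S_e deviation -> +infinity) or downward
# (S_e deviation -> -infinity).  A homoclinic sits exactly on the boundary
# between the two departure directions.
shot_outcome <- function(cc, sys, sp, V1, eps, xi_len, dxi) {
  orb <- tw_integrate(sp$P_bar + eps * V1, cc, sys, xi_len, dxi)
  se <- orb$traj[, 1]
  rest <- sp$P_bar[1]
  amp <- max(se) - rest
  n <- nrow(orb$traj)
  Sdev <- orb$traj[n, 4] - sp$P_bar[4]
  list(kind = if (Sdev > 0) "up" else "down", orb = orb, amp = amp)
}

#' Shoot for the traveling pulse of the reduced (sigma_i = 0) system
#'
#' The 5-dimensional system has a 1-dimensional unstable manifold, so the
#' speed is the only unknown.  The trajectory leaves the rest point along
#' the unstable eigenvector; below the pulse speed it relaunches a second
#' excursion, above it decays back to rest after one excursion.  The speed
#' is located by bisection on that boundary.
#'
#' @param sys a \code{\link{tw_system}} with \code{sigma_i = 0}.
#' @param c_range bracket of speeds searched.
#' @param branch \code{"fast"} (upper boundary of the returning window, the
#'   branch that is stable as a wave) or \code{"slow"}.
#' @param eps departure amplitude along the unstable eigenvector.
#' @param xi_len integration length in \eqn{\xi}.
#' @param dxi integration step.
#' @param tol bisection tolerance on \code{c}.
#' @return List with \code{c}, the orbit (\code{xi}, \code{traj}), the
#'   splitting, and the scan table; error when no pulse is found.
#' @export
shoot_5d <- function(sys, c_range = c(0.05, 3), branch = c("fast", "slow"),
                     eps = 1e-5, xi_len = 80, dxi = 0.02, tol = 1e-8) {
  branch <- match.arg(branch)
  stopifnot(sys$dim == 5L)
  sp <- rest_point_and_splitting(sys, mean(c_range))
  if (sp$n_unstable != 1L)
    stop("rest-point splitting is (", sp$n_unstable, ",", sp$n_stable,
         "), not the (1,4) required for the reduced system")
  fr <- unstable_frames(sp)
  amp_min <- 10 * max(sp$P_bar[1], 1e-4)
  for (sgn in c(-1, 1)) {
    V1 <- sgn * drop(fr$V[, 1])
    probe <- tw_integrate(sp$P_bar + eps * V1, mean(c_range), sys,
                          xi_len, dxi)
    if (max(probe$traj[, 1]) - sp$P_bar[1] < amp_min) next
    cs <- seq(c_range[1], c_range[2], length.out = 60)
    kinds <- vapply(cs, function(cc)
      shot_outcome(cc, sys, sp, V1, eps, xi_len, dxi)$kind, character(1))
    dn <- which(kinds == "down")
    if (!length(dn) || length(dn) == length(cs)) next
    # the "down" window is bounded below by the slow and above by the fast
    # homoclinic
    bnd <- if (branch == "fast") {
      j <- max(dn)
      if (j == length(cs)) next
      c(cs[j], cs[j + 1])
    } else {
      j <- min(dn)
      if (j == 1L) next
      c(cs[j - 1], cs[j])
    }
    lo <- bnd[1]; hi <- bnd[2]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      k <- shot_outcome(mid, sys, sp, V1, eps, xi_len, dxi)$kind
      if (branch == "fast") {
        if (k == "down") lo <- mid else hi <- mid
      } else {
        if (k == "down") hi <- mid else lo <- mid
      }
    }
    c_star <- (lo + hi) / 2
    out <- shot_outcome(c_star, sys, sp, V1, eps, xi_len, dxi)
    return(list(c = c_star, xi = out$orb$xi, traj = out$orb$traj,
                splitting = sp, sign = sgn, eps = eps, xi_len = xi_len,
                dxi = dxi, branch = branch))
  }
  stop("no pulse found: no return/escape boundary inside the speed bracket")
}

## ---------------------------------------------------------------------
## Boundary-value formulation: midpoint collocation on [0, L_xi], the left
## end anchored on a small circle in the unstable eigenplane (radius delta,
## angle phi), projection conditions onto the unstable left eigenvectors at
## the right end.  Unknowns: (c, phi, U_1..U_N) and optionally a model
## parameter for pseudo-arclength continuation.
## ---------------------------------------------------------------------

tw_set_param <- function(sys, param, value) {
  if (is.null(param)) return(sys)
  if (param == "sigma_i") tw_system(sys$lp, sys$rp, sys$sigma_e, value)
  else {
    lp <- sys$lp; lp[[param]] <- value
    tw_system(lp, sys$rp, sys$sigma_e, sys$sigma_i)
  }
}

# Residual of the BVP.  y = (c, phi, vec(U_1..U_N)); when `param` is given,
# y = (p, c, phi, vec(...)) and an arclength row (pred, tang) is appended.
tw_bvp_residual <- function(y, sys, N, h, delta, param = NULL,
                            pred = NULL, tang = NULL) {
  off <- if (is.null(param)) 0L else 1L
  if (!is.null(param)) sys <- tw_set_param(sys, param, y[1])
  cc <- y[off + 1L]; phi <- y[off + 2L]
  if (cc <= 0) return(rep(1e3, 7 * N + 2 + off))
  sp <- rest_point_and_splitting(sys, cc)
  if (sp$n_unstable != 2L) return(rep(1e3, 7 * N + 2 + off))
  fr <- unstable_frames(sp)
  U0 <- sp$P_bar + delta * (cos(phi) * fr$V[, 1] + sin(phi) * fr$V[, 2])
  U <- cbind(U0, matrix(y[(off + 3L):length(y)], nrow = 7L))
  mid <- (U[, 1:N] + U[, 2:(N + 1)]) / 2
  f <- tw_rhs_mat(mid, cc, sys)
  Rcol <- U[, 2:(N + 1)] - U[, 1:N] - h * f
  Rbc <- as.numeric(fr$L %*% (U[, N + 1L] - sp$P_bar))
  out <- c(as.numeric(Rcol), Rbc)
  if (!is.null(param)) {
    arc <- sum(tang * (y[1:2] - pred[1:2]))
    out <- c(out, arc)
  }
  out
}

# Sparse Newton solve of the BVP; returns the solution vector and residual.
tw_bvp_newton <- function(y, sys, N, h, delta, param = NULL, pred = NULL,
                          tang = NULL, tol = 1e-9, maxit = 60) {
  off <- if (is.null(param)) 0L else 1L
  nvar <- length(y)
  resid <- function(yy) tw_bvp_residual(yy, sys, N, h, delta, param,
                                        pred, tang)
  R <- resid(y)
  for (it in seq_len(maxit)) {
    nR <- max(abs(R))
    if (nR < tol) return(list(y = y, R = R, converged = TRUE, iter = it))
    J <- tw_bvp_jacobian(y, R, sys, N, h, delta, param, pred, tang, resid)
    dy <- tryCatch(as.numeric(Matrix::solve(J, -R)),
                   error = function(e) NULL)
    if (is.null(dy) || !all(is.finite(dy)))
      return(list(y = y, R = R, converged = FALSE, iter = it))
    lam <- 1
    repeat {
      yn <- y + lam * dy
      Rn <- resid(yn)
      if (max(abs(Rn)) < nR || lam < 1e-3) break
      lam <- lam / 2
    }
    y <- yn; R <- Rn
  }
  list(y = y, R = R, converged = max(abs(R)) < tol * 100, iter = maxit)
}

tw_bvp_jacobian <- function(y, R, sys, N, h, delta, param, pred, tang,
                            resid) {
  off <- if (is.null(param)) 0L else 1L
  nvar <- length(y)
  nres <- length(R)
  sys_c <- if (is.null(param)) sys else tw_set_param(sys, param, y[1])
  cc <- y[off + 1L]; phi <- y[off + 2L]
  sp <- rest_point_and_splitting(sys_c, cc)
  fr <- unstable_frames(sp)
  U0 <- sp$P_bar + delta * (cos(phi) * fr$V[, 1] + sin(phi) * fr$V[, 2])
  U <- cbind(U0, matrix(y[(off + 3L):length(y)], nrow = 7L))
  mid <- (U[, 1:N] + U[, 2:(N + 1)]) / 2
  f0 <- tw_rhs_mat(mid, cc, sys_c)
  # df/dU at every midpoint via vectorized finite differences
  A <- array(0, c(7, 7, N))
  for (j in 1:7) {
    dm <- mid
    hj <- 1e-7 * pmax(1, abs(mid[j, ]))
    dm[j, ] <- dm[j, ] + hj
    A[, j, ] <- (tw_rhs_mat(dm, cc, sys_c) - f0) / rep(hj, each = 7)
  }
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  idxU <- function(k) off + 2L + (k - 1L) * 7L + 1:7  # columns of U_k
  for (k in 1:N) {
    rows <- (k - 1L) * 7L + 1:7
    Bk <- diag(7) - (h / 2) * A[, , k]
    ii <- c(ii, rep(rows, times = 7)); jj <- c(jj, rep(idxU(k), each = 7))
    vv <- c(vv, as.numeric(Bk))
    if (k > 1L) {
      Ck <- -diag(7) - (h / 2) * A[, , k]
      ii <- c(ii, rep(rows, times = 7))
      jj <- c(jj, rep(idxU(k - 1L), each = 7))
      vv <- c(vv, as.numeric(Ck))
    }
  }
  # right boundary rows
  rbc <- 7L * N + 1:2
  ii <- c(ii, rep(rbc, times = 7)); jj <- c(jj, rep(idxU(N), each = 2))
  vv <- c(vv, as.numeric(fr$L))
  J <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nres, nvar))
  # dense columns (parameter, c, phi) by full-residual finite differences
  dense_cols <- seq_len(off + 2L)
  for (q in dense_cols) {
    hq <- 1e-7 * max(1, abs(y[q]))
    yq <- y; yq[q] <- yq[q] + hq
    J[, q] <- (resid(yq) - R) / hq
  }
  if (!is.null(param)) {
    # arclength row: only p and c enter
    J[nres, ] <- 0
    J[nres, 1L] <- tang[1]
    J[nres, 2L] <- tang[2]
  }
  J
}

#' Refine a crude pulse into a boundary-value solution of the full system
#'
#' Takes a crude orbit (from \code{\link{shoot_5d}} or a field-simulation
#' profile), builds the 7-component mesh profile, and solves the collocation
#' boundary-value problem for \code{(c, phi, profile)}.
#'
#' @param sys a 7-dimensional \code{\link{tw_system}}.
#' @param guess list with \code{c} and either \code{xi}/\code{traj} (columns
#'   s_e, s_i, z, S_e, S_e', [S_i, S_i']) or nothing (a field simulation is
#'   run to build the profile).
#' @param L_xi truncation length of the \eqn{\xi} interval.
#' @param N number of mesh intervals.
#' @param delta radius of the departure circle in the unstable eigenplane.
#' @return An object of class \code{"tw_pulse"}: \code{c}, \code{phi},
#'   mesh \code{xi}, profile matrix \code{traj} (rows = mesh points,
#'   columns = the 7 components), rest point, residual norm, and solver
#'   metadata.
#' @export
tw_bvp_refine <- function(sys, guess, L_xi = 50, N = 700, delta = 1e-4) {
  stopifnot(sys$dim == 7L)
  h <- L_xi / N
  xi <- seq(0, L_xi, length.out = N + 1L)
  sp <- rest_point_and_splitting(sys, guess$c)
  if (sp$n_unstable != 2L)
    stop("rest-point splitting is (", sp$n_unstable, ",", sp$n_stable,
         "), outside the validity region of the pulse construction")
  U <- tw_guess_profile(sys, guess, sp, xi, delta)
  y0 <- c(guess$c, attr(U, "phi"), as.numeric(U[, -1L]))
  res <- tw_bvp_newton(y0, sys, N, h, delta)
  if (!res$converged)
    stop("BVP refinement did not converge; last residual ",
         format(max(abs(res$R))))
  tw_pulse_from_y(res$y, sys, N, h, delta, xi, residual = max(abs(res$R)))
}

tw_pulse_from_y <- function(y, sys, N, h, delta, xi, residual,
                            param = NULL) {
  off <- if (is.null(param)) 0L else 1L
  if (!is.null(param)) sys <- tw_set_param(sys, param, y[1])
  cc <- y[off + 1L]; phi <- y[off + 2L]
  sp <- rest_point_and_splitting(sys, cc)
  fr <- unstable_frames(sp)
  U0 <- sp$P_bar + delta * (cos(phi) * fr$V[, 1] + sin(phi) * fr$V[, 2])
  U <- cbind(U0, matrix(y[(off + 3L):length(y)], nrow = 7L))
  structure(list(c = cc, phi = phi, xi = xi, traj = t(U),
                 P_bar = sp$P_bar, splitting = sp, residual = residual,
                 delta = delta, N = N, h = h, L_xi = max(xi), sys = sys),
            class = "tw_pulse")
}

# Build a mesh profile from a crude orbit: align the s_e upstroke, pad the
# tail with the rest point, and estimate the departure angle phi.
tw_guess_profile <- function(sys, guess, sp, xi, delta) {
  tr <- guess$traj
  if (ncol(tr) == 5L) {
    # lift the reduced orbit: S_i = s_i, S_i' by finite differences
    dsi <- c(diff(tr[, 2]) / diff(guess$xi), 0)
    tr <- cbind(tr[, 1:5], tr[, 2], dsi)
  }
  # truncate the crude orbit where it starts to escape again; the slaved
  # adaptation (slowest tail) is excluded from the distance so the return
  # point reflects the coupled variables
  se <- tr[, 1]
  ipk <- which.max(se)
  dev <- sqrt(rowSums(sweep(tr[, -3L, drop = FALSE], 2L,
                            sp$P_bar[-3L])^2))
  iend <- ipk - 1L + which.min(dev[ipk:length(dev)])
  tr <- tr[seq_len(iend), , drop = FALSE]
  xig <- guess$xi[seq_len(iend)]
  # shift so that the profile starts where |U - P_bar| = delta-ish
  dev <- dev[seq_len(iend)]
  i0 <- which(dev > 10 * delta)[1]
  if (is.na(i0)) i0 <- 1L
  xig <- xig - xig[i0]
  U <- matrix(rep(sp$P_bar, length(xi)), nrow = 7L)
  for (j in 1:7) {
    keep <- xig >= 0
    U[j, ] <- stats::approx(xig[keep], tr[keep, j], xout = xi,
                            rule = 2)$y
  }
  # beyond the crude orbit, decay the deviation at the slowest stable rate
  xi_end <- max(xig)
  tail_idx <- which(xi > xi_end)
  if (length(tail_idx)) {
    rate <- 1 / (guess$c * sys$lp$tau_z)
    dev_end <- U[, tail_idx[1]] - sp$P_bar
    for (m in tail_idx)
      U[, m] <- sp$P_bar + dev_end * exp(-rate * (xi[m] - xi_end))
  }
  fr <- unstable_frames(sp)
  d0 <- U[, 1] - sp$P_bar
  a <- sum(fr$V[, 1] * d0); b <- sum(fr$V[, 2] * d0)
  phi <- atan2(b, a)
  U[, 1] <- sp$P_bar + delta * (cos(phi) * fr$V[, 1] + sin(phi) * fr$V[, 2])
  attr(U, "phi") <- phi
  U
}

#' Compute the traveling pulse of the full system at given parameters
#'
#' Convenience driver: solves the reduced \code{sigma_i = 0} system by
#' shooting, lifts the orbit to seven dimensions, refines it as a
#' boundary-value problem at a small inhibitory footprint, and continues the
#' solution in \code{sigma_i} up to the requested value.
#'
#' @param sys target \code{\link{tw_system}} (with the desired
#'   \code{sigma_i}).
#' @param sigma_start footprint at which the lifted solution is first
#'   refined.
#' @param L_xi,N,delta boundary-value controls, see
#'   \code{\link{tw_bvp_refine}}.
#' @param ds continuation step in \code{sigma_i}.
#' @return A \code{"tw_pulse"} at the target parameters.
#' @export
lift_and_refine <- function(sys, sigma_start = 0.15, L_xi = 50, N = 700,
                            delta = 1e-4, ds = 0.1) {
  sys0 <- tw_system(sys$lp, sys$rp, sys$sigma_e, 0)
  crude <- shoot_5d(sys0)
  sys_s <- tw_system(sys$lp, sys$rp, sys$sigma_e, sigma_start)
  pulse <- tw_bvp_refine(sys_s, crude, L_xi = L_xi, N = N, delta = delta)
  if (abs(sys$sigma_i - sigma_start) < 1e-12) return(pulse)
  br <- continue_branch(pulse, "sigma_i", to = sys$sigma_i, ds = ds,
                        stop_at_target = TRUE)
  if (is.null(br$final) ||
      abs(utils::tail(br$points$param, 1) - sys$sigma_i) > 1e-8)
    stop("continuation in sigma_i stopped before the target (",
         br$reason, ")")
  br$final
}

# Excursion plateau length: xi-extent where s_e exceeds half its max above
# rest.  Grows without bound at a pulse-to-front transition.
plateau_length <- function(pulse) {
  se <- pulse$traj[, 1]
  rest <- pulse$P_bar[1]
  thr <- rest + 0.5 * (max(se) - rest)
  sum(se > thr) * (pulse$xi[2] - pulse$xi[1])
}

#' Continue a pulse branch in one parameter
#'
#' Pseudo-arclength continuation of the boundary-value pulse in
#' (parameter, c): at each step the full collocation system is re-solved
#' with an arclength constraint, so the branch can round folds.  Folds are
#' detected as sign changes of the parameter progression and refined by a
#' quadratic fit of parameter against speed; a pulse-to-front transition is
#' flagged when the excursion plateau grows beyond \code{plateau_max}.
#'
#' @param pulse converged \code{"tw_pulse"} at the branch start.
#' @param param one of \code{"g_ei"}, \code{"g_ad"}, \code{"sigma_i"}.
#' @param to parameter value toward which to continue.
#' @param ds initial arclength step (parameter units).
#' @param max_steps maximum number of branch points.
#' @param ds_min smallest step before the branch is terminated.
#' @param ds_max largest step.
#' @param plateau_max excursion length (xi units) beyond which the orbit is
#'   declared front-like.
#' @param stop_at_target land exactly on \code{to} (used when the branch is
#'   a means to reach a parameter value rather than to trace a curve).
#' @param stop_after_fold stop a few points after the first fold instead of
#'   tracing the returning (slow) branch to its end.
#' @return An object of class \code{"tw_branch"}: data frame \code{points}
#'   (param, c, amplitude, plateau), \code{fold} (refined location or NA),
#'   \code{front_transition} (parameter or NA), the termination
#'   \code{reason}, and \code{final} (the last converged pulse).
#' @export
continue_branch <- function(pulse, param = c("g_ei", "g_ad", "sigma_i"),
                            to, ds = 0.1, max_steps = 300, ds_min = 1e-4,
                            ds_max = NULL, plateau_max = 30,
                            stop_at_target = FALSE,
                            stop_after_fold = FALSE) {
  param <- match.arg(param)
  sys <- pulse$sys
  p0 <- if (param == "sigma_i") sys$sigma_i else sys$lp[[param]]
  if (is.null(ds_max)) ds_max <- ds
  N <- pulse$N; h <- pulse$h; delta <- pulse$delta; xi <- pulse$xi
  dirn <- sign(to - p0)
  amp0 <- max(pulse$traj[, 1])
  pts <- data.frame(param = p0, c = pulse$c, amplitude = amp0,
                    plateau = plateau_length(pulse))
  y <- c(p0, pulse$c, pulse$phi, as.numeric(t(pulse$traj)[, -1L]))
  tang <- c(dirn, 0)
  reason <- "max steps reached"
  front_at <- NA_real_
  step <- ds
  final <- pulse
  base_sys <- tw_set_param(sys, param, p0)  # template; param overridden by y[1]
  for (k in seq_len(max_steps)) {
    pred <- y
    pred[1] <- y[1] + step * tang[1]
    pred[2] <- y[2] + step * tang[2]
    if (stop_at_target && dirn * (pred[1] - to) > 0) {
      # land exactly on the target with a plain (non-arclength) solve
      yt <- y; yt[1] <- to
      rest <- tw_bvp_newton(yt[-1L], tw_set_param(base_sys, param, to),
                            N, h, delta)
      if (rest$converged) {
        final <- tw_pulse_from_y(rest$y, tw_set_param(base_sys, param, to),
                                 N, h, delta, xi,
                                 residual = max(abs(rest$R)))
        pts <- rbind(pts, data.frame(param = to, c = final$c,
                                     amplitude = max(final$traj[, 1]),
                                     plateau = plateau_length(final)))
        reason <- "reached target"
        break
      }
      step <- step / 2
      if (step < ds_min) { reason <- "step-size underflow"; break }
      next
    }
    res <- tw_bvp_newton(pred, base_sys, N, h, delta, param = param,
                         pred = pred, tang = tang)
    ok <- res$converged && res$y[2] > 0
    if (ok) {
      cand <- tw_pulse_from_y(res$y, base_sys, N, h, delta, xi,
                              residual = max(abs(res$R)), param = param)
      amp <- max(cand$traj[, 1]) - cand$P_bar[1]
      pl <- plateau_length(cand)
      if (amp < 5 * max(cand$P_bar[1], 1e-4)) ok <- FALSE
      if (ok && pl > plateau_max) {
        front_at <- res$y[1]
        reason <- "pulse-to-front transition"
        pts <- rbind(pts, data.frame(param = res$y[1], c = res$y[2],
                                     amplitude = amp + cand$P_bar[1],
                                     plateau = pl))
        final <- cand
        break
      }
    }
    if (!ok) {
      step <- step / 2
      if (step < ds_min) { reason <- "step-size underflow"; break }
      next
    }
    dp <- res$y[1] - y[1]; dc <- res$y[2] - y[2]
    nrm <- sqrt(dp^2 + dc^2)
    tang <- c(dp, dc) / nrm
    y <- res$y
    final <- tw_pulse_from_y(y, base_sys, N, h, delta, xi,
                             residual = max(abs(res$R)), param = param)
    pts <- rbind(pts, data.frame(param = y[1], c = y[2],
                                 amplitude = max(final$traj[, 1]),
                                 plateau = plateau_length(final)))
    step <- min(ds_max, step * 1.5)
    if (!stop_at_target &&
        ((dirn > 0 && y[1] >= to) || (dirn < 0 && y[1] <= to))) {
      reason <- "reached target"
      break
    }
    if (stop_at_target && dirn * (y[1] - to) >= 0) {
      reason <- "reached target"
      break
    }
    if (nrow(pts) > 5 && ((dirn > 0 && tang[1] < 0 && y[1] < p0) ||
                          (dirn < 0 && tang[1] > 0 && y[1] > p0))) {
      reason <- "returned past start after fold"
      break
    }
    if (stop_after_fold && nrow(pts) > 4) {
      dpar <- diff(pts$param)
      if (any(dpar[-1] * dpar[-length(dpar)] < 0) &&
          sign(tang[1]) != dirn &&
          abs(y[1] - max(dirn * pts$param) * dirn) >
            0.02 * abs(to - p0)) {
        reason <- "fold traversed"
        break
      }
    }
  }
  fold_at <- NA_real_
  dpar <- diff(pts$param)
  flip <- which(dpar[-1] * dpar[-length(dpar)] < 0)
  if (length(flip)) {
    i <- flip[1] + 1L
    idx <- max(1, i - 1):min(nrow(pts), i + 1)
    if (length(idx) == 3 && length(unique(pts$c[idx])) == 3) {
      fit <- stats::lm(param ~ c + I(c^2), data = pts[idx, ])
      cf <- stats::coef(fit)
      c_star <- -cf[2] / (2 * cf[3])
      fold_at <- unname(cf[1] + cf[2] * c_star + cf[3] * c_star^2)
    } else {
      fold_at <- pts$param[i]
    }
    if (reason == "max steps reached") reason <- "fold traversed"
  }
  structure(list(points = pts, fold = fold_at, front_transition = front_at,
                 reason = reason, param = param, final = final),
            class = "tw_branch")
}
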