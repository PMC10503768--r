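#' Right-hand side of the space-clamped mean-field kinetics
#'
#' The three-variable \eqn{(s_e, s_i, z)} Wilson-Cowan-like system:
#' \deqn{\dot s_e = -s_e/\tau_e + F(g_{ee}\gamma_e s_e - g_{ei}\gamma_i s_i -
#'   g_{ad}\gamma_z z,\; d_e)}
#' \deqn{\dot s_i = -s_i/\tau_i + F(g_{ie}\gamma_e s_e - g_{ii}\gamma_i s_i,\;
#'   d_i)}
#' \deqn{\dot z = -z/\tau_z + F(\cdot, d_e)} with the adaptation driven by
#' the same input as \eqn{s_e}.
#'
#' @param state numeric(3): \code{c(s_e, s_i, z)}.
#' @param lp a \code{\link{local_params}} object.
#' @param rp a \code{\link{rate_params}} object.
#' @return numeric(3) time derivatives (1/msec).
#' @export
local_rhs <- function(state, lp = local_params(), rp = rate_params()) {
  se <- state[1]; si <- state[2]; z <- state[3]
  Ge <- lp$g_ee * lp$gamma_e * se - lp$g_ei * lp$gamma_i * si -
    lp$g_ad * lp$gamma_z * z
  Gi <- lp$g_ie * lp$gamma_e * se - lp$g_ii * lp$gamma_i * si
  Gz <- if (lp$z_input == "literal") {
    lp$g_ee * lp$gamma_i * se - lp$g_ei * lp$gamma_i * si -
      lp$g_ad * lp$gamma_z * z
  } else Ge
  c(-se / lp$tau_e + firing_rate(Ge, rp$d_e, rp),
    -si / lp$tau_i + firing_rate(Gi, rp$d_i, rp),
    -z / lp$tau_z + firing_rate(Gz, rp$d_e, rp))
}

#' Simulate the space-clamped mean-field kinetics
#'
#' @param init numeric(3) initial state.
#' @param lp,rp parameter objects.
#' @param T_total,dt time span and output step (msec).
#' @return A matrix with columns \code{time, s_e, s_i, z}.
#' @export
simulate_local <- function(init = c(0.015, 0, 0), lp = local_params(),
                           rp = rate_params(), T_total = 300, dt = 0.1) {
  f <- function(t, y, parms) list(local_rhs(y, lp, rp))
  out <- deSolve::ode(y = c(s_e = init[1], s_i = init[2], z = init[3]),
                      times = seq(0, T_total, by = dt), func = f,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  colnames(out)[1] <- "time"
  unclass(out)
}

local_jacobian <- function(state, lp, rp, h = 1e-7) {
  J <- matrix(0, 3, 3)
  f0 <- local_rhs(state, lp, rp)
  for (j in 1:3) {
    e <- state; e[j] <- e[j] + h
    J[, j] <- (local_rhs(e, lp, rp) - f0) / h
  }
  J
}

classify_eigen <- function(ev) {
  re <- Re(ev)
  n_pos <- sum(re > 0)
  cplx <- any(abs(Im(ev)) > 1e-9)
  if (n_pos == 0) {
    if (cplx) "stable focus" else "stable node"
  } else if (n_pos == length(ev)) {
    if (cplx) "unstable focus" else "unstable node"
  } else "saddle"
}

#' Locate and classify equilibria of the local kinetics
#'
#' Multi-start Newton search over a box, followed by de-duplication and
#' Jacobian-based classification of each root.
#'
#' @param lp,rp parameter objects.
#' @param box upper corner of the search box; starts are taken on a grid in
#'   \code{[0, box]} for each variable.
#' @param n_starts grid resolution per dimension.
#' @param tol root tolerance on the vector field norm.
#' @return A data frame with columns \code{s_e, s_i, z, class} and
#'   eigenvalue real parts \code{re1 <= re2 <= re3}; zero rows (with a
#'   warning) when no root is found.
#' @export
find_equilibria <- function(lp = local_params(), rp = rate_params(),
                            box = c(0.4, 0.25, 6), n_starts = 8L,
                            tol = 1e-9) {
  newton <- function(x0) {
    x <- x0
    for (it in 1:80) {
      f <- local_rhs(x, lp, rp)
      if (!all(is.finite(f))) return(NULL)
      if (sqrt(sum(f^2)) < tol) return(x)
      J <- local_jacobian(x, lp, rp)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      # damped update, state kept non-negative-ish for the search
      lam <- 1
      repeat {
        xn <- x - lam * step
        fn <- local_rhs(xn, lp, rp)
        if (all(is.finite(fn)) &&
            (sqrt(sum(fn^2)) < sqrt(sum(f^2)) || lam < 1e-3)) break
        lam <- lam / 2
      }
      x <- xn
    }
    if (sqrt(sum(local_rhs(x, lp, rp)^2)) < tol * 100) x else NULL
  }
  grids <- lapply(box, function(b) seq(0, b, length.out = n_starts))
  starts <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    r <- newton(starts[k, ])
    if (is.null(r)) next
    if (any(r < -1e-6) || any(r > 2 * box)) next
    dup <- any(vapply(roots, function(q) sqrt(sum((q - r)^2)) < 1e-6,
                      logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots)) {
    warning("no equilibrium found in the search box")
    return(data.frame(s_e = numeric(0), s_i = numeric(0), z = numeric(0),
                      class = character(0)))
  }
  rows <- lapply(roots, function(r) {
    ev <- eigen(local_jacobian(r, lp, rp), only.values = TRUE)$values
    re <- sort(Re(ev))
    data.frame(s_e = r[1], s_i = r[2], z = r[3],
               class = classify_eigen(ev),
               re1 = re[1], re2 = re[2], re3 = re[3])
  })
  out <- do.call(rbind, rows)
  out[order(out$s_e), , drop = FALSE]
}

#' Rest state of the local kinetics
#'
#' The smallest-\code{s_e} stable equilibrium (the quiescent state the
#' traveling pulse leaves and returns to).
#'
#' @param lp,rp parameter objects.
#' @return numeric(3) rest state \code{c(s_e, s_i, z)}.
#' @export
rest_state <- function(lp = local_params(), rp = rate_params()) {
  key <- paste(signif(c(lp$g_ee, lp$g_ei, lp$g_ie, lp$g_ii, lp$g_ad,
                        lp$gamma_e, lp$gamma_i, lp$gamma_z,
                        lp$tau_e, lp$tau_i, lp$tau_z,
                        rp$g_L, rp$C_m, rp$E_L, rp$E_T, rp$d_e, rp$d_i),
                      14), collapse = "|")
  hit <- .eiwaves_cache$rest[[key]]
  if (!is.null(hit)) return(hit)
  # relaxed fixed-point iteration of s = tau * F(...) from zero stays in the
  # quiescent basin even when the kinetics are bistable
  tau <- c(lp$tau_e, lp$tau_i, lp$tau_z)
  x <- c(0, 0, 0)
  for (it in 1:5000) {
    f <- local_rhs(x, lp, rp)
    xn <- x + 0.2 * tau * f
    if (max(abs(xn - x)) < 1e-15) break
    x <- xn
  }
  # Newton polish with a step clamp so we do not leave the quiescent basin
  for (it in 1:50) {
    f <- local_rhs(x, lp, rp)
    if (sqrt(sum(f^2)) < 1e-13) break
    st <- solve(local_jacobian(x, lp, rp), f)
    st <- pmin(pmax(st, -0.01), 0.01)
    x <- x - st
  }
  if (length(.eiwaves_cache$rest) > 4096) .eiwaves_cache$rest <- list()
  .eiwaves_cache$rest[[key]] <- x
  x
}

.eiwaves_cache <- new.env(parent = emptyenv())
.eiwaves_cache$rest <- list()
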