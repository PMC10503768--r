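# Small damped Newton solver with a finite-difference Jacobian, used by the
# dense root-finding problems (threshold equations, equilibrium search
# helpers).
newton_fd <- function(fun, x0, tol = 1e-10, maxit = 40, h = 1e-7,
                      damp_min = 1e-4) {
  x <- x0
  f <- fun(x)
  for (it in seq_len(maxit)) {
    nf <- sqrt(sum(f^2))
    if (nf < tol) return(list(x = x, f = f, converged = TRUE, iter = it))
    J <- matrix(0, length(f), length(x))
    for (j in seq_along(x)) {
      hj <- h * max(1, abs(x[j]))
      e <- x; e[j] <- e[j] + hj
      J[, j] <- (fun(e) - f) / hj
    }
    step <- tryCatch(qr.solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      return(list(x = x, f = f, converged = FALSE, iter = it))
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- fun(xn)
      if (sqrt(sum(fn^2)) < nf || lam < damp_min) break
      lam <- lam / 2
    }
    x <- xn; f <- fn
  }
  list(x = x, f = f, converged = sqrt(sum(f^2)) < tol * 100, iter = maxit)
}
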