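#' Distance-dependent Bernoulli connection-probability kernels
#'
#' Probability that a source at position \code{y} connects to a target at
#' position \code{x}, for each of the four projections.  Excitatory axons
#' have footprint 1/10 of the domain (E-to-E additionally thinned to a peak
#' probability of 0.35); inhibitory axons are twice as local.
#'
#' @param x,y positions in \code{[0, 1)} (vectors recycle).
#' @param projection one of \code{"ee"}, \code{"ei"} (E onto I), \code{"ie"}
#'   (I onto E), \code{"ii"}.
#' @return Connection probabilities in \code{[0, 1]}.
#' @export
connection_prob <- function(x, y, projection = c("ee", "ei", "ie", "ii")) {
  projection <- match.arg(projection)
  d <- abs(x - y)
  switch(projection,
         ee = 0.35 * exp(-10 * d),
         ei = exp(-10 * d),
         ie = exp(-20 * d),
         ii = exp(-20 * d))
}

prob_matrix <- function(x_t, x_s, projection) {
  outer(x_t, x_s, function(x, y) connection_prob(x, y, projection))
}

#' Build one random connectivity realization
#'
#' Draws the four binary coupling matrices of the spiking network.  Entry
#' \code{(target, source)} is 1 when an independent uniform draw falls below
#' the distance-dependent probability kernel; self-connections are allowed
#' and the matrices are fixed for the lifetime of a simulation.  The same
#' seed always reproduces the same ensemble.
#'
#' @param params a \code{\link{spiking_params}} object (population sizes).
#' @param seed integer seed for the connectivity draw.
#' @return An object of class \code{"connectivity"}: binary matrices
#'   \code{W_ee} (N_e x N_e), \code{W_ei} (N_e x N_i; inhibitory inputs to E),
#'   \code{W_ie} (N_i x N_e), \code{W_ii} (N_i x N_i), positions
#'   \code{x_e}, \code{x_i}, and the seed.  Rows index targets, columns
#'   sources.
#' @export
build_connectivity <- function(params = spiking_params(), seed = 1L) {
  x_e <- (seq_len(params$N_e) - 1L) / params$N_e
  x_i <- (seq_len(params$N_i) - 1L) / params$N_i
  draws <- function(p) matrix(as.double(stats::runif(length(p)) < p),
                              nrow(p), ncol(p))
  old <- .Random.seed_exists()
  on.exit(old(), add = TRUE)
  set.seed(seed)
  P_ee <- prob_matrix(x_e, x_e, "ee")
  P_ei <- prob_matrix(x_e, x_i, "ie")  # I sources onto E targets use the I kernel
  P_ie <- prob_matrix(x_i, x_e, "ei")  # E sources onto I targets use the E->I kernel
  P_ii <- prob_matrix(x_i, x_i, "ii")
  out <- list(W_ee = draws(P_ee), W_ei = draws(P_ei),
              W_ie = draws(P_ie), W_ii = draws(P_ii),
              x_e = x_e, x_i = x_i, seed = as.integer(seed))
  structure(out, class = "connectivity")
}

# Save and later restore the global RNG state so connectivity draws do not
# perturb a caller's random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
  }
}

#' Analytic expected in-degrees of the random connectivity
#'
#' Sums the Bernoulli kernels over the discrete source positions, giving the
#' exact expected number of inputs per target cell (and its grand mean over
#' targets).  With the standard 400E/80I layout the grand means are about 27
#' excitatory and 8 inhibitory inputs per E cell, and 80 excitatory and 8
#' inhibitory inputs per I cell.
#'
#' @param params a \code{\link{spiking_params}} object.
#' @return A list with per-target expected in-degree vectors
#'   (\code{ee}, \code{ei}, \code{ie}, \code{ii}; target population first
#'   index as in \code{\link{build_connectivity}}) and their means
#'   \code{mean_ee}, \code{mean_ei}, \code{mean_ie}, \code{mean_ii}.
#' @export
expected_indegree <- function(params = spiking_params()) {
  x_e <- (seq_len(params$N_e) - 1L) / params$N_e
  x_i <- (seq_len(params$N_i) - 1L) / params$N_i
  deg <- function(P) rowSums(P)
  d_ee <- deg(prob_matrix(x_e, x_e, "ee"))
  d_ei <- deg(prob_matrix(x_e, x_i, "ie"))
  d_ie <- deg(prob_matrix(x_i, x_e, "ei"))
  d_ii <- deg(prob_matrix(x_i, x_i, "ii"))
  list(ee = d_ee, ei = d_ei, ie = d_ie, ii = d_ii,
       mean_ee = mean(d_ee), mean_ei = mean(d_ei),
       mean_ie = mean(d_ie), mean_ii = mean(d_ii))
}

#' Empirical mean in-degrees over many connectivity seeds
#'
#' @param params a \code{\link{spiking_params}} object.
#' @param seeds integer vector of connectivity seeds.
#' @return A data frame with one row per seed and the mean in-degree of each
#'   projection (target population first index).
#' @export
indegree_stats <- function(params = spiking_params(), seeds = 1:50) {
  rows <- lapply(seeds, function(s) {
    W <- build_connectivity(params, seed = s)
    data.frame(seed = s,
               ee = mean(rowSums(W$W_ee)), ei = mean(rowSums(W$W_ei)),
               ie = mean(rowSums(W$W_ie)), ii = mean(rowSums(W$W_ii)))
  })
  do.call(rbind, rows)
}
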