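#' Model specification
#'
#' Fixes the dimensions and Dirichlet hyper-parameters of the three-level
#' mixed-membership model: each sample mixes K metabosystems (weights
#' theta_n ~ Dir(alpha_theta)), each metabosystem mixes L subnetworks
#' (phi_k ~ Dir(alpha_phi)), and each subnetwork carries a substrate
#' distribution delta_l and a product distribution gamma_l over the C
#' catalog compounds (Dir(alpha_delta), Dir(alpha_gamma)).
#'
#' All four concentrations default to 0.01: values close to zero favour
#' metabosystems dominated by a few subnetworks and subnetworks made of a
#' few compounds, which is what makes the decomposition interpretable.
#'
#' @param K Number of metabosystems (>= 1).
#' @param L Number of subnetworks (>= 1).
#' @param alpha Default symmetric Dirichlet concentration applied to all
#'   four levels.
#' @param alpha_theta,alpha_phi,alpha_delta,alpha_gamma Per-level overrides;
#'   all must be strictly positive.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(K, L, alpha = 0.01,
                       alpha_theta = alpha, alpha_phi = alpha,
                       alpha_delta = alpha, alpha_gamma = alpha) {
  if (!is_count(K) || !is_count(L)) stop_usage("K and L must be positive integers")
  for (a in list(alpha_theta, alpha_phi, alpha_delta, alpha_gamma)) {
    if (!is_positive_scalar(a)) {
      stop_usage("all concentration parameters must be strictly positive")
    }
  }
  structure(list(K = as.integer(K), L = as.integer(L),
                 alpha_theta = alpha_theta, alpha_phi = alpha_phi,
                 alpha_delta = alpha_delta, alpha_gamma = alpha_gamma),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> K = %d, L = %d, alpha = (theta %.4g, phi %.4g, delta %.4g, gamma %.4g)\n",
    x$K, x$L, x$alpha_theta, x$alpha_phi, x$alpha_delta, x$alpha_gamma))
  invisible(x)
}

#' Gibbs sampling schedule
#'
#' Defaults follow common practice for this model family: 100 burn-in
#' sweeps discarded, then 500 retained draws with a lag of 20 sweeps
#' between them (2100 sweeps in total).
#'
#' @param burn_in Sweeps discarded before retention starts.
#' @param n_retained Number of retained draws.
#' @param lag Sweeps between consecutive retained draws.
#' @param seed Integer seed for the sampler's random stream.
#' @return An object of class `sampler_schedule`.
#' @export
sampler_schedule <- function(burn_in = 100L, n_retained = 500L, lag = 20L,
                             seed = 1L) {
  if (!is_count(burn_in) || !is_count(n_retained) || !is_count(lag)) {
    stop_usage("burn_in, n_retained and lag must be positive integers")
  }
  structure(list(burn_in = as.integer(burn_in),
                 n_retained = as.integer(n_retained),
                 lag = as.integer(lag),
                 seed = as.integer(seed)),
            class = "sampler_schedule")
}

#' Total number of Gibbs sweeps a schedule performs
#' @param schedule A [sampler_schedule()].
#' @return `burn_in + n_retained * lag`.
#' @export
total_sweeps <- function(schedule) {
  schedule$burn_in + schedule$n_retained * schedule$lag
}
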