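#' Log prior of a branch relative rate under the white-noise relaxed clock
#'
#' In the reparametrized independent-gamma (white-noise) clock, the
#' relative rate `r_ij` of branch `i` in partition `j` is gamma
#' distributed with mean 1 and variance `sigma_j / (t_i * c)`: shape and
#' rate both equal `t_i * c / sigma_j`, where `t_i` is the branch time
#' duration (Myr), `c` the mean clock rate (substitutions per character
#' per Myr) and `sigma_j` the partition's variance parameter. Branches of
#' zero duration (sampled-ancestor attachments) carry no rate variable
#' and must be excluded by the caller.
#'
#' @param r relative rate (> 0).
#' @param t_i branch duration in Myr (> 0).
#' @param c_rate mean clock rate (> 0).
#' @param sigma_j partition variance parameter (> 0).
#' @return log density; `-Inf` for `r <= 0`.
#' @export
branch_rel_rate_log_prior <- function(r, t_i, c_rate, sigma_j) {
  if (t_i <= 0) stop("zero-duration branches carry no rate variable")
  if (c_rate <= 0 || sigma_j <= 0) stop("c and sigma must be positive")
  shape <- t_i * c_rate / sigma_j
  ifelse(r <= 0, -Inf, stats::dgamma(r, shape = shape, rate = shape, log = TRUE))
}

#' Effective branch distance
#'
#' The branch length entering the Mkv likelihood, in expected
#' substitutions per character: the product of time duration, mean clock
#' rate and relative rate, `b_ij = t_i * c * r_ij`.
#'
#' @param t_i branch duration (Myr).
#' @param c_rate mean clock rate.
#' @param r_ij relative rate.
#' @return numeric distance.
#' @export
effective_branch_distance <- function(t_i, c_rate, r_ij) {
  t_i * c_rate * r_ij
}

#' Log hyperprior density of the clock parameters
#'
#' The mean clock rate `c` has a gamma prior (default shape 2, rate 200:
#' mean 0.01, sd ~0.007) and each partition variance `sigma_j` an
#' exponential prior (default rate 10).
#'
#' @param c_rate mean clock rate.
#' @param sigma numeric vector of partition variance parameters.
#' @param c_shape,c_rate_prior gamma prior parameters for `c`.
#' @param sigma_rate exponential prior rate for each `sigma_j`.
#' @return log density; `-Inf` for nonpositive arguments.
#' @export
clock_hyperprior_log_density <- function(c_rate, sigma, c_shape = 2,
                                         c_rate_prior = 200, sigma_rate = 10) {
  if (c_rate <= 0 || any(sigma <= 0)) return(-Inf)
  stats::dgamma(c_rate, shape = c_shape, rate = c_rate_prior, log = TRUE) +
    sum(stats::dexp(sigma, rate = sigma_rate, log = TRUE))
}
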