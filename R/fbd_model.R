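#' Fossilized birth-death process parameters
#'
#' The constant-rate fossilized birth-death (FBD) process: each lineage
#' speciates at rate `lambda` (/Myr), goes extinct at rate `mu`, is
#' fossil-sampled at rate `psi`, and is removed from the process upon
#' sampling with probability `r`; extant lineages are sampled with
#' probability `rho`. For inference the rates are reparametrized as net
#' diversification `d = lambda - mu - r*psi`, turnover
#' `v = (mu + r*psi)/lambda` and fossil-sampling proportion
#' `s = psi/(mu + psi)`. Negative net diversification is not allowed
#' (`d > 0`).
#'
#' @param lambda,mu,psi FBD rates per Myr.
#' @param r removal probability in `[0, 1]`.
#' @param rho extant sampling probability in `(0, 1]`.
#' @return a list classed `fbd_params` with the rates, `r`, `rho` and the
#'   derived `d`, `v`, `s`.
#' @export
fbd_params <- function(lambda, mu, psi, r, rho) {
  if (lambda <= 0 || mu < 0 || psi < 0) stop("invalid FBD rates")
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  d <- lambda - mu - r * psi
  if (d <= 0) stop("negative or zero net diversification d = lambda - mu - r*psi")
  v <- (mu + r * psi) / lambda
  s <- if (mu + psi > 0) psi / (mu + psi) else 0
  structure(list(lambda = lambda, mu = mu, psi = psi, r = r, rho = rho,
                 d = d, v = v, s = s), class = "fbd_params")
}

#' Recover FBD rates from the (d, v, s) reparametrization
#'
#' Inverts `d = lambda - mu - r*psi`, `v = (mu + r*psi)/lambda`,
#' `s = psi/(mu + psi)`: `lambda = d/(1 - v)`,
#' `psi = v*lambda*s/(1 - s + r*s)` and `mu = psi*(1 - s)/s` (with
#' `psi = 0`, `mu = v*lambda` in the limit `s = 0`).
#'
#' @param d net diversification (> 0), per Myr.
#' @param v turnover in `[0, 1)`.
#' @param s fossil-sampling proportion in `[0, 1)`.
#' @param r removal probability in `[0, 1]`.
#' @param rho extant sampling probability.
#' @return an `fbd_params` object.
#' @export
fbd_rates_from_reparam <- function(d, v, s, r, rho = 1) {
  if (d <= 0) stop("d must be positive")
  if (v < 0 || v >= 1) stop("v must lie in [0, 1)")
  if (s < 0 || s >= 1) stop("s must lie in [0, 1)")
  lambda <- d / (1 - v)
  if (s == 0) {
    psi <- 0
    mu <- v * lambda
  } else {
    psi <- v * lambda * s / (1 - s + r * s)
    mu <- psi * (1 - s) / s
  }
  fbd_params(lambda, mu, psi, r, rho)
}

# Stadler-style helper functions for the sampled-tree density.
# c1 = sqrt((lambda - mu - psi)^2 + 4 lambda psi)
# c2 = -(lambda - mu - 2 lambda rho - psi)/c1
.fbd_c12 <- function(p) {
  c1 <- sqrt((p$lambda - p$mu - p$psi)^2 + 4 * p$lambda * p$psi)
  c2 <- -(p$lambda - p$mu - 2 * p$lambda * p$rho - p$psi) / c1
  list(c1 = c1, c2 = c2)
}

# probability that a lineage alive at time t before present leaves no
# sampled extant or fossil descendant
.fbd_p0 <- function(t, p, cc = .fbd_c12(p)) {
  e <- exp(-cc$c1 * t)
  (p$lambda + p$mu + p$psi +
     cc$c1 * (e * (1 - cc$c2) - (1 + cc$c2)) /
             (e * (1 - cc$c2) + (1 + cc$c2))) / (2 * p$lambda)
}

# log q(t); q(0) = 1
.fbd_log_q <- function(t, p, cc = .fbd_c12(p)) {
  # q(t) = 4 e^{-c1 t} / (e^{-c1 t}(1 - c2) + (1 + c2))^2, computed on
  # log scale for stability at large c1 t
  x <- -cc$c1 * t
  log(4) + x - 2 * log(exp(x) * (1 - cc$c2) + (1 + cc$c2))
}

#' Log prior density of a dated tree under the fossilized birth-death
#' process
#'
#' The constant-rate FBD-with-removal density of a sampled tree
#' (topology, bifurcation ages, fossil-tip ages and sampled-ancestor
#' placements), conditioned on the root age: the process starts at the
#' root with two lineages. Each non-root bifurcation contributes
#' `lambda q(x)`, the root `q(t_root)^2`, each fossil tip
#' `psi (r + (1-r) p0(y)) / q(y)`, each sampled ancestor `psi (1-r)` and
#' each extant sample `rho`, where `p0` and `q` are the usual
#' non-sampling and lineage-propagation functions of the process. With
#' `condition = "sampling"` (default) the density is additionally
#' conditioned on at least one lineage being sampled
#' (divide by `1 - p0(t_root)^2`).
#'
#' @param tree a `time_tree`; extant tips at age 0, fossil tips at their
#'   ages, sampled ancestors flagged.
#' @param params an `fbd_params` object.
#' @param condition `"sampling"` (root age + sampled survival),
#'   or `"root"` (root age only).
#' @return log density; `-Inf` for impossible configurations (fossil
#'   samples with `psi = 0`, sampled ancestors with `r = 1`).
#' @export
fbd_log_density <- function(tree, params, condition = c("sampling", "root")) {
  condition <- match.arg(condition)
  p <- params
  ntip <- tree$ntip
  ages <- tree$age
  tip_age <- ages[seq_len(ntip)]
  sa <- tree$sampled_ancestor
  fossil_tip <- tip_age > 1e-9 & !sa
  extant <- tip_age <= 1e-9 & !sa
  n_sa <- sum(sa)
  if ((any(fossil_tip) || n_sa > 0) && p$psi == 0) return(-Inf)
  if (n_sa > 0 && p$r >= 1) return(-Inf)
  cc <- .fbd_c12(p)
  root <- tree_root(tree)
  # sampled-ancestor attachment nodes are not birth events
  sa_parents <- tree$parent[which(sa)]
  internal <- setdiff((ntip + 1L):(2L * ntip - 1L), c(root, sa_parents))
  ll <- 2 * .fbd_log_q(ages[root], p, cc)
  if (length(internal))
    ll <- ll + sum(log(p$lambda) + .fbd_log_q(ages[internal], p, cc))
  if (any(fossil_tip)) {
    y <- tip_age[fossil_tip]
    ll <- ll + sum(log(p$psi) +
                     log(p$r + (1 - p$r) * .fbd_p0(y, p, cc)) -
                     .fbd_log_q(y, p, cc))
  }
  if (n_sa > 0) ll <- ll + n_sa * (log(p$psi) + log1p(-p$r))
  ll <- ll + sum(extant) * log(p$rho)
  if (condition == "sampling") {
    p0r <- .fbd_p0(ages[root], p, cc)
    ll <- ll - log1p(-p0r^2)
  }
  ll
}

#' Offset-exponential log prior for the root age
#'
#' Exponential with rate `1/(mean - offset)` shifted to start at
#' `offset`; default offset 153 Ma with mean 169 Ma.
#'
#' @param t root age in Ma.
#' @param offset minimum age.
#' @param mean prior mean (> offset).
#' @return log density; `-Inf` below the offset.
#' @export
root_age_log_prior <- function(t, offset = 153, mean = 169) {
  if (mean <= offset) stop("mean must exceed offset")
  rate <- 1 / (mean - offset)
  ifelse(t < offset, -Inf, log(rate) - rate * (t - offset))
}

#' Uniform stratigraphic log prior for a fossil tip age
#'
#' @param t proposed tip age in Ma.
#' @param age_min,age_max stratigraphic range bounds.
#' @return `-log(age_max - age_min)` inside the window, 0 for point
#'   calibrations (fixed ages, including extant tips), `-Inf` outside.
#' @export
tip_age_log_prior <- function(t, age_min, age_max) {
  w <- age_max - age_min
  out <- ifelse(t < age_min | t > age_max, -Inf,
                ifelse(w > 0, -log(w), 0))
  out
}

#' Normal log prior for a calibrated internal node age
#'
#' Optional extra calibration on a constrained clade's age (for example a
#' normal(55, 5) prior on the split of the two extant taxa).
#'
#' @param t clade age in Ma.
#' @param mean,sd normal parameters.
#' @return log density.
#' @export
node_calibration_log_prior <- function(t, mean, sd) {
  stats::dnorm(t, mean, sd, log = TRUE)
}

#' Count sampled ancestors in a tree
#'
#' @param tree a `time_tree`.
#' @return a list with `count` (number of fossil samples flagged
#'   ancestral), `n_fossils` (total fossil samples) and `fraction`
#'   (`count/n_fossils`, `NaN` when there are no fossils).
#' @export
count_sampled_ancestors <- function(tree) {
  tips <- seq_len(tree$ntip)
  fossil <- tree$age[tips] > 1e-9 | tree$sampled_ancestor
  count <- sum(tree$sampled_ancestor)
  n_fossils <- sum(fossil)
  list(count = count, n_fossils = n_fossils, fraction = count / n_fossils)
}
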