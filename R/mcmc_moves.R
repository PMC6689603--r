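# Proposal moves. Each move takes (st, prep, cfg) and returns
#   list(st = proposed state, log_hr = log Hastings ratio,
#        ll_update = "none" | "all" | partition index,
#        valid = FALSE when rejected at generation)
# Relative rates ride with their node index through topology changes;
# zero-duration (sampled-ancestor) branches hold the placeholder rate 1,
# which is masked out of priors and contributes zero distance.

.reject <- list(valid = FALSE)

.children_of <- function(st, nd) which(st$parent == nd)

.sa_parents <- function(st, prep) {
  sa <- which(st$sa)
  if (length(sa)) st$parent[sa] else integer(0)
}

.mv_node_age <- function(st, prep, cfg) {
  ntip <- prep$ntip
  internals <- (ntip + 1L):(2L * ntip - 1L)
  elig <- setdiff(internals, .sa_parents(st, prep))
  if (!length(elig)) return(.reject)
  nd <- if (length(elig) == 1L) elig else sample(elig, 1L)
  kids <- .children_of(st, nd)
  lb <- max(st$age[kids])
  p <- st$parent[nd]
  if (is.na(p)) {             # root: symmetric sliding window, unbounded above
    t2 <- st$age[nd] + stats::runif(1, -cfg$tune$root_window, cfg$tune$root_window)
    if (t2 < lb) return(.reject)
  } else {
    ub <- st$age[p]
    if (ub <= lb) return(.reject)
    t2 <- stats::runif(1, lb, ub)
  }
  st$age[nd] <- t2
  list(st = st, log_hr = 0, ll_update = "all", valid = TRUE)
}

.mv_tip_age <- function(st, prep, cfg) {
  ca <- prep$calib
  elig <- which(!ca$is_extant & ca$age_max > ca$age_min)
  if (!length(elig)) return(.reject)
  f <- if (length(elig) == 1L) elig else sample(elig, 1L)
  w <- min(cfg$tune$tip_window, ca$age_max[f] - ca$age_min[f])
  t2 <- st$age[f] + stats::runif(1, -w, w)
  if (t2 < ca$age_min[f] || t2 > ca$age_max[f]) return(.reject)
  p <- st$parent[f]
  if (!st$sa[f]) {
    if (t2 > st$age[p]) return(.reject)
    st$age[f] <- t2
  } else {
    # sampled ancestor: tip and attachment node move together
    sib <- setdiff(.children_of(st, p), f)
    if (t2 < st$age[sib]) return(.reject)
    gp <- st$parent[p]
    if (!is.na(gp) && t2 > st$age[gp]) return(.reject)
    st$age[f] <- t2
    st$age[p] <- t2
  }
  list(st = st, log_hr = 0, ll_update = "all", valid = TRUE)
}

.mv_nni <- function(st, prep, cfg) {
  ntip <- prep$ntip
  internals <- (ntip + 1L):(2L * ntip - 1L)
  root <- which(is.na(st$parent))
  cand <- setdiff(internals, root)
  if (!length(cand)) return(.reject)
  cc <- if (length(cand) == 1L) cand else sample(cand, 1L)
  p <- st$parent[cc]
  a <- setdiff(.children_of(st, p), cc)
  g <- .children_of(st, cc)
  g <- g[sample.int(2L, 1L)]
  is_sa_tip <- function(x) x <= ntip && st$sa[x]
  if (is_sa_tip(a) || is_sa_tip(g)) return(.reject)
  if (st$age[cc] <= st$age[a]) return(.reject)
  st$parent[g] <- p
  st$parent[a] <- cc
  if (!.constraints_ok(st, prep)) return(.reject)
  list(st = st, log_hr = 0, ll_update = "all", valid = TRUE)
}

.subtree_nodes <- function(st, x) {
  nn <- length(st$parent)
  inset <- logical(nn)
  inset[x] <- TRUE
  # parent vector is acyclic; sweep until closure
  repeat {
    idx <- which(!inset & !is.na(st$parent))
    idx <- idx[inset[st$parent[idx]]]
    if (!length(idx)) break
    inset[idx] <- TRUE
  }
  which(inset)
}

.mv_spr <- function(st, prep, cfg) {
  ntip <- prep$ntip
  nn <- 2L * ntip - 1L
  root <- which(is.na(st$parent))
  is_sa_tip <- function(x) x <= ntip && st$sa[x]
  cand_x <- setdiff(seq_len(nn), root)
  cand_x <- cand_x[st$parent[cand_x] != root]
  cand_x <- cand_x[!vapply(cand_x, is_sa_tip, logical(1))]
  # exclude nodes whose sibling is a sampled-ancestor tip (pruning would
  # break the attachment)
  sib_of <- function(x) setdiff(.children_of(st, st$parent[x]), x)
  cand_x <- cand_x[!vapply(cand_x, function(x) is_sa_tip(sib_of(x)), logical(1))]
  if (!length(cand_x)) return(.reject)
  x <- if (length(cand_x) == 1L) cand_x else sample(cand_x, 1L)
  p <- st$parent[x]
  s <- sib_of(x)
  gp <- st$parent[p]
  sub <- .subtree_nodes(st, x)
  # candidate regraft branches in the pruned tree (p suppressed, s -> gp)
  pruned_parent <- st$parent
  pruned_parent[s] <- gp
  cand_m <- setdiff(seq_len(nn), c(sub, p, root))
  hi <- st$age[pruned_parent[cand_m]]
  lo <- pmax(st$age[x], st$age[cand_m])
  keep <- hi > lo
  cand_m <- cand_m[keep]; hi <- hi[keep]; lo <- lo[keep]
  if (!length(cand_m)) return(.reject)
  pick <- if (length(cand_m) == 1L) 1L else sample.int(length(cand_m), 1L)
  m <- cand_m[pick]
  u <- stats::runif(1, lo[pick], hi[pick])
  # reverse interval: the branch above s in the pruned tree
  lo_rev <- max(st$age[x], st$age[s])
  hi_rev <- st$age[gp]
  log_hr <- log(hi[pick] - lo[pick]) - log(hi_rev - lo_rev)
  # detach p, reinsert on branch above m
  mp <- pruned_parent[m]
  st$parent[s] <- gp
  st$parent[p] <- mp
  st$parent[m] <- p
  st$age[p] <- u
  if (!.constraints_ok(st, prep)) return(.reject)
  list(st = st, log_hr = log_hr, ll_update = "all", valid = TRUE)
}

# scale all internal-node ages by a common factor (tips fixed); the
# classic whole-tree scaler that decorrelates the root age from the
# one-node-at-a-time slides. Sampled-ancestor attachment nodes are tied
# to their fossil's age and stay fixed, so proposals that would push a
# scaled node below (or above) such a fixed neighbour are rejected by
# the age-order check.
.mv_tree_scale <- function(st, prep, cfg) {
  ntip <- prep$ntip
  internals <- (ntip + 1L):(2L * ntip - 1L)
  free <- setdiff(internals, .sa_parents(st, prep))
  m <- .mult(1, cfg$tune$mult_tree)$x
  st$age[free] <- st$age[free] * m
  # validity: every parent must stay older than its children
  dur <- st$age[st$parent] - st$age
  if (any(dur < 0, na.rm = TRUE)) return(.reject)
  list(st = st, log_hr = length(free) * log(m), ll_update = "all",
       valid = TRUE)
}

.mv_rel_rate <- function(st, prep, cfg) {
  dur <- .durations(st, prep)
  act <- which(dur > 0)
  i <- if (length(act) == 1L) act else sample(act, 1L)
  j <- if (prep$npart == 1L) 1L else sample.int(prep$npart, 1L)
  m <- exp(cfg$tune$mult_rel * (stats::runif(1) - 0.5))
  st$rel[i, j] <- st$rel[i, j] * m
  list(st = st, log_hr = log(m), ll_update = j, valid = TRUE)
}

# joint rescaling along the time-rate ridge: internal ages scale by m
# while the mean clock rate scales by 1/m, leaving branch distances of
# internal-to-internal branches unchanged (only tip-adjacent distances
# move). Jacobian m^(n_free) from the ages times m^(-1) from the rate.
.mv_time_rate_rescale <- function(st, prep, cfg) {
  ntip <- prep$ntip
  internals <- (ntip + 1L):(2L * ntip - 1L)
  free <- setdiff(internals, .sa_parents(st, prep))
  m <- .mult(1, cfg$tune$mult_tree)$x
  st$age[free] <- st$age[free] * m
  dur <- st$age[st$parent] - st$age
  if (any(dur < 0, na.rm = TRUE)) return(.reject)
  st$c <- st$c / m
  list(st = st, log_hr = (length(free) - 1) * log(m), ll_update = "all",
       valid = TRUE)
}

# independence redraw of one relative rate from its prior; the Hastings
# ratio cancels the prior terms, so acceptance reduces to the likelihood
# ratio (and is certain in prior-only runs)
.mv_rel_redraw <- function(st, prep, cfg) {
  dur <- .durations(st, prep)
  act <- which(dur > 0)
  i <- if (length(act) == 1L) act else sample(act, 1L)
  j <- if (prep$npart == 1L) 1L else sample.int(prep$npart, 1L)
  shp <- dur[i] * st$c / st$sigma[j]
  rnew <- stats::rgamma(1, shape = shp, rate = shp)
  if (rnew <= 1e-300 || !is.finite(rnew)) return(.reject)
  log_hr <- stats::dgamma(st$rel[i, j], shape = shp, rate = shp, log = TRUE) -
    stats::dgamma(rnew, shape = shp, rate = shp, log = TRUE)
  st$rel[i, j] <- rnew
  list(st = st, log_hr = log_hr, ll_update = j, valid = TRUE)
}

.mult <- function(x, tun) {
  # two-scale multiplier: occasional 4x-wider strides jump across
  # low-density valleys; the mixture kernel keeps log(m) as the Hastings
  # term
  if (stats::runif(1) < 0.2) tun <- 4 * tun
  m <- exp(tun * (stats::runif(1) - 0.5))
  list(x = x * m, log_hr = log(m))
}

.mv_clock_rate <- function(st, prep, cfg) {
  z <- .mult(st$c, cfg$tune$mult_scalar)
  st$c <- z$x
  list(st = st, log_hr = z$log_hr, ll_update = "all", valid = TRUE)
}

.mv_alpha <- function(st, prep, cfg) {
  j <- if (length(st$alpha) == 1L) 1L else sample.int(length(st$alpha), 1L)
  if (stats::runif(1) < 0.2) {
    # prior-independence component: jumps between rate-variation regimes
    # (e.g. near-invariant-rates vs homogeneous) that random walks cannot
    # bridge; the Hastings ratio cancels the prior, leaving the
    # likelihood ratio
    a2 <- stats::rexp(1, cfg$alpha_prior_rate)
    if (a2 <= 1e-300) return(.reject)
    log_hr <- stats::dexp(st$alpha[j], cfg$alpha_prior_rate, log = TRUE) -
      stats::dexp(a2, cfg$alpha_prior_rate, log = TRUE)
    st$alpha[j] <- a2
  } else {
    z <- .mult(st$alpha[j], cfg$tune$mult_scalar)
    st$alpha[j] <- z$x
    log_hr <- z$log_hr
  }
  st$rates_mat <- .rates_mat(st$alpha, prep$npart, cfg$ncat)
  upd <- if (length(st$alpha) == 1L) "all" else j
  list(st = st, log_hr = log_hr, ll_update = upd, valid = TRUE)
}

# funnel-sliding move on one partition variance: scale sigma_j while
# mapping every branch rate through its gamma CDF so each keeps its
# quantile under the new shape. The relative-rate prior terms cancel
# against the transform's Jacobian, so acceptance reduces to the
# likelihood x hyperprior ratio x the sigma-multiplier term; here the
# Jacobian piece of the Hastings ratio is reported explicitly and the
# cancellation happens in the full posterior ratio.
.mv_sigma_rates <- function(st, prep, cfg) {
  j <- if (prep$npart == 1L) 1L else sample.int(prep$npart, 1L)
  z <- .mult(st$sigma[j], cfg$tune$mult_scalar)
  m <- z$x / st$sigma[j]
  dur <- .durations(st, prep)
  act <- which(dur > 0)
  shp <- dur[act] * st$c / st$sigma[j]
  shp2 <- shp / m
  r <- st$rel[act, j]
  u <- stats::pgamma(r, shape = shp, rate = shp)
  if (any(u <= 0 | u >= 1)) return(.reject)
  r2 <- stats::qgamma(u, shape = shp2, rate = shp2)
  if (any(!is.finite(r2) | r2 <= 1e-300)) return(.reject)
  log_jac <- log(m) +
    sum(stats::dgamma(r, shape = shp, rate = shp, log = TRUE) -
          stats::dgamma(r2, shape = shp2, rate = shp2, log = TRUE))
  st$sigma[j] <- z$x
  st$rel[act, j] <- r2
  list(st = st, log_hr = log_jac, ll_update = j, valid = TRUE)
}

.mv_sigma <- function(st, prep, cfg) {
  j <- if (prep$npart == 1L) 1L else sample.int(prep$npart, 1L)
  z <- .mult(st$sigma[j], cfg$tune$mult_scalar)
  st$sigma[j] <- z$x
  list(st = st, log_hr = z$log_hr, ll_update = "none", valid = TRUE)
}

.mv_div_d <- function(st, prep, cfg) {
  z <- .mult(st$d, cfg$tune$mult_scalar)
  st$d <- z$x
  list(st = st, log_hr = z$log_hr, ll_update = "none", valid = TRUE)
}

.win01 <- function(x, w) {
  y <- x + stats::runif(1, -w, w)
  if (y < 0) y <- -y
  if (y > 1) y <- 2 - y
  y
}

.mv_div_v <- function(st, prep, cfg) {
  st$v <- .win01(st$v, cfg$tune$win_unit)
  list(st = st, log_hr = 0, ll_update = "none", valid = TRUE)
}

.mv_div_s <- function(st, prep, cfg) {
  st$s <- .win01(st$s, cfg$tune$win_unit)
  list(st = st, log_hr = 0, ll_update = "none", valid = TRUE)
}

# reversible-jump toggle of a fossil between tip and sampled ancestor.
# Becoming a tip draws the attachment age uniformly between the fossil
# age and its parent's age and draws the branch's relative rates from
# their priors; the reverse move discards them. Both proposal densities
# enter the Hastings ratio; the relative-rate prior terms in the target
# cancel against the prior proposal analytically, but are kept explicit
# here for clarity and generality.
.mv_rj_ancestor <- function(st, prep, cfg) {
  ntip <- prep$ntip
  fossil <- which(st$age[seq_len(ntip)] > 1e-9 | st$sa)
  if (!length(fossil)) return(.reject)
  f <- if (length(fossil) == 1L) fossil else sample(fossil, 1L)
  p <- st$parent[f]
  gp <- st$parent[p]
  if (is.na(gp)) return(.reject)    # no ancestor toggling at the root
  yf <- st$age[f]
  tgp <- st$age[gp]
  if (tgp <= yf) return(.reject)
  if (!st$sa[f]) {
    # tip -> ancestor: delete the subtending branch and its rates
    sib <- setdiff(.children_of(st, p), f)
    if (st$age[sib] > yf) return(.reject)
    durf <- st$age[p] - yf
    if (durf <= 0) return(.reject)
    shp <- durf * st$c / st$sigma
    log_hr <- -log(tgp - yf) +
      sum(stats::dgamma(st$rel[f, ], shape = shp, rate = shp, log = TRUE))
    st$age[p] <- yf
    st$sa[f] <- TRUE
    st$rel[f, ] <- 1
  } else {
    # ancestor -> tip: draw attachment age and new branch rates
    x <- stats::runif(1, yf, tgp)
    shp <- (x - yf) * st$c / st$sigma
    rnew <- stats::rgamma(prep$npart, shape = shp, rate = shp)
    if (any(rnew <= 1e-300) || any(!is.finite(rnew))) return(.reject)
    log_hr <- log(tgp - yf) -
      sum(stats::dgamma(rnew, shape = shp, rate = shp, log = TRUE))
    st$age[p] <- x
    st$sa[f] <- FALSE
    st$rel[f, ] <- rnew
  }
  list(st = st, log_hr = log_hr, ll_update = "all", valid = TRUE)
}

.move_table <- list(
  node_age = .mv_node_age, tree_scale = .mv_tree_scale,
  time_rate_rescale = .mv_time_rate_rescale,
  tip_age = .mv_tip_age, nni = .mv_nni,
  spr = .mv_spr, rel_rate = .mv_rel_rate, rel_redraw = .mv_rel_redraw,
  sigma_rates = .mv_sigma_rates,
  clock_rate = .mv_clock_rate,
  sigma = .mv_sigma, alpha = .mv_alpha, div_d = .mv_div_d,
  div_v = .mv_div_v, div_s = .mv_div_s, rj_ancestor = .mv_rj_ancestor)
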