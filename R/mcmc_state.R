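# Internal MCMC state machinery: data preparation, state initialization
# and posterior evaluation. The sampler state is a plain list holding the
# tree (parent/age/sampled-ancestor vectors), the clock and tree-process
# scalars, the per-branch per-partition relative-rate matrix, and cached
# log-likelihood / log-prior values.

# Precompute everything that stays constant across iterations.
.prepare_mcmc_data <- function(data, cfg) {
  m <- data$matrix
  ntip <- length(m$taxa)
  parts <- unique(m$partition)
  npart <- length(parts)
  part_data <- vector("list", npart)
  for (j in seq_len(npart)) {
    idx <- which(m$partition == parts[j])
    cls <- paste0(m$state_count[idx], ifelse(m$ordered[idx] & m$state_count[idx] > 2, "o", "u"))
    groups <- lapply(unique(cls), function(cl) {
      jj <- idx[cls == cl]
      k <- m$state_count[jj[1]]
      mod <- mk_rate_matrix(k, m$ordered[jj[1]])
      nch <- length(jj)
      # slice-per-tip layout with the k constant columns appended, as the
      # pruning kernel expects
      tipc <- array(0, dim = c(k, nch + k, ntip))
      for (g in seq_len(nch)) {
        col <- m$cells[[jj[g]]]
        for (i in seq_len(ntip)) tipc[col[[i]] + 1L, g, i] <- 1
      }
      for (s in seq_len(k)) tipc[s, nch + s, ] <- 1
      list(k = k, ordered = mod$ordered, evec = mod$evec, eval = mod$eval,
           tipflat = as.numeric(tipc), nchar = nch)
    })
    part_data[[j]] <- list(label = parts[j], idx = idx, groups = groups)
  }
  cons <- NULL
  if (!is.null(data$constraints)) {
    cons <- lapply(data$constraints, function(cl) sort(match(cl, m$taxa)))
  }
  calib_node <- NULL
  if (!is.null(cfg$node_calibration)) {
    calib_node <- list(tips = sort(match(cfg$node_calibration$taxa, m$taxa)),
                       mean = cfg$node_calibration$mean,
                       sd = cfg$node_calibration$sd)
  }
  ca <- data$calibrations
  fos <- which(!ca$is_extant)
  w <- ca$age_max[fos] - ca$age_min[fos]
  prior_pack <- list(
    removal_prob = cfg$removal_prob, rho = cfg$rho,
    cond_sampling = cfg$condition == "sampling", ntip = ntip,
    fossil_mask = c(!ca$is_extant), fossil_idx = fos - 1L,
    fossil_min = ca$age_min[fos], fossil_max = ca$age_max[fos],
    tip_window_const = -sum(log(w[w > 0])),
    n_extant = as.integer(sum(ca$is_extant)),
    root_offset = cfg$root_offset,
    root_rate = 1 / (cfg$root_mean - cfg$root_offset),
    c_shape = cfg$c_prior_shape, c_rate = cfg$c_prior_rate,
    sigma_rate = cfg$sigma_prior_rate, alpha_rate = cfg$alpha_prior_rate,
    d_rate = cfg$d_prior_rate,
    calib_tips = if (is.null(calib_node)) integer(0) else calib_node$tips - 1L,
    calib_mean = if (is.null(calib_node)) 0 else calib_node$mean,
    calib_sd = if (is.null(calib_node)) 1 else calib_node$sd)
  list(ntip = ntip, taxa = m$taxa, npart = npart, part_labels = parts,
       part_data = part_data,
       groups_by_part = lapply(part_data, `[[`, "groups"),
       calib = ca,
       fossil_mask = c(!ca$is_extant),
       fossil_idx = fos,
       fossil_min = ca$age_min[fos], fossil_max = ca$age_max[fos],
       tip_window_const = -sum(log(w[w > 0])),
       n_extant = sum(ca$is_extant),
       root_hint = 2L * ntip - 1L,
       prior_pack = prior_pack,
       constraints = cons,
       constraints0 = if (is.null(cons)) NULL else lapply(cons, function(x) x - 1L),
       calib_node = calib_node)
}

# random topology respecting nested constraints, tips at given ages
.build_constrained_tree <- function(tip_ages, constraints, root_offset) {
  ntip <- length(tip_ages)
  nn <- 2L * ntip - 1L
  parent <- rep(NA_integer_, nn)
  age <- c(tip_ages, rep(NA_real_, ntip - 1L))
  next_node <- ntip + 1L

  # order constraints smallest-first so inner clades are joined first
  cons <- constraints[order(lengths(constraints))]
  # unit = a built subtree (root node index); start with tips
  join_set <- function(units) {
    while (length(units) > 1L) {
      pick <- sample.int(length(units), 2L)
      a <- units[pick[1]]; b <- units[pick[2]]
      nd <- next_node; next_node <<- next_node + 1L
      parent[a] <<- nd; parent[b] <<- nd
      # compact heights: start near the youngest tree compatible with the
      # tip ages so burn-in descends, not climbs
      age[nd] <<- max(age[a], age[b]) + stats::rexp(1, 1 / 1.5)
      units <- c(units[-pick], nd)
    }
    units
  }
  owner <- rep(0L, ntip)  # which constraint (index in cons) owns each tip; 0 = free
  roots <- integer(length(cons))
  covered <- vector("list", length(cons))
  for (ci in seq_along(cons)) {
    tipset <- cons[[ci]]
    units <- tipset[owner[tipset] == 0L]
    # sub-clades already built within this constraint
    for (cj in seq_len(ci - 1L)) {
      if (length(covered[[cj]]) && all(covered[[cj]] %in% tipset) &&
          !is.na(roots[cj]) && roots[cj] > 0L && is.na(parent[roots[cj]]))
        units <- c(units, roots[cj])
    }
    roots[ci] <- join_set(units)
    covered[[ci]] <- tipset
    owner[tipset] <- ci
  }
  top <- which(owner == 0L)
  for (ci in seq_along(cons)) if (is.na(parent[roots[ci]])) top <- c(top, roots[ci])
  root <- join_set(top)
  if (age[root] < root_offset)
    age[root] <- root_offset + stats::rexp(1, 1 / 2)
  list(parent = parent, age = age)
}

.state_tree <- function(st, prep) {
  structure(list(ntip = prep$ntip, parent = st$parent, age = st$age,
                 tip_label = prep$taxa, sampled_ancestor = st$sa),
            class = "time_tree")
}

# branch time durations; 0 at the root slot
.durations <- function(st, prep) {
  dur <- st$age[st$parent] - st$age
  dur[is.na(dur)] <- 0
  dur
}

.cat_rates <- function(st, cfg, j) {
  a <- if (length(st$alpha) > 1L) st$alpha[j] else st$alpha
  gamma_category_rates(a, cfg$ncat)
}

# discrete-gamma rates per partition for the state's alpha (cached in
# the state as rates_mat; recomputed by the alpha move and at init)
.rates_mat <- function(alpha, npart, ncat) {
  if (length(alpha) == 1L) {
    matrix(gamma_category_rates(alpha, ncat), ncat, npart)
  } else {
    r <- vapply(alpha, gamma_category_rates, numeric(ncat), ncat = ncat)
    matrix(r, nrow = ncat)
  }
}

# shared inputs of the pruning kernel for the current state
.ll_inputs <- function(st, prep, cfg) {
  dur <- st$age[st$parent] - st$age
  dur[is.na(dur)] <- 0
  brlen <- (dur * st$c) * st$rel
  parent0 <- st$parent
  parent0[is.na(parent0)] <- 0L
  parent0 <- parent0 - 1L
  rates <- st$rates_mat
  if (is.null(rates)) rates <- .rates_mat(st$alpha, prep$npart, cfg$ncat)
  list(parent0 = parent0, brlen = brlen, rates = rates)
}

# log-likelihood of partition j given current distances
.ll_partition <- function(st, prep, cfg, j) {
  z <- .ll_inputs(st, prep, cfg)
  mk_loglik_parts_cpp(z$parent0, prep$ntip, z$brlen, prep$groups_by_part,
                      z$rates, cfg$mkv_correct, j)[j]
}

.ll_all <- function(st, prep, cfg) {
  z <- .ll_inputs(st, prep, cfg)
  mk_loglik_parts_cpp(z$parent0, prep$ntip, z$brlen, prep$groups_by_part,
                      z$rates, cfg$mkv_correct, seq_len(prep$npart))
}

# total log prior: FBD tree density, root/tip/node-age priors, relative
# rate priors, clock and tree-process hyperpriors. Hot path: plain
# vector arithmetic on the state, no classed objects.
.lp_prior <- function(st, prep, cfg) {
  if (st$d <= 0 || st$v < 0 || st$v >= 1 || st$s < 0 || st$s >= 1)
    return(-Inf)
  if (st$c <= 0 || any(st$sigma <= 0) || any(st$alpha <= 0)) return(-Inf)
  r <- cfg$removal_prob
  lambda <- st$d / (1 - st$v)
  if (st$s == 0) { psi <- 0; mu <- st$v * lambda }
  else {
    psi <- st$v * lambda * st$s / (1 - st$s + r * st$s)
    mu <- psi * (1 - st$s) / st$s
  }
  ntip <- prep$ntip
  age <- st$age
  sa <- st$sa

  # --- FBD sampled-tree density (conditioned on the root age) ---
  fossil_tip <- prep$fossil_mask & !sa
  if ((any(fossil_tip) || any(sa)) && psi == 0) return(-Inf)
  if (any(sa) && r >= 1) return(-Inf)
  c1 <- sqrt((lambda - mu - psi)^2 + 4 * lambda * psi)
  c2 <- -(lambda - mu - 2 * lambda * cfg$rho - psi) / c1
  log_q <- function(t) {
    x <- -c1 * t
    log(4) + x - 2 * log(exp(x) * (1 - c2) + (1 + c2))
  }
  p0 <- function(t) {
    e <- exp(-c1 * t)
    (lambda + mu + psi +
       c1 * (e * (1 - c2) - (1 + c2)) / (e * (1 - c2) + (1 + c2))) /
      (2 * lambda)
  }
  root <- st$parent
  rooti <- prep$root_hint
  if (!is.na(root[rooti])) rooti <- which(is.na(root))
  # birth nodes: internal nodes that are not sampled-ancestor attachments
  birth <- rep(TRUE, 2L * ntip - 1L)
  birth[seq_len(ntip)] <- FALSE
  birth[rooti] <- FALSE
  if (any(sa)) birth[st$parent[which(sa)]] <- FALSE
  lp <- 2 * log_q(age[rooti]) +
    sum(log(lambda) + log_q(age[birth])) +
    prep$n_extant * log(cfg$rho)
  if (any(fossil_tip)) {
    y <- age[which(fossil_tip)]
    lp <- lp + sum(log(psi) + log(r + (1 - r) * p0(y)) - log_q(y))
  }
  nsa <- sum(sa)
  if (nsa > 0) lp <- lp + nsa * (log(psi) + log1p(-r))
  if (cfg$condition == "sampling") lp <- lp - log1p(-p0(age[rooti])^2)

  # --- root and fossil tip-age priors ---
  troot <- age[rooti]
  if (troot < cfg$root_offset) return(-Inf)
  root_rate <- 1 / (cfg$root_mean - cfg$root_offset)
  lp <- lp + log(root_rate) - root_rate * (troot - cfg$root_offset)
  fos <- prep$fossil_idx
  if (length(fos)) {
    ta <- age[fos]
    if (any(ta < prep$fossil_min | ta > prep$fossil_max)) return(-Inf)
    lp <- lp + prep$tip_window_const
  }

  # --- relative-rate priors over active branches ---
  dur <- age[st$parent] - age
  act <- which(dur > 0)
  shp <- (dur[act] * st$c) / rep(st$sigma, each = length(act))
  lp <- lp + sum(stats::dgamma(st$rel[act, ], shape = shp, rate = shp,
                               log = TRUE))

  # --- hyperpriors ---
  lp <- lp +
    stats::dgamma(st$c, cfg$c_prior_shape, rate = cfg$c_prior_rate, log = TRUE) +
    sum(stats::dexp(st$sigma, cfg$sigma_prior_rate, log = TRUE)) +
    sum(stats::dexp(st$alpha, cfg$alpha_prior_rate, log = TRUE)) +
    stats::dexp(st$d, cfg$d_prior_rate, log = TRUE)
  if (!is.null(prep$calib_node)) {
    nd <- .mrca_from_parent(st$parent, prep$calib_node$tips, ntip)
    lp <- lp + stats::dnorm(age[nd], prep$calib_node$mean,
                            prep$calib_node$sd, log = TRUE)
  }
  lp
}

# fast path: identical quantity computed in C++; the R implementation
# above is kept as the reference the tests compare against
.lp_prior_fast <- function(st, prep, cfg) {
  p0 <- st$parent
  p0[is.na(p0)] <- 0L
  lp_prior_cpp(p0 - 1L, st$age, st$sa, st$rel, st$c, st$sigma, st$alpha,
               st$d, st$v, st$s, prep$prior_pack)
}

# MRCA from a parent vector, without building a classed tree
.mrca_from_parent <- function(parent, tips, ntip) {
  anc <- function(i) {
    path <- i
    while (!is.na(parent[i])) { i <- parent[i]; path <- c(path, i) }
    path
  }
  p <- anc(tips[1L])
  for (j in tips[-1L]) p <- p[p %in% anc(j)]
  p[1L]
}

.lp_total <- function(st, prep, cfg) {
  lp <- .lp_prior_fast(st, prep, cfg)
  if (!is.finite(lp)) return(list(lp = -Inf, ll = rep(-Inf, prep$npart)))
  ll <- if (cfg$prior_only) rep(0, prep$npart) else .ll_all(st, prep, cfg)
  list(lp = lp + sum(ll), ll = ll)
}

# fast monophyly check of all constraints on the state's tree
.constraints_ok <- function(st, prep) {
  if (is.null(prep$constraints0)) return(TRUE)
  p0 <- st$parent
  p0[is.na(p0)] <- 0L
  constraints_ok_cpp(p0 - 1L, prep$ntip, prep$constraints0)
}

# draw an initial state; retried by the caller if the posterior is -Inf
.init_state <- function(prep, cfg) {
  ca <- prep$calib
  tip_ages <- ifelse(ca$is_extant, 0,
                     stats::runif(nrow(ca), ca$age_min, ca$age_max))
  cons <- prep$constraints
  if (is.null(cons)) cons <- list()
  tp <- .build_constrained_tree(tip_ages, cons, cfg$root_offset)
  nalpha <- if (cfg$alpha_per_partition) prep$npart else 1L
  nn <- 2L * prep$ntip - 1L
  st <- list(
    parent = tp$parent, age = tp$age,
    sa = rep(FALSE, prep$ntip),
    rel = matrix(1, nn, prep$npart),
    c = stats::rgamma(1, cfg$c_prior_shape, cfg$c_prior_rate),
    sigma = stats::rexp(prep$npart, cfg$sigma_prior_rate),
    alpha = stats::rexp(nalpha, cfg$alpha_prior_rate),
    d = stats::rexp(1, cfg$d_prior_rate),
    v = stats::runif(1), s = stats::runif(1))
  # relative rates drawn from their prior (an all-ones start sits on the
  # density ridge of the clock prior and mixes poorly out of it)
  dur <- tp$age[tp$parent] - tp$age
  act <- which(!is.na(dur) & dur > 0)
  for (j in seq_len(prep$npart)) {
    shp <- dur[act] * st$c / st$sigma[j]
    st$rel[act, j] <- pmax(stats::rgamma(length(act), shape = shp, rate = shp),
                           1e-200)
  }
  st$rates_mat <- .rates_mat(st$alpha, prep$npart, cfg$ncat)
  st
}
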