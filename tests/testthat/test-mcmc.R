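# A small reusable dataset for sampler tests
small_dataset <- function(seed = 11, npart = 2L, n_per_part = 25L,
                          root_age = 40, taxa = c(8, 18)) {
  set.seed(seed)
  p <- fbd_params(0.08, 0.05, 0.05, r = 0, rho = 0.9)
  tr <- simulate_fbd_tree(p, root_age, taxon_range = taxa)
  rel <- simulate_branch_rates(tr, 0.01, rep(0.05, npart))
  parts <- lapply(seq_len(npart), function(i)
    list(n = n_per_part, p_binary = 0.7, k_multi = 3L, p_ordered = 0.4))
  names(parts) <- paste0("p", seq_len(npart))
  m <- simulate_characters(tr, rel, 0.01, 1.5, parts)
  list(tree = tr, data = tip_dating_data(m, stratigraphic_windows(tr, 5)))
}

random_state <- function(dat, cfg, seed) {
  prep <- morphclock:::.prepare_mcmc_data(dat, cfg)
  set.seed(seed)
  st <- morphclock:::.init_state(prep, cfg)
  # perturb relative rates away from the all-ones start
  act <- which(!is.na(morphclock:::.durations(st, prep)) &
                 morphclock:::.durations(st, prep) > 0)
  st$rel[act, ] <- rgamma(length(act) * ncol(st$rel), 2, 2)
  list(st = st, prep = prep)
}

test_that("log posterior equals an independently composed component sum", {
  sd <- small_dataset(seed = 11)
  dat <- sd$data
  cfg <- mcmc_config(removal_prob = 0, root_offset = 35, root_mean = 45,
                     ncat = 4)
  for (seed in c(1, 2, 3)) {
    z <- random_state(dat, cfg, seed)
    st <- z$st; prep <- z$prep
    state <- morphclock:::.as_user_state(st, prep)
    got <- log_posterior(state, dat, cfg)

    # independent composition from the module-level functions
    m <- dat$matrix
    tree <- state$tree
    dur <- branch_durations(tree); dur[is.na(dur)] <- 0
    ll <- 0
    for (j in seq_along(unique(m$partition))) {
      lab <- unique(m$partition)[j]
      idx <- which(m$partition == lab)
      b <- dur * st$c * st$rel[, j]
      ll <- ll + mkv_partition_log_likelihood(
        tree, b, m$cells[idx], m$state_count[idx], m$ordered[idx],
        gamma_category_rates(st$alpha, 4))
    }
    params <- fbd_rates_from_reparam(st$d, st$v, st$s, 0, cfg$rho)
    lp <- fbd_log_density(tree, params, "sampling") +
      root_age_log_prior(tree_root_age(tree), 35, 45)
    ca <- dat$calibrations
    fos <- which(!ca$is_extant)
    lp <- lp + sum(tip_age_log_prior(tree$age[fos], ca$age_min[fos],
                                     ca$age_max[fos]))
    act <- which(dur > 0)
    for (j in seq_len(prep$npart))
      lp <- lp + sum(vapply(act, function(i)
        branch_rel_rate_log_prior(st$rel[i, j], dur[i], st$c, st$sigma[j]),
        numeric(1)))
    lp <- lp + clock_hyperprior_log_density(st$c, st$sigma) +
      dexp(st$alpha, 1, log = TRUE) + dexp(st$d, 100, log = TRUE)
    expect_equal(got, ll + lp, tolerance = 1e-6)
  }
})

test_that("prior-only posterior is exactly the prior component sum", {
  sd <- small_dataset(seed = 12)
  cfg <- mcmc_config(prior_only = TRUE, removal_prob = 0, root_offset = 35,
                     root_mean = 45)
  z <- random_state(sd$data, cfg, 4)
  state <- morphclock:::.as_user_state(z$st, z$prep)
  expect_equal(log_posterior(state, sd$data, cfg),
               morphclock:::.lp_prior(z$st, z$prep, cfg), tolerance = 1e-9)
})

test_that("C++ prior evaluation matches the R reference on random states", {
  sd <- small_dataset(seed = 13)
  for (r in c(0, 1)) {
    cfg <- mcmc_config(removal_prob = r, root_offset = 35, root_mean = 45)
    for (seed in 1:5) {
      z <- random_state(sd$data, cfg, seed + 10 * r)
      expect_equal(morphclock:::.lp_prior_fast(z$st, z$prep, cfg),
                   morphclock:::.lp_prior(z$st, z$prep, cfg),
                   tolerance = 1e-9)
    }
  }
})

test_that("proposals respect constraints and report correct Hastings ratios", {
  sd <- small_dataset(seed = 14)
  taxa <- sd$data$matrix$taxa
  # constrain a clade present in the true tree
  sets <- morphclock:::tip_descendant_sets(sd$tree)
  inner <- sets[[length(taxa) + 2L]]
  cons <- list(CladeA = taxa[inner])
  dat <- tip_dating_data(sd$data$matrix, sd$data$calibrations, cons)
  cfg <- mcmc_config(removal_prob = 0, root_offset = 35, root_mean = 45)
  prep <- morphclock:::.prepare_mcmc_data(dat, cfg)
  set.seed(2)
  st <- morphclock:::.init_state(prep, cfg)
  state <- morphclock:::.as_user_state(st, prep)

  set.seed(33)
  n_valid <- 0L
  for (i in 1:200) {
    pr <- propose_move(state, dat, cfg, move = "nni")
    if (pr$valid) {
      n_valid <- n_valid + 1L
      expect_true(is_monophyletic(pr$state$tree, cons$CladeA))
      expect_equal(pr$log_hr, 0)
    }
  }
  expect_gt(n_valid, 0L)
  # multiplier move: log Hastings ratio is the log of the factor
  for (i in 1:20) {
    pr <- propose_move(state, dat, cfg, move = "rel_rate")
    ratio <- pr$state$rel / state$rel
    changed <- which(abs(ratio - 1) > 1e-12)
    expect_length(changed, 1L)
    expect_equal(pr$log_hr, log(ratio[changed]), tolerance = 1e-12)
  }
  for (i in 1:10) {
    pr <- propose_move(state, dat, cfg, move = "clock_rate")
    expect_equal(pr$log_hr, log(pr$state$c / state$c), tolerance = 1e-12)
  }
})

test_that("chain swaps follow the Metropolis-coupled acceptance rule", {
  set.seed(9)
  # identical posteriors: always accepted
  for (i in 1:20) {
    sw <- mc3_swap(c(-100, -100), heats = c(1, 0.8))
    expect_true(sw$accepted)
  }
  # equal heats: always accepted regardless of posteriors
  for (i in 1:20) {
    sw <- mc3_swap(c(-50, -500), heats = c(1, 1))
    expect_true(sw$accepted)
  }
  # acceptance decreases with the heat gap on a fixed posterior pair
  rates <- vapply(c(0.05, 0.3, 0.8), function(gap) {
    mean(replicate(400, mc3_swap(c(-10, -20), heats = c(1, 1 - gap),
                                 pair = c(1L, 2L))$accepted))
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("runs are reproducible, sized and burned in as configured", {
  sd <- small_dataset(seed = 15, npart = 1L, n_per_part = 20L,
                      taxa = c(6, 12))
  cfg <- mcmc_config(n_runs = 2, n_chains = 2, n_iter = 600,
                     sample_every = 10, burnin_frac = 0.25, seed = 42,
                     removal_prob = 0, root_offset = 35, root_mean = 45,
                     swap_every = 5)
  res1 <- run_tip_dating(sd$data, cfg)
  res2 <- run_tip_dating(sd$data, cfg)
  expect_equal(res1$runs[[1]]$params, res2$runs[[1]]$params)
  expect_equal(res1$runs[[2]]$params, res2$runs[[2]]$params)
  # sample count = floor(n_iter / sample_every) + 1
  expect_equal(nrow(res1$runs[[1]]$params), 61L)
  expect_equal(nrow(trace_samples(res1$runs[[1]])), 61L - 15L)
  # acceptance rates of age moves lie strictly inside (0, 1)
  accs <- res1$runs[[1]]$acceptance
  na <- accs[accs$move == "node_age", ]
  expect_gt(na$rate, 0)
  expect_lt(na$rate, 1)
  # between-run diagnostics are well defined
  diag <- convergence_summary(res1)
  expect_true(all(is.finite(diag$ess)))
  expect_gte(diag$split_sd, 0)
  expect_lte(diag$split_sd, 1)
})

test_that("recorded log posteriors match recomputation from recorded states", {
  sd <- small_dataset(seed = 16, npart = 2L, n_per_part = 15L,
                      taxa = c(6, 14))
  cfg <- mcmc_config(n_runs = 1, n_chains = 1, n_iter = 800,
                     sample_every = 40, seed = 5, removal_prob = 0,
                     root_offset = 35, root_mean = 45)
  res <- run_tip_dating(sd$data, cfg)
  tr <- res$runs[[1]]
  s <- tr$params
  for (row in c(2L, 11L, 21L)) {
    tree <- tr$trees[[row]]
    state <- list(tree = tree, rel = tree$rel, c = s$c[row],
                  sigma = unlist(s[row, grep("^sigma_", names(s))]),
                  alpha = s$alpha[row], d = s$d[row], v = s$v[row],
                  s = s$s[row])
    expect_equal(log_posterior(state, sd$data, cfg),
                 s$log_posterior[row], tolerance = 1e-6)
  }
})

test_that("compiled and plain-R engines sample the same target", {
  sd <- small_dataset(seed = 19, npart = 1L, n_per_part = 15L,
                      taxa = c(6, 12))
  cfg <- mcmc_config(n_runs = 1, n_chains = 1, n_iter = 4000,
                     sample_every = 50, seed = 8, removal_prob = 0,
                     root_offset = 35, root_mean = 45)
  res_r <- run_tip_dating(sd$data, cfg, engine = "r")
  res_c <- run_tip_dating(sd$data, cfg, engine = "cpp")
  # both engines record internally consistent log posteriors
  for (res in list(res_r, res_c)) {
    tr <- res$runs[[1]]
    for (row in c(20L, 60L)) {
      tree <- tr$trees[[row]]
      sml <- tr$params[row, ]
      state <- list(tree = tree, rel = tree$rel, c = sml$c,
                    sigma = sml$sigma_1, alpha = sml$alpha, d = sml$d,
                    v = sml$v, s = sml$s)
      expect_equal(log_posterior(state, sd$data, cfg), sml$log_posterior,
                   tolerance = 1e-6)
    }
  }
  # post-burn-in clock-rate distributions overlap (same target)
  xr <- trace_samples(res_r$runs[[1]])$c
  xc <- trace_samples(res_c$runs[[1]])$c
  expect_lt(abs(median(log(xr)) - median(log(xc))), 2)
})

test_that("ancestor bookkeeping follows the removal-probability mode", {
  set.seed(17)
  p <- fbd_params(0.06, 0.03, 0.08, r = 0, rho = 0.9)
  tr <- simulate_fbd_tree(p, 30, taxon_range = c(8, 16))
  rel <- simulate_branch_rates(tr, 0.01, 0.05)
  m <- simulate_characters(tr, rel, 0.01, 1.5,
                           list(p1 = list(n = 20, p_binary = 1,
                                          k_multi = 3L, p_ordered = 0)))
  dat <- tip_dating_data(m, stratigraphic_windows(tr, 5))
  # r = 1: the toggle move is disabled and the count stays exactly 0
  cfg1 <- mcmc_config(n_runs = 1, n_chains = 1, n_iter = 500,
                      sample_every = 10, seed = 3, removal_prob = 1,
                      root_offset = 25, root_mean = 35)
  res1 <- run_tip_dating(dat, cfg1)
  expect_true(all(res1$runs[[1]]$params$n_ancestors == 0))
  expect_equal(res1$runs[[1]]$acceptance$attempts[
    res1$runs[[1]]$acceptance$move == "rj_ancestor"], 0L)
  # r = 0: ancestors are proposed and visited
  cfg0 <- mcmc_config(n_runs = 1, n_chains = 1, n_iter = 3000,
                      sample_every = 10, seed = 3, removal_prob = 0,
                      prior_only = TRUE, root_offset = 25, root_mean = 35)
  res0 <- run_tip_dating(dat, cfg0)
  expect_gt(max(res0$runs[[1]]$params$n_ancestors), 0)
})
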