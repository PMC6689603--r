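# MCMC driver: Metropolis-coupled chains, sampling, traces.

#' Joint log posterior of a tip-dating state
#'
#' Sums the Mkv-corrected character log-likelihood over partitions (unless
#' `config$prior_only`), the fossilized birth-death tree density, the
#' root-, tip- and node-age priors, the relaxed-clock relative-rate
#' priors and all hyperpriors.
#'
#' @param state a list with elements `tree` (a `time_tree`), `c`, `sigma`
#'   (length = number of partitions), `alpha`, `d`, `v`, `s`, and
#'   optionally `rel` (nodes x partitions relative-rate matrix, default
#'   all 1).
#' @param data a `tip_dating_data` object.
#' @param config an `mcmc_config`.
#' @return log posterior density (`-Inf` for invalid states).
#' @export
log_posterior <- function(state, data, config = mcmc_config()) {
  prep <- .prepare_mcmc_data(data, config)
  st <- .as_internal_state(state, prep)
  .lp_total(st, prep, config)$lp
}

.as_internal_state <- function(state, prep) {
  tr <- state$tree
  ord <- match(prep$taxa, tr$tip_label)
  if (anyNA(ord)) stop("state tree taxa do not match the data")
  nn <- 2L * tr$ntip - 1L
  # re-index tips so tip i corresponds to data taxon i
  perm <- integer(nn)
  perm[ord] <- seq_len(tr$ntip)
  perm[(tr$ntip + 1L):nn] <- (tr$ntip + 1L):nn
  parent <- rep(NA_integer_, nn)
  age <- numeric(nn)
  sa <- logical(tr$ntip)
  for (i in seq_len(nn)) {
    tgt <- perm[i]
    parent[tgt] <- if (is.na(tr$parent[i])) NA_integer_ else perm[tr$parent[i]]
    age[tgt] <- tr$age[i]
  }
  sa[perm[seq_len(tr$ntip)]] <- tr$sampled_ancestor
  rel <- state$rel
  if (is.null(rel)) rel <- matrix(1, nn, prep$npart)
  list(parent = parent, age = age, sa = sa, rel = rel,
       c = state$c, sigma = state$sigma, alpha = state$alpha,
       d = state$d, v = state$v, s = state$s)
}

.as_user_state <- function(st, prep) {
  list(tree = .state_tree(st, prep), rel = st$rel, c = st$c,
       sigma = st$sigma, alpha = st$alpha, d = st$d, v = st$v, s = st$s)
}

#' Draw a single MCMC proposal
#'
#' Applies one randomly chosen (or named) move to a state and returns the
#' proposed state together with its log Hastings ratio. Mainly useful for
#' testing and for inspecting the move set.
#'
#' @param state a state list as in [log_posterior()].
#' @param data a `tip_dating_data` object.
#' @param config an `mcmc_config`.
#' @param move optional move name (see [mcmc_config()]).
#' @return list with `state`, `log_hr`, `move`, and `valid` (`FALSE` when
#'   the move rejected at generation).
#' @export
propose_move <- function(state, data, config = mcmc_config(), move = NULL) {
  prep <- .prepare_mcmc_data(data, config)
  st <- .as_internal_state(state, prep)
  w <- .effective_weights(config, prep)
  if (is.null(move)) move <- sample(names(w), 1L, prob = w)
  res <- .move_table[[move]](st, prep, config)
  if (!isTRUE(res$valid))
    return(list(state = NULL, log_hr = NA_real_, move = move, valid = FALSE))
  list(state = .as_user_state(res$st, prep), log_hr = res$log_hr,
       move = move, valid = TRUE)
}

#' Metropolis-coupled chain swap
#'
#' Proposes exchanging the states of two chains with heats `heats[i]` and
#' `heats[j]`, given their cold-scale log posteriors. The acceptance
#' probability is `min(1, exp((heats[i]-heats[j]) * (lp[j]-lp[i])))`.
#'
#' @param lp numeric vector of cold-scale (unheated) log posteriors.
#' @param heats numeric vector of chain heats (cold chain = 1).
#' @param pair integer vector of two chain indices; by default a random
#'   adjacent pair (adjacent heats give useful exchange rates).
#' @return list with `order` (new assignment of states to chains),
#'   `accepted` and `pair`.
#' @export
mc3_swap <- function(lp, heats, pair = NULL) {
  nch <- length(lp)
  stopifnot(length(heats) == nch, nch >= 2L)
  if (is.null(pair)) {
    i <- if (nch == 2L) 1L else sample.int(nch - 1L, 1L)
    pair <- c(i, i + 1L)
  }
  i <- pair[1L]; j <- pair[2L]
  log_acc <- (heats[i] - heats[j]) * (lp[j] - lp[i])
  ord <- seq_len(nch)
  accepted <- log(stats::runif(1)) < log_acc
  if (accepted) { ord[i] <- j; ord[j] <- i }
  list(order = ord, accepted = accepted, pair = pair)
}

.effective_weights <- function(cfg, prep) {
  w <- cfg$proposal_weights
  if (cfg$removal_prob >= 1) w["rj_ancestor"] <- 0
  ca <- prep$calib
  if (!any(!ca$is_extant & ca$age_max > ca$age_min)) w["tip_age"] <- 0
  if (!any(!ca$is_extant)) w["rj_ancestor"] <- 0
  if (prep$ntip <= 3L) w["spr"] <- 0
  w / sum(w)
}

.chain_step <- function(st, prep, cfg, beta, mi, move_fns) {
  res <- move_fns[[mi]](st, prep, cfg)
  out <- list(st = st, accepted = FALSE)
  if (!isTRUE(res$valid)) return(out)
  st2 <- res$st
  lpr <- .lp_prior_fast(st2, prep, cfg)
  if (!is.finite(lpr)) return(out)
  ll2 <- st$ll
  if (!cfg$prior_only && !identical(res$ll_update, "none")) {
    if (identical(res$ll_update, "all")) {
      ll2 <- .ll_all(st2, prep, cfg)
    } else {
      j <- res$ll_update
      ll2[j] <- .ll_partition(st2, prep, cfg, j)
    }
    if (any(!is.finite(ll2))) return(out)
  }
  lp2 <- lpr + sum(ll2)
  log_acc <- beta * (lp2 - st$lp) + res$log_hr
  if (log(stats::runif(1)) < log_acc) {
    st2$lp <- lp2
    st2$ll <- ll2
    out$st <- st2
    out$accepted <- TRUE
  }
  out
}

.init_chain <- function(prep, cfg, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    st <- .init_state(prep, cfg)
    z <- .lp_total(st, prep, cfg)
    if (is.finite(z$lp)) {
      st$lp <- z$lp
      st$ll <- z$ll
      return(st)
    }
  }
  stop("could not initialize a finite-posterior state after ", max_tries,
       " attempts")
}

# canonical move order shared with the C++ core
.move_order <- c("node_age", "tree_scale", "time_rate_rescale", "tip_age",
                 "nni", "spr", "rel_rate", "rel_redraw", "sigma_rates",
                 "clock_rate", "sigma", "alpha", "div_d", "div_v", "div_s",
                 "rj_ancestor")

.run_one <- function(prep, cfg, run, verbose) {
  w <- .effective_weights(cfg, prep)[.move_order]
  nalpha <- if (cfg$alpha_per_partition) prep$npart else 1L
  heats <- 1 / (1 + cfg$heat_delta * (seq_len(cfg$n_chains) - 1))
  chains <- lapply(seq_len(cfg$n_chains), function(i) .init_chain(prep, cfg))
  to_cpp <- function(st) {
    p0 <- st$parent
    p0[is.na(p0)] <- 0L
    list(parent0 = p0 - 1L, age = st$age, sa = st$sa, rel = st$rel,
         sigma = st$sigma, alpha = st$alpha, c = st$c, d = st$d,
         v = st$v, s = st$s)
  }
  cfg_pack <- list(
    npart = prep$npart, ncat = cfg$ncat, nalpha = nalpha,
    prior_only = cfg$prior_only, mkv_correct = cfg$mkv_correct,
    n_iter = cfg$n_iter, sample_every = cfg$sample_every,
    swap_every = cfg$swap_every, anneal_start = cfg$anneal_start,
    burnin_frac = cfg$burnin_frac, heats = heats,
    constraints = if (is.null(prep$constraints0)) list() else prep$constraints0)
  out <- run_mcmc_cpp(lapply(chains, to_cpp), prep$prior_pack,
                      prep$groups_by_part, w, cfg$tune, cfg_pack)
  pcols <- c("iter", "log_posterior", "log_likelihood", "t_mrca", "c",
             paste0("sigma_", seq_len(prep$npart)),
             if (nalpha == 1L) "alpha" else paste0("alpha_", seq_len(nalpha)),
             "d", "v", "s", "n_ancestors")
  params <- as.data.frame(out$params)
  names(params) <- pcols
  trees <- lapply(out$trees, function(tr) {
    tt <- structure(list(ntip = prep$ntip, parent = tr$parent, age = tr$age,
                         tip_label = prep$taxa, sampled_ancestor = tr$sa),
                    class = "time_tree")
    tt$rel <- tr$rel
    tt
  })
  nsamp <- nrow(params)
  structure(list(
    params = params, trees = trees,
    n_burnin = floor(cfg$burnin_frac * nsamp), run = run,
    acceptance = data.frame(move = .move_order,
                            attempts = as.integer(out$att),
                            accepts = as.integer(out$acc),
                            rate = ifelse(out$att > 0, out$acc / out$att,
                                          NA_real_)),
    swap_rate = if (out$swap_att > 0) out$swap_acc / out$swap_att else NA_real_),
    class = "mcmc_trace")
}

# plain-R driver retained as the reference implementation for the C++
# core; exercised by the unit tests on short chains
.run_one_r <- function(prep, cfg, run, verbose) {
  w <- .effective_weights(cfg, prep)
  move_names <- names(w)
  heats <- 1 / (1 + cfg$heat_delta * (seq_len(cfg$n_chains) - 1))
  chains <- lapply(seq_len(cfg$n_chains), function(i) .init_chain(prep, cfg))
  nsamp <- floor(cfg$n_iter / cfg$sample_every) + 1L
  npar <- prep$npart
  nalpha <- if (cfg$alpha_per_partition) npar else 1L
  pcols <- c("iter", "log_posterior", "log_likelihood", "t_mrca", "c",
             paste0("sigma_", seq_len(npar)),
             if (nalpha == 1L) "alpha" else paste0("alpha_", seq_len(nalpha)),
             "d", "v", "s", "n_ancestors")
  params <- matrix(NA_real_, nsamp, length(pcols),
                   dimnames = list(NULL, pcols))
  trees <- vector("list", nsamp)
  att <- acc <- stats::setNames(numeric(length(move_names)), move_names)
  n_swap_att <- n_swap_acc <- 0L
  record <- function(row, it) {
    st <- chains[[1L]]
    root <- which(is.na(st$parent))
    params[row, ] <<- c(it, st$lp, sum(st$ll), st$age[root], st$c,
                        st$sigma, st$alpha, st$d, st$v, st$s, sum(st$sa))
    tt <- .state_tree(st, prep)
    tt$rel <- st$rel          # per-branch per-partition relative rates
    trees[[row]] <<- tt
  }
  record(1L, 0L)
  row <- 1L
  move_fns <- .move_table[move_names]
  nmove <- length(move_names)
  # annealed burn-in: the posterior power ramps from anneal_start to the
  # chain's heat over the burn-in window; those iterations are discarded
  n_anneal <- floor(cfg$burnin_frac * cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    anneal <- if (it < n_anneal && cfg$anneal_start < 1)
      cfg$anneal_start + (1 - cfg$anneal_start) * (it / n_anneal) else 1
    for (ch in seq_len(cfg$n_chains)) {
      mi <- sample.int(nmove, 1L, prob = w)
      z <- .chain_step(chains[[ch]], prep, cfg, heats[ch] * anneal, mi,
                       move_fns)
      chains[[ch]] <- z$st
      att[mi] <- att[mi] + 1
      if (z$accepted) acc[mi] <- acc[mi] + 1
    }
    if (cfg$n_chains > 1L && it %% cfg$swap_every == 0L) {
      lp <- vapply(chains, `[[`, numeric(1), "lp")
      sw <- mc3_swap(lp, heats)
      n_swap_att <- n_swap_att + 1L
      if (sw$accepted) {
        chains <- chains[sw$order]
        n_swap_acc <- n_swap_acc + 1L
      }
    }
    if (it %% cfg$sample_every == 0L) {
      row <- row + 1L
      record(row, it)
    }
    if (verbose && it %% max(1L, cfg$n_iter %/% 10L) == 0L)
      message(sprintf("run %d: %d/%d iterations", run, it, cfg$n_iter))
  }
  structure(list(
    params = as.data.frame(params), trees = trees,
    n_burnin = floor(cfg$burnin_frac * nsamp), run = run,
    acceptance = data.frame(move = move_names, attempts = as.integer(att),
                            accepts = as.integer(acc),
                            rate = ifelse(att > 0, acc / att, NA_real_)),
    swap_rate = if (n_swap_att > 0) n_swap_acc / n_swap_att else NA_real_),
    class = "mcmc_trace")
}

#' Run a Bayesian tip-dating analysis
#'
#' Metropolis-coupled MCMC over tree topology, node and fossil-tip ages,
#' sampled-ancestor placements (when `removal_prob < 1`), the clock state
#' and the tree-process parameters. Returns one trace per independent
#' run; samples are recorded from the cold chain at iteration 0 and every
#' `sample_every` iterations.
#'
#' @param data a `tip_dating_data` object.
#' @param config an `mcmc_config`.
#' @param verbose print progress messages (plain-R engine only).
#' @param engine `"cpp"` for the compiled sampler (default), `"r"` for
#'   the plain-R reference implementation of the same kernel.
#' @return a `tip_dating_result`: list with `runs` (list of
#'   `mcmc_trace`), `config`, `taxa` and `part_labels`.
#' @export
run_tip_dating <- function(data, config = mcmc_config(), verbose = FALSE,
                           engine = c("cpp", "r")) {
  cfg <- config
  engine <- match.arg(engine)
  runner <- if (engine == "cpp") .run_one else .run_one_r
  prep <- .prepare_mcmc_data(data, cfg)
  set.seed(cfg$seed)
  runs <- lapply(seq_len(cfg$n_runs), function(run)
    runner(prep, cfg, run, verbose))
  structure(list(runs = runs, config = cfg, taxa = prep$taxa,
                 part_labels = prep$part_labels),
            class = "tip_dating_result")
}

#' @export
print.tip_dating_result <- function(x, ...) {
  cat(sprintf("tip_dating_result: %d run(s), %d samples each (%d burn-in)\n",
              length(x$runs), nrow(x$runs[[1]]$params),
              x$runs[[1]]$n_burnin))
  s <- combined_samples(x)
  cat(sprintf("  post-burn-in t_mrca mean %.2f Ma, c mean %.4f\n",
              mean(s$t_mrca), mean(s$c)))
  invisible(x)
}

#' Post-burn-in parameter samples of one trace
#' @param trace an `mcmc_trace`.
#' @return data.frame of retained samples.
#' @export
trace_samples <- function(trace) {
  n <- nrow(trace$params)
  trace$params[(trace$n_burnin + 1L):n, , drop = FALSE]
}

#' Post-burn-in tree samples of one trace
#' @param trace an `mcmc_trace`.
#' @return list of `time_tree` samples.
#' @export
trace_trees <- function(trace) {
  n <- length(trace$trees)
  trace$trees[(trace$n_burnin + 1L):n]
}

#' Combine post-burn-in samples across runs
#' @param result a `tip_dating_result`.
#' @return data.frame of pooled parameter samples.
#' @export
combined_samples <- function(result) {
  do.call(rbind, lapply(result$runs, trace_samples))
}

#' Combine post-burn-in trees across runs
#' @param result a `tip_dating_result`.
#' @return list of pooled `time_tree` samples.
#' @export
combined_trees <- function(result) {
  do.call(c, lapply(result$runs, trace_trees))
}

#' Effective sample size of a scalar trace
#'
#' Spectral-density-at-zero estimate via an AR fit, as conventional for
#' MCMC output.
#'
#' @param x numeric vector of samples.
#' @return estimated effective sample size.
#' @export
trace_ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(n)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(50L, n %/% 4L)),
             silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0L) return(n)
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(1, min(n, n * v / spec0))
}

#' Between-run topological consistency
#'
#' Average across splits of the standard deviation of split (clade)
#' frequencies between independent runs, the usual convergence summary
#' for tree samples.
#'
#' @param result a `tip_dating_result` with at least two runs.
#' @param min_freq splits below this frequency in every run are ignored.
#' @return average standard deviation of split frequencies.
#' @export
split_frequency_sd <- function(result, min_freq = 0.1) {
  if (length(result$runs) < 2L) return(NA_real_)
  freqs <- lapply(result$runs, function(tr) .clade_freqs(trace_trees(tr)))
  keys <- unique(unlist(lapply(freqs, names)))
  tab <- sapply(freqs, function(f) ifelse(keys %in% names(f), f[keys], 0))
  rownames(tab) <- keys
  tab <- tab[apply(tab, 1L, max) >= min_freq, , drop = FALSE]
  if (!nrow(tab)) return(0)
  mean(apply(tab, 1L, stats::sd))
}

#' Convergence diagnostics of a tip-dating result
#'
#' @param result a `tip_dating_result`.
#' @return list with per-parameter effective sample sizes (pooled across
#'   runs) and the average split-frequency standard deviation between
#'   runs.
#' @export
convergence_summary <- function(result) {
  s <- combined_samples(result)
  keep <- setdiff(colnames(s), c("iter"))
  ess <- vapply(keep, function(cn) trace_ess(s[[cn]]), numeric(1))
  list(ess = ess, split_sd = split_frequency_sd(result))
}
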