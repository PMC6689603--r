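#' Bundle the inputs of a tip-dating analysis
#'
#' Joins the character matrix, tip-age calibrations and topology
#' constraints, aligning calibrations to the matrix taxa.
#'
#' @param matrix a `character_matrix`.
#' @param calibrations data.frame from [read_tip_calibrations()] /
#'   [tip_calibrations()] covering every taxon.
#' @param constraints optional `constraint_set` (or named list of taxon
#'   vectors) of clades forced to be monophyletic.
#' @return a list classed `tip_dating_data`.
#' @export
tip_dating_data <- function(matrix, calibrations, constraints = NULL) {
  taxa <- matrix$taxa
  idx <- match(taxa, calibrations$taxon)
  if (anyNA(idx))
    stop("missing calibrations for: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  calib <- calibrations[idx, , drop = FALSE]
  rownames(calib) <- NULL
  if (!is.null(constraints) && !inherits(constraints, "constraint_set"))
    constraints <- constraint_set(constraints, taxa)
  structure(list(matrix = matrix, calibrations = calib,
                 constraints = constraints),
            class = "tip_dating_data")
}

#' MCMC configuration for tip dating
#'
#' Defaults give a desk-scale schedule (2 runs x 4 chains x 200k
#' iterations, sampling every 100 iterations with 25% burn-in); the
#' full-scale schedule (40M iterations sampled every 2000) is reached by
#' raising `n_iter` and `sample_every`.
#'
#' @param n_runs independent runs.
#' @param n_chains Metropolis-coupled chains per run (1 cold + hot).
#' @param heat_delta incremental heating: chain i has power
#'   `1/(1 + heat_delta * i)`.
#' @param n_iter iterations per run.
#' @param sample_every sampling (thinning) interval.
#' @param burnin_frac fraction of samples discarded as burn-in.
#' @param seed integer RNG seed.
#' @param removal_prob FBD removal probability `r`; 0 allows fossil
#'   ancestors (reversible-jump moves enabled), 1 forces all fossils to
#'   tips.
#' @param rho extant sampling probability.
#' @param prior_only drop the character likelihood (sample the joint
#'   prior).
#' @param mkv_correct apply the acquisition-bias correction.
#' @param ncat discrete-gamma categories for among-character rates.
#' @param alpha_per_partition estimate a separate gamma shape per
#'   partition instead of one shared shape.
#' @param root_offset,root_mean offset-exponential root-age prior (Ma).
#' @param condition FBD conditioning, see [fbd_log_density()].
#' @param d_prior_rate exponential prior rate on net diversification `d`.
#' @param c_prior_shape,c_prior_rate gamma prior on the mean clock rate.
#' @param sigma_prior_rate exponential prior rate on each `sigma_j`.
#' @param alpha_prior_rate exponential prior rate on the gamma shape.
#' @param node_calibration optional list(`taxa`, `mean`, `sd`): a normal
#'   age calibration on the MRCA of `taxa`.
#' @param proposal_weights named numeric vector of relative move weights;
#'   see Details. Missing names keep their defaults.
#' @param swap_every interval between chain-swap attempts.
#' @param anneal_start initial posterior power of the annealed burn-in:
#'   every chain's power ramps linearly from this value to its target
#'   heat across the burn-in window (all annealed iterations are
#'   discarded with the burn-in, so retained samples come from the exact
#'   target). Set to 1 to disable annealing.
#' @param tune named list of proposal tuning constants.
#' @details Move types: `node_age` (single-node age slide, the root by a
#'   symmetric window), `tree_scale` (scale all free internal ages),
#'   `time_rate_rescale` (scale ages against the mean clock rate along
#'   the time-rate ridge), `tip_age` (fossil-age slide within its
#'   stratigraphic window), `nni` and `spr` (constraint-respecting
#'   topology moves on the dated tree), `rel_rate` (multiplier on one
#'   branch/partition relative rate), `rel_redraw` (independence redraw
#'   of one relative rate from its prior), `sigma_rates`
#'   (quantile-preserving joint rescaling of one partition's variance
#'   and its branch rates), `clock_rate`, `sigma`, `alpha`
#'   (multipliers; `alpha` mixes in a prior-independence proposal),
#'   `div_d` (multiplier), `div_v`, `div_s` (reflected windows on
#'   (0,1)), `rj_ancestor` (reversible-jump fossil tip/ancestor toggle).
#' @return a list classed `mcmc_config`.
#' @export
mcmc_config <- function(n_runs = 2L, n_chains = 4L, heat_delta = 0.1,
                        n_iter = 200000L, sample_every = 100L,
                        burnin_frac = 0.25, seed = 1L,
                        removal_prob = 0, rho = 0.0002,
                        prior_only = FALSE, mkv_correct = TRUE, ncat = 4L,
                        alpha_per_partition = FALSE,
                        root_offset = 153, root_mean = 169,
                        condition = "sampling",
                        d_prior_rate = 100,
                        c_prior_shape = 2, c_prior_rate = 200,
                        sigma_prior_rate = 10, alpha_prior_rate = 1,
                        node_calibration = NULL,
                        proposal_weights = NULL,
                        swap_every = 10L,
                        anneal_start = 0.5,
                        tune = list()) {
  stopifnot(n_chains >= 1, burnin_frac >= 0, burnin_frac < 1,
            sample_every >= 1, removal_prob >= 0, removal_prob <= 1)
  w <- c(node_age = 20, tree_scale = 5, time_rate_rescale = 5, tip_age = 10,
         nni = 15, spr = 10, rel_rate = 20, rel_redraw = 10,
         sigma_rates = 6, clock_rate = 4,
         sigma = 4, alpha = 3, div_d = 2, div_v = 2, div_s = 2,
         rj_ancestor = 10)
  if (!is.null(proposal_weights)) {
    bad <- setdiff(names(proposal_weights), names(w))
    if (length(bad)) stop("unknown proposal types: ", paste(bad, collapse = ", "))
    w[names(proposal_weights)] <- proposal_weights
  }
  tn <- list(age_window = 4, root_window = 10, tip_window = 4,
             mult_rel = 1.8, mult_scalar = 1.4, mult_tree = 0.2,
             win_unit = 0.25)
  tn[names(tune)] <- tune
  structure(list(
    n_runs = as.integer(n_runs), n_chains = as.integer(n_chains),
    heat_delta = heat_delta, n_iter = as.integer(n_iter),
    sample_every = as.integer(sample_every), burnin_frac = burnin_frac,
    seed = as.integer(seed), removal_prob = removal_prob, rho = rho,
    prior_only = prior_only, mkv_correct = mkv_correct,
    ncat = as.integer(ncat), alpha_per_partition = alpha_per_partition,
    root_offset = root_offset, root_mean = root_mean, condition = condition,
    d_prior_rate = d_prior_rate, c_prior_shape = c_prior_shape,
    c_prior_rate = c_prior_rate, sigma_prior_rate = sigma_prior_rate,
    alpha_prior_rate = alpha_prior_rate,
    node_calibration = node_calibration,
    proposal_weights = w / sum(w), swap_every = as.integer(swap_every),
    anneal_start = anneal_start,
    tune = tn), class = "mcmc_config")
}
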