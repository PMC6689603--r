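# Synthetic data: forward simulation of fossilized birth-death trees,
# white-noise branch rates and Mk character matrices with
# acquisition-bias filtering, for end-to-end validation of the pipeline.

#' Simulate a fossilized birth-death tree
#'
#' Forward simulation from the root: two lineages start at `root_age`;
#' each bifurcates at rate `lambda`, dies at rate `mu` and is
#' fossil-sampled at rate `psi`, being removed upon sampling with
#' probability `r` (a surviving lineage can be sampled repeatedly);
#' lineages reaching the present are sampled with probability `rho`. The
#' returned tree is pruned to sampled lineages: fossil samples with
#' sampled descendants become sampled-ancestor tips on zero-duration
#' branches. Simulation is rejection-resampled until both root lineages
#' carry samples (so the returned root age equals `root_age`) and the
#' number of samples falls within `taxon_range`.
#'
#' @param params an `fbd_params` object.
#' @param root_age root age in Ma.
#' @param taxon_range integer vector `c(min, max)` accepted sample counts.
#' @param extant_range optional accepted range for the number of extant
#'   samples.
#' @param max_tries rejection-sampling cap.
#' @return a `time_tree`.
#' @export
simulate_fbd_tree <- function(params, root_age, taxon_range = c(2, Inf),
                              extant_range = NULL, max_tries = 10000L) {
  if (root_age <= 0) stop("root_age must be positive")
  if (params$psi == 0 && params$rho == 0)
    stop("psi = 0 and rho = 0 cannot produce samples")
  for (try in seq_len(max_tries)) {
    left <- .sim_lineage(root_age, params)
    right <- .sim_lineage(root_age, params)
    if (is.null(left) || is.null(right)) next
    spec <- list(age = root_age, kind = "birth", children = list(left, right))
    tr <- .spec_to_time_tree(spec)
    n <- tr$ntip
    n_ext <- sum(tr$age[seq_len(n)] <= 1e-9 & !tr$sampled_ancestor)
    if (n < taxon_range[1] || n > taxon_range[2]) next
    if (!is.null(extant_range) &&
        (n_ext < extant_range[1] || n_ext > extant_range[2])) next
    return(tr)
  }
  stop("no acceptable tree in ", max_tries, " tries")
}

# simulate one lineage downward from age t; returns a reduced subtree
# spec (nested lists with fields age/kind/children) or NULL if nothing
# below is sampled. kinds: "tip" (extant or fossil-tip sample), "birth",
# "sa" (sampled-ancestor attachment: children = (sa tip, continuation)).
.sim_lineage <- function(t, p) {
  samples <- numeric(0)  # fossil-sample ages on this lineage, decreasing
  total <- p$lambda + p$mu + p$psi
  base <- NULL
  repeat {
    tnext <- if (total > 0) t - stats::rexp(1, total) else -1
    if (tnext <= 0) {
      # reached the present
      if (stats::runif(1) < p$rho)
        base <- list(age = 0, kind = "tip", extant = TRUE)
      break
    }
    u <- stats::runif(1) * total
    if (u < p$lambda) {
      left <- .sim_lineage(tnext, p)
      right <- .sim_lineage(tnext, p)
      if (!is.null(left) && !is.null(right)) {
        base <- list(age = tnext, kind = "birth", children = list(left, right))
      } else if (!is.null(left)) base <- left
      else if (!is.null(right)) base <- right
      break
    } else if (u < p$lambda + p$mu) {
      break  # extinction
    } else {
      samples <- c(samples, tnext)
      if (stats::runif(1) < p$r) break  # removed upon sampling
      t <- tnext                        # lineage continues below the sample
    }
  }
  # fold fossil samples on this lineage onto the reduced result, youngest
  # first: with surviving sampled descendants a sample is an ancestor,
  # otherwise the youngest sample becomes the fossil tip
  for (s in rev(samples)) {
    if (is.null(base)) {
      base <- list(age = s, kind = "tip", extant = FALSE)
    } else {
      base <- list(age = s, kind = "sa",
                   children = list(list(age = s, kind = "tip", extant = FALSE,
                                        sa = TRUE),
                                   base))
    }
  }
  base
}

# convert a nested spec into time_tree vectors
.spec_to_time_tree <- function(spec) {
  tips <- list(); internals <- list()
  count_tips <- function(nd) {
    if (nd$kind == "tip") 1L
    else sum(vapply(nd$children, count_tips, integer(1)))
  }
  ntip <- count_tips(spec)
  nn <- 2L * ntip - 1L
  parent <- rep(NA_integer_, nn)
  age <- numeric(nn)
  sa <- logical(ntip)
  extant <- logical(ntip)
  tip_i <- 0L
  int_i <- ntip
  assign_node <- function(nd, par) {
    if (nd$kind == "tip") {
      tip_i <<- tip_i + 1L
      parent[tip_i] <<- par
      age[tip_i] <<- nd$age
      sa[tip_i] <<- isTRUE(nd$sa)
      extant[tip_i] <<- isTRUE(nd$extant)
      tip_i
    } else {
      int_i <<- int_i + 1L
      me <- int_i
      parent[me] <<- par
      age[me] <<- nd$age
      for (ch in nd$children) assign_node(ch, me)
      me
    }
  }
  assign_node(spec, NA_integer_)
  lab <- character(ntip)
  lab[extant] <- paste0("extant_", seq_len(sum(extant)))
  lab[!extant] <- paste0("fossil_", seq_len(sum(!extant)))
  time_tree(parent, age, lab, sa)
}

#' Simulate white-noise branch rates
#'
#' Independent draws per branch and partition from the relaxed-clock
#' prior: gamma with mean 1 and variance `sigma[j] / (t_i * c)`.
#' Zero-duration branches keep the placeholder rate 1.
#'
#' @param tree a `time_tree`.
#' @param c_rate mean clock rate.
#' @param sigma vector of partition variance parameters.
#' @return matrix of relative rates, nodes x partitions.
#' @export
simulate_branch_rates <- function(tree, c_rate, sigma) {
  nn <- 2L * tree$ntip - 1L
  dur <- branch_durations(tree)
  rel <- matrix(1, nn, length(sigma))
  act <- which(!is.na(dur) & dur > 0)
  for (j in seq_along(sigma)) {
    shp <- dur[act] * c_rate / sigma[j]
    rel[act, j] <- stats::rgamma(length(act), shape = shp, rate = shp)
  }
  rel
}

#' Simulate a character matrix under the Mk process with acquisition bias
#'
#' Evolves each character down the tree from a uniform root state, with
#' per-character gamma rate multipliers of shape `alpha`, per-partition
#' branch distances `t_i * c * r_ij`, and the partition's ordered or
#' unordered transition model. Characters that come out invariant (or,
#' for multistate characters, show fewer than 3 observed states) are
#' discarded and re-simulated, emulating the coding of variable
#' characters only.
#'
#' @param tree a `time_tree`.
#' @param rel relative-rate matrix (nodes x partitions).
#' @param c_rate mean clock rate.
#' @param alpha gamma shape of among-character rate variation.
#' @param partitions named list; each element
#'   `list(n =, p_binary =, k_multi =, p_ordered =)`: number of
#'   characters, probability a character is binary, candidate multistate
#'   state counts, and probability a multistate character is ordered.
#'   Exact composition can be requested instead with `n_multi` and
#'   `n_ordered` counts (then `p_binary`/`p_ordered` are ignored).
#' @param max_tries_per_char redraw cap per character.
#' @return a `character_matrix` whose `truth` attribute records the
#'   generating state counts, ordering flags and character rates.
#' @export
simulate_characters <- function(tree, rel, c_rate, alpha, partitions,
                                max_tries_per_char = 2000L) {
  dur <- branch_durations(tree)
  dur[is.na(dur)] <- 0
  if (all(dur * c_rate == 0)) stop("all branch distances are zero")
  ntip <- tree$ntip
  po <- tree_postorder(tree)
  preord <- rev(po)
  models <- list()
  get_model <- function(k, ordered) {
    key <- paste0(k, ordered)
    if (is.null(models[[key]])) models[[key]] <<- mk_rate_matrix(k, ordered)
    models[[key]]
  }
  cells <- list(); kvec <- integer(0); ovec <- logical(0); plab <- character(0)
  rates_used <- numeric(0)
  for (pi in seq_along(partitions)) {
    ps <- partitions[[pi]]
    b <- dur * c_rate * rel[, pi]
    # per-character plan: exact multistate/ordered counts when given,
    # otherwise Bernoulli draws with the stated proportions
    if (!is.null(ps$n_multi)) {
      is_multi <- rep(FALSE, ps$n)
      pos <- sample.int(ps$n, ps$n_multi)
      is_multi[pos] <- TRUE
      is_ord <- rep(FALSE, ps$n)
      is_ord[pos[seq_len(ps$n_ordered)]] <- TRUE
    } else {
      is_multi <- stats::runif(ps$n) >= ps$p_binary
      is_ord <- is_multi & stats::runif(ps$n) < ps$p_ordered
    }
    for (ci in seq_len(ps$n)) {
      binary <- !is_multi[ci]
      k <- if (binary) 2L else
        if (length(ps$k_multi) == 1L) ps$k_multi else sample(ps$k_multi, 1L)
      ordered <- is_ord[ci]
      mod <- get_model(k, ordered)
      need_obs <- if (binary) 2L else 3L
      done <- FALSE
      for (tr_i in seq_len(max_tries_per_char)) {
        g <- stats::rgamma(1, shape = alpha, rate = alpha)
        states <- integer(2L * ntip - 1L)
        for (nd in preord) {
          p <- tree$parent[nd]
          if (is.na(p)) {
            states[nd] <- sample.int(k, 1L) - 1L
          } else {
            P <- transition_probabilities(mod, b[nd] * g)
            states[nd] <- sample.int(k, 1L, prob = P[states[p] + 1L, ]) - 1L
          }
        }
        obs <- states[seq_len(ntip)]
        if (length(unique(obs)) >= need_obs) {
          cells[[length(cells) + 1L]] <- lapply(obs, function(s) s)
          kvec <- c(kvec, k); ovec <- c(ovec, ordered)
          plab <- c(plab, names(partitions)[pi])
          rates_used <- c(rates_used, g)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not simulate a variable character in partition ",
             names(partitions)[pi])
    }
  }
  m <- character_matrix(cells, tree$tip_label, kvec, ovec, plab)
  attr(m, "truth") <- list(state_count = kvec, ordered = ovec,
                           char_rates = rates_used)
  m
}

#' Stratigraphic age windows around true fossil ages
#'
#' Uniform windows centered on the true fossil ages with the given
#' half-width, truncated at 0; extant tips get point calibrations at 0.
#'
#' @param tree a `time_tree` with true tip ages.
#' @param half_width window half-width in Myr.
#' @return a calibration data.frame as from [tip_calibrations()].
#' @export
stratigraphic_windows <- function(tree, half_width = 5) {
  tips <- seq_len(tree$ntip)
  fossil <- tree$age[tips] > 1e-9 | tree$sampled_ancestor
  amin <- ifelse(fossil, pmax(0, tree$age[tips] - half_width), 0)
  amax <- ifelse(fossil, tree$age[tips] + half_width, 0)
  tip_calibrations(tree$tip_label, amin, amax)
}

#' Generate a complete synthetic tip-dating scenario
#'
#' Simulates an FBD tree, white-noise branch rates, an Mk character
#' matrix with acquisition-bias filtering, and stratigraphic windows,
#' returning the dataset together with the generating truth for
#' parameter-recovery checks.
#'
#' @param fbd an `fbd_params` object (the true tree-process parameters).
#' @param root_age true root age in Ma.
#' @param c_rate,sigma,alpha true clock and rate-variation parameters
#'   (`sigma` has one entry per partition).
#' @param partitions partition specification as in
#'   [simulate_characters()].
#' @param taxon_range,extant_range rejection bands for sample counts.
#' @param window_half_width stratigraphic window half-width (Myr).
#' @return a list with `tree`, `rel`, `matrix`, `calibrations`, `data`
#'   (a ready `tip_dating_data`) and `truth`.
#' @export
synthetic_scenario <- function(fbd, root_age, c_rate, sigma, alpha,
                               partitions, taxon_range = c(10, 100),
                               extant_range = NULL,
                               window_half_width = 5) {
  stopifnot(length(sigma) == length(partitions))
  tree <- simulate_fbd_tree(fbd, root_age, taxon_range, extant_range)
  rel <- simulate_branch_rates(tree, c_rate, sigma)
  m <- simulate_characters(tree, rel, c_rate, alpha, partitions)
  calib <- stratigraphic_windows(tree, window_half_width)
  list(tree = tree, rel = rel, matrix = m, calibrations = calib,
       data = tip_dating_data(m, calib),
       truth = list(root_age = tree_root_age(tree), c = c_rate,
                    sigma = sigma, alpha = alpha, fbd = fbd))
}

#' A bird-matrix-scale synthetic scenario
#'
#' Emulates the structure of a comprehensive Mesozoic-bird morphological
#' matrix: six anatomical partitions of sizes 53/36/48/65/23/55 (280
#' characters), roughly 69% binary characters with 36 ordered multistate
#' characters, a few dozen fossil samples spanning ~160 Myr plus two
#' extant taxa, and 5-Myr stratigraphic windows.
#'
#' @param taxon_range accepted number of samples (default 50-90, around
#'   the 68-taxon scale).
#' @param c_rate,sigma,alpha,root_age generating clock parameters.
#' @return as [synthetic_scenario()].
#' @export
make_bird_scale_scenario <- function(taxon_range = c(50, 90), c_rate = 0.01,
                                     sigma = rep(0.06, 6), alpha = 1.8,
                                     root_age = 160) {
  sizes <- c(skull = 53, axial = 36, pectoral = 48, forelimb = 65,
             pelvic = 23, hindlimb = 55)
  # exactly 193 binary and 87 multistate characters overall, 36 of the
  # multistate ones ordered, apportioned across the six regions
  n_multi <- c(17, 11, 15, 20, 7, 17)
  n_ord <- c(7, 5, 6, 8, 3, 7)
  parts <- lapply(seq_along(sizes), function(i) {
    list(n = unname(sizes[i]), n_multi = n_multi[i], n_ordered = n_ord[i],
         k_multi = c(3L, 3L, 4L))
  })
  names(parts) <- names(sizes)
  fbd <- fbd_params(lambda = 0.04, mu = 0.03, psi = 0.08, r = 0, rho = 0.2)
  synthetic_scenario(fbd, root_age, c_rate, sigma, alpha, parts,
                     taxon_range = taxon_range, extant_range = c(1, 4),
                     window_half_width = 5)
}

#' Write a synthetic scenario to disk
#'
#' Emits the NEXUS matrix, the tab-separated tip-age table, a YAML
#' configuration (partitions, ordered characters) and a tab-separated
#' truth record, in the formats the readers of this package consume.
#'
#' @param scen result of [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- scen$matrix
  write_character_matrix(m, file.path(dir, "matrix.nex"))
  utils::write.table(scen$calibrations[, c("taxon", "age_min", "age_max")],
                     file.path(dir, "tip_ages.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  parts <- split(seq_len(m$nchar), factor(m$partition, unique(m$partition)))
  cfg <- list(partitions = lapply(parts, function(ix)
    paste0(min(ix), "-", max(ix))),
    ordered = paste(which(m$ordered), collapse = " "))
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  truth <- data.frame(parameter = c("root_age", "c",
                                    paste0("sigma_", seq_along(scen$truth$sigma)),
                                    "alpha"),
                      value = c(scen$truth$root_age, scen$truth$c,
                                scen$truth$sigma, scen$truth$alpha))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
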