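test_that("pure-birth simulation matches the Yule expectation", {
  set.seed(31)
  p <- fbd_params(0.08, 0, 0, r = 1, rho = 1)
  counts <- replicate(300, {
    tr <- simulate_fbd_tree(p, 12, taxon_range = c(2, 1e6))
    tr$ntip
  })
  # E[extant | both root lineages survive] = 2 e^(lambda t) for a Yule
  # process (survival is certain with mu = 0)
  expect_equal(mean(counts), 2 * exp(0.08 * 12), tolerance = 0.08)
})

test_that("simulated trees satisfy the dated-tree invariants", {
  set.seed(32)
  p <- fbd_params(0.1, 0.05, 0.06, r = 0, rho = 0.8)
  for (i in 1:10) {
    tr <- simulate_fbd_tree(p, 30, taxon_range = c(3, 200))
    expect_silent(validate_time_tree(tr))
    expect_equal(tree_root_age(tr), 30)
    # sampled ancestors sit exactly on their attachment nodes
    sa <- which(tr$sampled_ancestor)
    if (length(sa))
      expect_equal(tr$age[tr$parent[sa]], tr$age[sa], tolerance = 1e-12)
  }
  # removal upon sampling (r = 1) never leaves sampled ancestors
  p1 <- fbd_params(0.1, 0.05, 0.04, r = 1, rho = 0.8)
  for (i in 1:10) {
    tr <- simulate_fbd_tree(p1, 30, taxon_range = c(2, 200))
    expect_false(any(tr$sampled_ancestor))
  }
  expect_error(simulate_fbd_tree(fbd_params(0.1, 0.05, 0, 1, 1e-9), 30,
                                 taxon_range = c(2, 10), max_tries = 5),
               "tries|samples")
})

test_that("forward simulation agrees with the FBD density on 3-tip trees", {
  # inner-node ages of extant 3-tip birth-death trees: the sampled ages
  # must follow the density implied by fbd_log_density up to a constant
  set.seed(33)
  lambda <- 0.15; mu <- 0.05
  p <- fbd_params(lambda, mu, 0, r = 1, rho = 1)
  root_age <- 15
  inner <- replicate(2000, {
    tr <- simulate_fbd_tree(p, root_age, taxon_range = c(3, 3))
    setdiff(tr$age[(tr$ntip + 1L):(2L * tr$ntip - 1L)], root_age)[1]
  })
  # density of the non-root bifurcation age given 3 extant tips
  f <- function(x) {
    tr <- three_tip_tree(x, root_age)
    exp(fbd_log_density(tr, p))
  }
  xs <- seq(1e-3, root_age - 1e-3, length.out = 400)
  fx <- vapply(xs, f, numeric(1))
  cdf <- cumsum(fx) / sum(fx)
  ks <- suppressWarnings(ks.test(inner, function(q)
    approx(xs, cdf, q, rule = 2)$y))
  expect_gt(ks$p.value, 0.01)
})

test_that("character simulation filters invariant characters like the
           Mkv denominator predicts", {
  set.seed(34)
  tr <- four_tip_tree()
  rel <- matrix(1, 7, 1)
  c_rate <- 0.02
  # direct simulation of raw (unfiltered) binary characters
  mod <- mk_rate_matrix(2)
  dur <- branch_durations(tr); dur[is.na(dur)] <- 0
  b <- dur * c_rate
  po <- rev(tree_postorder(tr))
  nsim <- 2000
  alpha_big <- 1e8   # effectively rate 1 for every character
  n_var <- 0
  for (i in seq_len(nsim)) {
    states <- integer(7)
    for (nd in po) {
      pnode <- tr$parent[nd]
      if (is.na(pnode)) states[nd] <- sample.int(2, 1) - 1L
      else {
        P <- transition_probabilities(mod, b[nd])
        states[nd] <- sample.int(2, 1, prob = P[states[pnode] + 1L, ]) - 1L
      }
    }
    if (length(unique(states[1:4])) > 1) n_var <- n_var + 1
  }
  # P(variable) from the Mkv correction denominator
  pconst <- sum(vapply(0:1, function(s)
    oracle_column_lik(tr, b, rep(list(s), 4), mod, 1), numeric(1)))
  bt <- binom.test(n_var, nsim, 1 - pconst)
  expect_gt(bt$p.value, 0.01)
})

test_that("simulated matrices are variable and record their truth", {
  set.seed(35)
  p <- fbd_params(0.1, 0.05, 0.05, r = 0, rho = 0.9)
  tr <- simulate_fbd_tree(p, 40, taxon_range = c(8, 40))
  rel <- simulate_branch_rates(tr, 0.01, c(0.05, 0.05))
  parts <- list(p1 = list(n = 12, p_binary = 0.7, k_multi = 3L,
                          p_ordered = 0.5),
                p2 = list(n = 8, p_binary = 1, k_multi = 3L, p_ordered = 0))
  m <- simulate_characters(tr, rel, 0.01, 1.5, parts)
  expect_silent(validate_character_matrix(m, require_variable = TRUE))
  expect_equal(m$nchar, 20L)
  expect_equal(unname(classify_characters(m)$partition_sizes), c(12L, 8L))
  truth <- attr(m, "truth")
  expect_equal(length(truth$char_rates), 20L)
  expect_true(all(m$state_count[m$partition == "p2"] == 2L))
  expect_error(
    simulate_characters(tr, matrix(0, 2 * tr$ntip - 1, 2), 0, 1, parts),
    "zero")
})

test_that("the bird-scale scenario reproduces the target data shape", {
  set.seed(36)
  scen <- make_bird_scale_scenario()
  cl <- classify_characters(scen$matrix)
  expect_equal(unname(cl$partition_sizes), c(53L, 36L, 48L, 65L, 23L, 55L))
  expect_equal(cl$n_char, 280L)
  expect_gte(cl$n_taxa, 50L)
  expect_lte(cl$n_taxa, 90L)
  # fossil ages fall inside their stratigraphic windows
  ca <- scen$calibrations
  tips <- seq_len(scen$tree$ntip)
  expect_true(all(scen$tree$age[tips] >= ca$age_min - 1e-9 &
                    scen$tree$age[tips] <= ca$age_max + 1e-9))
  # round trip through the on-disk formats
  dir <- tempfile("scen")
  write_scenario(scen, dir)
  cfg <- read_analysis_config(file.path(dir, "config.yml"))
  m2 <- read_character_matrix(file.path(dir, "matrix.nex"),
                              ordered = cfg$ordered,
                              partition = cfg$partitions)
  expect_equal(length(m2$taxa), cl$n_taxa)
  expect_equal(m2$nchar, 280L)
  expect_equal(which(m2$ordered), which(scen$matrix$ordered))
  ca2 <- read_tip_calibrations(file.path(dir, "tip_ages.tsv"),
                               taxa = m2$taxa)
  expect_equal(ca2$age_max, ca$age_max, tolerance = 1e-6)
})
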