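test_that("Mk rate matrices are normalized to unit mean rate", {
  for (k in 2:5) for (ord in c(FALSE, TRUE)) {
    mod <- mk_rate_matrix(k, ord)
    Q <- mod$Q
    expect_equal(rowSums(Q), rep(0, k), tolerance = 1e-12)
    expect_true(all(Q[upper.tri(Q) | lower.tri(Q)] >= 0))
    # expected rate at uniform stationary frequencies is 1
    expect_equal(-sum(diag(Q)) / k, 1, tolerance = 1e-12)
    if (ord && k > 2) {
      off <- Q[abs(row(Q) - col(Q)) > 1]
      expect_true(all(off == 0))
    }
  }
  # k = 3 ordered: adjacent rate 3/4 from the normalization algebra
  m3 <- mk_rate_matrix(3, TRUE)
  expect_equal(m3$Q[1, 2], 0.75)
  expect_equal(m3$Q[1, 3], 0)
  expect_error(mk_rate_matrix(1), "k")
})

test_that("transition probabilities match closed forms and limits", {
  m2 <- mk_rate_matrix(2)
  expect_equal(transition_probabilities(m2, 0), diag(2))
  # Mk2: P(stay) = 1/2 + 1/2 exp(-2b)
  for (b in c(0.1, 1, 3)) {
    P <- transition_probabilities(m2, b)
    expect_equal(P[1, 1], 0.5 + 0.5 * exp(-2 * b), tolerance = 1e-12)
    expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
  }
  # long branches converge to uniform
  for (k in 2:4) {
    mod <- mk_rate_matrix(k, k > 2)
    P <- transition_probabilities(mod, 500)
    expect_equal(P, matrix(1 / k, k, k), tolerance = 1e-9)
  }
  expect_error(transition_probabilities(m2, -1), "negative")
})

test_that("discrete-gamma category rates have mean 1 and are nondecreasing", {
  expect_equal(gamma_category_rates(0.5, 1), 1)
  for (alpha in c(0.2, 1, 5)) {
    r <- gamma_category_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-8)
    expect_true(all(diff(r) >= 0))
  }
  expect_equal(gamma_category_rates(1e5, 4), rep(1, 4), tolerance = 1e-2)
  # category means of the unit-mean gamma over its quartiles (numerical
  # integration oracle)
  alpha <- 1
  qs <- qgamma(c(0, 0.25, 0.5, 0.75, 1), alpha, alpha)
  means <- vapply(1:4, function(i) {
    stats::integrate(function(x) x * dgamma(x, alpha, alpha),
                     qs[i], qs[i + 1])$value / 0.25
  }, numeric(1))
  expect_equal(gamma_category_rates(alpha, 4), means, tolerance = 1e-6)
  expect_error(gamma_category_rates(0, 4), "positive")
})

test_that("pruning equals brute-force enumeration on 4-taxon trees", {
  set.seed(42)
  tr <- four_tip_tree()
  dist <- c(0.3, 0.1, 0.25, 0.4, 0, 0.15, 0.2)
  for (k in 2:4) for (ord in c(FALSE, TRUE)) {
    mod <- mk_rate_matrix(k, ord)
    rates <- gamma_category_rates(0.7, 3)
    cols <- list(
      list(0L, 1L, 0L, 1L),                              # resolved
      list(0L, c(0L, 1L), 0:(k - 1L), as.integer(k - 1L)))  # ambiguous
    for (col in cols) {
      ll <- character_log_likelihood(tr, dist, col, mod, rates)
      orc <- oracle_column_lik(tr, dist, col, mod, rates)
      expect_equal(ll, log(orc), tolerance = 1e-8)
    }
  }
})

test_that("likelihoods of all resolved columns sum to one", {
  tr <- three_tip_tree()
  dist <- c(0.2, 0.5, 0.8, 0, 0.3)
  for (k in 2:3) {
    mod <- mk_rate_matrix(k, k > 2)
    tot <- sum(vapply(all_columns(k, 3), function(col)
      exp(character_log_likelihood(tr, dist, col, mod,
                                   gamma_category_rates(1.2, 2))),
      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("Mkv correction conditions on variability", {
  tr <- three_tip_tree()
  dist <- c(0.2, 0.5, 0.8, 0, 0.3)
  mod <- mk_rate_matrix(2)
  # corrected likelihoods over all variable columns sum to 1
  tot <- sum(vapply(variable_columns(2, 3), function(col)
    exp(mkv_partition_log_likelihood(tr, dist, list(col), 2L, FALSE,
                                     category_rates = 1)), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-9)
  # all distances zero: no character can vary
  expect_identical(
    mkv_partition_log_likelihood(tr, rep(0, 5), list(list(0L, 0L, 1L)),
                                 2L, FALSE), -Inf)
  # 4-taxon ordered k=3 corrected value equals the enumeration oracle
  tr4 <- four_tip_tree()
  dist4 <- c(0.3, 0.1, 0.25, 0.4, 0, 0.15, 0.2)
  mod3 <- mk_rate_matrix(3, TRUE)
  rates <- gamma_category_rates(0.9, 4)
  col <- list(0L, 2L, 1L, 0L)
  got <- mkv_partition_log_likelihood(tr4, dist4, list(col), 3L, TRUE, rates)
  expect_equal(got, log(oracle_mkv_lik(tr4, dist4, col, mod3, rates)),
               tolerance = 1e-8)
})

test_that("fast pruning path agrees with the R reference across classes", {
  set.seed(7)
  tr <- four_tip_tree()
  dist <- runif(7, 0.05, 0.6); dist[5] <- 0
  parent0 <- ifelse(is.na(tr$parent), 0L, tr$parent) - 1L
  for (k in 2:4) for (ord in c(FALSE, TRUE)) {
    mod <- mk_rate_matrix(k, ord)
    rates <- gamma_category_rates(0.8, 4)
    cols <- replicate(5, lapply(sample(0:(k - 1L), 4, replace = TRUE),
                                identity), simplify = FALSE)
    cols <- Filter(function(cl) length(unique(unlist(cl))) > 1, cols)
    tipL <- array(0, dim = c(k, 4, length(cols)))
    for (g in seq_along(cols))
      for (i in 1:4) tipL[cols[[g]][[i]] + 1L, i, g] <- 1
    fast <- morphclock:::mk_group_loglik_cpp(parent0, 4L, dist, mod$evec,
                                             mod$eval, tipL, rates, TRUE)
    slow <- mkv_partition_log_likelihood(tr, dist, cols,
                                         rep(k, length(cols)),
                                         rep(ord, length(cols)), rates)
    expect_equal(fast, slow, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to child rotation and continuous in scale", {
  tr <- four_tip_tree()
  # rotate children of the root: swap subtree assignment by relabeling
  tr_rot <- time_tree(parent = c(7L, 7L, 6L, 6L, NA, 5L, 5L),
                      age = c(0, 0, 0, 0, 30, 20, 10),
                      tip_label = c("c", "d", "a", "b"))
  dist <- c(0.3, 0.1, 0.25, 0.4, 0, 0.15, 0.2)
  dist_rot <- c(0.25, 0.4, 0.3, 0.1, 0, 0.2, 0.15)
  mod <- mk_rate_matrix(2)
  col <- list(0L, 1L, 1L, 0L)       # a,b,c,d
  col_rot <- list(1L, 0L, 0L, 1L)   # c,d,a,b
  expect_equal(
    character_log_likelihood(tr, dist, col, mod),
    character_log_likelihood(tr_rot, dist_rot, col_rot, mod),
    tolerance = 1e-12)
  # scaling distances changes the likelihood continuously
  lls <- vapply(c(1, 0.99, 0.98), function(f)
    character_log_likelihood(tr, dist * f, col, mod), numeric(1))
  expect_lt(max(abs(diff(lls))), 0.05)
})

test_that("sampled-ancestor tips contribute via a zero-length branch", {
  # fossil b attached at its parent's age: conditional likelihood equals
  # the state's partial likelihood at the attachment node
  tr <- time_tree(parent = c(3L, 3L, NA), age = c(0, 10, 10),
                  tip_label = c("a", "b"), sampled_ancestor = c(FALSE, TRUE))
  mod <- mk_rate_matrix(2)
  dist <- c(0.4, 0, 0)
  ll <- character_log_likelihood(tr, dist, list(0L, 1L), mod)
  # root state must be 1 (fossil observed there), tip a reached via P(1->0)
  P <- transition_probabilities(mod, 0.4)
  expect_equal(exp(ll), 0.5 * P[2, 1], tolerance = 1e-12)
})
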