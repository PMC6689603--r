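# hand-built posterior tree samples over 4 taxa with rel matrices
sample_trees <- function() {
  # topology A: ((a,b),(c,d)); topology B: ((a,c),(b,d))
  tA <- time_tree(parent = c(6L, 6L, 7L, 7L, NA, 5L, 5L),
                  age = c(0, 0, 0, 0, 30, 10, 20),
                  tip_label = c("a", "b", "c", "d"))
  tB <- time_tree(parent = c(6L, 7L, 6L, 7L, NA, 5L, 5L),
                  age = c(0, 0, 0, 0, 30, 12, 22),
                  tip_label = c("a", "b", "c", "d"))
  tA$rel <- matrix(1, 7, 1)
  tB$rel <- matrix(1, 7, 1)
  list(tA = tA, tB = tB)
}

test_that("HPD intervals are the shortest covering intervals", {
  expect_equal(hpd_interval(rep(3, 10)), c(3, 3))
  # 1..100 at level 0.95: must contain 95 consecutive values, width 94
  h <- hpd_interval(1:100, 0.95)
  expect_equal(h[2] - h[1], 94)
  # sliding-window oracle on random samples
  set.seed(61)
  for (i in 1:5) {
    x <- sort(rlnorm(200))
    m <- ceiling(0.9 * 200)
    widths <- x[m:200] - x[1:(200 - m + 1)]
    i0 <- which.min(widths)
    expect_equal(hpd_interval(x, 0.9), c(x[i0], x[i0 + m - 1]))
  }
  # exponential samples: lower end at the sample minimum
  x <- rexp(2000)
  h <- hpd_interval(x, 0.95)
  expect_equal(h[1], min(x), tolerance = 0.02)
  # width non-increasing as the level decreases
  lv <- c(0.99, 0.95, 0.9, 0.5)
  w <- vapply(lv, function(l) diff(hpd_interval(x, l)), numeric(1))
  expect_true(all(diff(w) <= 0))
  # agrees with an independent HPD implementation (n chosen so that the
  # ceiling(n*level) convention used here and coda's round(n*level)+1
  # count the same number of points)
  y <- rgamma(458, 3, 2)
  expect_equal(hpd_interval(y, 0.9),
               as.numeric(coda::HPDinterval(coda::as.mcmc(y), 0.9)),
               tolerance = 1e-8)
  expect_error(hpd_interval(numeric(0)), "samples")
})

test_that("majority-rule consensus keeps clades above half frequency", {
  st <- sample_trees()
  # identical trees: same topology, all probabilities 1
  cons <- majority_rule_consensus(list(st$tA, st$tA, st$tA))
  expect_true(all(cons$clades$probability == 1))
  expect_equal(nrow(cons$clades), 3L)  # root, (a,b), (c,d)
  # clade (a,b) in 2 of 3 trees -> retained with probability 2/3
  cons2 <- majority_rule_consensus(list(st$tA, st$tA, st$tB))
  ab <- cons2$clades[cons2$clades$key == "1,2", ]
  expect_equal(ab$probability, 2 / 3, tolerance = 1e-12)
  # 50/50 split on the quartet -> unresolved polytomy (only the root)
  cons3 <- majority_rule_consensus(list(st$tA, st$tB))
  expect_equal(nrow(cons3$clades), 1L)
  expect_equal(cons3$phylo$Nnode, 1L)
  # consensus probabilities equal empirical clade frequencies exactly
  freqs <- morphclock:::.clade_freqs(list(st$tA, st$tA, st$tB))
  for (i in seq_len(nrow(cons2$clades)))
    expect_identical(cons2$clades$probability[i],
                     unname(freqs[cons2$clades$key[i]]))
  # age annotation: (a,b) ages are 10, 10 in the samples containing it
  expect_equal(ab$age_median, 10)
  # Newick export carries the annotations
  nwk <- write_consensus_newick(cons2)
  expect_match(nwk, "prob=0.667")
  expect_match(nwk, ";$")
})

test_that("clade tables summarize ages and branch rates conditionally", {
  st <- sample_trees()
  tA2 <- st$tA
  tA2$age[6] <- 14            # (a,b) age differs between samples
  tA2$rel <- matrix(2, 7, 1)  # elevated rates in this sample
  trees <- list(st$tA, tA2, st$tB)
  tab <- clade_table(trees, list(AB = c("a", "b"), CD = c("c", "d"),
                                 AC = c("a", "c")))
  expect_equal(tab$probability, c(2 / 3, 2 / 3, 1 / 3))
  expect_equal(tab$age_median[1], 12)   # median of 10, 14
  expect_equal(tab$age_mean[1], 12)
  # branch rate on the (a,b) stem: mean of 1 and 2
  expect_equal(tab$rate_mean_p1[1], 1.5)
  # a clade never sampled
  tab2 <- clade_table(trees, list(AD = c("a", "d")))
  expect_equal(tab2$probability, 0)
  expect_true(is.na(tab2$age_median))
})

test_that("summaries are invariant to sample concatenation order", {
  st <- sample_trees()
  trees <- list(st$tA, st$tA, st$tB)
  t1 <- clade_table(trees, list(AB = c("a", "b")))
  t2 <- clade_table(rev(trees), list(AB = c("a", "b")))
  expect_equal(t1$probability, t2$probability)
  expect_equal(t1$age_median, t2$age_median)
  c1 <- majority_rule_consensus(trees)
  c2 <- majority_rule_consensus(rev(trees))
  expect_equal(c1$clades[order(c1$clades$key), ],
               c2$clades[order(c2$clades$key), ], ignore_attr = TRUE)
})

test_that("ancestor summaries count flags and fractions", {
  # one fossil f; ancestor in half the samples
  t_tip <- time_tree(parent = c(4L, 4L, 5L, 5L, NA),
                     age = c(0, 0, 15, 20, 25),
                     tip_label = c("a", "b", "f"))
  t_sa <- time_tree(parent = c(4L, 4L, 5L, 5L, NA),
                    age = c(0, 0, 15, 10, 15),
                    tip_label = c("a", "b", "f"),
                    sampled_ancestor = c(FALSE, FALSE, TRUE))
  asum <- ancestor_summary(list(t_tip, t_sa, t_tip, t_sa))
  expect_equal(asum$fraction_mean, 0.5)
  expect_equal(unname(asum$per_fossil["f"]), 0.5)
  expect_true(asum$any_ancestors)
  # all-tip traces (as under r = 1): exactly zero, flagged
  asum1 <- ancestor_summary(list(t_tip, t_tip))
  expect_equal(asum1$fraction_mean, 0)
  expect_false(asum1$any_ancestors)
})

test_that("clade rate distributions find quartiles and outliers", {
  st <- sample_trees()
  trees <- replicate(10, {
    tt <- st$tA
    tt$rel <- matrix(rep(c(1, 1, 1, 1, 1, 1, 1), 1), 7, 1)
    tt
  }, simplify = FALSE)
  # all branch means equal: zero IQR, no outliers
  z <- clade_rate_distribution(trees, c("a", "b", "c", "d"), 1)
  expect_equal(unname(z$iqr), 0)
  expect_length(z$outliers, 0L)
  expect_equal(unname(z$quartiles), c(1, 1, 1))
  # one branch elevated tenfold: flagged as a high outlier
  trees10 <- lapply(trees, function(tt) {
    tt$rel[6, 1] <- 10   # stem of (a,b)
    tt
  })
  z10 <- clade_rate_distribution(trees10, c("a", "b", "c", "d"), 1)
  expect_true("1,2" %in% names(z10$outliers))
  expect_equal(unname(z10$outliers["1,2"]), 10)
  # quartiles match the sort-based oracle
  expect_equal(unname(z10$quartiles),
               unname(quantile(z10$branch_means, c(0.25, 0.5, 0.75))))
  # exclusion list removes the pair and its stem
  zx <- clade_rate_distribution(trees10, c("a", "b", "c", "d"), 1,
                                exclude = c("a", "b"))
  expect_false("1,2" %in% names(zx$branch_means))
  expect_false("1" %in% names(zx$branch_means))
})
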