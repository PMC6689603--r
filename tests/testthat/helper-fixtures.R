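# Shared fixtures and independent oracles.

# --- small trees -----------------------------------------------------------

# ((a:1? ages): cherry of two extant tips
two_tip_tree <- function(root_age = 10) {
  time_tree(parent = c(3L, 3L, NA), age = c(0, 0, root_age),
            tip_label = c("a", "b"))
}

# balanced 4-taxon tree, extant tips
four_tip_tree <- function(ages = c(0, 0, 0, 0, 30, 10, 20)) {
  # topology ((a,b),(c,d)); node 5 = root, 6 = (a,b), 7 = (c,d)
  time_tree(parent = c(6L, 6L, 7L, 7L, NA, 5L, 5L),
            age = ages, tip_label = c("a", "b", "c", "d"))
}

# three extant tips, ((a,b),c)
three_tip_tree <- function(inner = 10, root = 30) {
  time_tree(parent = c(5L, 5L, 4L, NA, 4L), age = c(0, 0, 0, root, inner),
            tip_label = c("a", "b", "c"))
}

# --- brute-force Mk likelihood oracle --------------------------------------

# enumerate all internal-node state assignments; average over categories
oracle_column_lik <- function(tree, distances, column, model, rates = 1) {
  k <- model$k
  ntip <- tree$ntip
  nn <- 2L * ntip - 1L
  internals <- (ntip + 1L):nn
  root <- tree_root(tree)
  lik_rate <- function(rate) {
    P <- lapply(seq_len(nn), function(nd) {
      if (is.na(tree$parent[nd])) return(NULL)
      transition_probabilities(model, distances[nd] * rate)
    })
    total <- 0
    grid <- rep(list(0:(k - 1L)), length(internals))
    combos <- as.matrix(do.call(expand.grid, grid))
    for (ri in seq_len(nrow(combos))) {
      s <- integer(nn)
      s[internals] <- combos[ri, ]
      pr <- 1 / k  # uniform root frequency
      ok <- TRUE
      for (nd in seq_len(nn)) {
        p <- tree$parent[nd]
        if (is.na(p)) next
        if (nd <= ntip) {
          # sum over allowed tip states
          pr <- pr * sum(P[[nd]][s[p] + 1L, column[[nd]] + 1L])
        } else {
          pr <- pr * P[[nd]][s[p] + 1L, s[nd] + 1L]
        }
        if (pr == 0) { ok <- FALSE; break }
      }
      if (ok) total <- total + pr
    }
    total
  }
  mean(vapply(rates, lik_rate, numeric(1)))
}

# all fully resolved columns for k states and ntip tips
all_columns <- function(k, ntip) {
  grid <- do.call(expand.grid, rep(list(0:(k - 1L)), ntip))
  lapply(seq_len(nrow(grid)), function(i) {
    lapply(seq_len(ntip), function(j) grid[i, j])
  })
}

variable_columns <- function(k, ntip) {
  cols <- all_columns(k, ntip)
  keep <- vapply(cols, function(cl) length(unique(unlist(cl))) > 1L, logical(1))
  cols[keep]
}

# Mkv-corrected oracle: enumeration likelihood conditioned on variability
oracle_mkv_lik <- function(tree, distances, column, model, rates = 1) {
  raw <- oracle_column_lik(tree, distances, column, model, rates)
  pconst <- sum(vapply(0:(model$k - 1L), function(s) {
    oracle_column_lik(tree, distances, rep(list(s), tree$ntip), model, rates)
  }, numeric(1)))
  raw / (1 - pconst)
}

# --- closed-form birth-death density oracle (extant trees, psi = 0) --------

bd_p0_oracle <- function(t, lambda, mu, rho = 1) {
  e <- exp(-(lambda - mu) * t)
  1 - rho * (lambda - mu) / (rho * lambda + (lambda * (1 - rho) - mu) * e)
}

bd_p1_oracle <- function(t, lambda, mu, rho = 1) {
  e <- exp(-(lambda - mu) * t)
  rho * (lambda - mu)^2 * e / (rho * lambda + (lambda * (1 - rho) - mu) * e)^2
}

# log density of an extant-only dated tree conditioned on root age and
# on sampling (>= 1 sample), mirroring the package's conditioning but
# written from the classic birth-death formulas
oracle_bd_logdens <- function(tree, lambda, mu, rho = 1) {
  ntip <- tree$ntip
  root <- tree_root(tree)
  internal <- setdiff((ntip + 1L):(2L * ntip - 1L), root)
  # classic reconstructed-process form: one p1 factor per internal node
  # (root counted twice), each carrying its rho; no separate rho^n term
  ll <- 2 * log(bd_p1_oracle(tree$age[root], lambda, mu, rho))
  for (nd in internal)
    ll <- ll + log(lambda) + log(bd_p1_oracle(tree$age[nd], lambda, mu, rho))
  ll - log(1 - bd_p0_oracle(tree$age[root], lambda, mu, rho)^2)
}

# --- misc ------------------------------------------------------------------

write_tmp_nexus <- function(rows, symbols = "01", dir = tempdir()) {
  path <- tempfile("mat", fileext = ".nex", tmpdir = dir)
  nchar <- nchar(gsub("\\([^)]*\\)", "x", rows[[1]]))
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(rows), nchar),
             sprintf("FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                     symbols),
             "MATRIX",
             paste(names(rows), rows),
             ";", "END;")
  writeLines(lines, path)
  path
}
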