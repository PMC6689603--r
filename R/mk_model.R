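#' Mk instantaneous rate matrix
#'
#' Builds the k-state Mk rate matrix with uniform stationary frequencies,
#' normalized so the expected substitution rate at stationarity is 1
#' (branch lengths are then expected substitutions per character). For an
#' ordered character, instantaneous change is allowed only between
#' adjacent states (a linear chain); for k = 2 ordered and unordered
#' coincide.
#'
#' @param k number of states (>= 2).
#' @param ordered restrict changes to adjacent states.
#' @return a list with `k`, `ordered`, `Q` (k x k rate matrix), and its
#'   symmetric eigendecomposition `evec`, `eval` used for matrix
#'   exponentials.
#' @export
mk_rate_matrix <- function(k, ordered = FALSE) {
  if (k < 2) stop("k must be >= 2")
  if (ordered && k > 2) {
    # adjacent rate a with mean rate 1 at uniform frequencies:
    # sum of diagonal leaving-rates = 2a(k-1), so a = k / (2(k-1))
    a <- k / (2 * (k - 1))
    Q <- matrix(0, k, k)
    for (i in seq_len(k - 1)) {
      Q[i, i + 1] <- a
      Q[i + 1, i] <- a
    }
  } else {
    Q <- matrix(1 / (k - 1), k, k)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q, symmetric = TRUE)
  list(k = as.integer(k), ordered = isTRUE(ordered) && k > 2, Q = Q,
       evec = e$vectors, eval = e$values)
}

#' Transition probability matrix of an Mk process
#'
#' @param model result of [mk_rate_matrix()].
#' @param b branch length in expected substitutions per character (>= 0).
#' @return k x k stochastic matrix `exp(Q b)`.
#' @export
transition_probabilities <- function(model, b) {
  if (b < 0) stop("negative branch length")
  P <- model$evec %*% (exp(model$eval * b) * t(model$evec))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma category rates for among-character rate variation
#'
#' Mean rates of the `ncat` equal-probability categories of a unit-mean
#' gamma distribution with shape `alpha` (the usual discrete-gamma
#' treatment of rate variation across characters).
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories (>= 1).
#' @return nondecreasing numeric vector of length `ncat` with mean 1.
#' @export
gamma_category_rates <- function(alpha, ncat = 4L) {
  if (alpha <= 0) stop("alpha must be positive")
  if (ncat < 1) stop("ncat must be >= 1")
  if (ncat == 1L) return(1)
  phangorn::discrete.gamma(alpha, ncat)
}

# tip partial-likelihood matrix (k x ntip) for one character column of
# state sets (0-based)
.tip_partials <- function(column, k) {
  L <- matrix(0, k, length(column))
  for (i in seq_along(column)) L[column[[i]] + 1L, i] <- 1
  L
}

# Felsenstein pruning for one character at one rate, plain R reference.
# distances: per-node branch length (expected substitutions), NA/0 at root.
.prune_lik <- function(tree, distances, tipL, model, rate) {
  nn <- 2L * tree$ntip - 1L
  part <- vector("list", nn)
  for (i in seq_len(tree$ntip)) part[[i]] <- tipL[, i]
  for (nd in tree_postorder(tree)) {
    if (nd > tree$ntip) {
      kids <- which(tree$parent == nd)
      v <- 1
      for (ch in kids) {
        P <- transition_probabilities(model, distances[ch] * rate)
        v <- v * as.vector(P %*% part[[ch]])
      }
      part[[nd]] <- v
    }
  }
  sum(part[[tree_root(tree)]]) / model$k
}

#' Log-likelihood of a single character on a dated tree
#'
#' Felsenstein pruning over the rooted tree with uniform root state
#' frequencies 1/k. Ambiguous cells contribute partial likelihood 1 for
#' each allowed state. The likelihood is averaged over discrete-gamma
#' categories with equal weights. No acquisition-bias correction is
#' applied here (see [mkv_partition_log_likelihood()]).
#'
#' @param tree a `time_tree`.
#' @param distances numeric vector over nodes: branch length above each
#'   node in expected substitutions per character (ignored at the root).
#' @param column list of 0-based state sets, one per tip, in tip order.
#' @param model an Mk model from [mk_rate_matrix()].
#' @param category_rates discrete-gamma rates from
#'   [gamma_category_rates()].
#' @return log probability of the column.
#' @export
character_log_likelihood <- function(tree, distances, column, model,
                                     category_rates = 1) {
  if (length(column) != tree$ntip) stop("column length must equal tip count")
  if (any(distances[-tree_root(tree)] < 0, na.rm = TRUE))
    stop("negative branch distances")
  tipL <- .tip_partials(column, model$k)
  lik <- mean(vapply(category_rates, function(r)
    .prune_lik(tree, distances, tipL, model, r), numeric(1)))
  log(lik)
}

# likelihood that a character of this model class is constant (any of the
# k constant columns), averaged over gamma categories
.prob_constant <- function(tree, distances, model, category_rates) {
  k <- model$k
  tot <- 0
  for (s in 0:(k - 1L)) {
    col <- rep(list(s), tree$ntip)
    tipL <- .tip_partials(col, k)
    tot <- tot + mean(vapply(category_rates, function(r)
      .prune_lik(tree, distances, tipL, model, r), numeric(1)))
  }
  tot
}

#' Mkv-corrected log-likelihood of a character partition
#'
#' Sums per-character log-likelihoods over a partition, applying the
#' acquisition-bias (Mkv) correction: because only variable characters
#' are coded, each character's likelihood is divided by the probability
#' that a character of its state-count/ordering class is variable,
#' `1 - sum of constant-column likelihoods`, computed with the same
#' gamma-category averaging. A degenerate tree on which no character can
#' vary (all distances zero) yields `-Inf`.
#'
#' @param tree a `time_tree`.
#' @param distances numeric vector over nodes: branch length above each
#'   node in expected substitutions per character, for this partition.
#' @param columns list of character columns (each a list of 0-based state
#'   sets per tip).
#' @param k integer vector of per-character state counts.
#' @param ordered logical vector of per-character ordering flags.
#' @param category_rates discrete-gamma rates.
#' @param correct apply the Mkv variable-characters-only conditioning.
#' @return total log-likelihood of the partition.
#' @export
mkv_partition_log_likelihood <- function(tree, distances, columns, k, ordered,
                                         category_rates = 1, correct = TRUE) {
  classes <- paste0(k, ifelse(ordered & k > 2, "o", "u"))
  total <- 0
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    model <- mk_rate_matrix(k[idx[1]], ordered[idx[1]])
    ll <- vapply(idx, function(j)
      character_log_likelihood(tree, distances, columns[[j]], model,
                               category_rates), numeric(1))
    if (correct) {
      pconst <- .prob_constant(tree, distances, model, category_rates)
      denom <- 1 - pconst
      if (denom <= 0) return(-Inf)
      ll <- ll - log(denom)
    }
    total <- total + sum(ll)
  }
  total
}
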