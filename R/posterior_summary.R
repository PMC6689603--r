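# Posterior summaries: consensus topology, HPD intervals, clade tables,
# sampled-ancestor summaries and per-branch relative-rate distributions.
# Branches are identified across sampled topologies by their bipartition
# (the set of tips below them), so every branch-level summary is
# conditional on the samples in which that bipartition occurs.

# sorted-tip-index key for every node of a tree
.node_keys <- function(tree) {
  sets <- tip_descendant_sets(tree)
  vapply(sets, function(s) paste(s, collapse = ","), character(1))
}

# frequency of each internal clade (including the root clade) over trees
.clade_freqs <- function(trees) {
  counts <- new.env(hash = TRUE, parent = emptyenv())
  ntr <- length(trees)
  for (tr in trees) {
    keys <- .node_keys(tr)[(tr$ntip + 1L):(2L * tr$ntip - 1L)]
    for (k in keys) {
      prev <- if (is.null(counts[[k]])) 0 else counts[[k]]
      counts[[k]] <- prev + 1
    }
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k) counts[[k]], numeric(1)) / ntr,
                  keys)
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(level * n)` of the sorted
#' samples; ties are broken toward the lower interval start.
#'
#' @param samples numeric vector (>= 1 finite values).
#' @param level credibility level.
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n == 0L) stop("no finite samples")
  m <- min(n, ceiling(level * n))
  if (m == n) return(c(x[1L], x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

#' Majority-rule consensus of sampled trees
#'
#' Includes exactly the clades occurring in more than half of the
#' post-burn-in tree samples (these are mutually compatible), leaving
#' polytomies elsewhere. Each retained clade is annotated with its
#' posterior frequency and with the median, mean and 95% HPD of its age
#' over the samples in which it occurs.
#'
#' @param trees list of `time_tree` samples on identical taxon sets.
#' @param level HPD level for age annotation.
#' @return a `consensus_tree`: list with `phylo` (an [ape::phylo] with
#'   node labels giving clade probabilities), `clades` (data.frame with
#'   key, size, probability and age summaries) and `tip_ages` (median
#'   sampled tip ages).
#' @export
majority_rule_consensus <- function(trees, level = 0.95) {
  if (!length(trees)) stop("no trees")
  taxa <- trees[[1L]]$tip_label
  for (tr in trees) if (!identical(tr$tip_label, taxa))
    stop("trees have mismatched taxon sets")
  ntip <- trees[[1L]]$ntip
  freqs <- .clade_freqs(trees)
  rootkey <- paste(seq_len(ntip), collapse = ",")
  sel <- names(freqs)[freqs > 0.5]
  if (!(rootkey %in% sel)) sel <- c(sel, rootkey)
  # collect ages conditional on clade presence
  ages <- stats::setNames(vector("list", length(sel)), sel)
  tip_age_mat <- matrix(0, length(trees), ntip)
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    keys <- .node_keys(tr)
    tip_age_mat[ti, ] <- tr$age[seq_len(ntip)]
    for (nd in (ntip + 1L):(2L * ntip - 1L)) {
      k <- keys[nd]
      if (k %in% sel) ages[[k]] <- c(ages[[k]], tr$age[nd])
    }
  }
  sets <- lapply(strsplit(sel, ","), as.integer)
  sizes <- lengths(sets)
  ord <- order(-sizes)
  sets <- sets[ord]; sel <- sel[ord]; sizes <- sizes[ord]
  nint <- length(sets)
  # parent of each clade/tip = smallest selected strict superset
  # (selected clades are pairwise compatible, so this is well defined)
  node_id <- ntip + seq_len(nint)
  parent_of <- function(member_set) {
    best <- NA_integer_; bestsize <- Inf
    for (i in seq_len(nint)) {
      if (sizes[i] <= length(member_set) || sizes[i] >= bestsize) next
      if (all(member_set %in% sets[[i]])) { best <- i; bestsize <- sizes[i] }
    }
    best
  }
  edges <- NULL
  for (i in seq_len(ntip))
    edges <- rbind(edges, c(node_id[parent_of(i)], i))
  for (i in seq_len(nint)) {
    if (sizes[i] == ntip) next
    edges <- rbind(edges, c(node_id[parent_of(sets[[i]])], node_id[i]))
  }
  med <- vapply(ages[sel], stats::median, numeric(1))
  mn <- vapply(ages[sel], mean, numeric(1))
  hpd <- t(vapply(ages[sel], hpd_interval, numeric(2), level = level))
  tip_med <- apply(tip_age_mat, 2L, stats::median)
  node_age <- c(tip_med, med)
  elen <- pmax(node_age[edges[, 1L]] - node_age[edges[, 2L]], 0)
  phy <- structure(list(edge = edges, edge.length = elen, tip.label = taxa,
                        Nnode = nint,
                        node.label = sprintf("%.3f", freqs[sel])),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  clades <- data.frame(key = sel, size = sizes,
                       probability = as.numeric(freqs[sel]),
                       age_median = med, age_mean = mn,
                       age_hpd_low = hpd[, 1L], age_hpd_high = hpd[, 2L],
                       stringsAsFactors = FALSE)
  structure(list(phylo = phy, clades = clades, tip_ages = tip_med,
                 taxa = taxa), class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("consensus_tree: %d tips, %d resolved clades, root age (median) %.2f Ma\n",
              length(x$taxa), nrow(x$clades),
              max(x$clades$age_median)))
  invisible(x)
}

#' Write an annotated consensus tree as Newick
#'
#' Nodes carry metadata comments with posterior probability, median age
#' and 95% HPD bounds.
#'
#' @param cons a `consensus_tree`.
#' @param path optional output file.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_consensus_newick <- function(cons, path = NULL) {
  phy <- cons$phylo
  ntip <- length(phy$tip.label)
  cl <- cons$clades
  lab <- function(nd) {
    if (nd <= ntip) return(phy$tip.label[nd])
    i <- nd - ntip
    sprintf("[&prob=%.3f,age_median=%.3f,age_hpd={%.3f,%.3f}]",
            cl$probability[i], cl$age_median[i], cl$age_hpd_low[i],
            cl$age_hpd_high[i])
  }
  kids <- vector("list", ntip + phy$Nnode)
  for (e in seq_len(nrow(phy$edge)))
    kids[[phy$edge[e, 1L]]] <- c(kids[[phy$edge[e, 1L]]], phy$edge[e, 2L])
  elen <- function(nd) {
    e <- which(phy$edge[, 2L] == nd)
    if (length(e)) sprintf(":%.6g", phy$edge.length[e]) else ""
  }
  rec <- function(nd) {
    if (nd <= ntip) return(paste0(lab(nd), elen(nd)))
    paste0("(", paste(vapply(kids[[nd]], rec, character(1)), collapse = ","),
           ")", lab(nd), elen(nd))
  }
  out <- paste0(rec(ntip + 1L), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Posterior summaries for named clades
#'
#' For each clade (a set of taxon labels): posterior probability (the
#' fraction of tree samples in which the set is monophyletic), age
#' median/mean and HPD over the samples containing the clade, and, per
#' partition, the mean and HPD of the relative clock rate on the branch
#' subtending the clade (conditional on the same samples).
#'
#' @param trees list of sampled `time_tree` objects (carrying `rel`
#'   matrices when produced by [run_tip_dating()]).
#' @param clades named list of taxon-label vectors.
#' @param part_labels partition labels for rate columns (default from the
#'   rel matrix width).
#' @param level HPD level.
#' @return a data.frame, one row per clade.
#' @export
clade_table <- function(trees, clades, part_labels = NULL, level = 0.95) {
  taxa <- trees[[1L]]$tip_label
  npart <- if (!is.null(trees[[1L]]$rel)) ncol(trees[[1L]]$rel) else 0L
  if (is.null(part_labels) && npart > 0L)
    part_labels <- paste0("p", seq_len(npart))
  keys <- vapply(clades, function(cl)
    paste(sort(match(cl, taxa)), collapse = ","), character(1))
  if (any(is.na(match(unlist(clades), taxa))))
    stop("clade taxa missing from trees")
  ages <- rates <- vector("list", length(clades))
  for (i in seq_along(clades)) {
    ages[[i]] <- numeric(0)
    rates[[i]] <- vector("list", npart)
    for (j in seq_len(npart)) rates[[i]][[j]] <- numeric(0)
  }
  for (tr in trees) {
    nk <- .node_keys(tr)
    for (i in seq_along(clades)) {
      nd <- match(keys[i], nk)
      if (!is.na(nd)) {
        ages[[i]] <- c(ages[[i]], tr$age[nd])
        if (npart > 0L) for (j in seq_len(npart))
          rates[[i]][[j]] <- c(rates[[i]][[j]], tr$rel[nd, j])
      }
    }
  }
  ntr <- length(trees)
  out <- data.frame(clade = names(clades),
                    probability = vapply(ages, length, numeric(1)) / ntr,
                    stringsAsFactors = FALSE)
  out$age_median <- vapply(ages, function(a)
    if (length(a)) stats::median(a) else NA_real_, numeric(1))
  out$age_mean <- vapply(ages, function(a)
    if (length(a)) mean(a) else NA_real_, numeric(1))
  h <- t(vapply(ages, function(a)
    if (length(a)) hpd_interval(a, level) else c(NA_real_, NA_real_),
    numeric(2)))
  out$age_hpd_low <- h[, 1L]; out$age_hpd_high <- h[, 2L]
  for (j in seq_len(npart)) {
    out[[paste0("rate_mean_", part_labels[j])]] <- vapply(rates, function(rr)
      if (length(rr[[j]])) mean(rr[[j]]) else NA_real_, numeric(1))
    hh <- t(vapply(rates, function(rr)
      if (length(rr[[j]])) hpd_interval(rr[[j]], level)
      else c(NA_real_, NA_real_), numeric(2)))
    out[[paste0("rate_hpd_low_", part_labels[j])]] <- hh[, 1L]
    out[[paste0("rate_hpd_high_", part_labels[j])]] <- hh[, 2L]
  }
  out
}

#' Sampled-ancestor summaries
#'
#' The posterior mean and HPD of the fraction of fossil samples placed as
#' ancestors, and the per-fossil posterior probability of being
#' ancestral. All values are identically zero for analyses disallowing
#' ancestors (`r = 1`), which is flagged.
#'
#' @param trees list of sampled `time_tree` objects.
#' @param level HPD level.
#' @return list with `fraction_mean`, `fraction_hpd`, `per_fossil`
#'   (named probabilities) and `any_ancestors`.
#' @export
ancestor_summary <- function(trees, level = 0.95) {
  tr1 <- trees[[1L]]
  tips <- seq_len(tr1$ntip)
  fossil <- tr1$age[tips] > 1e-9 | tr1$sampled_ancestor
  # fossil status is permanent across samples (ages vary within windows);
  # recompute per sample to be safe
  frac <- vapply(trees, function(tr) count_sampled_ancestors(tr)$fraction,
                 numeric(1))
  sa_mat <- t(vapply(trees, function(tr) tr$sampled_ancestor,
                     logical(tr1$ntip)))
  fos <- which(apply(sa_mat, 2L, any) |
                 (tr1$age[tips] > 1e-9))
  per <- colMeans(sa_mat)[fos]
  names(per) <- tr1$tip_label[fos]
  list(fraction_mean = mean(frac),
       fraction_hpd = hpd_interval(frac, level),
       per_fossil = per,
       any_ancestors = any(sa_mat))
}

#' Distribution of branch rates within a clade
#'
#' Summarizes, for one partition, the posterior-mean relative clock
#' rates of the branches inside a clade (branches identified by
#' bipartition; each branch's mean is taken over the samples containing
#' its bipartition). Returns the quartiles and flags 1.5 IQR outliers,
#' the usual boxplot summary.
#'
#' @param trees list of sampled `time_tree` objects with `rel` matrices.
#' @param clade character vector of taxon labels defining the clade.
#' @param partition partition index.
#' @param exclude taxa whose terminal branches and internal branches
#'   wholly composed of them are dropped (for instance an extant pair and
#'   their stem).
#' @param min_freq bipartitions occurring in fewer than this fraction of
#'   samples are ignored.
#' @return list with `branch_means` (named numeric, keyed by
#'   bipartition), `quartiles` (q1, median, q3), `iqr`, and `outliers`.
#' @export
clade_rate_distribution <- function(trees, clade, partition = 1L,
                                    exclude = NULL, min_freq = 0.05) {
  taxa <- trees[[1L]]$tip_label
  cl_idx <- sort(match(clade, taxa))
  if (anyNA(cl_idx)) stop("clade taxa missing from trees")
  ex_idx <- if (is.null(exclude)) integer(0) else sort(match(exclude, taxa))
  acc <- new.env(hash = TRUE, parent = emptyenv())
  ntr <- length(trees)
  for (tr in trees) {
    sets <- tip_descendant_sets(tr)
    dur <- branch_durations(tr)
    for (nd in seq_len(2L * tr$ntip - 1L)) {
      if (is.na(dur[nd]) || dur[nd] <= 0) next
      s <- sets[[nd]]
      if (!all(s %in% cl_idx)) next
      if (length(ex_idx) && all(s %in% ex_idx)) next
      k <- paste(s, collapse = ",")
      prev <- if (is.null(acc[[k]])) numeric(0) else acc[[k]]
      acc[[k]] <- c(prev, tr$rel[nd, partition])
    }
  }
  keys <- ls(acc)
  keep <- keys[vapply(keys, function(k) length(acc[[k]]), numeric(1)) / ntr >= min_freq]
  if (!length(keep)) stop("no branches found within the clade")
  means <- stats::setNames(
    vapply(keep, function(k) mean(acc[[k]]), numeric(1)), keep)
  q <- stats::quantile(means, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3L] - q[1L]
  out_hi <- means[means > q[3L] + 1.5 * iqr]
  out_lo <- means[means < q[1L] - 1.5 * iqr]
  list(branch_means = means,
       quartiles = stats::setNames(q, c("q1", "median", "q3")),
       iqr = iqr, outliers = c(out_lo, out_hi))
}
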