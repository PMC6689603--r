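#' Dated phylogenetic trees with sampled ancestors
#'
#' A `time_tree` is a rooted, binary, dated tree in which every sample
#' (extant taxon or fossil) is stored as a tip. Nodes are indexed
#' `1..ntip` for tips and `(ntip+1)..(2*ntip-1)` for internal nodes, as in
#' [ape::phylo] objects. Each node carries an age in Ma (million years
#' before present); extant tips sit at age 0 and fossil tips at their
#' sampled age. A fossil that lies *on* a lineage (a sampled ancestor) is
#' represented as a tip whose subtending branch has zero duration: its
#' attachment node has exactly the fossil's age and the flag
#' `sampled_ancestor` is set for that tip.
#'
#' @param parent integer vector of length `2*ntip - 1`; `parent[i]` is the
#'   index of the parent of node `i`, `NA` for the root.
#' @param age numeric vector of node ages in Ma, same length as `parent`.
#' @param tip_label character vector of `ntip` unique taxon labels.
#' @param sampled_ancestor logical vector of length `ntip`; `TRUE` for tips
#'   representing sampled ancestors (zero-duration terminal branch).
#' @return An object of class `time_tree`.
#' @export
time_tree <- function(parent, age, tip_label, sampled_ancestor = NULL) {
  ntip <- length(tip_label)
  if (is.null(sampled_ancestor)) sampled_ancestor <- rep(FALSE, ntip)
  tr <- structure(
    list(ntip = ntip,
         parent = as.integer(parent),
         age = as.numeric(age),
         tip_label = as.character(tip_label),
         sampled_ancestor = as.logical(sampled_ancestor)),
    class = "time_tree")
  validate_time_tree(tr)
  tr
}

#' Validate the structural invariants of a time tree
#'
#' Checks parent/child age ordering, uniqueness of tip labels, that the
#' tree is binary with a single root, and that sampled-ancestor tips have
#' zero-duration terminal branches.
#'
#' @param tree a `time_tree`.
#' @param tol numeric tolerance (Ma) for age comparisons.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_time_tree <- function(tree, tol = 1e-9) {
  ntip <- tree$ntip
  nn <- 2L * ntip - 1L
  stopifnot(length(tree$parent) == nn, length(tree$age) == nn,
            length(tree$sampled_ancestor) == ntip)
  if (anyDuplicated(tree$tip_label))
    stop("duplicate tip labels")
  root <- which(is.na(tree$parent))
  if (length(root) != 1L || root <= ntip)
    stop("tree must have exactly one internal root node")
  nchild <- tabulate(tree$parent[!is.na(tree$parent)], nbins = nn)
  if (any(nchild[seq_len(ntip)] > 0L))
    stop("tips cannot have children")
  if (any(nchild[(ntip + 1L):nn] != 2L))
    stop("internal nodes must be binary")
  prn <- tree$parent
  ok <- is.na(prn) | tree$age[prn] >= tree$age - tol
  if (!all(ok))
    stop("parent ages must be >= child ages")
  if (any(tree$age < -tol))
    stop("negative node ages")
  sa <- which(tree$sampled_ancestor)
  if (length(sa)) {
    dur <- tree$age[tree$parent[sa]] - tree$age[sa]
    if (any(dur > tol))
      stop("sampled-ancestor tips must attach with zero branch duration")
  }
  invisible(tree)
}

#' @export
print.time_tree <- function(x, ...) {
  nf <- sum(x$age[seq_len(x$ntip)] > 1e-9 | x$sampled_ancestor)
  cat(sprintf("time_tree: %d tips (%d fossil, %d sampled ancestors), root age %.2f Ma\n",
              x$ntip, nf, sum(x$sampled_ancestor), tree_root_age(x)))
  invisible(x)
}

#' Root node index of a time tree
#' @param tree a `time_tree`.
#' @return integer node index.
#' @export
tree_root <- function(tree) which(is.na(tree$parent))

#' Root age (time of most recent common ancestor) in Ma
#' @param tree a `time_tree`.
#' @return numeric age.
#' @export
tree_root_age <- function(tree) tree$age[tree_root(tree)]

#' Branch time durations
#'
#' Duration in Myr of the branch subtending each node (parent age minus
#' node age); `NA` for the root.
#'
#' @param tree a `time_tree`.
#' @return numeric vector over all nodes.
#' @export
branch_durations <- function(tree) {
  dur <- tree$age[tree$parent] - tree$age
  dur
}

# children as a 2 x n_internal matrix indexed by (node - ntip)
tree_children <- function(tree) {
  nn <- 2L * tree$ntip - 1L
  kids <- matrix(0L, 2L, tree$ntip - 1L)
  cnt <- integer(tree$ntip - 1L)
  for (i in seq_len(nn)) {
    p <- tree$parent[i]
    if (!is.na(p)) {
      j <- p - tree$ntip
      cnt[j] <- cnt[j] + 1L
      kids[cnt[j], j] <- i
    }
  }
  kids
}

# node indices in postorder (children before parents), tips included
tree_postorder <- function(tree) {
  nn <- 2L * tree$ntip - 1L
  ord <- integer(nn)
  kids <- tree_children(tree)
  stack <- tree_root(tree)
  w <- 0L
  # reverse preorder, then flip
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    w <- w + 1L
    ord[w] <- nd
    if (nd > tree$ntip) stack <- c(stack, kids[, nd - tree$ntip])
  }
  rev(ord)
}

# logical vector over nodes: is tip i (or any tip under internal node) ...
# tip_descendants: list over all nodes of the tip index sets below them
tip_descendant_sets <- function(tree) {
  nn <- 2L * tree$ntip - 1L
  sets <- vector("list", nn)
  for (i in seq_len(tree$ntip)) sets[[i]] <- i
  for (nd in tree_postorder(tree)) {
    if (nd > tree$ntip) {
      kids <- which(tree$parent == nd)
      sets[[nd]] <- sort(c(sets[[kids[1L]]], sets[[kids[2L]]]))
    }
  }
  sets
}

#' Most recent common ancestor of a set of taxa
#' @param tree a `time_tree`.
#' @param taxa character vector of tip labels.
#' @return internal node index of the MRCA.
#' @export
tree_mrca <- function(tree, taxa) {
  idx <- match(taxa, tree$tip_label)
  if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  # walk up from the oldest member until all are covered
  anc <- function(i) {
    path <- i
    while (!is.na(tree$parent[i])) { i <- tree$parent[i]; path <- c(path, i) }
    path
  }
  p <- anc(idx[1L])
  for (j in idx[-1L]) {
    pj <- anc(j)
    p <- p[p %in% pj]
  }
  p[1L]
}

#' Test monophyly of a taxon set
#'
#' A set is monophyletic when the tip set descending from its MRCA is
#' exactly the queried set. Sampled-ancestor tips count like any other tip.
#'
#' @param tree a `time_tree`.
#' @param taxa character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  idx <- sort(match(taxa, tree$tip_label))
  if (anyNA(idx)) stop("unknown taxa in constraint")
  m <- tree_mrca(tree, taxa)
  if (m <= tree$ntip) return(length(idx) == 1L)
  below <- tip_descendant_sets(tree)[[m]]
  identical(as.integer(below), as.integer(idx))
}

#' Convert a time tree to an ape "phylo" object
#'
#' Branch lengths are time durations in Myr. Sampled-ancestor tips become
#' zero-length terminal edges.
#'
#' @param x a `time_tree`.
#' @param ... unused.
#' @return an [ape::phylo] object.
#' @exportS3Method ape::as.phylo
as.phylo.time_tree <- function(x, ...) {
  nn <- 2L * x$ntip - 1L
  child <- which(!is.na(x$parent))
  edge <- cbind(x$parent[child], child)
  len <- x$age[x$parent[child]] - x$age[child]
  phy <- structure(list(edge = edge, edge.length = pmax(len, 0),
                        tip.label = x$tip_label, Nnode = x$ntip - 1L),
                   class = "phylo", order = NULL)
  ape::reorder.phylo(phy, "cladewise")
}

#' Build a time tree from an ape "phylo" object with dated tips
#'
#' Node ages are reconstructed from edge lengths (in Myr), anchoring the
#' deepest leaf-path at `youngest_age` (default: the youngest tip sits at
#' age 0). Terminal edges of zero length are flagged as sampled ancestors
#' when `detect_sa` is `TRUE`.
#'
#' @param phy an [ape::phylo] object, rooted and binary.
#' @param youngest_age age in Ma of the most recent tip.
#' @param detect_sa flag zero-length terminal branches as sampled ancestors.
#' @return a `time_tree`.
#' @export
time_tree_from_phylo <- function(phy, youngest_age = 0, detect_sa = TRUE) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  if (phy$Nnode != ntip - 1L) stop("tree must be binary and rooted")
  depth <- numeric(nn)
  parent <- rep(NA_integer_, nn)
  for (e in seq_len(nrow(phy$edge))) {
    parent[phy$edge[e, 2L]] <- phy$edge[e, 1L]
  }
  # depths by preorder
  po <- rev(postorder_from_parent(parent, ntip))
  for (nd in po) {
    p <- parent[nd]
    if (!is.na(p)) {
      e <- which(phy$edge[, 2L] == nd)
      depth[nd] <- depth[p] + phy$edge.length[e]
    }
  }
  age <- max(depth) - depth + youngest_age
  sa <- rep(FALSE, ntip)
  if (detect_sa) {
    term <- match(seq_len(ntip), phy$edge[, 2L])
    sa <- phy$edge.length[term] <= 1e-12
  }
  time_tree(parent, age, phy$tip.label, sa)
}

postorder_from_parent <- function(parent, ntip) {
  nn <- length(parent)
  root <- which(is.na(parent))
  kids <- vector("list", nn)
  for (i in seq_len(nn)) {
    p <- parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  ord <- integer(nn); w <- 0L
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    w <- w + 1L; ord[w] <- nd
    stack <- c(stack, kids[[nd]])
  }
  rev(ord)
}

#' Serialize a time tree as Newick
#'
#' Branch lengths are time durations in Myr; sampled-ancestor tips are
#' annotated with a `[&sa=1]` metadata comment when `annotate` is `TRUE`.
#'
#' @param tree a `time_tree`.
#' @param annotate include sampled-ancestor metadata comments.
#' @param digits branch-length precision.
#' @return a single Newick string (with trailing semicolon).
#' @export
write_tree_newick <- function(tree, annotate = TRUE, digits = 8) {
  kids <- tree_children(tree)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(nd) {
    if (nd <= tree$ntip) {
      lab <- tree$tip_label[nd]
      tag <- if (annotate && tree$sampled_ancestor[nd]) "[&sa=1]" else ""
      paste0(lab, tag, ":", fmt(tree$age[tree$parent[nd]] - tree$age[nd]))
    } else {
      s <- paste0("(", rec(kids[1L, nd - tree$ntip]), ",",
                  rec(kids[2L, nd - tree$ntip]), ")")
      p <- tree$parent[nd]
      if (is.na(p)) paste0(s, ";")
      else paste0(s, ":", fmt(tree$age[p] - tree$age[nd]))
    }
  }
  rec(tree_root(tree))
}
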