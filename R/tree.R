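#' @importFrom ape read.tree write.tree
NULL

# ---------------------------------------------------------------------------
# lineage_tree: a phylo-backed tree whose branch-length slot carries per-edge
# mutation probabilities (the IS model's p(e)). A terminal edge with
# probability exactly 0 is "fake": it attaches a sampled cell that is
# identical to the ancestral vertex it hangs from. The root.edge slot carries
# stem mass created by restriction (a mutation there puts every retained cell
# in state 1) and `null.prob` carries the mass of source edges invisible in
# the retained cell set (the all-zero pattern), so that
# sum(edge) + stem + null = 1 for every sub-model.
# Optional exact bookkeeping: `prob.num` (per-edge integer numerators),
# `root.num`, `null.num` over the common denominator `prob.den`.
# ---------------------------------------------------------------------------

.n_tips <- function(tree) length(tree$tip.label)

.root_node <- function(tree) {
  cand <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  if (length(cand) != 1L) stop("tree has no unique root vertex")
  cand
}

.has_probs <- function(tree) !is.null(tree$edge.length)

.stem_prob <- function(tree) if (is.null(tree$root.edge)) 0 else tree$root.edge

.null_prob <- function(tree) if (is.null(tree$null.prob)) 0 else tree$null.prob

# breadth-first node order from the root (parents before children)
.topdown_nodes <- function(tree) {
  nn <- .n_tips(tree) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  out <- integer(nn)
  out[1] <- .root_node(tree)
  head <- 1L; tail <- 1L
  while (head <= tail) {
    for (ch in kids[[out[head]]]) {
      tail <- tail + 1L
      out[tail] <- ch
    }
    head <- head + 1L
  }
  out[seq_len(tail)]
}

# edge order in which every child edge precedes its parent edge
.bottomup_edges <- function(tree) {
  ord <- .topdown_nodes(tree)
  rank <- integer(max(ord))
  rank[ord] <- seq_along(ord)
  rev(order(rank[tree$edge[, 1]]))
}

# per-edge bitmask of subset members below the edge; pos[i] gives the bit
# position (1-based) of tip i, or 0 if tip i is outside the subset
.edge_masks <- function(tree, pos) {
  nn <- .n_tips(tree) + tree$Nnode
  mask <- integer(nn)
  tips <- which(pos > 0L)
  mask[tips] <- bitwShiftL(1L, pos[tips] - 1L)
  out <- integer(nrow(tree$edge))
  for (i in .bottomup_edges(tree)) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    out[i] <- mask[ch]
    mask[p] <- bitwOr(mask[p], mask[ch])
  }
  out
}

# per-edge integer vectors of tip indices below the edge
.edge_tipsets <- function(tree) {
  nn <- .n_tips(tree) + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(.n_tips(tree))) below[[i]] <- i
  out <- vector("list", nrow(tree$edge))
  for (i in .bottomup_edges(tree)) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    out[[i]] <- below[[ch]]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  out
}

.popcount <- function(x) {
  r <- integer(length(x))
  for (s in 0:29) r <- r + bitwAnd(bitwShiftR(x, s), 1L)
  r
}

# build a phylo from edges given as arbitrary integer vertex ids;
# pp, cc: parent/child ids per edge; labels: named chr, names = tip ids;
# len: optional per-edge values kept in edge.length (aligned with pp)
.phylo_build <- function(pp, cc, labels, len = NULL) {
  tip_ids <- as.integer(names(labels))
  root_id <- setdiff(unique(pp), cc)
  if (length(root_id) != 1L) stop("edge list has no unique root")
  n <- length(tip_ids)
  # BFS from root for stable internal numbering
  ordered <- root_id
  head <- 1L
  while (head <= length(ordered)) {
    ch <- cc[pp == ordered[head]]
    ordered <- c(ordered, ch[!(ch %in% tip_ids)])
    head <- head + 1L
  }
  id2num <- integer(0)
  id2num[as.character(tip_ids)] <- seq_len(n)
  id2num[as.character(ordered)] <- n + seq_along(ordered)
  phy <- list(edge = cbind(unname(id2num[as.character(pp)]),
                           unname(id2num[as.character(cc)])),
              Nnode = length(ordered),
              tip.label = unname(labels))
  storage.mode(phy$edge) <- "integer"
  if (!is.null(len)) phy$edge.length <- len
  class(phy) <- "phylo"
  phy
}

.new_lineage_tree <- function(phy, rooted = TRUE, root.prob = NULL,
                              null.prob = NULL, prob.num = NULL,
                              prob.den = NULL, root.num = NULL,
                              null.num = NULL) {
  tree <- phy
  tree$rooted <- isTRUE(rooted)
  if (!is.null(root.prob) && root.prob != 0) tree$root.edge <- root.prob
  if (!is.null(null.prob) && null.prob != 0) tree$null.prob <- null.prob
  if (!is.null(prob.den)) {
    tree$prob.num <- prob.num
    tree$prob.den <- prob.den
    tree$root.num <- if (is.null(root.num)) 0 else root.num
    tree$null.num <- if (is.null(null.num)) 0 else null.num
  }
  class(tree) <- c("lineage_tree", "phylo")
  tree
}

#' Is a lineage tree rooted?
#' @param tree a `lineage_tree`.
#' @export
is_rooted_lineage <- function(tree) isTRUE(tree$rooted)

#' Which edges are fake?
#'
#' Fake edges are terminal edges with mutation probability exactly 0; they
#' attach sampled cells that are identical to an ancestral (internal) cell.
#' @param tree a `lineage_tree` with probabilities.
#' @return logical vector over edges.
#' @export
fake_edges <- function(tree) {
  if (!.has_probs(tree)) stop("tree carries no probabilities")
  tree$edge[, 2] <= .n_tips(tree) & tree$edge.length == 0
}

#' Validate a lineage tree
#'
#' Checks the structural invariants: unique non-empty leaf labels, a unique
#' root vertex, no degree-2 vertices except possibly the root of a rooted
#' tree, and (when probabilities are present) per-edge probabilities in
#' \[0,1\] summing to 1 together with the stem and all-zero masses, strictly
#' positive probability on internal edges, and fake edges (probability 0)
#' only on terminal edges.
#'
#' @param tree a `lineage_tree`.
#' @param tol numeric tolerance on the sum-to-one check.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_lineage_tree <- function(tree, tol = 1e-9) {
  lab <- tree$tip.label
  if (any(is.na(lab)) || any(lab == "")) stop("empty leaf label")
  if (anyDuplicated(lab)) {
    stop("duplicate leaf labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  n <- .n_tips(tree)
  root <- .root_node(tree)
  if (anyDuplicated(tree$edge[, 2])) stop("vertex with in-degree > 1")
  deg <- tabulate(c(tree$edge[, 1], tree$edge[, 2]), nbins = n + tree$Nnode)
  bad <- which(deg == 2)
  bad <- setdiff(bad, root)
  if (n > 2 && length(bad) > 0) stop("unsuppressed degree-2 vertex")
  if (!isTRUE(tree$rooted) && n > 2 && deg[root] == 2) {
    stop("unrooted tree stored with a degree-2 basal vertex")
  }
  if (.has_probs(tree)) {
    p <- tree$edge.length
    if (any(p < 0) || any(p > 1)) stop("edge probabilities outside [0, 1]")
    tot <- sum(p) + .stem_prob(tree) + .null_prob(tree)
    if (abs(tot - 1) > tol) {
      stop(sprintf("edge probabilities sum to %.12g, not 1", tot))
    }
    terminal <- tree$edge[, 2] <= n
    if (any(!terminal & p <= 0)) stop("internal edge with zero probability")
  }
  invisible(tree)
}

#' Read a lineage tree from Newick
#'
#' Per-edge mutation probabilities ride in the Newick branch-length slot; a
#' fake edge is a terminal edge with probability exactly 0. A trailing root
#' edge length is kept as stem mass.
#'
#' @param text Newick string; exactly one of `text`/`file` must be given.
#' @param file path to a Newick file.
#' @param rooted logical; interpret the tree as rooted (default `TRUE`).
#' @param probabilities `"auto"` keeps branch lengths as probabilities when
#'   present, `"required"` errors when absent, `"none"` discards them.
#' @param tol tolerance for the probabilities-sum-to-one check.
#' @return a `lineage_tree`.
#' @examples
#' read_lineage_tree("((A:0.25,B:0.25):0.25,C:0.25);")
#' read_lineage_tree("((A,B),(C,D));", rooted = FALSE)
#' @export
read_lineage_tree <- function(text = NULL, file = NULL, rooted = TRUE,
                              probabilities = c("auto", "required", "none"),
                              tol = 1e-9) {
  probabilities <- match.arg(probabilities)
  phy <- if (!is.null(text)) ape::read.tree(text = text)
         else ape::read.tree(file = file)
  if (is.null(phy)) stop("malformed Newick input")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single Newick tree")
    phy <- phy[[1]]
  }
  has_len <- !is.null(phy$edge.length)
  if (probabilities == "required" && !has_len) {
    stop("edge probabilities requested but absent from Newick input")
  }
  if (probabilities == "none" || !has_len) phy$edge.length <- NULL
  root.prob <- NULL
  if (!is.null(phy$root.edge)) {
    if (!is.null(phy$edge.length)) root.prob <- phy$root.edge
    phy$root.edge <- NULL
  }
  tree <- .new_lineage_tree(phy, rooted = TRUE, root.prob = root.prob)
  if (!rooted) tree <- unroot_lineage(tree)
  validate_lineage_tree(tree, tol = tol)
  tree
}

#' Write a lineage tree as Newick
#' @param tree a `lineage_tree`.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for probabilities.
#' @export
write_lineage_tree <- function(tree, file = NULL, digits = 12) {
  phy <- tree
  class(phy) <- "phylo"
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %s, %d leaves, %d edges%s\n",
              if (isTRUE(x$rooted)) "rooted" else "unrooted",
              .n_tips(x), nrow(x$edge),
              if (.has_probs(x)) ", with mutation probabilities" else ""))
  if (.n_tips(x) <= 12) cat("  ", write_lineage_tree(x), "\n", sep = "")
  invisible(x)
}

.tip_index <- function(tree, labels) {
  idx <- match(labels, tree$tip.label)
  if (anyNA(idx)) {
    stop("labels absent from tree: ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

# ---------------------------------------------------------------------------
# restriction
# ---------------------------------------------------------------------------

# Build a rooted tree from a laminar family of clade bitmasks over `labels`.
# Optionally attach one extra tip directly at the root (used to re-assemble
# unrooted restrictions around a reference leaf). Returns the phylo and the
# numerators re-ordered to match its edge rows.
.tree_from_clades <- function(masks, probs, labels, nums = NULL,
                              extra_tip = NULL, extra_prob = 0,
                              extra_num = 0) {
  m <- length(labels)
  singles <- bitwShiftL(1L, seq_len(m) - 1L)
  add <- !(singles %in% masks)
  if (any(add)) {
    masks <- c(masks, singles[add])
    probs <- c(probs, rep(0, sum(add)))
    if (!is.null(nums)) nums <- c(nums, rep(0, sum(add)))
  }
  sz <- .popcount(masks)
  ord <- order(-sz, masks)
  masks <- masks[ord]; probs <- probs[ord]; sz <- sz[ord]
  if (!is.null(nums)) nums <- nums[ord]
  k <- length(masks)
  root_id <- k + 1L
  parent <- rep(root_id, k)
  for (i in seq_len(k)) {
    if (i > 1) {
      sup <- which(sz[seq_len(i - 1)] > sz[i] &
                     bitwAnd(masks[seq_len(i - 1)], masks[i]) == masks[i])
      if (length(sup) > 0) parent[i] <- sup[which.min(sz[sup])]
    }
  }
  is_tip <- sz == 1L
  ids <- seq_len(k)
  tip_bit <- as.integer(round(log2(masks[is_tip]))) + 1L
  labels_named <- labels[tip_bit]
  names(labels_named) <- ids[is_tip]
  pp <- parent; cc <- ids
  if (!is.null(extra_tip)) {
    extra_id <- k + 2L
    pp <- c(pp, root_id)
    cc <- c(cc, extra_id)
    probs <- c(probs, extra_prob)
    if (!is.null(nums)) nums <- c(nums, extra_num)
    labels_named <- c(labels_named, structure(extra_tip, names = extra_id))
  }
  phy <- .phylo_build(pp, cc, labels_named, len = probs)
  list(phy = phy, nums = nums)
}

#' Restrict a lineage tree to a subset of its leaves
#'
#' Produces the sub-model on label set `labels`: deleted leaves are pruned
#' and suppressed degree-2 vertices merge their incident edges with
#' probabilities added. For a rooted tree the result stays rooted; the
#' probability mass of edges above the MRCA of the retained set (a mutation
#' there puts every retained cell in state 1) moves to a root-stem edge, and
#' the mass of edges invisible in the subset (the all-zero pattern) is kept
#' in `null.prob`, so the sub-model's total mass is still 1. Exact integer
#' numerators are propagated when the source tree carries them.
#'
#' @param tree a `lineage_tree`.
#' @param labels leaf labels to keep (at least 2, at most 30).
#' @return the restricted `lineage_tree`.
#' @export
restrict_tree <- function(tree, labels) {
  labels <- as.character(labels)
  if (length(labels) < 2) stop("restriction needs at least two labels")
  if (length(labels) > 30) stop("restriction capped at 30 labels")
  if (anyDuplicated(labels)) stop("duplicate labels in restriction set")
  tips <- .tip_index(tree, labels)
  n <- .n_tips(tree)
  pos <- integer(n)
  pos[tips] <- seq_along(tips)
  masks <- .edge_masks(tree, pos)
  full <- bitwShiftL(1L, length(labels)) - 1L
  probs <- if (.has_probs(tree)) tree$edge.length
           else rep(NA_real_, nrow(tree$edge))
  nums <- tree$prob.num
  if (isTRUE(tree$rooted)) {
    .restrict_rooted(tree, masks, probs, nums, labels, full)
  } else {
    .restrict_unrooted(tree, masks, probs, nums, labels, full)
  }
}

.aggregate_masks <- function(masks, probs, nums, keep) {
  km <- masks[keep]
  um <- unique(km)
  grp <- match(km, um)
  has_p <- !anyNA(probs)
  p <- if (has_p) as.vector(tapply(probs[keep], grp, sum))
       else rep(0, length(um))
  nm <- if (!is.null(nums)) as.vector(tapply(nums[keep], grp, sum)) else NULL
  list(masks = um, probs = p, nums = nm)
}

.restrict_rooted <- function(tree, masks, probs, nums, labels, full) {
  has_p <- !anyNA(probs)
  stem_idx <- masks == full
  null_idx <- masks == 0L
  keep <- !stem_idx & !null_idx
  agg <- .aggregate_masks(masks, probs, nums, keep)
  built <- .tree_from_clades(agg$masks, agg$probs, labels, nums = agg$nums)
  stem <- if (has_p) sum(probs[stem_idx]) + .stem_prob(tree) else 0
  nul <- if (has_p) sum(probs[null_idx]) + .null_prob(tree) else 0
  exact <- !is.null(nums)
  phy <- built$phy
  if (!has_p) phy$edge.length <- NULL
  .new_lineage_tree(phy, rooted = TRUE,
                    root.prob = if (has_p) stem else NULL,
                    null.prob = if (has_p) nul else NULL,
                    prob.num = if (exact) built$nums else NULL,
                    prob.den = if (exact) tree$prob.den else NULL,
                    root.num = if (exact) {
                      sum(nums[stem_idx]) +
                        (if (is.null(tree$root.num)) 0 else tree$root.num)
                    } else NULL,
                    null.num = if (exact) {
                      sum(nums[null_idx]) +
                        (if (is.null(tree$null.num)) 0 else tree$null.num)
                    } else NULL)
}

.restrict_unrooted <- function(tree, masks, probs, nums, labels, full) {
  has_p <- !anyNA(probs)
  # canonical side: the side NOT containing the first retained label
  bit1 <- 1L
  side <- ifelse(bitwAnd(masks, bit1) > 0L,
                 bitwAnd(bitwNot(masks), full), masks)
  null_idx <- side == 0L
  ref_side <- bitwAnd(bitwNot(bit1), full)  # the split {r} | rest
  r_idx <- side == ref_side
  keep <- !null_idx & !r_idx
  agg <- .aggregate_masks(bitwShiftR(side, 1L), probs, nums, keep)
  built <- .tree_from_clades(agg$masks, agg$probs, labels[-1],
                             nums = agg$nums,
                             extra_tip = labels[1],
                             extra_prob = if (has_p) sum(probs[r_idx]) else 0,
                             extra_num = if (!is.null(nums)) sum(nums[r_idx]) else 0)
  nul <- if (has_p) {
    sum(probs[null_idx]) + .null_prob(tree) + .stem_prob(tree)
  } else 0
  exact <- !is.null(nums)
  phy <- built$phy
  if (!has_p) phy$edge.length <- NULL
  .new_lineage_tree(phy, rooted = FALSE,
                    null.prob = if (has_p) nul else NULL,
                    prob.num = if (exact) built$nums else NULL,
                    prob.den = if (exact) tree$prob.den else NULL,
                    root.num = if (exact) 0 else NULL,
                    null.num = if (exact) {
                      sum(nums[null_idx]) +
                        (if (is.null(tree$null.num)) 0 else tree$null.num) +
                        (if (is.null(tree$root.num)) 0 else tree$root.num)
                    } else NULL)
}

# ---------------------------------------------------------------------------
# unrooting / rooting
# ---------------------------------------------------------------------------

#' Forget the root of a lineage tree
#'
#' Returns the unrooted version: a degree-2 basal vertex is suppressed (its
#' two incident edges merge, probabilities added) and any root-stem mass is
#' folded into `null.prob` (an all-ones mutation is uninformative once the
#' root is forgotten).
#'
#' @param tree a `lineage_tree`.
#' @return an unrooted `lineage_tree`.
#' @export
unroot_lineage <- function(tree) {
  if (!isTRUE(tree$rooted) && is.null(tree$root.edge)) {
    tree$rooted <- FALSE
    return(tree)
  }
  n <- .n_tips(tree)
  root <- .root_node(tree)
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  pp <- tree$edge[, 1]; cc <- tree$edge[, 2]
  probs <- tree$edge.length
  nums <- tree$prob.num
  if (length(kids) == 2 && n > 2) {
    # suppress the basal vertex: keep the internal child as new basal vertex
    i1 <- which(pp == root & cc == kids[1])
    i2 <- which(pp == root & cc == kids[2])
    anchor <- if (kids[1] > n) kids[1] else kids[2]
    if (anchor <= n) stop("cannot unroot a 2-leaf tree")
    drop <- if (anchor == kids[1]) i1 else i2
    keep <- if (anchor == kids[1]) i2 else i1
    if (!is.null(probs)) probs[keep] <- probs[keep] + probs[drop]
    if (!is.null(nums)) nums[keep] <- nums[keep] + nums[drop]
    pp[keep] <- anchor
    pp <- pp[-drop]; cc <- cc[-drop]
    if (!is.null(probs)) probs <- probs[-drop]
    if (!is.null(nums)) nums <- nums[-drop]
  }
  labels_named <- structure(tree$tip.label, names = seq_len(n))
  phy <- .phylo_build(pp, cc, labels_named, len = probs)
  nul <- if (!is.null(probs)) .null_prob(tree) + .stem_prob(tree) else NULL
  exact <- !is.null(nums)
  .new_lineage_tree(phy, rooted = FALSE, null.prob = nul,
                    prob.num = if (exact) nums else NULL,
                    prob.den = if (exact) tree$prob.den else NULL,
                    null.num = if (exact) {
                      (if (is.null(tree$null.num)) 0 else tree$null.num) +
                        (if (is.null(tree$root.num)) 0 else tree$root.num)
                    } else NULL)
}

#' Root a tree on the terminal edge of a designated cell
#'
#' Topology-only rerooting used to orient estimates at the healthy cell:
#' a new root vertex is placed on the terminal edge of `label`. Mutation
#' probabilities, if any, are discarded (the operation serves estimated
#' trees, which carry none).
#'
#' @param tree a `lineage_tree`.
#' @param label the leaf (healthy cell) to root at.
#' @return a rooted `lineage_tree` without probabilities.
#' @export
root_at_cell <- function(tree, label) {
  tip <- .tip_index(tree, label)
  adj <- .adjacency(tree)
  v <- adj[[tip]]
  if (length(v) != 1L) stop("leaf with more than one neighbor")
  new_root <- .n_tips(tree) + tree$Nnode + 1L
  # orient all edges away from new_root by DFS over the adjacency
  pp <- integer(0); cc <- integer(0)
  stack_node <- c(tip, v)
  stack_par <- c(new_root, new_root)
  while (length(stack_node) > 0) {
    i <- length(stack_node)
    node <- stack_node[i]; par <- stack_par[i]
    stack_node <- stack_node[-i]; stack_par <- stack_par[-i]
    pp <- c(pp, par); cc <- c(cc, node)
    nb <- setdiff(adj[[node]], par)
    if (par == new_root) nb <- setdiff(nb, c(tip, v))
    if (node > .n_tips(tree) || node == tip) {
      for (w in nb) {
        stack_node <- c(stack_node, w)
        stack_par <- c(stack_par, node)
      }
    }
  }
  labels_named <- structure(tree$tip.label, names = seq_len(.n_tips(tree)))
  phy <- .phylo_build(pp, cc, labels_named)
  .new_lineage_tree(phy, rooted = TRUE)
}

# undirected adjacency lists over node numbers
.adjacency <- function(tree) {
  nn <- .n_tips(tree) + tree$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    adj[[p]] <- c(adj[[p]], ch)
    adj[[ch]] <- c(adj[[ch]], p)
  }
  adj
}

# ---------------------------------------------------------------------------
# canonical forms, splits, encodings
# ---------------------------------------------------------------------------

#' Canonical Newick string of a tree topology
#'
#' A deterministic topology key: children are ordered lexicographically by
#' their canonical substring, and unrooted trees are keyed from a virtual
#' root on the terminal edge of the lexicographically smallest label.
#' Degree-2 vertices are suppressed. Probabilities are omitted.
#'
#' @param tree a `lineage_tree`.
#' @return a Newick string; equal strings iff equal (un)rooted topologies.
#' @export
canonical_newick <- function(tree) {
  adj <- .adjacency(tree)
  n <- .n_tips(tree)
  lab <- tree$tip.label
  sub <- function(node, parent) {
    if (node <= n) return(lab[node])
    ch <- setdiff(adj[[node]], parent)
    if (length(ch) == 1L) return(sub(ch, node))
    parts <- sort(vapply(ch, sub, "", node), method = "radix")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  if (isTRUE(tree$rooted)) {
    root <- .root_node(tree)
    return(paste0(sub(root, 0L), ";"))
  }
  r <- which(lab == sort(lab, method = "radix")[1])
  v <- adj[[r]]
  paste0("(", lab[r], ",", sub(v, r), ");")
}

# canonical internal split masks over sorted labels; side not containing the
# lexicographically smallest label
.split_masks <- function(tree) {
  n <- .n_tips(tree)
  if (n > 30) stop("split encodings capped at 30 leaves")
  ord <- order(tree$tip.label, method = "radix")
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  masks <- .edge_masks(tree, pos)
  full <- bitwShiftL(1L, n) - 1L
  side <- ifelse(bitwAnd(masks, 1L) > 0L, bitwAnd(bitwNot(masks), full), masks)
  pc <- .popcount(side)
  internal <- side[pc >= 2L & pc <= n - 2L]
  unique(internal)
}

# sorted label universe helper
.sorted_labels <- function(tree) sort(tree$tip.label, method = "radix")

#' Bipartition encoding of a tree
#'
#' One bipartition per edge of the unrooted view, in canonical orientation
#' (the side holding the lexicographically smallest label printed first).
#' A bipartition is flagged internal when both sides have at least two
#' labels.
#'
#' @param tree a `lineage_tree`.
#' @return a data.frame with columns `side1`, `side2` (comma-joined labels)
#'   and `internal`.
#' @export
bipartition_set <- function(tree) {
  u <- if (isTRUE(tree$rooted)) unroot_lineage(tree) else tree
  n <- .n_tips(u)
  labs <- .sorted_labels(u)
  ord <- order(u$tip.label, method = "radix")
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  masks <- .edge_masks(u, pos)
  full <- bitwShiftL(1L, n) - 1L
  side <- ifelse(bitwAnd(masks, 1L) > 0L, bitwAnd(bitwNot(masks), full), masks)
  side <- unique(side[side != 0L & side != full])
  pc <- .popcount(side)
  to_labels <- function(m) paste(labs[bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L) > 0],
                                 collapse = ",")
  other <- bitwAnd(bitwNot(side), full)
  data.frame(side1 = vapply(other, to_labels, ""),
             side2 = vapply(side, to_labels, ""),
             internal = pc >= 2L & pc <= n - 2L,
             stringsAsFactors = FALSE)
}

.quartet_name <- function(s4, topo) {
  # s4 sorted labels; topo 1: 12|34, 2: 13|24, 3: 14|23
  pair <- switch(topo, c(1, 2), c(1, 3), c(1, 4))
  rest <- setdiff(1:4, pair)
  paste0(s4[pair[1]], ",", s4[pair[2]], "|", s4[rest[1]], ",", s4[rest[2]])
}

.triplet_name <- function(s3, out) {
  rest <- setdiff(1:3, out)
  paste0(s3[out], "|", s3[rest[1]], ",", s3[rest[2]])
}

# topology index (1..3, NA = star) of a 4-subset given split masks and the
# bit positions of the subset members (ascending label order)
.quartet_topo_from_masks <- function(split_masks, bits4) {
  b <- bits4
  for (m in split_masks) {
    inb <- bitwAnd(m, b) == b
    x <- c(bitwAnd(m, b[1]) > 0, bitwAnd(m, b[2]) > 0,
           bitwAnd(m, b[3]) > 0, bitwAnd(m, b[4]) > 0)
    s <- sum(x)
    if (s == 2L) {
      if (x[1]) {
        if (x[2]) return(1L)
        if (x[3]) return(2L)
        return(3L)
      } else {
        if (x[2]) return(if (x[3]) 3L else 2L)  # {2,3} -> q3? see below
      }
    }
  }
  NA_integer_
}

#' Which quartet does a tree display on four labels?
#'
#' @param tree a `lineage_tree` (rooted trees are compared unrooted).
#' @param labels four leaf labels.
#' @return list with `topology` (1, 2, 3 indexed against the sorted labels,
#'   or `NA` for a star) and `name` (canonical `a,b|c,d` string or `NA`).
#' @export
displayed_quartet <- function(tree, labels) {
  labels <- sort(as.character(labels), method = "radix")
  if (length(labels) != 4) stop("need exactly four labels")
  tips <- .tip_index(tree, labels)
  pos <- integer(.n_tips(tree))
  pos[tips] <- seq_along(tips)
  masks <- .edge_masks(tree, pos)
  topo <- NA_integer_
  for (m in masks) {
    pc <- .popcount(m)
    if (pc == 2L) {
      topo <- if (bitwAnd(m, 1L) > 0L) {
        if (bitwAnd(m, 2L) > 0L) 1L else if (bitwAnd(m, 4L) > 0L) 2L else 3L
      } else {
        if (bitwAnd(m, 2L) > 0L) {
          if (bitwAnd(m, 4L) > 0L) 3L else 2L
        } else 1L
      }
      break
    }
  }
  list(topology = topo,
       name = if (is.na(topo)) NA_character_ else .quartet_name(labels, topo))
}

#' Which triplet does a rooted tree display on three labels?
#'
#' @param tree a rooted `lineage_tree`.
#' @param labels three leaf labels.
#' @return list with `outgroup` (1, 2 or 3 indexed against the sorted
#'   labels, or `NA` when the restriction is non-binary) and `name`.
#' @export
displayed_triplet <- function(tree, labels) {
  if (!isTRUE(tree$rooted)) stop("triplets are defined on rooted trees")
  labels <- sort(as.character(labels), method = "radix")
  if (length(labels) != 3) stop("need exactly three labels")
  tips <- .tip_index(tree, labels)
  pos <- integer(.n_tips(tree))
  pos[tips] <- seq_along(tips)
  masks <- .edge_masks(tree, pos)
  out <- NA_integer_
  for (m in masks) {
    if (.popcount(m) == 2L) {
      out <- if (bitwAnd(m, 1L) == 0L) 1L else if (bitwAnd(m, 2L) == 0L) 2L else 3L
      break
    }
  }
  list(outgroup = out,
       name = if (is.na(out)) NA_character_ else .triplet_name(labels, out))
}

#' Quartet encoding of a tree
#'
#' The set of quartets displayed by the unrooted view of `tree`: one quartet
#' for every 4-subset whose restriction is binary; subsets restricting to
#' stars contribute nothing.
#'
#' @param tree a `lineage_tree` with at least 4 leaves.
#' @return character vector of canonical `a,b|c,d` quartet names, sorted.
#' @export
quartet_encoding <- function(tree) {
  if (.n_tips(tree) < 4) stop("quartet encoding needs at least 4 leaves")
  u <- if (isTRUE(tree$rooted)) unroot_lineage(tree) else tree
  labs <- .sorted_labels(u)
  n <- length(labs)
  masks <- .split_masks(u)
  out <- character(0)
  for (m in masks) {
    ones <- which(bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L) > 0)
    zeros <- setdiff(seq_len(n), ones)
    for (i1 in seq_along(ones)) for (i2 in seq_len(i1 - 1L)) {
      a <- ones[i2]; b <- ones[i1]
      for (j1 in seq_along(zeros)) for (j2 in seq_len(j1 - 1L)) {
        c_ <- zeros[j2]; d_ <- zeros[j1]
        s4 <- sort(c(labs[a], labs[b], labs[c_], labs[d_]), method = "radix")
        pr <- sort(c(labs[a], labs[b]), method = "radix")
        topo <- if (all(pr == s4[1:2])) 1L
                else if (all(pr == s4[c(1, 3)])) 2L
                else if (all(pr == s4[c(1, 4)])) 3L
                else if (all(pr == s4[3:4])) 1L
                else if (all(pr == s4[c(2, 4)])) 2L
                else 3L
        out <- c(out, .quartet_name(s4, topo))
      }
    }
  }
  sort(unique(out), method = "radix")
}

#' Triplet encoding of a rooted tree
#'
#' One triplet for every 3-subset whose rooted restriction is binary.
#'
#' @param tree a rooted `lineage_tree` with at least 3 leaves.
#' @return character vector of canonical `out|a,b` triplet names, sorted.
#' @export
triplet_encoding <- function(tree) {
  if (!isTRUE(tree$rooted)) stop("triplet encoding needs a rooted tree")
  if (.n_tips(tree) < 3) stop("triplet encoding needs at least 3 leaves")
  labs <- .sorted_labels(tree)
  subsets <- utils::combn(labs, 3)
  out <- character(0)
  for (j in seq_len(ncol(subsets))) {
    d <- displayed_triplet(tree, subsets[, j])
    if (!is.na(d$outgroup)) out <- c(out, d$name)
  }
  sort(unique(out), method = "radix")
}

#' Is one tree a refinement of another?
#'
#' `TRUE` iff every internal bipartition of `tree` is an internal
#' bipartition of `refinement` (so `refinement` can be obtained from `tree`
#' by resolving polytomies). Both trees are compared unrooted.
#'
#' @param refinement,tree `lineage_tree`s on the same label set.
#' @export
is_refinement <- function(refinement, tree) {
  if (!setequal(refinement$tip.label, tree$tip.label)) {
    stop("trees are on different label sets")
  }
  b <- .split_masks(if (isTRUE(refinement$rooted)) unroot_lineage(refinement) else refinement)
  t <- .split_masks(if (isTRUE(tree$rooted)) unroot_lineage(tree) else tree)
  all(t %in% b)
}

#' False negative / false positive branch error
#'
#' Compares internal bipartitions of the unrooted views: a false negative
#' branch is an internal bipartition of `reference` missing from `estimate`;
#' a false positive branch is the converse. FN error is the metric of
#' choice for highly unresolved reference trees: it is 0 exactly when the
#' estimate refines the reference.
#'
#' @param reference,estimate `lineage_tree`s on the same label set.
#' @return list with integer components `fn` and `fp`.
#' @export
tree_error <- function(reference, estimate) {
  if (!setequal(reference$tip.label, estimate$tip.label)) {
    stop("trees are on different label sets")
  }
  r <- .split_masks(if (isTRUE(reference$rooted)) unroot_lineage(reference) else reference)
  e <- .split_masks(if (isTRUE(estimate$rooted)) unroot_lineage(estimate) else estimate)
  list(fn = sum(!(r %in% e)), fp = sum(!(e %in% r)))
}

# ---------------------------------------------------------------------------
# enumeration of binary topologies
# ---------------------------------------------------------------------------

# all unrooted binary topologies on tips 1..n as 2-column edge matrices;
# internal vertex ids are n+1 .. 2n-2; deterministic order via the classic
# leaf-insertion recursion (tip j is inserted into every edge in turn)
.enum_edgelists <- function(n) {
  base <- cbind(c(n + 1L, n + 1L, n + 1L), c(1L, 2L, 3L))
  trees <- list(base)
  if (n == 3L) return(trees)
  for (j in 4L:n) {
    newv <- n + j - 2L
    nxt <- vector("list", length(trees) * (2L * (j - 1L) - 3L))
    k <- 0L
    for (E in trees) {
      for (i in seq_len(nrow(E))) {
        k <- k + 1L
        nxt[[k]] <- rbind(E[-i, , drop = FALSE],
                          c(E[i, 1], newv), c(newv, E[i, 2]), c(newv, j))
      }
    }
    trees <- nxt
  }
  trees
}

.edgelist_to_lineage <- function(E, labels, rooted = FALSE) {
  labels_named <- structure(labels, names = seq_along(labels))
  phy <- .phylo_build(E[, 1], E[, 2], labels_named)
  .new_lineage_tree(phy, rooted = rooted)
}

#' Enumerate all unrooted binary topologies on a label set
#'
#' Produces all (2n-5)!! distinct unrooted binary trees, each exactly once,
#' in a deterministic order. Intended for exhaustive search and oracles at
#' small n.
#'
#' @param labels leaf labels (4 to `cap` of them).
#' @param cap refusal threshold (default 8; (2*8-5)!! = 10395 topologies).
#' @return list of `lineage_tree`s (unrooted, no probabilities).
#' @export
enumerate_unrooted_binary <- function(labels, cap = 8) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 4) stop("enumeration needs at least 4 labels")
  if (n > cap) stop("n = ", n, " exceeds enumeration cap ", cap)
  lapply(.enum_edgelists(n), .edgelist_to_lineage, labels = labels)
}

# rooted binary topologies on labels = unrooted ones on labels + a root
# handle; returns lineage_trees rooted above the handle's neighbor
.enum_rooted <- function(labels) {
  n <- length(labels)
  handle <- n + 1L
  lists <- .enum_edgelists(handle)
  lapply(lists, function(E) {
    # delete the handle tip and its edge; its neighbor becomes the root
    i <- which(E[, 2] == handle)
    labels_named <- structure(labels, names = seq_len(n))
    E <- E[-i, , drop = FALSE]
    phy <- .phylo_build(E[, 1], E[, 2], labels_named)
    .new_lineage_tree(phy, rooted = TRUE)
  })
}

#' Enumerate all rooted binary topologies on a label set
#'
#' All (2n-3)!! rooted binary trees, each once, deterministic order.
#'
#' @inheritParams enumerate_unrooted_binary
#' @export
enumerate_rooted_binary <- function(labels, cap = 7) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 3) stop("enumeration needs at least 3 labels")
  if (n > cap) stop("n = ", n, " exceeds enumeration cap ", cap)
  .enum_rooted(labels)
}
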