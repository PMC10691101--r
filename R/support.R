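# ---------------------------------------------------------------------------
# Mutations as splits, quartet/triplet weight tables, and the support
# scores QS_D and TS_D.
# ---------------------------------------------------------------------------

#' View one mutation column as a split
#'
#' A mutation partitions the non-missing cells by observed state; the
#' column is equivalent to an unrooted tree with at most one internal
#' branch (or a rooted one, with the 1-side as the derived clade). It is
#' quartet-informative when both sides hold at least two cells, and
#' triplet-informative when the 1-side holds at least two and the 0-side at
#' least one.
#'
#' @param D mutation matrix (integer 0/1/`NA`, rownames = cells).
#' @param j column index.
#' @return list with `ones`, `zeros`, `missing` (label vectors),
#'   `quartet_informative`, `triplet_informative`.
#' @export
column_to_split <- function(D, j) {
  col <- D[, j]
  cells <- rownames(D)
  ones <- cells[!is.na(col) & col == 1L]
  zeros <- cells[!is.na(col) & col == 0L]
  list(ones = ones, zeros = zeros,
       missing = cells[is.na(col)],
       quartet_informative = length(ones) >= 2 && length(zeros) >= 2,
       triplet_informative = length(ones) >= 2 && length(zeros) >= 1)
}

.check_matrix <- function(D) {
  if (is.null(rownames(D))) stop("mutation matrix needs cell rownames")
  if (anyDuplicated(rownames(D))) stop("duplicate cell labels")
  if (!all(D %in% c(0L, 1L, NA_integer_))) {
    stop("matrix entries must be 0, 1 or NA")
  }
  invisible(D)
}

# reorder rows to sorted label order
.sorted_matrix <- function(D) {
  D[order(rownames(D), method = "radix"), , drop = FALSE]
}

#' Quartet weight table of a mutation matrix
#'
#' For every 4-subset of cells, counts how many mutations imply each of the
#' three quartet topologies: a fully observed column restricted to the
#' subset implies a quartet exactly when two cells read 1 and two read 0
#' (the pattern and its complement induce the same split). Equivalent to
#' restricting every informative split-tree to every 4-subset.
#'
#' @param D mutation matrix.
#' @return a `quartet_weight_table`: list with `labels` (sorted cells),
#'   `subsets` (4 x C(n,4) index matrix), `counts` (C(n,4) x 3 integer;
#'   topology j pairs the j-th smallest subset member with... see
#'   [displayed_quartet()] for the indexing), and `k`.
#' @export
quartet_weights <- function(D) {
  .check_matrix(D)
  D <- .sorted_matrix(D)
  n <- nrow(D)
  if (n < 4) stop("quartet weights need at least 4 cells")
  subsets <- utils::combn(n, 4)
  counts <- matrix(0L, ncol = 3, nrow = ncol(subsets))
  for (s in seq_len(ncol(subsets))) {
    X <- D[subsets[, s], , drop = FALSE]
    ok <- colSums(is.na(X)) == 0L
    ones <- colSums(X == 1L, na.rm = TRUE)
    inf <- which(ok & ones == 2L)
    if (length(inf) == 0L) next
    x1 <- X[1, inf] == 1L; x2 <- X[2, inf] == 1L
    x3 <- X[3, inf] == 1L; x4 <- X[4, inf] == 1L
    topo <- ifelse(x1,
                   ifelse(x2, 1L, ifelse(x3, 2L, 3L)),
                   ifelse(x4, ifelse(x3, 1L, 2L), 3L))
    counts[s, ] <- tabulate(topo, nbins = 3L)
  }
  structure(list(labels = rownames(D), subsets = subsets, counts = counts,
                 k = ncol(D)),
            class = "quartet_weight_table")
}

#' Triplet weight table of a mutation matrix
#'
#' As [quartet_weights()], for rooted triplets: a column restricted to a
#' 3-subset implies a triplet exactly when two cells carry the derived
#' state 1 and one the ancestral state 0; the 0-cell is the outgroup.
#'
#' @param D mutation matrix (1 = derived).
#' @return a `triplet_weight_table`; counts column j corresponds to the
#'   triplet whose outgroup is the j-th smallest subset member.
#' @export
triplet_weights <- function(D) {
  .check_matrix(D)
  D <- .sorted_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("triplet weights need at least 3 cells")
  subsets <- utils::combn(n, 3)
  counts <- matrix(0L, ncol = 3, nrow = ncol(subsets))
  for (s in seq_len(ncol(subsets))) {
    X <- D[subsets[, s], , drop = FALSE]
    ok <- colSums(is.na(X)) == 0L
    ones <- colSums(X == 1L, na.rm = TRUE)
    inf <- which(ok & ones == 2L)
    if (length(inf) == 0L) next
    x1 <- X[1, inf] == 1L; x2 <- X[2, inf] == 1L
    out <- ifelse(!x1, 1L, ifelse(!x2, 2L, 3L))
    counts[s, ] <- tabulate(out, nbins = 3L)
  }
  structure(list(labels = rownames(D), subsets = subsets, counts = counts,
                 k = ncol(D)),
            class = "triplet_weight_table")
}

# topology index per 4-subset given canonical internal split masks;
# returns integer vector (NA = star) aligned with table rows
.topo_of_subsets <- function(masks, subsets) {
  ns <- ncol(subsets)
  bits <- matrix(bitwShiftL(1L, subsets - 1L), nrow = 4)
  topo <- rep(NA_integer_, ns)
  und <- rep(TRUE, ns)
  for (m in masks) {
    if (!any(und)) break
    i1 <- bitwAnd(m, bits[1, ]) > 0L
    i2 <- bitwAnd(m, bits[2, ]) > 0L
    i3 <- bitwAnd(m, bits[3, ]) > 0L
    i4 <- bitwAnd(m, bits[4, ]) > 0L
    s <- i1 + i2 + i3 + i4
    sel <- und & s == 2L
    if (!any(sel)) next
    t <- ifelse(i1,
                ifelse(i2, 1L, ifelse(i3, 2L, 3L)),
                ifelse(i4, ifelse(i3, 1L, 2L), 3L))
    topo[sel] <- t[sel]
    und[sel] <- FALSE
  }
  topo
}

# outgroup index per 3-subset given rooted clade masks (descendant sets)
.outgroup_of_subsets <- function(clades, subsets) {
  ns <- ncol(subsets)
  bits <- matrix(bitwShiftL(1L, subsets - 1L), nrow = 3)
  out <- rep(NA_integer_, ns)
  und <- rep(TRUE, ns)
  for (m in clades) {
    if (!any(und)) break
    i1 <- bitwAnd(m, bits[1, ]) > 0L
    i2 <- bitwAnd(m, bits[2, ]) > 0L
    i3 <- bitwAnd(m, bits[3, ]) > 0L
    s <- i1 + i2 + i3
    sel <- und & s == 2L
    if (!any(sel)) next
    t <- ifelse(!i1, 1L, ifelse(!i2, 2L, 3L))
    out[sel] <- t[sel]
    und[sel] <- FALSE
  }
  out
}

.score_quartet_masks <- function(tab, masks) {
  topo <- .topo_of_subsets(masks, tab$subsets)
  got <- which(!is.na(topo))
  if (length(got) == 0L) return(0L)
  sum(tab$counts[cbind(got, topo[got])])
}

.clade_masks <- function(tree) {
  n <- .n_tips(tree)
  if (n > 30) stop("clade encodings capped at 30 leaves")
  ord <- order(tree$tip.label, method = "radix")
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  unique(.edge_masks(tree, pos))
}

.score_triplet_masks <- function(tab, clades) {
  out <- .outgroup_of_subsets(clades, tab$subsets)
  got <- which(!is.na(out))
  if (length(got) == 0L) return(0L)
  sum(tab$counts[cbind(got, out[got])])
}

#' Quartet support score QS of a tree given mutation data
#'
#' The total number of (mutation, 4-subset) pairs on which the mutation's
#' implied quartet equals the quartet displayed by the tree. The tree may
#' be non-binary; subsets where it restricts to a star contribute nothing.
#' Implemented through split masks, and equal to the brute-force sum over
#' all 4-subsets of the weight of the restricted topology.
#'
#' @param x a mutation matrix or a `quartet_weight_table`.
#' @param tree a `lineage_tree` on the same cell set (compared unrooted).
#' @return integer score.
#' @export
quartet_support <- function(x, tree) {
  tab <- if (inherits(x, "quartet_weight_table")) x else quartet_weights(x)
  if (!setequal(tab$labels, tree$tip.label)) {
    stop("tree and matrix are on different cell sets")
  }
  u <- if (isTRUE(tree$rooted)) unroot_lineage(tree) else tree
  .score_quartet_masks(tab, .split_masks(u))
}

#' Triplet support score TS of a rooted tree given mutation data
#'
#' @param x a mutation matrix or a `triplet_weight_table`.
#' @param tree a rooted `lineage_tree` on the same cell set.
#' @return integer score.
#' @export
triplet_support <- function(x, tree) {
  if (!isTRUE(tree$rooted)) stop("triplet support needs a rooted tree")
  tab <- if (inherits(x, "triplet_weight_table")) x else triplet_weights(x)
  if (!setequal(tab$labels, tree$tip.label)) {
    stop("tree and matrix are on different cell sets")
  }
  .score_triplet_masks(tab, .clade_masks(tree))
}

#' Export mutations as split trees (multi-Newick)
#'
#' Writes one Newick tree per informative mutation: the cells observed 1
#' form one side of the single internal branch, the cells observed 0 the
#' other; missing cells are left out. In quartet mode, splits on fewer than
#' four cells (or without two cells on each side) are omitted; in triplet
#' mode the 1-side is written as the derived clade of a rooted tree and
#' splits need two 1-cells and one 0-cell.
#'
#' @param D mutation matrix.
#' @param file output path.
#' @param mode `"quartet"` or `"triplet"`.
#' @return number of trees written, invisibly.
#' @export
export_split_trees <- function(D, file, mode = c("quartet", "triplet")) {
  mode <- match.arg(mode)
  .check_matrix(D)
  out <- character(0)
  for (j in seq_len(ncol(D))) {
    sp <- column_to_split(D, j)
    if (mode == "quartet") {
      if (!sp$quartet_informative) next
      out <- c(out, sprintf("((%s),(%s));",
                            paste(sp$ones, collapse = ","),
                            paste(sp$zeros, collapse = ",")))
    } else {
      if (!sp$triplet_informative) next
      out <- c(out, sprintf("((%s),%s);",
                            paste(sp$ones, collapse = ","),
                            paste(sp$zeros, collapse = ",")))
    }
  }
  writeLines(out, file)
  invisible(length(out))
}
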