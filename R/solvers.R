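# ---------------------------------------------------------------------------
# Maximum Quartet / Triplet Support Supertree solvers and the consistency
# experiment harness.
# ---------------------------------------------------------------------------

.solver_result <- function(tree, score, mode, evaluations, ties,
                           seed = NULL) {
  structure(list(tree = tree, score = as.integer(score), mode = mode,
                 evaluations = as.integer(evaluations),
                 ties = as.integer(ties), seed = seed),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf("<solver_result> mode = %s, score = %d, evaluations = %d, co-optima = %d\n",
              x$mode, x$score, x$evaluations, x$ties))
  cat("  ", canonical_newick(x$tree), "\n", sep = "")
  invisible(x)
}

#' Exhaustive Maximum Quartet Support Supertree
#'
#' Scores every unrooted binary topology on the cell set and returns a
#' global optimum of the quartet support QS. Ties are broken
#' deterministically towards the lexicographically smallest canonical
#' Newick string; the number of co-optima is reported.
#'
#' @param D mutation matrix with 4 to `cap` cells.
#' @param cap enumeration cap (default 8).
#' @return a `solver_result` (unrooted binary tree, score, evaluations,
#'   ties).
#' @export
mqss_exhaustive <- function(D, cap = 8) {
  .check_matrix(D)
  labels <- sort(rownames(D), method = "radix")
  n <- length(labels)
  if (n < 4) stop("quartet estimation needs at least 4 cells")
  if (n > cap) stop("n = ", n, " exceeds exhaustive cap ", cap)
  tab <- quartet_weights(D)
  best <- NULL; best_score <- -1L; ties <- 0L; evals <- 0L
  for (E in .enum_edgelists(n)) {
    tree <- .edgelist_to_lineage(E, labels, rooted = FALSE)
    sc <- .score_quartet_masks(tab, .split_masks(tree))
    evals <- evals + 1L
    if (sc > best_score) {
      best <- tree; best_score <- sc; ties <- 1L
    } else if (sc == best_score) {
      ties <- ties + 1L
      if (canonical_newick(tree) < canonical_newick(best)) best <- tree
    }
  }
  .solver_result(best, best_score, "exhaustive", evals, ties)
}

#' Exhaustive Maximum Triplet Support Supertree
#'
#' As [mqss_exhaustive()], over all rooted binary topologies, maximising
#' the triplet support TS.
#'
#' @param D mutation matrix with 3 to `cap` cells (1 = derived state).
#' @param cap enumeration cap (default 7).
#' @export
mtss_exhaustive <- function(D, cap = 7) {
  .check_matrix(D)
  labels <- sort(rownames(D), method = "radix")
  n <- length(labels)
  if (n < 3) stop("triplet estimation needs at least 3 cells")
  if (n > cap) stop("n = ", n, " exceeds exhaustive cap ", cap)
  tab <- triplet_weights(D)
  best <- NULL; best_score <- -1L; ties <- 0L; evals <- 0L
  for (tree in .enum_rooted(labels)) {
    sc <- .score_triplet_masks(tab, .clade_masks(tree))
    evals <- evals + 1L
    if (sc > best_score) {
      best <- tree; best_score <- sc; ties <- 1L
    } else if (sc == best_score) {
      ties <- ties + 1L
      if (canonical_newick(tree) < canonical_newick(best)) best <- tree
    }
  }
  .solver_result(best, best_score, "exhaustive", evals, ties)
}

#' Constraint space of candidate bipartitions
#'
#' Collects the bipartitions induced by the informative mutations, each
#' completed to the full cell set, plus all trivial bipartitions. Cells
#' with missing entries join the zero (ancestral-majority) side under the
#' default completion, or the column is dropped. Stored canonically (side
#' not containing the smallest cell), which also closes the set under
#' complement.
#'
#' @param D mutation matrix.
#' @param completion `"zero"` (missing cells join the 0-side) or `"drop"`
#'   (columns with missing entries are skipped).
#' @param extra optional list of `lineage_tree`s whose bipartitions augment
#'   the space (heuristic starting trees).
#' @return a `constraint_space`: list with `labels` and internal `masks`.
#' @export
build_constraint_space <- function(D, completion = c("zero", "drop"),
                                   extra = NULL) {
  completion <- match.arg(completion)
  .check_matrix(D)
  D <- .sorted_matrix(D)
  labels <- rownames(D)
  n <- length(labels)
  if (n > 30) stop("constraint spaces capped at 30 cells")
  full <- bitwShiftL(1L, n) - 1L
  masks <- integer(0)
  for (j in seq_len(ncol(D))) {
    col <- D[, j]
    if (completion == "drop" && anyNA(col)) next
    ones <- which(!is.na(col) & col == 1L)
    if (length(ones) < 2 || n - length(ones) < 2) next
    m <- sum(bitwShiftL(1L, ones - 1L))
    if (bitwAnd(m, 1L) > 0L) m <- bitwAnd(bitwNot(m), full)
    masks <- c(masks, m)
  }
  for (tr in extra) {
    u <- if (isTRUE(tr$rooted)) unroot_lineage(tr) else tr
    if (!setequal(u$tip.label, labels)) stop("extra tree on different cells")
    masks <- c(masks, .split_masks(u))
  }
  structure(list(labels = labels, masks = unique(masks)),
            class = "constraint_space")
}

#' Constrained Maximum Quartet Support Supertree
#'
#' Optimal QS over binary trees all of whose bipartitions lie in the
#' constraint space (the search-space restriction used by constrained
#' supertree methods). Solved by filtered enumeration, so it shares the
#' exhaustive cap; its optimum can never exceed the unconstrained one.
#'
#' @param D mutation matrix.
#' @param space a `constraint_space` from [build_constraint_space()].
#' @param cap enumeration cap (default 8).
#' @return a `solver_result`; errors if the space admits no binary tree.
#' @export
mqss_constrained <- function(D, space, cap = 8) {
  .check_matrix(D)
  labels <- sort(rownames(D), method = "radix")
  if (!identical(labels, space$labels)) {
    stop("constraint space is on a different cell set")
  }
  n <- length(labels)
  if (n < 4) stop("quartet estimation needs at least 4 cells")
  if (n > cap) stop("n = ", n, " exceeds constrained-search cap ", cap)
  tab <- quartet_weights(D)
  best <- NULL; best_score <- -1L; ties <- 0L; evals <- 0L
  for (E in .enum_edgelists(n)) {
    tree <- .edgelist_to_lineage(E, labels, rooted = FALSE)
    masks <- .split_masks(tree)
    if (!all(masks %in% space$masks)) next
    sc <- .score_quartet_masks(tab, masks)
    evals <- evals + 1L
    if (sc > best_score) {
      best <- tree; best_score <- sc; ties <- 1L
    } else if (sc == best_score) {
      ties <- ties + 1L
      if (canonical_newick(tree) < canonical_newick(best)) best <- tree
    }
  }
  if (is.null(best)) stop("constraint space admits no binary tree")
  .solver_result(best, best_score, "constrained", evals, ties)
}

# --- NNI machinery on undirected edge lists -------------------------------

.tree_to_edgelist <- function(tree, labels) {
  idx <- match(tree$tip.label, labels)
  n <- length(labels)
  E <- tree$edge
  remap <- function(v) ifelse(v <= n, idx[v], v)
  cbind(remap(E[, 1]), remap(E[, 2]))
}

.nni_neighbors <- function(E, n) {
  adj <- list()
  key <- function(v) as.character(v)
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1]; v <- E[i, 2]
    adj[[key(u)]] <- c(adj[[key(u)]], v)
    adj[[key(v)]] <- c(adj[[key(v)]], u)
  }
  out <- list()
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1]; v <- E[i, 2]
    if (u <= n || v <= n) next
    au <- setdiff(adj[[key(u)]], v)
    av <- setdiff(adj[[key(v)]], u)
    for (bi in seq_along(av)) {
      b <- av[bi]
      a <- au[1]
      E2 <- E
      ia <- which((E2[, 1] == u & E2[, 2] == a) | (E2[, 1] == a & E2[, 2] == u))
      ib <- which((E2[, 1] == v & E2[, 2] == b) | (E2[, 1] == b & E2[, 2] == v))
      E2[ia, 1] <- u; E2[ia, 2] <- b
      E2[ib, 1] <- v; E2[ib, 2] <- a
      out[[length(out) + 1L]] <- E2
    }
  }
  out
}

# re-root an undirected edge list so .phylo_build accepts it
.orient_edgelist <- function(E, n) {
  adj <- vector("list", max(E))
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1]; v <- E[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  root <- E[which(E[, 1] > n | E[, 2] > n)[1], ]
  root <- root[root > n][1]
  pp <- integer(0); cc <- integer(0)
  stack_node <- root; stack_par <- 0L
  while (length(stack_node) > 0) {
    i <- length(stack_node)
    node <- stack_node[i]; par <- stack_par[i]
    stack_node <- stack_node[-i]; stack_par <- stack_par[-i]
    for (w in setdiff(adj[[node]], par)) {
      pp <- c(pp, node); cc <- c(cc, w)
      if (w > n) {
        stack_node <- c(stack_node, w)
        stack_par <- c(stack_par, node)
      }
    }
  }
  cbind(pp, cc)
}

#' Hill-climbing MQSS search by nearest-neighbor interchange
#'
#' Seeded local search for cell sets beyond the exhaustive cap: from a
#' binary starting tree, repeatedly examines NNI moves in a shuffled order
#' and accepts the first improvement; stops at a local optimum or after
#' `max_rounds` rounds. The score never decreases.
#'
#' @param D mutation matrix.
#' @param start binary unrooted `lineage_tree` on the cell set (default: a
#'   random topology).
#' @param max_rounds round cap.
#' @param seed integer seed for the move order (and the random start).
#' @return a `solver_result`.
#' @export
mqss_nni <- function(D, start = NULL, max_rounds = 100, seed = NULL) {
  .check_matrix(D)
  labels <- sort(rownames(D), method = "radix")
  n <- length(labels)
  if (n < 4) stop("quartet estimation needs at least 4 cells")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(start)) start <- random_binary_topology(labels)
  if (!setequal(start$tip.label, labels)) {
    stop("starting tree is on a different cell set")
  }
  tab <- quartet_weights(D)
  E <- .tree_to_edgelist(start, labels)
  score_of <- function(E) {
    tree <- .edgelist_to_lineage(.orient_edgelist(E, n), labels,
                                 rooted = FALSE)
    list(tree = tree, score = .score_quartet_masks(tab, .split_masks(tree)))
  }
  cur <- score_of(E)
  evals <- 1L
  for (round in seq_len(max_rounds)) {
    nbs <- .nni_neighbors(E, n)
    improved <- FALSE
    for (i in sample.int(length(nbs))) {
      cand <- score_of(nbs[[i]])
      evals <- evals + 1L
      if (cand$score > cur$score) {
        E <- nbs[[i]]
        cur <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  .solver_result(cur$tree, cur$score, "nni", evals, 1L, seed = seed)
}

#' Empirical consistency experiment
#'
#' For every mutation count in `k_grid` and every replicate: simulate a
#' matrix from the model tree under the error model, estimate a tree with
#' the requested solver, and record the false negative and false positive
#' branch error against the model tree (compared unrooted for quartet
#' solvers, rooted input for the triplet solver). Fully seeded: replicate
#' r at grid position g uses seed `seed + 1000 * g + r`.
#'
#' @param sigma rooted `lineage_tree` with probabilities.
#' @param em an [error_model()].
#' @param k_grid integer vector of mutation counts.
#' @param replicates replicates per grid point.
#' @param solver `"mqss"` (exhaustive), `"mtss"` (exhaustive) or
#'   `"mqss_nni"`.
#' @param seed base integer seed.
#' @return data.frame with columns k, replicate, seed, fn, fp, score.
#' @export
consistency_experiment <- function(sigma, em, k_grid, replicates = 10,
                                   solver = c("mqss", "mtss", "mqss_nni"),
                                   seed = 1) {
  solver <- match.arg(solver)
  rows <- vector("list", length(k_grid) * replicates)
  ri <- 0L
  for (g in seq_along(k_grid)) {
    for (r in seq_len(replicates)) {
      ri <- ri + 1L
      s <- as.integer(seed + 1000 * g + r)
      sim <- simulate_mutation_matrix(sigma, em, k = k_grid[g], seed = s)
      res <- switch(solver,
                    mqss = mqss_exhaustive(sim$D),
                    mtss = mtss_exhaustive(sim$D),
                    mqss_nni = mqss_nni(sim$D, seed = s))
      err <- tree_error(sigma, res$tree)
      rows[[ri]] <- data.frame(k = k_grid[g], replicate = r, seed = s,
                               fn = err$fn, fp = err$fp, score = res$score)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
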