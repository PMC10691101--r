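# ---------------------------------------------------------------------------
# Seedable generation of mutation matrices under IS+UEM and construction of
# the worked fixture trees.
# ---------------------------------------------------------------------------

#' Simulate a mutation matrix under the IS+UEM model
#'
#' Two-step hierarchical generation. Step 1 (infinite sites): each of the
#' `k` mutations independently picks one edge with the tree's edge
#' probabilities and marks exactly the cells below that edge with 1 (the
#' stem mass of a sub-model yields an all-ones column and the all-zero mass
#' an all-zero column). Step 2 (unbiased error and missingness): every entry
#' independently flips 0->1 with alpha, 1->0 with beta, and is masked as
#' missing with gamma. Fake leaves receive observed states through the same
#' channel; their ground truth is the state of the internal cell they
#' duplicate.
#'
#' The pseudo-random stream is consumed in a fixed order (all edge draws,
#' then one error uniform per entry, then one missingness uniform per entry,
#' both in column-major order), so a seed pins the output exactly.
#'
#' @param sigma a rooted `lineage_tree` with edge probabilities.
#' @param em an [error_model()].
#' @param k number of mutations (columns).
#' @param seed optional integer seed.
#' @param return_ground_truth also return the pre-error matrix `G`.
#' @param include_fake keep rows for fake leaves (default `TRUE`: fake
#'   leaves are sampled ancestral cells and are real observations); set
#'   `FALSE` to drop them.
#' @return list with `D` (integer matrix, `NA` = missing), optionally `G`,
#'   and `edges` (the drawn edge index per column; 0 denotes the stem, -1
#'   the invisible/all-zero mass).
#' @export
simulate_mutation_matrix <- function(sigma, em, k, seed = NULL,
                                     return_ground_truth = FALSE,
                                     include_fake = TRUE) {
  if (!isTRUE(sigma$rooted)) stop("simulation needs a rooted tree")
  if (!.has_probs(sigma)) stop("tree carries no edge probabilities")
  if (k < 1) stop("k must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- .n_tips(sigma)
  p <- c(sigma$edge.length, .stem_prob(sigma), .null_prob(sigma))
  idx <- c(seq_len(nrow(sigma$edge)), 0L, -1L)
  draw <- sample(idx, size = k, replace = TRUE, prob = p)
  below <- .edge_tipsets(sigma)
  G <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(sigma$tip.label,
                              paste0("m", seq_len(k))))
  for (j in seq_len(k)) {
    e <- draw[j]
    if (e > 0L) G[below[[e]], j] <- 1L else if (e == 0L) G[, j] <- 1L
  }
  D <- G
  u_err <- matrix(stats::runif(n * k), nrow = n)
  D[G == 0L & u_err < em$a] <- 1L
  D[G == 1L & u_err < em$b] <- 0L
  u_mis <- matrix(stats::runif(n * k), nrow = n)
  D[u_mis < em$g] <- NA_integer_
  if (!include_fake) {
    fake_tips <- sigma$edge[fake_edges(sigma), 2]
    fake_tips <- fake_tips[fake_tips <= n]
    if (length(fake_tips) > 0) {
      D <- D[-fake_tips, , drop = FALSE]
      G <- G[-fake_tips, , drop = FALSE]
    }
  }
  out <- list(D = D, edges = draw)
  if (return_ground_truth) out$G <- G
  out
}

#' Write / read a mutation matrix as TSV
#'
#' Tab-separated dialect: a header row of mutation ids, first column `cell`
#' holding cell labels, entries `0`, `1` or `?` for missing.
#'
#' @param D integer matrix with `NA` for missing, rownames = cell labels.
#' @param file path.
#' @export
write_mutation_matrix <- function(D, file) {
  ch <- matrix(as.character(D), nrow = nrow(D))
  ch[is.na(D)] <- "?"
  df <- data.frame(cell = rownames(D), ch, stringsAsFactors = FALSE)
  colnames(df) <- c("cell", colnames(D))
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_mutation_matrix
#' @export
read_mutation_matrix <- function(file) {
  df <- utils::read.delim(file, colClasses = "character",
                          check.names = FALSE)
  if (colnames(df)[1] != "cell") stop("first column must be 'cell'")
  cells <- df[[1]]
  if (anyDuplicated(cells)) stop("duplicate cell labels")
  ch <- as.matrix(df[, -1, drop = FALSE])
  if (!all(ch %in% c("0", "1", "?"))) {
    stop("matrix entries must be 0, 1 or ?")
  }
  D <- matrix(NA_integer_, nrow = nrow(ch), ncol = ncol(ch),
              dimnames = list(cells, colnames(ch)))
  D[ch == "0"] <- 0L
  D[ch == "1"] <- 1L
  D
}

#' The five rooted tree shapes on four leaves
#'
#' `S1` balanced `((a,b),(c,d))`, `S2` caterpillar `(((a,b),c),d)`, `S3`
#' cherry plus two at a trifurcating root `((a,b),c,d)`, `S4` resolved
#' triple plus one `((a,b,c),d)`, `S5` star. S1-S3 display a quartet when
#' unrooted; S4-S5 display a star. Each edge receives equal mutation
#' probability by default.
#'
#' @param shape one of `"S1"` .. `"S5"`.
#' @param labels four leaf labels, used in order as a, b, c, d.
#' @return a rooted `lineage_tree` with uniform edge probabilities.
#' @export
build_shape_tree <- function(shape = c("S1", "S2", "S3", "S4", "S5"),
                             labels = c("A", "B", "C", "D")) {
  shape <- match.arg(shape)
  labels <- as.character(labels)
  if (length(labels) != 4) stop("need exactly four labels")
  a <- labels[1]; b <- labels[2]; c_ <- labels[3]; d <- labels[4]
  tpl <- switch(shape,
    S1 = sprintf("((%s,%s),(%s,%s));", a, b, c_, d),
    S2 = sprintf("(((%s,%s),%s),%s);", a, b, c_, d),
    S3 = sprintf("((%s,%s),%s,%s);", a, b, c_, d),
    S4 = sprintf("((%s,%s,%s),%s);", a, b, c_, d),
    S5 = sprintf("(%s,%s,%s,%s);", a, b, c_, d))
  tree <- read_lineage_tree(tpl, rooted = TRUE, probabilities = "none")
  ne <- nrow(tree$edge)
  tree$edge.length <- rep(1 / ne, ne)
  tree$prob.num <- rep(1, ne)
  tree$prob.den <- ne
  tree$root.num <- 0
  tree$null.num <- 0
  validate_lineage_tree(tree)
  tree
}

#' Augmented cell lineage fixture with an anomalous triplet
#'
#' Builds the rooted lineage tree used to demonstrate anomalous triplets: a
#' small clone (cells 1 and 4, with cell 1 sampled as a fake copy of its
#' ancestor) sits beside a long chain of `m + 8` successive clones leading
#' to cell 10, each chain clone contributing one sampled side cell on a
#' fake edge; a fake healthy cell 0 hangs at the root. Mutations occur on
#' every non-fake edge with equal probability, so there are `m + 12`
#' mutation-bearing edges, and restricting to cells 1, 4 and 10 yields
#' exactly: a root stem of mass 1/(m+12), a cherry edge for 1 and 4 of mass
#' 1/(m+12), a terminal edge for 4 of mass 1/(m+12), a fake terminal edge
#' for 1, and a terminal edge for 10 of mass (m+9)/(m+12). With m = 1000
#' the singleton pattern for cell 10 has probability 1009/1012 while the
#' displayed triplet 10|1,4 has only 1/1012, which makes the alternative
#' triplets anomalous once false positives are possible.
#'
#' @param m number of inserted chain cells (default 1000).
#' @return a rooted `lineage_tree` with exact rational probabilities.
#' @export
build_augmented_lineage_fixture <- function(m = 1000) {
  if (m < 0) stop("m must be non-negative")
  den <- m + 12
  side_labels <- c("2", "3", "5", "6", "7", "8", "9", "11")
  if (m > 0) side_labels <- c(side_labels, paste0("n", seq_len(m)))
  n_chain <- m + 8        # chain internal vertices, each with one side cell
  # ids: tips first
  tip_labels <- c("0", "1", "4", "10", side_labels)
  n <- length(tip_labels)
  tip_ids <- seq_len(n)
  names(tip_labels) <- tip_ids
  root_id <- n + 1L
  a_id <- n + 2L          # MRCA of {1, 4, 10}
  b_id <- n + 3L          # cherry vertex of {1, 4}
  chain_ids <- n + 3L + seq_len(n_chain)
  pp <- c(root_id, root_id, a_id, b_id, b_id, a_id)
  cc <- c(1L,      a_id,    b_id, 2L,   3L,   chain_ids[1])
  pr <- c(0,       1,       1,    0,    1,    1)
  for (i in seq_len(n_chain)) {
    v <- chain_ids[i]
    side_tip <- 4L + i
    pp <- c(pp, v)
    cc <- c(cc, side_tip)
    pr <- c(pr, 0)
    nxt <- if (i < n_chain) chain_ids[i + 1] else 4L  # tip "10"
    pp <- c(pp, v)
    cc <- c(cc, nxt)
    pr <- c(pr, 1)
  }
  phy <- .phylo_build(pp, cc, tip_labels, len = pr / den)
  # numerators follow the (possibly reordered) edge rows via matching probs
  tree <- .new_lineage_tree(phy, rooted = TRUE,
                            prob.num = round(phy$edge.length * den),
                            prob.den = den)
  validate_lineage_tree(tree)
  tree
}

#' Random partially resolved lineage tree
#'
#' A random rooted binary topology (uniform sequential leaf insertion) in
#' which a fraction `1 - resolution` of the internal edges is contracted,
#' leaving polytomies; surviving edges receive symmetric-Dirichlet(1)
#' mutation probabilities normalised to 1.
#'
#' @param n number of leaves (>= 3); labels are `c1..cn`.
#' @param resolution fraction of internal edges kept, in \[0,1\].
#' @param seed optional integer seed.
#' @param labels optional explicit labels.
#' @return a rooted `lineage_tree` with probabilities.
#' @export
random_lineage_tree <- function(n, resolution = 1, seed = NULL,
                                labels = NULL) {
  if (n < 3) stop("need at least three leaves")
  if (resolution < 0 || resolution > 1) stop("resolution must be in [0,1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(labels)) labels <- paste0("c", seq_len(n))
  labels <- as.character(labels)
  # sequential random insertion: rooted binary via its unrooted analogue on
  # n + 1 handles is overkill here; grow a rooted edge list directly
  root_id <- n + 1L
  next_id <- n + 2L
  pp <- c(root_id, root_id)
  cc <- c(1L, 2L)
  for (tip in 3L:n) {
    i <- sample.int(length(pp), 1L)
    v <- next_id; next_id <- next_id + 1L
    old_child <- cc[i]
    cc[i] <- v
    pp <- c(pp, v, v)
    cc <- c(cc, old_child, tip)
  }
  # contract a fraction of internal edges
  internal <- which(cc > n)
  n_drop <- round((1 - resolution) * length(internal))
  if (n_drop > 0) {
    drop <- sample(internal, n_drop)
    for (i in drop) {
      v <- cc[i]
      pp[pp == v] <- pp[i]
    }
    keepers <- setdiff(seq_along(pp), drop)
    pp <- pp[keepers]; cc <- cc[keepers]
  }
  probs <- stats::rgamma(length(pp), shape = 1)
  probs <- probs / sum(probs)
  phy <- .phylo_build(pp, cc, structure(labels, names = seq_len(n)),
                      len = probs)
  tree <- .new_lineage_tree(phy, rooted = TRUE)
  validate_lineage_tree(tree)
  tree
}

#' Random unrooted binary topology
#'
#' Uniform-insertion random binary tree without probabilities; used for
#' search starting points.
#'
#' @param labels leaf labels (>= 4).
#' @param seed optional integer seed.
#' @return an unrooted binary `lineage_tree`.
#' @export
random_binary_topology <- function(labels, seed = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 4) stop("need at least four labels")
  if (!is.null(seed)) set.seed(as.integer(seed))
  E <- cbind(c(n + 1L, n + 1L, n + 1L), c(1L, 2L, 3L))
  next_id <- n + 2L
  for (tip in 4L:n) {
    i <- sample.int(nrow(E), 1L)
    v <- next_id; next_id <- next_id + 1L
    E <- rbind(E[-i, , drop = FALSE],
               c(E[i, 1], v), c(v, E[i, 2]), c(v, tip))
  }
  .edgelist_to_lineage(E, labels, rooted = FALSE)
}
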