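# Fixtures built in code: small model trees with uniform edge probabilities
# (the convention that mutations fall on every non-fake edge with equal
# probability) and brute-force oracles used to cross-check fast paths.

# balanced rooted binary 6-leaf tree, 10 edges at 1/10
balanced6 <- function() {
  read_lineage_tree(
    "(((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1):0.1,(E:0.1,F:0.1):0.1);")
}

# the same tree with the AB|CDEF edge contracted: one polytomy, 9 edges
poly6 <- function() {
  t <- read_lineage_tree("((A,B,(C,D)),(E,F));", probabilities = "none")
  t$edge.length <- rep(1 / 9, nrow(t$edge))
  validate_lineage_tree(t)
  t
}

# rooted 3-leaf shapes: binary and star, uniform probabilities
triplet_shape_binary <- function() {
  read_lineage_tree("((A:0.25,B:0.25):0.25,C:0.25);")
}
triplet_shape_star <- function() {
  t <- read_lineage_tree("(A,B,C);", probabilities = "none")
  t$edge.length <- rep(1 / 3, 3)
  t
}

random_error_model <- function(max = 0.4) {
  repeat {
    a <- stats::runif(1, 0, max)
    b <- stats::runif(1, 0, max)
    if (abs(a + b - 1) > 1e-6) break
  }
  error_model(a, b, stats::runif(1, 0, max))
}

# quartet probabilities straight from the enumeration oracle
oracle_quartet_probs <- function(sigma, subset, em) {
  base <- is_pattern_distribution(sigma, sort(subset, method = "radix"))
  cor <- corrupted_pattern_distribution(base, em)
  p <- function(s) cor$prob[[match(s, cor$patterns)]]
  c(p("1100") + p("0011"), p("1010") + p("0101"), p("1001") + p("0110"))
}

oracle_triplet_probs <- function(sigma, subset, em) {
  base <- is_pattern_distribution(sigma, sort(subset, method = "radix"))
  cor <- corrupted_pattern_distribution(base, em)
  p <- function(s) cor$prob[[match(s, cor$patterns)]]
  c(p("011"), p("101"), p("110"))
}

# quartet encoding by per-subset restriction (independent of split masks)
brute_quartet_encoding <- function(tree) {
  u <- if (is_rooted_lineage(tree)) unroot_lineage(tree) else tree
  labs <- sort(u$tip.label, method = "radix")
  cm <- utils::combn(labs, 4)
  out <- character(0)
  for (j in seq_len(ncol(cm))) {
    r <- restrict_tree(u, cm[, j])
    bp <- bipartition_set(r)
    int <- bp[bp$internal, , drop = FALSE]
    if (nrow(int) == 1) {
      s1 <- sort(strsplit(int$side1, ",")[[1]], method = "radix")
      s2 <- sort(strsplit(int$side2, ",")[[1]], method = "radix")
      out <- c(out, paste0(paste(s1, collapse = ","), "|",
                           paste(s2, collapse = ",")))
    }
  }
  sort(out, method = "radix")
}

# QS by explicit restriction of every mutation to every 4-subset
brute_quartet_support <- function(D, tree) {
  labs <- sort(rownames(D), method = "radix")
  cm <- utils::combn(labs, 4)
  total <- 0L
  for (s in seq_len(ncol(cm))) {
    sub <- cm[, s]
    dq <- displayed_quartet(tree, sub)
    if (is.na(dq$topology)) next
    X <- D[sub, , drop = FALSE]
    for (j in seq_len(ncol(X))) {
      v <- X[, j]
      if (anyNA(v) || sum(v) != 2L) next
      topo <- if (v[1] == 1L) {
        if (v[2] == 1L) 1L else if (v[3] == 1L) 2L else 3L
      } else {
        if (v[4] == 1L) {
          if (v[3] == 1L) 1L else 2L
        } else 3L
      }
      if (topo == dq$topology) total <- total + 1L
    }
  }
  total
}

# random 0/1/NA matrix
random_matrix <- function(n, k, p_na = 0.1) {
  D <- matrix(sample(c(0L, 1L), n * k, replace = TRUE), nrow = n)
  D[matrix(stats::runif(n * k) < p_na, nrow = n)] <- NA_integer_
  rownames(D) <- paste0("c", seq_len(n))
  colnames(D) <- paste0("m", seq_len(k))
  D
}
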