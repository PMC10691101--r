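# ---------------------------------------------------------------------------
# Exact probability calculators for the infinite-sites (IS) model and its
# composition with the unbiased error-and-missingness (UEM) channel, plus
# anomaly detection for quartets and triplets.
# ---------------------------------------------------------------------------

#' Unbiased error and missingness model
#'
#' The three-parameter channel applied independently to every matrix entry:
#' a true 0 is observed as 1 with probability `alpha` (false positive), a
#' true 1 as 0 with probability `beta` (false negative), and any entry is
#' masked as missing with probability `gamma`. Parameters may be given as
#' exact [ratio()] values, in which case downstream analytic calculators run
#' in exact rational arithmetic.
#'
#' @param alpha false positive probability in \[0,1).
#' @param beta false negative probability in \[0,1).
#' @param gamma missingness probability in \[0,1).
#' @return an `error_model` object. When `alpha + beta == 1` the object is
#'   flagged `degenerate` (quartet signal vanishes there) and a warning is
#'   emitted.
#' @examples
#' error_model(0.001, 0.2, 0.05)
#' error_model(ratio(1, 1000), ratio(1, 5))
#' @export
error_model <- function(alpha = 0, beta = 0, gamma = 0) {
  num <- function(x) if (is_ratio(x)) as.numeric(x) else x
  a <- num(alpha); b <- num(beta); g <- num(gamma)
  for (v in c(a, b, g)) {
    if (!is.finite(v) || v < 0 || v >= 1) {
      stop("error model parameters must lie in [0, 1)")
    }
  }
  exact <- is_ratio(alpha) || is_ratio(beta) || is_ratio(gamma)
  if (exact) {
    alpha <- .as_ratio_param(alpha)
    beta <- .as_ratio_param(beta)
    gamma <- .as_ratio_param(gamma)
  }
  degenerate <- a + b == 1
  if (degenerate) {
    warning("alpha + beta = 1: quartet frequencies carry no topological signal")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 a = a, b = b, g = g,
                 exact = exact, degenerate = degenerate),
            class = "error_model")
}

.as_ratio_param <- function(x) {
  if (is_ratio(x)) return(x)
  if (x == trunc(x)) return(ratio(x))
  stop("mixing exact and non-integer numeric error parameters; ",
       "supply all of alpha, beta, gamma as ratio()")
}

#' @export
print.error_model <- function(x, ...) {
  fmt <- function(v) if (is_ratio(v)) format(v) else format(v)
  cat(sprintf("<error_model> alpha = %s, beta = %s, gamma = %s%s\n",
              fmt(x$alpha), fmt(x$beta), fmt(x$gamma),
              if (x$exact) " (exact)" else ""))
  invisible(x)
}

.em_scalars <- function(em, exact) {
  if (exact) {
    if (!em$exact) stop("exact computation requires a ratio-valued error model")
    list(a = em$alpha, b = em$beta, g = em$gamma, one = ratio(1))
  } else {
    list(a = em$a, b = em$b, g = em$g, one = 1)
  }
}

.pattern_strings <- function(m) {
  vapply(0:(2^m - 1), function(mask) {
    paste(ifelse(bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) > 0, "1", "0"),
          collapse = "")
  }, "")
}

.pattern_index <- function(s) {
  bits <- strsplit(s, "")[[1]] == "1"
  sum(bitwShiftL(1L, which(bits) - 1L)) + 1L
}

#' Infinite-sites mutation pattern distribution on a cell subset
#'
#' Under the IS model each mutation falls on one edge (with the edge's
#' probability) and marks exactly the cells below it, so the probability of
#' a binary pattern on `subset` is the total mass of edges whose descendant
#' set meets the subset in exactly the pattern's 1-cells. The stem mass of a
#' sub-model produces the all-ones pattern and the invisible-edge mass the
#' all-zero pattern. Computed directly on `sigma`; identical to computing on
#' `restrict_tree(sigma, subset)` (a property the test suite checks).
#'
#' @param sigma a rooted `lineage_tree` with edge probabilities.
#' @param subset character vector of 1 to 8 leaf labels; pattern strings are
#'   ordered as given here.
#' @return a `pattern_distribution`: list with `labels`, `patterns`, `prob`
#'   (named numeric summing to 1) and, when `sigma` carries exact
#'   numerators, `exact` (a [ratio()] vector).
#' @export
is_pattern_distribution <- function(sigma, subset) {
  if (!isTRUE(sigma$rooted)) stop("pattern distributions need a rooted tree")
  if (!.has_probs(sigma)) stop("tree carries no edge probabilities")
  subset <- as.character(subset)
  m <- length(subset)
  if (m < 1 || m > 8) stop("subset size must be between 1 and 8")
  tips <- .tip_index(sigma, subset)
  pos <- integer(.n_tips(sigma))
  pos[tips] <- seq_len(m)
  masks <- .edge_masks(sigma, pos)
  full <- bitwShiftL(1L, m) - 1L
  p <- numeric(2^m)
  agg <- tapply(sigma$edge.length, masks, sum)
  p[as.integer(names(agg)) + 1L] <- agg
  p[full + 1L] <- p[full + 1L] + .stem_prob(sigma)
  p[1L] <- p[1L] + .null_prob(sigma)
  pats <- .pattern_strings(m)
  names(p) <- pats
  out <- list(labels = subset, patterns = pats, prob = p, exact = NULL)
  if (!is.null(sigma$prob.den)) {
    nums <- numeric(2^m)
    agg_n <- tapply(sigma$prob.num, masks, sum)
    nums[as.integer(names(agg_n)) + 1L] <- agg_n
    nums[full + 1L] <- nums[full + 1L] +
      (if (is.null(sigma$root.num)) 0 else sigma$root.num)
    nums[1L] <- nums[1L] + (if (is.null(sigma$null.num)) 0 else sigma$null.num)
    out$exact <- ratio(nums, sigma$prob.den)
  }
  class(out) <- "pattern_distribution"
  out
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat("<pattern_distribution> on {", paste(x$labels, collapse = ", "), "}\n")
  nz <- x$prob > 0
  if (!is.null(x$exact)) {
    cat(paste0("  ", x$patterns[nz], ": ", format(x$exact[which(nz)]),
               collapse = "\n"), "\n")
  } else {
    cat(paste0("  ", x$patterns[nz], ": ", signif(x$prob[nz], 6),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Per-entry error/missingness channel probability
#'
#' Probability of observing pattern `d` given true pattern `g` under the
#' unbiased error and missingness channel: per cell, 0 stays 0 with
#' (1-alpha)(1-gamma), flips to 1 with alpha(1-gamma); 1 drops to 0 with
#' beta(1-gamma), stays 1 with (1-beta)(1-gamma); any state is masked `?`
#' with gamma. Cells are independent, so the result is a product.
#'
#' @param g_pattern true pattern, string over `{0,1}`.
#' @param d_pattern observed pattern, string over `{0,1,?}`, same length.
#' @param em an [error_model()].
#' @param exact compute in exact rational arithmetic (requires a
#'   ratio-valued `em`).
#' @return probability (numeric, or [ratio()] when `exact`).
#' @export
uem_channel <- function(g_pattern, d_pattern, em, exact = FALSE) {
  g <- strsplit(g_pattern, "")[[1]]
  d <- strsplit(d_pattern, "")[[1]]
  if (length(g) != length(d)) stop("patterns of unequal length")
  if (!all(g %in% c("0", "1"))) stop("true pattern must be over {0,1}")
  if (!all(d %in% c("0", "1", "?"))) stop("observed pattern must be over {0,1,?}")
  s <- .em_scalars(em, exact)
  acc <- s$one
  for (i in seq_along(g)) {
    f <- if (d[i] == "?") {
      s$g
    } else if (g[i] == "0") {
      if (d[i] == "1") s$a * (s$one - s$g) else (s$one - s$a) * (s$one - s$g)
    } else {
      if (d[i] == "0") s$b * (s$one - s$g) else (s$one - s$b) * (s$one - s$g)
    }
    acc <- acc * f
  }
  acc
}

#' Push a pattern distribution through the error/missingness channel
#'
#' The enumeration oracle: for every observable pattern (over `{0,1}`, plus
#' `?` when missingness is active) it sums, over all true patterns, the base
#' probability times the per-cell channel probability. This reproduces the
#' table-style enumeration of single and multiple flips and is the
#' independent check for the closed-form quartet and triplet formulas.
#'
#' @param base a `pattern_distribution` over `{0,1}` patterns.
#' @param em an [error_model()].
#' @param exact `"auto"` (exact when both inputs carry exact values), or
#'   logical.
#' @return a `pattern_distribution` over observable patterns.
#' @export
corrupted_pattern_distribution <- function(base, em, exact = "auto") {
  if (identical(exact, "auto")) exact <- !is.null(base$exact) && em$exact
  m <- length(base$labels)
  s <- .em_scalars(em, exact)
  with_missing <- if (exact) s$g > ratio(0) else s$g > 0
  alph <- if (with_missing) c("0", "1", "?") else c("0", "1")
  obs <- do.call(expand.grid,
                 c(rep(list(alph), m), stringsAsFactors = FALSE))
  obs_pat <- do.call(paste0, obs)
  K <- 2^m
  gbit <- matrix(0L, nrow = K, ncol = m)
  for (i in seq_len(m)) gbit[, i] <- bitwAnd(bitwShiftR(0:(K - 1), i - 1L), 1L)
  base_p <- if (exact) base$exact else base$prob
  out_p <- if (exact) NULL else numeric(length(obs_pat))
  out_num <- if (exact) numeric(length(obs_pat)) else NULL
  out_den <- if (exact) numeric(length(obs_pat)) else NULL
  for (j in seq_along(obs_pat)) {
    dch <- as.character(obs[j, ])
    if (exact) {
      acc <- ratio(rep(1, K))
      for (i in seq_len(m)) {
        f <- if (dch[i] == "?") {
          .ratio_ifelse(rep(TRUE, K), s$g, s$g)
        } else if (dch[i] == "1") {
          .ratio_ifelse(gbit[, i] == 1L,
                        (s$one - s$b) * (s$one - s$g),
                        s$a * (s$one - s$g))
        } else {
          .ratio_ifelse(gbit[, i] == 1L,
                        s$b * (s$one - s$g),
                        (s$one - s$a) * (s$one - s$g))
        }
        acc <- acc * f
      }
      tot <- sum(acc * base_p)
      out_num[j] <- tot$num
      out_den[j] <- tot$den
    } else {
      acc <- rep(1, K)
      for (i in seq_len(m)) {
        f <- if (dch[i] == "?") {
          rep(s$g, K)
        } else if (dch[i] == "1") {
          ifelse(gbit[, i] == 1L, (1 - s$b) * (1 - s$g), s$a * (1 - s$g))
        } else {
          ifelse(gbit[, i] == 1L, s$b * (1 - s$g), (1 - s$a) * (1 - s$g))
        }
        acc <- acc * f
      }
      out_p[j] <- sum(acc * base_p)
    }
  }
  res <- list(labels = base$labels, patterns = obs_pat, exact = NULL)
  if (exact) {
    res$exact <- ratio(out_num, out_den)
    res$prob <- as.numeric(res$exact)
  } else {
    res$prob <- out_p
  }
  names(res$prob) <- obs_pat
  class(res) <- "pattern_distribution"
  res
}

# scalar accessor into a pattern distribution
.pd_at <- function(pd, pattern, exact) {
  i <- match(pattern, pd$patterns)
  if (exact) pd$exact[i] else pd$prob[[i]]
}

#' Quartet probabilities under the error-and-missingness model
#'
#' Closed-form probabilities of the three quartet topologies on four cells,
#' obtained from the IS pattern distribution of the restricted sub-model.
#' Only fully observed 2-vs-2 patterns are quartet-informative, so every
#' base pattern probability picks up a factor (1-gamma)^4; errors then mix
#' patterns with weights that leave the background term `f` (shared by all
#' three topologies) plus retention and leakage coefficients. The pairwise
#' difference collapses to
#' (1-(alpha+beta))^2 (1-gamma)^4 (P_IS(q_i) - P_IS(q_j)).
#'
#' @param sigma a rooted `lineage_tree` with probabilities.
#' @param subset four leaf labels; topologies are indexed against the sorted
#'   labels: q1 = s1,s2|s3,s4; q2 = s1,s3|s2,s4; q3 = s1,s4|s2,s3.
#' @param em an [error_model()].
#' @param exact `"auto"`, or logical; exact needs exact tree numerators and
#'   a ratio-valued `em`.
#' @return a `quartet_distribution`: list with `labels`, `q` (numeric,
#'   named by topology), `f`, `q_is` (IS probabilities before the channel)
#'   and exact counterparts when applicable.
#' @export
quartet_distribution_uem <- function(sigma, subset, em, exact = "auto") {
  subset <- sort(as.character(subset), method = "radix")
  if (length(subset) != 4) stop("need exactly four labels")
  pd <- is_pattern_distribution(sigma, subset)
  if (identical(exact, "auto")) exact <- !is.null(pd$exact) && em$exact
  s <- .em_scalars(em, exact)
  a <- s$a; b <- s$b; one <- s$one
  gs <- (one - s$g)^4
  P <- function(pat) gs * .pd_at(pd, pat, exact)
  f <- (2 * a^2 * (one - a)^2) * P("0000") +
    (2 * b^2 * (one - b)^2) * P("1111") +
    ((a * (one - a)^2 * (one - b)) + (a^2 * (one - a) * b)) *
      (P("0001") + P("0010") + P("0100") + P("1000")) +
    ((b * (one - b)^2 * (one - a)) + (b^2 * (one - b) * a)) *
      (P("1110") + P("1101") + P("1011") + P("0111"))
  qis <- list(P("1100") + P("0011"),
              P("1010") + P("0101"),
              P("1001") + P("0110"))
  keepc <- (one - a)^2 * (one - b)^2 + a^2 * b^2
  crossc <- 2 * a * b * (one - a) * (one - b)
  qq <- vector("list", 3)
  for (i in 1:3) {
    jk <- setdiff(1:3, i)
    qq[[i]] <- f + keepc * qis[[i]] +
      crossc * (qis[[jk[1]]] + qis[[jk[2]]])
  }
  nm <- vapply(1:3, function(i) .quartet_name(subset, i), "")
  # IS probabilities without the missingness scaling
  qis_plain <- c(.pd_at(pd, "1100", FALSE) + .pd_at(pd, "0011", FALSE),
                 .pd_at(pd, "1010", FALSE) + .pd_at(pd, "0101", FALSE),
                 .pd_at(pd, "1001", FALSE) + .pd_at(pd, "0110", FALSE))
  out <- list(labels = subset,
              q = structure(vapply(qq, as.numeric, 0), names = nm),
              f = as.numeric(f),
              q_is = structure(qis_plain, names = nm))
  if (exact) {
    out$q_exact <- .ratio_c(qq[[1]], qq[[2]], qq[[3]])
    out$f_exact <- f
  }
  class(out) <- "quartet_distribution"
  out
}

#' Triplet probabilities under the error-and-missingness model
#'
#' Closed-form probabilities of the three rooted triplets on three cells.
#' A triplet is implied by a pattern with two derived (1) cells and one
#' ancestral (0) cell, so rooting matters. The background term `g` collects
#' flips out of the invariant patterns; singleton patterns x and triplet
#' patterns t mix with coefficients in alpha and beta. Unlike quartets, the
#' pairwise difference keeps a term proportional to alpha times the
#' difference of singleton-pattern probabilities, which is what permits
#' anomalous triplets when alpha > 0.
#'
#' @param sigma a rooted `lineage_tree` with probabilities.
#' @param subset three leaf labels; triplets are indexed against the sorted
#'   labels by their outgroup: t1 = s1|s2,s3; t2 = s2|s1,s3; t3 = s3|s1,s2.
#' @inheritParams quartet_distribution_uem
#' @return a `triplet_distribution`: list with `labels`, `t` (named
#'   numeric), `g`, `t_is`, `x_is`, and exact counterparts when applicable.
#' @export
triplet_distribution_uem <- function(sigma, subset, em, exact = "auto") {
  if (!isTRUE(sigma$rooted)) stop("triplet probabilities need a rooted tree")
  subset <- sort(as.character(subset), method = "radix")
  if (length(subset) != 3) stop("need exactly three labels")
  pd <- is_pattern_distribution(sigma, subset)
  if (identical(exact, "auto")) exact <- !is.null(pd$exact) && em$exact
  s <- .em_scalars(em, exact)
  a <- s$a; b <- s$b; one <- s$one
  gs <- (one - s$g)^3
  P <- function(pat) gs * .pd_at(pd, pat, exact)
  # x_i: only cell i derived; t_i: cell i ancestral, other two derived
  xpat <- c("100", "010", "001")
  tpat <- c("011", "101", "110")
  gbg <- a^2 * (one - a) * P("000") + b * (one - b)^2 * P("111")
  tt <- vector("list", 3)
  for (i in 1:3) {
    jk <- setdiff(1:3, i)
    tt[[i]] <- gbg +
      a^2 * b * P(xpat[i]) +
      a * (one - a) * (one - b) * (P(xpat[jk[1]]) + P(xpat[jk[2]])) +
      (one - a) * (one - b)^2 * P(tpat[i]) +
      a * b * (one - b) * (P(tpat[jk[1]]) + P(tpat[jk[2]]))
  }
  nm <- vapply(1:3, function(i) .triplet_name(subset, i), "")
  out <- list(labels = subset,
              t = structure(vapply(tt, as.numeric, 0), names = nm),
              g = as.numeric(gbg),
              t_is = structure(vapply(tpat, function(p) .pd_at(pd, p, FALSE), 0),
                               names = nm),
              x_is = structure(vapply(xpat, function(p) .pd_at(pd, p, FALSE), 0),
                               names = subset))
  if (exact) {
    out$t_exact <- .ratio_c(tt[[1]], tt[[2]], tt[[3]])
    out$g_exact <- gbg
    out$x_is_exact <- .ratio_c(.pd_at(pd, "100", TRUE), .pd_at(pd, "010", TRUE),
                               .pd_at(pd, "001", TRUE))
    out$t_is_exact <- .ratio_c(.pd_at(pd, "011", TRUE), .pd_at(pd, "101", TRUE),
                               .pd_at(pd, "110", TRUE))
  }
  class(out) <- "triplet_distribution"
  out
}

#' Anomalous-triplet condition
#'
#' Given IS probabilities of the singleton patterns (`px_i`, `px_j`) and of
#' the triplet patterns (`pt_i`, `pt_j`) for the displayed triplet i and an
#' alternative j, the alternative is anomalous under the error channel
#' exactly when
#' (alpha / (1 - beta)) (px_i - px_j) - (pt_i - pt_j) > 0.
#' Missingness scales both differences equally and cancels.
#'
#' @param px_i,px_j,pt_i,pt_j probabilities (numeric or [ratio()]).
#' @param em an [error_model()].
#' @return logical.
#' @export
triplet_anomaly_condition <- function(px_i, px_j, pt_i, pt_j, em) {
  exact <- em$exact && is_ratio(px_i) && is_ratio(px_j) &&
    is_ratio(pt_i) && is_ratio(pt_j)
  s <- .em_scalars(em, exact)
  if (!exact && s$b == 1) stop("beta = 1 leaves the condition undefined")
  lhs <- (s$a / (s$one - s$b)) * (px_i - px_j) - (pt_i - pt_j)
  if (exact) lhs > ratio(0) else lhs > 0
}

#' Quartet signal retention under the error channel
#'
#' The coefficient by which the channel shrinks pairwise differences of
#' quartet probabilities: both the expanded polynomial
#' ((1-b)^2 (1-a)^2 + b^2 a^2) - 2 b (1-b) a (1-a) and its factored form
#' (1-(a+b))^2 are returned; they are algebraically identical, positive
#' whenever alpha + beta != 1, and zero on that line.
#'
#' @param em an [error_model()].
#' @param exact logical; exact rational evaluation.
#' @return list with `expanded` and `factored`.
#' @export
quartet_error_gap <- function(em, exact = FALSE) {
  s <- .em_scalars(em, exact)
  a <- s$a; b <- s$b; one <- s$one
  list(expanded = ((one - b)^2 * (one - a)^2 + b^2 * a^2) -
         2 * b * (one - b) * a * (one - a),
       factored = (one - (a + b))^2)
}

#' Scan a model tree for anomalous quartets or triplets
#'
#' For every subset of four (or three) cells, compares the
#' error-and-missingness probabilities of the three topologies against the
#' topology actually displayed by the model tree. An alternative is
#' anomalous when its probability strictly exceeds the displayed topology's.
#' When the restriction is a star (or non-binary rooted triple), the model
#' requires the three probabilities to be equal; topologies exceeding the
#' minimum beyond tolerance are reported as violations of that equality.
#'
#' @param sigma a rooted `lineage_tree` with probabilities.
#' @param em an [error_model()].
#' @param mode `"quartet"` or `"triplet"`.
#' @param subsets optional list of label vectors to scan; default is every
#'   subset of the right size (refused above `max_subsets`).
#' @param max_subsets cap on the size of a full scan.
#' @param exact `"auto"` or logical.
#' @param tol strict-inequality margin for floating-point comparisons;
#'   ignored in exact mode, where comparisons are exact.
#' @return an `anomaly_report` data.frame with one row per subset scanned:
#'   the subset, its displayed topology, the three topology names and model
#'   probabilities, and the anomalous alternatives (comma-joined, empty if
#'   none).
#' @export
find_anomalies <- function(sigma, em, mode = c("quartet", "triplet"),
                           subsets = NULL, max_subsets = 1e6,
                           exact = "auto", tol = 1e-12) {
  mode <- match.arg(mode)
  size <- if (mode == "quartet") 4L else 3L
  labs <- .sorted_labels(sigma)
  if (is.null(subsets)) {
    if (choose(length(labs), size) > max_subsets) {
      stop("full scan of ", choose(length(labs), size),
           " subsets exceeds max_subsets; pass an explicit subset list")
    }
    cm <- utils::combn(labs, size)
    subsets <- lapply(seq_len(ncol(cm)), function(j) cm[, j])
  }
  rows <- vector("list", length(subsets))
  for (si in seq_along(subsets)) {
    sub <- sort(as.character(subsets[[si]]), method = "radix")
    if (mode == "quartet") {
      disp <- displayed_quartet(sigma, sub)$topology
      dist <- quartet_distribution_uem(sigma, sub, em, exact = exact)
      pv <- dist$q
      pe <- dist$q_exact
      nm <- names(dist$q)
      disp_name <- if (is.na(disp)) "star" else nm[disp]
    } else {
      disp <- displayed_triplet(sigma, sub)$outgroup
      dist <- triplet_distribution_uem(sigma, sub, em, exact = exact)
      pv <- dist$t
      pe <- dist$t_exact
      nm <- names(dist$t)
      disp_name <- if (is.na(disp)) "nonbinary" else nm[disp]
    }
    anom <- logical(3)
    if (!is.null(pe)) {
      if (is.na(disp)) {
        mn <- min(pe)
        for (j in 1:3) anom[j] <- pe[j] > mn
      } else {
        for (j in setdiff(1:3, disp)) anom[j] <- pe[j] > pe[disp]
      }
    } else {
      if (is.na(disp)) {
        anom <- pv > min(pv) + tol
      } else {
        anom <- pv > pv[disp] + tol
        anom[disp] <- FALSE
      }
    }
    rows[[si]] <- data.frame(
      subset = paste(sub, collapse = ","),
      displayed = disp_name,
      topo_1 = nm[1], p_1 = pv[1],
      topo_2 = nm[2], p_2 = pv[2],
      topo_3 = nm[3], p_3 = pv[3],
      anomalous = paste(nm[anom], collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anomaly_report", "data.frame")
  out
}

#' Write an anomaly report as TSV
#' @param report an `anomaly_report`.
#' @param file output path.
#' @export
write_anomaly_report <- function(report, file) {
  utils::write.table(report, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
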