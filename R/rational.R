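#' Exact rational numbers
#'
#' A small vectorised rational-number type used by the analytic probability
#' calculators. Pattern probabilities on the worked lineage fixtures are
#' ratios of small integers (denominators like 1012), and anomaly detection
#' compares probabilities by strict inequality, so the default analytic path
#' keeps numerators and denominators explicit instead of rounding through
#' floating point. Values are stored as doubles and every operation reduces
#' by the gcd; an error is raised if a numerator or denominator would exceed
#' 2^53, where double-backed integer arithmetic stops being exact.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), non-zero; recycled against `num`.
#'
#' @return An object of class `ratio`.
#' @examples
#' ratio(1, 1012) + ratio(1009, 1012)
#' ratio(1, 1000) / (1 - ratio(1, 5)) # alpha / (1 - beta)
#' @export
ratio <- function(num, den = 1) {
  num <- as.double(num)
  den <- as.double(den)
  if (any(!is.finite(num)) || any(!is.finite(den))) {
    stop("ratio() requires finite values")
  }
  if (any(num != trunc(num)) || any(den != trunc(den))) {
    stop("ratio() requires integer-valued numerator and denominator")
  }
  if (any(den == 0)) stop("zero denominator")
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  .ratio_new(num, den)
}

.ratio_new <- function(num, den) {
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- mapply(.gcd2, abs(num), den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  if (any(abs(num) > 2^53) || any(den > 2^53)) {
    stop("exact rational overflow: magnitude exceeds 2^53")
  }
  structure(list(num = num, den = den), class = "ratio")
}

.gcd2 <- function(a, b) {
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

#' @export
is_ratio <- function(x) inherits(x, "ratio")

.as_ratio <- function(x) {
  if (is_ratio(x)) return(x)
  if (is.numeric(x) && all(x == trunc(x))) return(ratio(x))
  stop("cannot mix non-integer numerics with exact rationals")
}

#' @export
length.ratio <- function(x) length(x$num)

#' @export
`[.ratio` <- function(x, i) .ratio_new(x$num[i], x$den[i])

#' @export
as.double.ratio <- function(x, ...) x$num / x$den

#' @export
as.numeric.ratio <- function(x, ...) x$num / x$den

#' @export
format.ratio <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.ratio <- function(x, ...) {
  cat("<ratio> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.ratio <- function(e1, e2) {
  if (missing(e2)) {
    e1 <- .as_ratio(e1)
    return(switch(.Generic,
      "-" = .ratio_new(-e1$num, e1$den),
      "+" = e1,
      stop("unsupported unary operator for ratio: ", .Generic)
    ))
  }
  if (.Generic == "^") {
    e1 <- .as_ratio(e1)
    if (is_ratio(e2)) {
      if (any(e2$den != 1)) stop("ratio exponent must be an integer")
      e2 <- e2$num
    }
    if (any(e2 != trunc(e2)) || any(e2 < 0)) {
      stop("ratio exponent must be a non-negative integer")
    }
    return(.ratio_new(e1$num^e2, e1$den^e2))
  }
  e1 <- .as_ratio(e1)
  e2 <- .as_ratio(e2)
  n1 <- e1$num; d1 <- e1$den
  n2 <- e2$num; d2 <- e2$den
  # cross-reduce before multiplying to delay overflow
  g <- mapply(.gcd2, d1, d2)
  switch(.Generic,
    "+" = .ratio_new(n1 * (d2 / g) + n2 * (d1 / g), (d1 / g) * d2),
    "-" = .ratio_new(n1 * (d2 / g) - n2 * (d1 / g), (d1 / g) * d2),
    "*" = {
      ga <- mapply(.gcd2, abs(n1), d2)
      gb <- mapply(.gcd2, abs(n2), d1)
      .ratio_new((n1 / ga) * (n2 / gb), (d1 / gb) * (d2 / ga))
    },
    "/" = {
      if (any(n2 == 0)) stop("division by zero ratio")
      ga <- mapply(.gcd2, abs(n1), abs(n2))
      gb <- mapply(.gcd2, d1, d2)
      .ratio_new((n1 / ga) * (d2 / gb), (d1 / gb) * (n2 / ga))
    },
    "==" = n1 * d2 == n2 * d1,
    "!=" = n1 * d2 != n2 * d1,
    "<"  = n1 * d2 <  n2 * d1,
    "<=" = n1 * d2 <= n2 * d1,
    ">"  = n1 * d2 >  n2 * d1,
    ">=" = n1 * d2 >= n2 * d1,
    stop("unsupported operator for ratio: ", .Generic)
  )
}

#' @export
Summary.ratio <- function(..., na.rm = FALSE) {
  args <- list(...)
  x <- args[[1]]
  switch(.Generic,
    "sum" = {
      acc <- ratio(0)
      for (a in args) {
        a <- .as_ratio(a)
        for (i in seq_along(a)) acc <- acc + a[i]
      }
      acc
    },
    "min" = {
      acc <- NULL
      for (a in args) {
        a <- .as_ratio(a)
        for (i in seq_along(a)) {
          if (is.null(acc) || a[i] < acc) acc <- a[i]
        }
      }
      acc
    },
    "max" = {
      acc <- NULL
      for (a in args) {
        a <- .as_ratio(a)
        for (i in seq_along(a)) {
          if (is.null(acc) || a[i] > acc) acc <- a[i]
        }
      }
      acc
    },
    stop("unsupported summary for ratio: ", .Generic)
  )
}

# elementwise select between two ratio vectors (recycled)
.ratio_ifelse <- function(cond, yes, no) {
  yn <- rep_len(yes$num, length(cond)); yd <- rep_len(yes$den, length(cond))
  nn <- rep_len(no$num, length(cond));  nd <- rep_len(no$den, length(cond))
  .ratio_new(ifelse(cond, yn, nn), ifelse(cond, yd, nd))
}

# concatenate ratio values
.ratio_c <- function(...) {
  parts <- lapply(list(...), .as_ratio)
  .ratio_new(unlist(lapply(parts, `[[`, "num")),
             unlist(lapply(parts, `[[`, "den")))
}
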