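#' Wallenius noncentral hypergeometric upper tail
#'
#' Computes the inclusive upper-tail probability \eqn{P(X \ge x)} of
#' Wallenius' noncentral hypergeometric distribution: the number of "white"
#' balls obtained when \code{n} balls are drawn one at a time, without
#' replacement, from an urn holding \code{m1} white and \code{m2} black
#' balls, each remaining white ball being \code{odds} times as likely to be
#' drawn as each remaining black ball.  With \code{odds = 1} the
#' distribution reduces to the central hypergeometric.
#'
#' This is the reference distribution for biased gene set
#' over-representation tests: \code{m1} genes in the set, \code{m2} genes on
#' the rest of the array, \code{n} significant genes "drawn", and
#' \code{odds} the relative enrichment propensity implied by the probability
#' weighting function (see [estimatePWF()] and [testGeneSets()]).
#'
#' The tail is evaluated by summing exact probability masses over the
#' shorter side of the support; each mass is computed from the integral
#' representation of the distribution with double-exponential quadrature in
#' log space, and is numerically stable for urns up to roughly \eqn{10^5}
#' balls.
#'
#' @param x integer vector of observed white-ball counts.  Values at or
#'   below the lower support end give 1; values above the upper support end
#'   give 0.
#' @param m1,m2 non-negative integer vectors: white and black ball counts.
#' @param n integer vector of draws, \code{0 <= n <= m1 + m2}.
#' @param odds positive numeric vector of white:black sampling odds.
#' @return numeric vector of upper-tail probabilities, recycled to the
#'   common length of the arguments.
#' @examples
#' walleniusUpperTail(2, m1 = 2, m2 = 2, n = 2, odds = 1)  # 1/6
#' walleniusUpperTail(2, m1 = 2, m2 = 1, n = 2, odds = 2)  # 8/15
#' @seealso [walleniusOracle()] for an exhaustive-enumeration cross-check on
#'   tiny urns.
#' @export
walleniusUpperTail <- function(x, m1, m2, n, odds = 1) {
  N <- max(length(x), length(m1), length(m2), length(n), length(odds))
  x <- rep_len(as.numeric(x), N)
  m1 <- rep_len(as.numeric(m1), N)
  m2 <- rep_len(as.numeric(m2), N)
  n <- rep_len(as.numeric(n), N)
  odds <- rep_len(as.numeric(odds), N)
  if (anyNA(c(x, m1, m2, n, odds)))
    stop("missing values are not allowed in urn parameters")
  if (any(odds <= 0))
    stop("'odds' must be strictly positive")
  if (any(m1 < 0) || any(m2 < 0))
    stop("'m1' and 'm2' must be non-negative")
  if (any(n < 0) || any(n > m1 + m2))
    stop("'n' must satisfy 0 <= n <= m1 + m2")
  if (any(x != round(x)) || any(m1 != round(m1)) || any(m2 != round(m2)) ||
      any(n != round(n)))
    stop("'x', 'm1', 'm2' and 'n' must be integers")
  .wnchgUpperTailCpp(x, m1, m2, n, odds)
}

#' Exact Wallenius tail by exhaustive draw enumeration
#'
#' Independent brute-force evaluation of the same upper-tail probability as
#' [walleniusUpperTail()], intended as a correctness anchor on tiny urns.
#' Every ordered draw sequence is enumerated recursively; a sequence's
#' probability is the product, over draws, of the weight of the chosen ball
#' divided by the total remaining weight.  Refuses urns with more than 12
#' balls (the sequence tree grows as \eqn{2^n}).
#'
#' @inheritParams walleniusUpperTail
#' @return scalar upper-tail probability \eqn{P(X \ge x)}.
#' @export
walleniusOracle <- function(x, m1, m2, n, odds = 1) {
  stopifnot(length(x) == 1, length(m1) == 1, length(m2) == 1,
            length(n) == 1, length(odds) == 1)
  pmf <- .walleniusPmfEnum(m1, m2, n, odds)
  x <- max(x, 0)
  if (x > n) return(0)
  sum(pmf[seq.int(x + 1L, n + 1L)])
}

# Full pmf vector over x = 0..n by enumerating every ordered draw sequence.
# Only suitable for m1 + m2 <= 12.
.walleniusPmfEnum <- function(m1, m2, n, odds) {
  if (m1 + m2 > 12)
    stop("urn too large for exhaustive enumeration (m1 + m2 must be <= 12)")
  if (odds <= 0) stop("'odds' must be strictly positive")
  if (n > m1 + m2) stop("'n' must satisfy n <= m1 + m2")
  pmf <- numeric(n + 1)
  recurse <- function(w, b, drawn, x, prob) {
    if (drawn == n) {
      pmf[x + 1L] <<- pmf[x + 1L] + prob
      return(invisible(NULL))
    }
    tot <- odds * w + b
    if (w > 0) recurse(w - 1, b, drawn + 1L, x + 1L, prob * odds * w / tot)
    if (b > 0) recurse(w, b - 1, drawn + 1L, x, prob * b / tot)
    invisible(NULL)
  }
  recurse(m1, m2, 0L, 0L, 1)
  pmf
}
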