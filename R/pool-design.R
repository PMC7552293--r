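# Mathematical-expectation (ME) design of a two-stage pooled screen:
# expected reaction counts as a function of pool size, the design curve and
# its optimum, pilot MAF estimation, and a cost-savings summary.

#' Expected reaction count of a two-stage pooled screen
#'
#' For `N` samples screened in pools of `a` with positive frequency `p`, the
#' expected number of PCR reactions is
#' \deqn{n = N \left( \frac{1}{a}(1-p)^a + \left(1+\frac{1}{a}\right)
#'   \left(1-(1-p)^a\right) \right),}
#' i.e. one reaction per pool plus a full-pool retest of every pool that is
#' not genotypically uniform. This is algebraically the classic Dorfman
#' group-testing expectation \eqn{N(1/a + 1 - (1-p)^a)}.
#'
#' @param N total sample size (>= 1).
#' @param p assumed frequency of detection-positive samples, in `[0, 1]`.
#'   Following field practice this is the estimated minor-allele frequency
#'   plugged in directly; see [screen_pools()] for the carrier-frequency
#'   simulation counterpart.
#' @param a pool size (individuals per group, >= 1).
#' @return data.frame (one row per `a`) with columns `a`, `n_expected`, `N`,
#'   `p`.
#' @examples
#' expected_reactions(2350, 0.01, 11) # 459.6 reactions
#' @export
expected_reactions <- function(N, p, a) {
  if (any(N < 1) || any(N != as.integer(N))) {
    stop_input("N must be a positive integer")
  }
  if (any(p < 0 | p > 1)) stop_input("p must lie in [0, 1]")
  if (any(a < 1) || any(a != as.integer(a))) {
    stop_input("pool size a must be a positive integer")
  }
  q <- (1 - p)^a
  n_expected <- N * (1 / a * q + (1 + 1 / a) * (1 - q))
  data.frame(a = as.integer(a), n_expected = n_expected, N = N, p = p)
}

#' Design curve of expected reactions over a pool-size range
#'
#' Evaluates [expected_reactions()] at every integer pool size in
#' `[a_min, a_max]` and flags the optimum (minimal expected reaction count;
#' ties broken toward the smaller pool).
#'
#' @inheritParams expected_reactions
#' @param a_min,a_max inclusive integer pool-size range.
#' @return data.frame of class `design_curve`: columns `a`, `n_expected`,
#'   `is_optimum`; attributes `N`, `p`.
#' @examples
#' curve <- design_curve(2350, 0.01, 3, 20)
#' curve[curve$is_optimum, ] # a = 11, 459.6
#' @export
design_curve <- function(N, p, a_min = 3, a_max = 20) {
  if (a_min < 1 || a_min > a_max) {
    stop_input("need 1 <= a_min <= a_max, got [%s, %s]", a_min, a_max)
  }
  pts <- expected_reactions(N, p, seq.int(a_min, a_max))
  curve <- data.frame(a = pts$a, n_expected = pts$n_expected)
  curve$is_optimum <- seq_len(nrow(curve)) == which.min(curve$n_expected)
  attr(curve, "N") <- N
  attr(curve, "p") <- p
  class(curve) <- c("design_curve", "data.frame")
  curve
}

#' @export
print.design_curve <- function(x, ...) {
  opt <- x[x$is_optimum, ]
  cat(sprintf("Pooled-screen design curve: N = %d, p = %g, a in [%d, %d]\n",
              attr(x, "N"), attr(x, "p"), min(x$a), max(x$a)))
  cat(sprintf("Optimum: pool size a = %d, expected reactions = %.1f\n",
              opt$a, opt$n_expected))
  print.data.frame(transform(as.data.frame(x),
                             n_expected = round(n_expected, 1)), ...)
  invisible(x)
}

#' Estimate minor-allele frequency from a pilot genotyping sample
#'
#' @param counts integer vector `c(n_II, n_ID, n_DD)` of pilot genotype
#'   counts (wild-type homozygote, heterozygote, deletion homozygote).
#' @return list with `n_pilot`, `counts`, and `maf_hat` (allele count of the
#'   rarer allele over `2 * n_pilot`, folded to `<= 0.5`).
#' @examples
#' estimate_pilot_maf(c(49, 1, 0))$maf_hat # 0.01
#' @export
estimate_pilot_maf <- function(counts) {
  if (length(counts) != 3 || any(counts < 0)) {
    stop_input("counts must be three nonnegative genotype counts (II, ID, DD)")
  }
  n <- sum(counts)
  if (n < 1) stop_input("pilot sample is empty")
  f_del <- (counts[2] + 2 * counts[3]) / (2 * n)
  list(n_pilot = n,
       counts = stats::setNames(as.integer(counts), c("n_II", "n_ID", "n_DD")),
       maf_hat = min(f_del, 1 - f_del))
}

#' Reaction-count savings of the pooled design relative to one-by-one PCR
#'
#' @param curve a [design_curve()].
#' @return list with the optimal pool size, expected reactions at the
#'   optimum, the one-by-one cost `N`, and their ratio.
#' @export
savings_report <- function(curve) {
  stopifnot(inherits(curve, "design_curve"))
  opt <- curve[curve$is_optimum, ]
  N <- attr(curve, "N")
  list(a_optimum = opt$a,
       n_expected = opt$n_expected,
       n_one_by_one = N,
       ratio = opt$n_expected / N)
}
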