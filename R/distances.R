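.check_shared_grid <- function(p, q) {
  if (!inherits(p, "pmf") || !inherits(q, "pmf")) {
    stop("both arguments must be pmf objects", call. = FALSE)
  }
  if (length(p$grid) != length(q$grid) ||
      !isTRUE(all.equal(p$grid, q$grid, tolerance = 1e-12))) {
    stop("the two pmfs must share the same grid", call. = FALSE)
  }
}

#' Hellinger distance between two probability mass functions
#'
#' The primary distribution distance of the workflow:
#' \deqn{H(P,Q) = \frac{1}{\sqrt 2}\sqrt{\sum_{m=1}^{k}(\sqrt{P_m}-\sqrt{Q_m})^2}}
#' It is symmetric, bounded in \eqn{[0,1]}, 0 iff the distributions are
#' identical and 1 iff their supports are disjoint, and makes no assumption
#' about the shape of either distribution.
#'
#' @param p,q [pmf()] objects on the same grid (as produced by
#'   [estimate_pair_pmfs()]).
#' @return Distance in `[0, 1]`.
#' @examples
#' g <- 1:3
#' hellinger(pmf(g, c(0.5, 0.5, 0)), pmf(g, c(0, 0.5, 0.5)))  # 1/sqrt(2)
#' @export
hellinger <- function(p, q) {
  .check_shared_grid(p, q)
  h2 <- sum((sqrt(p$masses) - sqrt(q$masses))^2) / 2
  sqrt(max(0, min(1, h2)))
}

#' Jensen-Shannon distance between two probability mass functions
#'
#' Square root of the Jensen-Shannon divergence, the symmetrised
#' Kullback-Leibler divergence of each distribution against the mixture
#' \eqn{M = (P+Q)/2}. With base-2 logarithms (the default) it lies in
#' \eqn{[0,1]}, matching the range of [hellinger()]. Terms with zero mass
#' contribute nothing (`0 log 0 = 0`).
#'
#' @inheritParams hellinger
#' @param log_base 2 (default, unit range) or `exp(1)`.
#' @return Distance in `[0, 1]` for base 2.
#' @examples
#' g <- 1:2
#' js_distance(pmf(g, c(1, 0)), pmf(g, c(0.5, 0.5)))  # sqrt(0.311278...)
#' @export
js_distance <- function(p, q, log_base = 2) {
  .check_shared_grid(p, q)
  .js_from_masses(p$masses, q$masses, log_base)
}

.js_from_masses <- function(a, b, log_base = 2) {
  m <- (a + b) / 2
  kl <- function(u) {
    i <- u > 0
    sum(u[i] * (log(u[i]) - log(m[i])))
  }
  jsd <- (kl(a) + kl(b)) / (2 * log(log_base))
  sqrt(max(0, jsd))
}

#' Kolmogorov-Smirnov distance between two raw expression samples
#'
#' Supremum of the absolute difference between the two empirical cumulative
#' distribution functions. Unlike [hellinger()] and [js_distance()] this
#' operates on the raw per-cell values directly, with no density estimation
#' step.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Distance in `[0, 1]`.
#' @examples
#' ks_distance(c(1, 3), c(2, 4))  # 0.5
#' @export
ks_distance <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  .ks_sorted(sort(x), sort(y))
}

# sup |F_x - F_y| evaluated at all pooled data points; inputs pre-sorted
.ks_sorted <- function(sx, sy) {
  z <- sort(c(sx, sy))
  max(abs(findInterval(z, sx) / length(sx) -
          findInterval(z, sy) / length(sy)))
}
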