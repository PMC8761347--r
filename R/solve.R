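#' Solve the reference-stratum rate from a consistency equation
#'
#' The disaggregation step at each cycle reduces to a scalar root-find: given
#' strata of sizes `alive_k` with rates tied to a reference rate `m` through
#' ratios `r_k` (reference first, `r_1 = 1`), find the `m >= 0` with
#' \deqn{\sum_k alive_k \exp(-r_k m) = target.}
#' The left side is strictly decreasing in `m` (for any stratum with
#' `alive_k > 0`), so the root is unique. A safeguarded Newton iteration with
#' the analytic derivative \eqn{-\sum_k r_k alive_k \exp(-r_k m)} is used,
#' with every iterate kept inside a shrinking bisection bracket; the bracket's
#' upper end starts at `max(implied aggregate rate, 1)` and doubles until the
#' residual changes sign.
#'
#' @param alive_by_stratum persons alive per stratum at the start of the
#'   cycle (non-negative).
#' @param ratios positive rate ratios, reference stratum first (`ratios[1] = 1`).
#' @param aggregate_survivors target total survivors at the end of the cycle;
#'   must satisfy `0 < aggregate_survivors <= sum(alive_by_stratum)`.
#' @param tol relative residual tolerance (default 1e-12 of the target).
#' @param rate_tol absolute tolerance on the rate bracket (default 1e-14).
#' @return the reference-stratum rate `m >= 0`, with residual
#'   `|sum_k alive_k exp(-r_k m) - target| <= tol * target`.
#' @examples
#' # Fig-1-style split: two equal strata, ratio 2, aggregate rate 0.01
#' solve_reference_rate(c(1000, 1000), c(1, 2), 2000 * exp(-0.01))
#' @export
solve_reference_rate <- function(alive_by_stratum, ratios, aggregate_survivors,
                                 tol = 1e-12, rate_tol = 1e-14) {
  alive <- as.numeric(alive_by_stratum)
  r <- as.numeric(ratios)
  target <- aggregate_survivors
  if (length(alive) != length(r)) {
    stop("`alive_by_stratum` and `ratios` must have equal length", call. = FALSE)
  }
  if (any(alive < 0)) stop("stratum counts must be non-negative", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("ratios must be positive and finite", call. = FALSE)
  }
  if (abs(r[1L] - 1) > 1e-12) {
    stop("the reference stratum's ratio must be 1", call. = FALSE)
  }
  total <- sum(alive)
  if (total == 0) {
    if (abs(target) <= tol) return(0)
    stop("no population to survive a positive target", call. = FALSE)
  }
  if (target <= 0) stop("`aggregate_survivors` must be positive", call. = FALSE)
  if (target > total * (1 + 1e-12)) {
    stop(sprintf(paste("infeasible: target survivors (%.6g) exceed the starting",
                       "population (%.6g); no non-negative rate exists"),
                 target, total), call. = FALSE)
  }
  if (target >= total) return(0)

  g <- function(m) sum(alive * exp(-r * m)) - target
  gprime <- function(m) -sum(r * alive * exp(-r * m))

  # bracket [lo, hi] with g(lo) >= 0 > g(hi)
  lo <- 0
  hi <- max(-log(target / total), 1)
  while (g(hi) > 0) hi <- hi * 2

  m <- min(max(-log(target / total), rate_tol), hi)
  for (iter in 1:200) {
    gm <- g(m)
    if (abs(gm) <= tol * target) break
    if (gm > 0) lo <- m else hi <- m
    m_new <- m - gm / gprime(m)
    if (!is.finite(m_new) || m_new <= lo || m_new >= hi) {
      m_new <- (lo + hi) / 2
    }
    if (hi - lo < rate_tol * max(1, m)) {
      m <- (lo + hi) / 2
      break
    }
    m <- m_new
  }
  m
}
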