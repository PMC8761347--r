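#' One mortality step of the lifetable recursion
#'
#' Survival over one annual cycle under a constant-within-cycle mortality rate
#' `m` is exponential: survivors are `alive_prev * exp(-m)` and deaths in the
#' cycle are `alive_prev * (1 - exp(-m))`.
#'
#' @param alive_prev persons alive at the start of the cycle (>= 0).
#' @param rate mortality rate per person-year (>= 0).
#' @return persons alive at the end of the cycle.
#' @examples
#' step_mortality(2000, 0.01)  # ~1980 alive after the first cycle
#' @export
step_mortality <- function(alive_prev, rate) {
  if (any(alive_prev < 0)) stop("`alive_prev` must be non-negative", call. = FALSE)
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  alive_prev * exp(-rate)
}

#' Simulate a mortality/morbidity lifetable
#'
#' Runs the discrete-time cohort recursion `A_t = A_{t-1} exp(-m_t)` from
#' `A_0 = N`, with deaths `D_t = N - A_t`, half-cycle person-years
#' `L_t = (A_t + A_{t-1}) / 2`, and health-adjusted life years (HALYs)
#' `L*_t = L_t (1 - w_t)` where `w_t` is the prevalent YLD (morbidity) rate.
#'
#' @param N initial cohort size (persons, > 0).
#' @param mortality mortality rate per cycle ([rate_schedule] or numeric),
#'   length `T`.
#' @param yld YLD rate `w_t` per cycle; a scalar is recycled to length `T`.
#' @return an object of class `mortality_lifetable`: a list with elements
#'   `N`, `alive` (`A_0..A_T`), `dead`, `life_years` (`L_1..L_T`), `yld_rate`,
#'   `halys`, `cum_halys` and the input `mortality` schedule.
#' @examples
#' lt <- simulate_mortality(2000, 0.01 * 1.2^(0:19))
#' lt$life_years[20]  # 367.4 person-years in the 20th cycle
#' @export
simulate_mortality <- function(N, mortality, yld = 0) {
  if (length(N) != 1L || !is.finite(N) || N <= 0) {
    stop("`N` must be a single positive number", call. = FALSE)
  }
  m <- as.numeric(mortality)
  T <- length(m)
  w <- as.numeric(yld)
  if (length(w) == 1L) w <- rep(w, T)
  if (length(w) != T) {
    stop("`mortality` and `yld` schedules must have equal length", call. = FALSE)
  }
  if (any(m < 0) || any(w < 0)) stop("rates must be non-negative", call. = FALSE)
  alive <- N * exp(-cumsum(c(0, m)))
  life_years <- (alive[-1L] + alive[-(T + 1L)]) / 2
  halys <- life_years * (1 - w)
  structure(list(N = N,
                 alive = alive,
                 dead = N - alive,
                 life_years = life_years,
                 yld_rate = w,
                 halys = halys,
                 cum_halys = cumsum(halys),
                 mortality = m),
            class = "mortality_lifetable")
}

#' @export
print.mortality_lifetable <- function(x, ...) {
  T <- length(x$life_years)
  cat(sprintf("Mortality/morbidity lifetable: N = %g, %d annual cycles\n", x$N, T))
  cat(sprintf("  survivors at end: %.1f (%.1f%%); total HALYs: %.1f\n",
              x$alive[T + 1L], 100 * x$alive[T + 1L] / x$N, x$cum_halys[T]))
  invisible(x)
}

#' @export
as.data.frame.mortality_lifetable <- function(x, ...) {
  T <- length(x$life_years)
  data.frame(cycle = 1:T,
             mortality = x$mortality,
             alive = x$alive[-1L],
             dead = x$dead[-1L],
             life_years = x$life_years,
             yld_rate = x$yld_rate,
             halys = x$halys,
             cum_halys = x$cum_halys)
}

#' @export
plot.mortality_lifetable <- function(x, ylab = "person-years lived", ...) {
  graphics::plot(seq_along(x$life_years), x$life_years, type = "b",
                 xlab = "annual cycle", ylab = ylab, ...)
  invisible(x)
}

#' Simulate a three-compartment disease lifetable
#'
#' Tracks a healthy compartment `S`, a diseased compartment `C` and a dead
#' compartment `D` for one disease. Per cycle, `S_t = S_{t-1} exp(-i_t)`,
#' `C_t = C_{t-1} exp(-f_t) + S_{t-1} (1 - exp(-i_t))` and
#' `D_t = N - S_t - C_t`, with incidence rate `i_t` and case-fatality rate
#' `f_t`. New cases cannot die of the disease within their incident cycle (a
#' deliberate discrete-time simplification; choose a small cycle length if
#' this matters). Remission is not modelled.
#'
#' @param S0,C0 initial healthy and diseased counts (persons, >= 0).
#' @param incidence,fatality per-cycle rate schedules of equal length.
#' @param disease_name label for the disease.
#' @return an object of class `disease_lifetable`: a list with `healthy`
#'   (`S_0..S_T`), `diseased`, `dead`, the rate schedules and `disease_name`.
#' @examples
#' simulate_disease(900, 100, rep(0.05, 10), rep(0.2, 10), "CHD")
#' @export
simulate_disease <- function(S0, C0, incidence, fatality,
                             disease_name = "disease") {
  if (S0 < 0 || C0 < 0) stop("initial compartments must be non-negative", call. = FALSE)
  i <- as.numeric(incidence)
  f <- as.numeric(fatality)
  if (length(i) != length(f)) {
    stop("`incidence` and `fatality` schedules must have equal length", call. = FALSE)
  }
  if (any(i < 0) || any(f < 0)) stop("rates must be non-negative", call. = FALSE)
  T <- length(i)
  N <- S0 + C0
  S <- C <- numeric(T + 1L)
  S[1L] <- S0
  C[1L] <- C0
  for (t in seq_len(T)) {
    S[t + 1L] <- S[t] * exp(-i[t])
    C[t + 1L] <- C[t] * exp(-f[t]) + S[t] * (1 - exp(-i[t]))
  }
  structure(list(healthy = S,
                 diseased = C,
                 dead = N - S - C,
                 incidence = i,
                 fatality = f,
                 N = N,
                 disease_name = disease_name),
            class = "disease_lifetable")
}

#' @export
print.disease_lifetable <- function(x, ...) {
  T <- length(x$incidence)
  cat(sprintf("Disease lifetable (%s): N = %g, %d cycles\n",
              x$disease_name, x$N, T))
  cat(sprintf("  end state: healthy %.1f, diseased %.1f, dead %.1f\n",
              x$healthy[T + 1L], x$diseased[T + 1L], x$dead[T + 1L]))
  invisible(x)
}

#' @export
as.data.frame.disease_lifetable <- function(x, ...) {
  T <- length(x$incidence)
  data.frame(cycle = 1:T,
             incidence = x$incidence,
             fatality = x$fatality,
             healthy = x$healthy[-1L],
             diseased = x$diseased[-1L],
             dead = x$dead[-1L])
}

#' Aggregate rate implied by successive alive counts
#'
#' Inverse of [step_mortality()]: the constant-within-cycle rate that takes
#' `alive_sum_prev` persons to `alive_sum_now`, i.e.
#' `-log(alive_sum_now / alive_sum_prev)`.
#'
#' @param alive_sum_prev,alive_sum_now positive person counts with
#'   `alive_sum_now <= alive_sum_prev`.
#' @return rate per person-year.
#' @export
implied_aggregate_rate <- function(alive_sum_prev, alive_sum_now) {
  if (any(alive_sum_prev <= 0) || any(alive_sum_now <= 0)) {
    stop("alive counts must be positive", call. = FALSE)
  }
  if (any(alive_sum_now > alive_sum_prev)) {
    stop("`alive_sum_now` cannot exceed `alive_sum_prev`", call. = FALSE)
  }
  -log(alive_sum_now / alive_sum_prev)
}
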