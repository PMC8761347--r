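#' Rate ratio and rate difference between two strata
#'
#' Compares the most-deprived stratum's rate to the least-deprived stratum's:
#' ratio `most / least` and difference `most - least` (most minus least, so
#' a disadvantaged stratum with higher mortality gives ratio > 1 and a
#' positive difference).
#'
#' @param rate_most,rate_least positive rates (per person-year).
#' @return named vector `c(ratio, difference)`.
#' @examples
#' rate_gap(0.0176, 0.0111)
#' @export
rate_gap <- function(rate_most, rate_least) {
  rate_most <- unname(rate_most)
  rate_least <- unname(rate_least)
  if (any(rate_least == 0)) stop("rate ratio undefined: `rate_least` is 0", call. = FALSE)
  c(ratio = rate_most / rate_least, difference = rate_most - rate_least)
}

#' Percentage shift of inequality measures towards the null
#'
#' Quantifies how far an intervention moves the between-strata rate ratio
#' towards 1 and the rate difference towards 0, relative to BAU:
#' `shift_rr = (RR_bau - RR_int) / (RR_bau - 1) * 100` and
#' `shift_rd = (RD_bau - RD_int) / RD_bau * 100`.
#'
#' @param bau_ratio,int_ratio rate ratios under BAU and intervention.
#' @param bau_diff,int_diff rate differences under BAU and intervention.
#' @return named vector `c(shift_rr, shift_rd)` in percent; `shift_rr` is
#'   `NA` when the BAU ratio is exactly 1 (null has already been reached).
#' @examples
#' shift_to_null(1.5812, 1.5812, 0.0065, 0.00325)  # (0, 50)
#' @export
shift_to_null <- function(bau_ratio, int_ratio, bau_diff, int_diff) {
  bau_ratio <- unname(bau_ratio)
  int_ratio <- unname(int_ratio)
  bau_diff <- unname(bau_diff)
  int_diff <- unname(int_diff)
  shift_rr <- if (bau_ratio == 1) NA_real_ else
    (bau_ratio - int_ratio) / (bau_ratio - 1) * 100
  if (bau_diff == 0) stop("`bau_diff` must be non-zero", call. = FALSE)
  c(shift_rr = shift_rr,
    shift_rd = (bau_diff - int_diff) / bau_diff * 100)
}

#' HALY ratio and difference between two strata
#'
#' Compares HALYs accrued (mode `"total"`) or HALYs gained relative to BAU
#' (mode `"incremental"`) by the most- vs least-deprived stratum. The
#' convention matches [rate_gap()]: ratio `most / least`, difference
#' `most - least` (so under BAU, where the most deprived accrue fewer HALYs,
#' the ratio is < 1 and the difference negative).
#'
#' @param halys_least,halys_most HALYs for the least and most deprived
#'   stratum; `halys_least` must be non-zero.
#' @param mode `"total"` or `"incremental"` (label only; the arithmetic is
#'   identical).
#' @return named vector `c(ratio, difference)`.
#' @examples
#' haly_gap(1578, 1518)
#' @export
haly_gap <- function(halys_least, halys_most,
                     mode = c("total", "incremental")) {
  mode <- match.arg(mode)
  halys_least <- unname(halys_least)
  halys_most <- unname(halys_most)
  if (any(halys_least == 0)) {
    stop("HALY ratio undefined: least-deprived HALYs are 0", call. = FALSE)
  }
  c(ratio = halys_most / halys_least, difference = halys_most - halys_least)
}

#' Per-cycle inequality table for a stratified run
#'
#' Builds the per-cycle inequality rows comparing the most- and
#' least-deprived strata (by default the last and first stratum, matching
#' deprivation quintiles ordered least to most deprived): all-cause mortality
#' rate ratio and difference, and the HALY ratio and difference. When an
#' intervention run is supplied alongside BAU, shift-to-null percentages and
#' incremental HALY gaps are added. All measures are computed at full
#' precision; round only for presentation.
#'
#' @param strata_bau list of per-stratum BAU [mortality
#'   lifetables][simulate_mortality] (least deprived first).
#' @param strata_int optional list of per-stratum intervention lifetables.
#' @param least,most indices of the strata to compare (default first and
#'   last).
#' @return a data frame with one row per cycle.
#' @export
inequality_table <- function(strata_bau, strata_int = NULL,
                             least = 1L, most = length(strata_bau)) {
  lo <- strata_bau[[least]]
  hi <- strata_bau[[most]]
  T <- length(lo$life_years)
  gaps <- vapply(seq_len(T), function(t) rate_gap(hi$mortality[t], lo$mortality[t]),
                 numeric(2))
  out <- data.frame(cycle = seq_len(T),
                    rate_least = lo$mortality,
                    rate_most = hi$mortality,
                    rate_ratio = gaps["ratio", ],
                    rate_difference = gaps["difference", ],
                    halys_least = lo$halys,
                    halys_most = hi$halys,
                    haly_ratio = hi$halys / lo$halys,
                    haly_difference = hi$halys - lo$halys)
  if (!is.null(strata_int)) {
    ilo <- strata_int[[least]]
    ihi <- strata_int[[most]]
    igaps <- vapply(seq_len(T), function(t) rate_gap(ihi$mortality[t], ilo$mortality[t]),
                    numeric(2))
    shifts <- vapply(seq_len(T), function(t) {
      shift_to_null(out$rate_ratio[t], igaps["ratio", t],
                    out$rate_difference[t], igaps["difference", t])
    }, numeric(2))
    incr_lo <- ilo$halys - lo$halys
    incr_hi <- ihi$halys - hi$halys
    out$int_rate_ratio <- igaps["ratio", ]
    out$int_rate_difference <- igaps["difference", ]
    out$shift_rr_pct <- shifts["shift_rr", ]
    out$shift_rd_pct <- shifts["shift_rd", ]
    out$incr_halys_least <- incr_lo
    out$incr_halys_most <- incr_hi
    out$incr_haly_ratio <- ifelse(incr_lo != 0, incr_hi / incr_lo, NA_real_)
    out$incr_haly_difference <- incr_hi - incr_lo
  }
  out
}
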