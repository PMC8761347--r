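#' Rate schedules
#'
#' A rate schedule is a per-cycle sequence of non-negative transition rates
#' (per person-year) for one quantity: all-cause mortality, disease incidence,
#' case fatality, or the YLD (morbidity) rate. Cycles are annual; cycle `t`
#' covers calendar year `base_year + t - 1`.
#'
#' @param values numeric vector of non-negative, finite rates, one per cycle.
#' @param base_year calendar year of the first cycle (optional).
#' @param quantity one of `"mortality"`, `"incidence"`, `"fatality"`, `"yld"`.
#' @return a numeric vector of class `rate_schedule` with attributes
#'   `base_year` and `quantity`.
#' @examples
#' rate_schedule(0.01 * 1.2^(0:19), base_year = 2011, quantity = "mortality")
#' @export
rate_schedule <- function(values,
                          base_year = NA_integer_,
                          quantity = c("mortality", "incidence", "fatality", "yld")) {
  quantity <- match.arg(quantity)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a rate schedule needs at least one cycle", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("rates must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(values,
            base_year = as.integer(base_year),
            quantity = quantity,
            class = c("rate_schedule", "numeric"))
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat(sprintf("<rate_schedule: %s, %d cycle%s%s>\n",
              attr(x, "quantity"), length(x), if (length(x) == 1L) "" else "s",
              if (is.na(attr(x, "base_year"))) ""
              else sprintf(", base year %d", attr(x, "base_year"))))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Project a rate forward with an annual percentage change
#'
#' Builds a rate schedule from a base-year rate and a multiplicative annual
#' percentage change (APC). The rate in calendar year `y` is
#' `base_rate * (1 + apc)^(y - base_year)` for `base_year <= y <= apc_end_year`;
#' after `apc_end_year` the trend is frozen at its final value.
#'
#' @param base_rate rate (per person-year) in `base_year`.
#' @param apc annual percentage change as a fraction (e.g. `-0.025` for
#'   -2.5\% per annum); must exceed -1.
#' @param base_year calendar year the base rate refers to (cycle 1).
#' @param horizon number of annual cycles to generate.
#' @param apc_end_year last calendar year in which the trend applies; the
#'   schedule is constant thereafter. Defaults to the end of the horizon
#'   (no freeze).
#' @param quantity passed to [rate_schedule()].
#' @return a [rate_schedule] of length `horizon`.
#' @examples
#' apply_apc(0.0144, -0.025, base_year = 2011, horizon = 3, apc_end_year = 2026)
#' @export
apply_apc <- function(base_rate, apc, base_year, horizon,
                      apc_end_year = base_year + horizon - 1L,
                      quantity = "mortality") {
  if (!is.finite(apc) || apc <= -1) {
    stop("`apc` must be a finite fraction greater than -1", call. = FALSE)
  }
  if (base_rate < 0) stop("`base_rate` must be non-negative", call. = FALSE)
  years <- base_year + seq_len(horizon) - 1L
  expo <- pmin(years, apc_end_year) - base_year
  expo <- pmax(expo, 0L)
  rate_schedule(base_rate * (1 + apc)^expo, base_year = base_year,
                quantity = quantity)
}

#' Expand an age-indexed table into a per-cycle schedule
#'
#' Inputs tabulated by attained age (single ages or age bands) are looked up by
#' the cohort's attained age in each cycle: a cohort starting at `start_age`
#' has attained age `start_age + t - 1` during cycle `t`. Values are constant
#' within each tabulated band.
#'
#' @param table data frame with a `value` column and either an `age` column
#'   (exact attained age) or `age_band_start`/`age_band_end` columns
#'   (inclusive band).
#' @param start_age attained age of the cohort during the first cycle.
#' @param horizon number of cycles.
#' @param quantity passed to [rate_schedule()].
#' @return a [rate_schedule] of length `horizon`.
#' @export
schedule_from_age_table <- function(table, start_age, horizon,
                                    quantity = "mortality") {
  if (!"value" %in% names(table)) {
    stop("age table needs a `value` column", call. = FALSE)
  }
  ages <- start_age + seq_len(horizon) - 1L
  if ("age" %in% names(table)) {
    idx <- match(ages, table$age)
  } else if (all(c("age_band_start", "age_band_end") %in% names(table))) {
    idx <- vapply(ages, function(a) {
      hit <- which(table$age_band_start <= a & a <= table$age_band_end)
      if (length(hit) == 0L) NA_integer_ else hit[1L]
    }, integer(1))
  } else {
    stop("age table needs `age` or `age_band_start`/`age_band_end` columns",
         call. = FALSE)
  }
  if (anyNA(idx)) {
    stop(sprintf("no value tabulated for attained age(s): %s",
                 paste(ages[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  rate_schedule(table$value[idx], quantity = quantity)
}
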