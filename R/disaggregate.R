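#' Disaggregate an aggregate lifetable into strata
#'
#' `disaggregate()` fits the stratified model to an aggregate
#' business-as-usual lifetable: it solves, cycle by cycle, the unique
#' per-stratum rates implied by the stratum rate ratios such that the strata,
#' simulated forward with the solved rates, sum *exactly* to the aggregate
#' compartment counts at every cycle. The aggregate model is treated as the
#' working truth; the strata inherit its fidelity.
#'
#' For a [mortality_lifetable][simulate_mortality] the solved quantities are
#' the stratum mortality rates `m_{k,t} = r^mort_{k,t} m_{1,t}` (with
#' `m_{1,t}` the root of the survivor-consistency equation, see
#' [solve_reference_rate()]) and the stratum YLD rates `w_{k,t}` (closed form,
#' see [disaggregate_morbidity()]). For a
#' [disease_lifetable][simulate_disease] two consecutive solves per cycle are
#' used: incidence rates against the healthy compartment, then case-fatality
#' rates against the diseased compartment (the incidence flow terms cancel
#' from the diseased-compartment constraint once the incidence rates are
#' consistent). Initial stratum prevalence comes from
#' [split_initial_prevalence()].
#'
#' The algorithm is sequential in `t`: each cycle's stratum populations depend
#' on all previously solved rates.
#'
#' @param object the aggregate lifetable to disaggregate.
#' @param spec a [strata_spec()].
#' @param ... passed to methods.
#' @return an object of class `disagg_mortality` or `disagg_disease` (both
#'   inheriting from `disagg_fit`) with methods [coef()], [residuals()],
#'   [fitted()], `summary()`, `print()` and (for mortality fits) `plot()`.
#'   `coef()` returns the solved rate matrix/matrices (strata in rows, cycles
#'   in columns); `residuals()` returns per-cycle consistency residuals
#'   (stratum sums minus aggregate); `fitted()` returns the per-stratum
#'   compartment trajectories.
#' @examples
#' agg <- simulate_mortality(2000, 0.01 * 1.2^(0:19))
#' sp <- strata_spec(c("high_ses", "low_ses"), c(0.5, 0.5), mort_ratios = c(1, 2))
#' fit <- disaggregate(agg, sp)
#' max(abs(residuals(fit)))  # consistent to solver precision
#' @export
disaggregate <- function(object, spec, ...) UseMethod("disaggregate")

#' @rdname disaggregate
#' @export
disaggregate.mortality_lifetable <- function(object, spec, ...) {
  stopifnot(inherits(spec, "strata_spec"))
  n <- length(spec$labels)
  T <- length(object$life_years)
  Rm <- ratio_matrix(spec$mort_ratios, n, T)
  Rw <- ratio_matrix(spec$morb_ratios, n, T)

  A <- matrix(0, n, T + 1L, dimnames = list(spec$labels, NULL))
  A[, 1L] <- object$N * spec$shares
  rates <- matrix(0, n, T, dimnames = list(spec$labels, NULL))
  for (t in seq_len(T)) {
    m1 <- tryCatch(
      solve_reference_rate(A[, t], Rm[, t], object$alive[t + 1L]),
      error = function(e) {
        stop(sprintf("mortality disaggregation failed at cycle %d: %s",
                     t, conditionMessage(e)), call. = FALSE)
      })
    rates[, t] <- Rm[, t] * m1
    A[, t + 1L] <- A[, t] * exp(-rates[, t])
  }
  L <- (A[, seq_len(T), drop = FALSE] + A[, seq_len(T) + 1L, drop = FALSE]) / 2
  W <- matrix(0, n, T, dimnames = list(spec$labels, NULL))
  for (t in seq_len(T)) {
    W[, t] <- disaggregate_morbidity(object$life_years[t], object$yld_rate[t],
                                     L[, t], Rw[, t])
  }
  halys <- L * (1 - W)

  strata <- lapply(seq_len(n), function(k) {
    structure(list(N = A[k, 1L], alive = A[k, ], dead = A[k, 1L] - A[k, ],
                   life_years = L[k, ], yld_rate = W[k, ],
                   halys = halys[k, ], cum_halys = cumsum(halys[k, ]),
                   mortality = rates[k, ]),
              class = "mortality_lifetable")
  })
  names(strata) <- spec$labels

  structure(list(aggregate = object, spec = spec,
                 rates = rates, yld = W,
                 alive = A, life_years = L, halys = halys,
                 strata = strata),
            class = c("disagg_mortality", "disagg_fit"))
}

#' @rdname disaggregate
#' @param disease which entry of `spec$diseases` to use (name or index); by
#'   default the entry matching the lifetable's `disease_name`, or the sole
#'   entry if only one is given.
#' @export
disaggregate.disease_lifetable <- function(object, spec, disease = NULL, ...) {
  stopifnot(inherits(spec, "strata_spec"))
  n <- length(spec$labels)
  T <- length(object$incidence)
  if (is.null(disease)) {
    disease <- if (object$disease_name %in% names(spec$diseases)) {
      object$disease_name
    } else if (length(spec$diseases) == 1L) 1L else {
      stop(sprintf("no ratio entry for disease '%s' in `spec$diseases`",
                   object$disease_name), call. = FALSE)
    }
  }
  dspec <- spec$diseases[[disease]]
  if (is.null(dspec)) {
    stop("disease ratios not found in `spec$diseases`", call. = FALSE)
  }
  Ri <- ratio_matrix(dspec$inc_ratios, n, T)
  Rf <- ratio_matrix(dspec$fat_ratios, n, T)

  sizes <- object$N * spec$shares
  C0 <- split_initial_prevalence(object$diseased[1L], sizes, dspec$prev_ratios)
  S <- C <- matrix(0, n, T + 1L, dimnames = list(spec$labels, NULL))
  S[, 1L] <- sizes - C0
  C[, 1L] <- C0
  inc <- fat <- matrix(0, n, T, dimnames = list(spec$labels, NULL))

  for (t in seq_len(T)) {
    i1 <- tryCatch(
      solve_reference_rate(S[, t], Ri[, t], object$healthy[t + 1L]),
      error = function(e) {
        stop(sprintf("incidence disaggregation failed (healthy compartment, cycle %d): %s",
                     t, conditionMessage(e)), call. = FALSE)
      })
    inc[, t] <- Ri[, t] * i1
    # with consistent incidence flows, the diseased-compartment constraint
    # reduces to sum_k C_{k,t-1} e^{-f_{k,t}} = C_{t-1} e^{-f_t}
    if (sum(C[, t]) > 0) {
      f1 <- tryCatch(
        solve_reference_rate(C[, t], Rf[, t],
                             object$diseased[t] * exp(-object$fatality[t])),
        error = function(e) {
          stop(sprintf("fatality disaggregation failed (diseased compartment, cycle %d): %s",
                       t, conditionMessage(e)), call. = FALSE)
        })
    } else {
      f1 <- object$fatality[t]  # vacuous constraint: keep the aggregate rate
    }
    fat[, t] <- Rf[, t] * f1
    S[, t + 1L] <- S[, t] * exp(-inc[, t])
    C[, t + 1L] <- C[, t] * exp(-fat[, t]) + S[, t] * (1 - exp(-inc[, t]))
  }

  strata <- lapply(seq_len(n), function(k) {
    dl <- structure(list(healthy = S[k, ], diseased = C[k, ],
                         dead = sizes[k] - S[k, ] - C[k, ],
                         incidence = inc[k, ], fatality = fat[k, ],
                         N = sizes[k], disease_name = object$disease_name),
                    class = "disease_lifetable")
    dl
  })
  names(strata) <- spec$labels

  structure(list(aggregate = object, spec = spec,
                 incidence = inc, fatality = fat,
                 healthy = S, diseased = C,
                 strata = strata),
            class = c("disagg_disease", "disagg_fit"))
}

#' Disaggregate the YLD (morbidity) rate across strata
#'
#' Once the mortality problem is solved (so stratum life years sum to the
#' aggregate life years), the HALY-consistency constraint
#' `L_t w_t = sum_k L_{k,t} w_{k,t}` with `w_{k,t} = r^morb_{k,t} w_{1,t}` has
#' the closed-form solution
#' \deqn{w_{k,t} = r^{morb}_{k,t} \frac{L_t w_t}{\sum_j r^{morb}_{j,t} L_{j,t}}.}
#'
#' @param life_years_agg aggregate person-years `L_t` in the cycle.
#' @param w_agg aggregate YLD rate `w_t`.
#' @param life_years_strata stratum person-years `L_{k,t}`, summing to
#'   `life_years_agg`.
#' @param morb_ratios morbidity rate ratios (reference first, = 1).
#' @return stratum YLD rates `w_k`. A warning is raised (but values still
#'   returned) if any `w_k >= 1`, i.e. outside the meaningful HALY-weight
#'   range.
#' @examples
#' disaggregate_morbidity(1000, 0.10, c(600, 400), c(1, 2))
#' @export
disaggregate_morbidity <- function(life_years_agg, w_agg, life_years_strata,
                                   morb_ratios) {
  r <- as.numeric(morb_ratios)
  L <- as.numeric(life_years_strata)
  if (abs(r[1L] - 1) > 1e-12) {
    stop("the reference stratum's morbidity ratio must be 1", call. = FALSE)
  }
  if (abs(sum(L) - life_years_agg) >
      1e-6 * max(life_years_agg, 1)) {
    stop(paste("stratum life years do not sum to the aggregate;",
               "solve the mortality disaggregation first"), call. = FALSE)
  }
  denom <- sum(r * L)
  if (denom <= 0) return(rep(0, length(L)))
  w <- r * life_years_agg * w_agg / denom
  if (any(w >= 1)) {
    warning("disaggregated YLD rate >= 1 for some stratum; HALY weights fall outside [0, 1)",
            call. = FALSE)
  }
  w
}

#' Split initial disease prevalence across strata
#'
#' Distributes the aggregate initially-diseased count using stratum
#' prevalence ratios: the reference prevalence is
#' `prev_1 = C0 / sum_k sizes_k r^p_k`, and stratum counts are
#' `C0_k = sizes_k r^p_k prev_1`, which sum to `C0` exactly.
#'
#' @param C0_agg aggregate initially-diseased count (persons).
#' @param stratum_sizes initial stratum population sizes (persons).
#' @param prevalence_ratios positive prevalence ratios (reference first, = 1).
#' @return initially-diseased count per stratum.
#' @examples
#' split_initial_prevalence(100, c(1000, 1000), c(1, 3))  # 25, 75
#' @export
split_initial_prevalence <- function(C0_agg, stratum_sizes, prevalence_ratios) {
  sizes <- as.numeric(stratum_sizes)
  r <- as.numeric(prevalence_ratios)
  if (abs(r[1L] - 1) > 1e-12) {
    stop("the reference stratum's prevalence ratio must be 1", call. = FALSE)
  }
  if (C0_agg < 0 || C0_agg > sum(sizes)) {
    stop("`C0_agg` must lie between 0 and the total population", call. = FALSE)
  }
  if (C0_agg == 0) return(numeric(length(sizes)))
  prev1 <- C0_agg / sum(sizes * r)
  if (any(r * prev1 > 1 + 1e-12)) {
    stop("implied stratum prevalence exceeds 1; prevalence ratios are infeasible",
         call. = FALSE)
  }
  sizes * r * prev1
}
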