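#' Assemble a proportional multistate lifetable model
#'
#' A PMSLT couples a main all-cause mortality/morbidity lifetable to
#' independent per-disease three-compartment lifetables. Under
#' business-as-usual (BAU) the main lifetable uses the given all-cause
#' mortality and YLD rates directly (the disease burden is already embedded
#' in them); interventions act on disease incidence or all-cause mortality
#' and their effects are propagated to the main lifetable via
#' [link_diseases()].
#'
#' @param N initial cohort size.
#' @param mortality all-cause mortality rate schedule (length `T`).
#' @param yld all-cause YLD rate schedule (scalar or length `T`).
#' @param diseases named list of disease definitions, each a list with
#'   elements `incidence` and `fatality` (schedules of length `T`), `C0`
#'   (initially diseased persons) or `initial_prevalence` (fraction of `N`),
#'   and `disability_weight` (the disease's YLD weight used when linking
#'   prevalence changes to the main lifetable's morbidity).
#' @param base_year calendar year of cycle 1 (optional bookkeeping).
#' @return an object of class `pmslt`: the simulated BAU main lifetable
#'   (`$main`), BAU disease lifetables (`$diseases`), disability weights
#'   (`$dw`) and inputs.
#' @examples
#' mod <- pmslt(1000, rep(0.01, 10), yld = 0.05,
#'              diseases = list(CHD = list(incidence = rep(0.002, 10),
#'                                         fatality = rep(0.05, 10),
#'                                         initial_prevalence = 0.01,
#'                                         disability_weight = 0.2)))
#' @export
pmslt <- function(N, mortality, yld = 0, diseases = list(),
                  base_year = NA_integer_) {
  m <- as.numeric(mortality)
  T <- length(m)
  main <- simulate_mortality(N, m, yld)
  dlts <- list()
  dw <- numeric(0)
  for (nm in names(diseases)) {
    d <- diseases[[nm]]
    C0 <- d$C0 %||% (N * (d$initial_prevalence %||% 0))
    if (length(d$incidence) != T || length(d$fatality) != T) {
      stop(sprintf("disease '%s' schedules must cover all %d cycles", nm, T),
           call. = FALSE)
    }
    dlts[[nm]] <- simulate_disease(N - C0, C0, d$incidence, d$fatality,
                                   disease_name = nm)
    dw[nm] <- d$disability_weight %||% 0
  }
  structure(list(N = N, main = main, diseases = dlts, dw = dw,
                 base_year = base_year),
            class = "pmslt")
}

#' @export
print.pmslt <- function(x, ...) {
  cat(sprintf("PMSLT model: N = %g, %d cycles, %d disease lifetable%s\n",
              x$N, length(x$main$life_years), length(x$diseases),
              if (length(x$diseases) == 1L) "" else "s"))
  if (length(x$diseases)) cat("  diseases:", paste(names(x$diseases), collapse = ", "), "\n")
  invisible(x)
}

# Per-cycle disease-specific mortality rate of a disease lifetable:
# deaths_t = C_{t-1} (1 - exp(-f_t)) among alive_{t-1} = S_{t-1} + C_{t-1};
# expressed as a rate, mx_t = -log(1 - deaths_t / alive_{t-1}).
disease_mortality_rate <- function(dlt) {
  T <- length(dlt$fatality)
  idx <- seq_len(T)
  alive_prev <- dlt$healthy[idx] + dlt$diseased[idx]
  deaths <- dlt$diseased[idx] * (1 - exp(-dlt$fatality))
  mx <- numeric(T)
  pos <- alive_prev > 0
  mx[pos] <- -log(1 - deaths[pos] / alive_prev[pos])
  mx
}

# Prevalence proportion C/(S+C) among the alive, at the end of each cycle.
prevalence_proportion <- function(dlt) {
  T <- length(dlt$fatality)
  idx <- seq_len(T) + 1L
  alive <- dlt$healthy[idx] + dlt$diseased[idx]
  ifelse(alive > 0, dlt$diseased[idx] / alive, 0)
}

#' Propagate disease lifetable changes to the main lifetable
#'
#' Computes the adjusted all-cause mortality and YLD schedules for an
#' intervention scenario from the difference between BAU and intervention
#' disease lifetables, under the PMSLT convention that diseases are
#' independent and BAU already embeds their burden:
#' \itemize{
#'   \item mortality: `m'_t = m_t - sum_d (mx_{d,t,BAU} - mx_{d,t,int})`,
#'     floored at 0 (with a warning when flooring occurs), where `mx_{d,t}`
#'     is the disease-specific mortality rate;
#'   \item morbidity: `w'_t = w_t - sum_d dw_d (prev_{d,t,BAU} - prev_{d,t,int})`
#'     where `prev` is the prevalence proportion `C/(S+C)` and `dw_d` the
#'     disease's disability weight.
#' }
#' BAU schedules are never altered.
#'
#' @param main_bau the BAU main [mortality lifetable][simulate_mortality].
#' @param diseases_bau,diseases_int named lists of BAU and intervention
#'   [disease lifetables][simulate_disease] sharing initial conditions and
#'   horizon.
#' @param dw named vector of disability weights per disease.
#' @return list with adjusted `mortality` and `yld` schedules.
#' @export
link_diseases <- function(main_bau, diseases_bau, diseases_int, dw) {
  T <- length(main_bau$life_years)
  m_adj <- main_bau$mortality
  w_adj <- main_bau$yld_rate
  for (nm in names(diseases_bau)) {
    b <- diseases_bau[[nm]]
    i <- diseases_int[[nm]]
    if (is.null(i)) i <- b
    m_adj <- m_adj - (disease_mortality_rate(b) - disease_mortality_rate(i))
    w_adj <- w_adj - (dw[nm] %||% 0) *
      (prevalence_proportion(b) - prevalence_proportion(i))
  }
  if (any(m_adj < 0)) {
    warning(sprintf("adjusted all-cause mortality floored at 0 in cycle(s) %s",
                    paste(which(m_adj < 0), collapse = ", ")), call. = FALSE)
    m_adj <- pmax(m_adj, 0)
  }
  list(mortality = m_adj, yld = pmax(w_adj, 0))
}

#' Intervention scenarios
#'
#' Three scenario kinds are supported, mirroring common PMSLT intervention
#' analyses:
#' \describe{
#'   \item{`scenario_acmr_scale(scale)`}{multiply every BAU all-cause
#'     mortality rate by `scale`; disease lifetables are untouched.}
#'   \item{`scenario_incidence_scale(scale, diseases)`}{multiply the BAU
#'     incidence rate of the target diseases by `scale`; the change flows
#'     through disease mortality and prevalence into the main lifetable.}
#'   \item{`scenario_pif(pif, diseases)`}{scale the BAU incidence of each
#'     target disease by `1 - PIF_d,t`; `pif` is a named list/vector per
#'     disease, each entry a scalar or per-cycle vector (values < 1), e.g.
#'     from [pif_rr_shift()].}
#' }
#' `scenario_null()` is an explicit no-op useful for validation.
#'
#' @param scale positive multiplier.
#' @param diseases character vector of target disease names.
#' @param pif named list or vector of PIFs per disease.
#' @return an object of class `pmslt_scenario`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_acmr_scale <- function(scale) {
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  structure(list(kind = "acmr_scale", scale = scale), class = "pmslt_scenario")
}

#' @rdname scenarios
#' @export
scenario_incidence_scale <- function(scale, diseases) {
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  structure(list(kind = "incidence_scale", scale = scale,
                 target_diseases = diseases), class = "pmslt_scenario")
}

#' @rdname scenarios
#' @export
scenario_pif <- function(pif, diseases = names(pif)) {
  pif <- as.list(pif)
  if (any(unlist(pif) >= 1)) stop("PIF values must be < 1", call. = FALSE)
  structure(list(kind = "pif_table", pif = pif, target_diseases = diseases),
            class = "pmslt_scenario")
}

#' @rdname scenarios
#' @export
scenario_null <- function() scenario_acmr_scale(1)

#' @export
print.pmslt_scenario <- function(x, ...) {
  cat(switch(x$kind,
             acmr_scale = sprintf("Scenario: scale all-cause mortality by %g\n", x$scale),
             incidence_scale = sprintf("Scenario: scale incidence of %s by %g\n",
                                       paste(x$target_diseases, collapse = ", "), x$scale),
             pif_table = sprintf("Scenario: PIF-scaled incidence for %s\n",
                                 paste(x$target_diseases, collapse = ", "))))
  invisible(x)
}

#' Run an intervention scenario on a PMSLT model
#'
#' Applies a [scenario][scenarios] to a BAU [pmslt()] model: rate schedules
#' are adjusted, disease lifetables re-simulated from the same initial
#' compartments, the changes propagated to the main lifetable via
#' [link_diseases()], and the main lifetable re-simulated. The result pairs
#' BAU and intervention outputs.
#'
#' @param bau a [pmslt()] model (the BAU counterfactual).
#' @param scenario a [pmslt_scenario][scenarios].
#' @return an object of class `pmslt_run` with elements `bau`, `main`
#'   (intervention main lifetable), `diseases` (intervention disease
#'   lifetables), and `incremental_halys` (intervention minus BAU, per cycle).
#' @examples
#' mod <- pmslt(1000, rep(0.01, 10))
#' run <- apply_scenario(mod, scenario_acmr_scale(0.5))
#' sum(run$incremental_halys)
#' @export
apply_scenario <- function(bau, scenario) {
  stopifnot(inherits(bau, "pmslt"), inherits(scenario, "pmslt_scenario"))
  T <- length(bau$main$life_years)
  unknown <- setdiff(scenario$target_diseases %||% character(0),
                     names(bau$diseases))
  if (length(unknown)) {
    stop(sprintf("scenario targets unknown disease(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (scenario$kind == "acmr_scale") {
    main_int <- simulate_mortality(bau$N, scenario$scale * bau$main$mortality,
                                   bau$main$yld_rate)
    dis_int <- bau$diseases
  } else {
    dis_int <- bau$diseases
    for (nm in scenario$target_diseases) {
      b <- bau$diseases[[nm]]
      mult <- if (scenario$kind == "incidence_scale") {
        rep(scenario$scale, T)
      } else {
        p <- scenario$pif[[nm]]
        if (length(p) == 1L) p <- rep(p, T)
        if (length(p) != T) {
          stop(sprintf("PIF schedule for '%s' must be scalar or length %d", nm, T),
               call. = FALSE)
        }
        1 - p
      }
      dis_int[[nm]] <- simulate_disease(b$healthy[1L], b$diseased[1L],
                                        mult * b$incidence, b$fatality,
                                        disease_name = nm)
    }
    adj <- link_diseases(bau$main, bau$diseases, dis_int, bau$dw)
    main_int <- simulate_mortality(bau$N, adj$mortality, adj$yld)
  }
  structure(list(bau = bau, scenario = scenario,
                 main = main_int, diseases = dis_int,
                 incremental_halys = main_int$halys - bau$main$halys),
            class = "pmslt_run")
}

#' @export
print.pmslt_run <- function(x, ...) {
  cat("PMSLT scenario run\n")
  print(x$scenario)
  cat(sprintf("  incremental HALYs (sum over %d cycles): %.2f\n",
              length(x$incremental_halys), sum(x$incremental_halys)))
  invisible(x)
}
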