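# Evaluate code with a temporary, explicit RNG seed; the caller's global RNG
# state is untouched.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' The two-stratum illustrative example
#'
#' Reconstructs the small worked example that motivates consistent
#' disaggregation: a cohort of 2000 with mortality rate 1 per 100
#' person-years in the first year, increasing 20\% per annum for 20 years,
#' split 50:50 into a low- and a high-mortality stratum whose rates are in
#' ratio 1:2. Naively assigning the strata baseline rates of 2/3 and 4/3 per
#' 100 (which reproduces the aggregate's first-cycle survivors) and trending
#' each independently overshoots the aggregate person-years by cycle 20; the
#' solver-based disaggregation sums exactly.
#'
#' @return a list with `N`, `horizon`, the aggregate mortality schedule
#'   `m_agg`, the simulated `aggregate` lifetable, `naive` (list of the two
#'   independently-trended stratum lifetables), `spec` (the ratio-2
#'   [strata_spec()]), and `solved` (the [disaggregate()] fit).
#' @examples
#' fx <- make_fig1_fixture()
#' fx$aggregate$life_years[20]                      # 367.4
#' sum(vapply(fx$naive, function(l) l$life_years[20], 1))  # 427.3, overshoot
#' @export
make_fig1_fixture <- function() {
  N <- 2000
  horizon <- 20L
  m_agg <- rate_schedule(0.01 * 1.2^(0:19), quantity = "mortality")
  aggregate <- simulate_mortality(N, m_agg)
  naive <- list(
    low_mortality = simulate_mortality(1000, (2 / 3) * 0.01 * 1.2^(0:19)),
    high_mortality = simulate_mortality(1000, (4 / 3) * 0.01 * 1.2^(0:19))
  )
  spec <- strata_spec(c("low_mortality", "high_mortality"), c(0.5, 0.5),
                      mort_ratios = c(1, 2))
  solved <- disaggregate(aggregate, spec)
  list(N = N, horizon = horizon, m_agg = m_agg, aggregate = aggregate,
       naive = naive, spec = spec, solved = solved)
}

#' Generate a random stratified model with known truth
#'
#' Draws per-stratum rate schedules (mortality, YLD, and per-disease
#' incidence/fatality) from uniform ranges, simulates each stratum forward,
#' and derives the exact aggregate inputs (implied aggregate rates via
#' [implied_aggregate_rate()], aggregate YLD, aggregate disease compartments)
#' together with the true per-cycle rate ratios. The returned pair of
#' (aggregate inputs, true ratios) is exactly what [disaggregate()] consumes,
#' while the generating rates serve as the recovery oracle.
#'
#' Generation is reproducible from `seed` and leaves the global RNG state
#' untouched.
#'
#' @param n_strata number of strata (>= 1).
#' @param T number of annual cycles.
#' @param seed integer seed.
#' @param n_diseases number of disease lifetables (>= 0).
#' @param mort_range,ratio_range,yld_range,inc_range,fat_range,prev_range
#'   uniform ranges for the reference-stratum rates and the non-reference
#'   rate ratios.
#' @return a list with `spec` (the [strata_spec()] carrying the true
#'   ratios), `aggregate` (list: `mortality` lifetable, `diseases` list),
#'   and `truth` (per-stratum generating rates and simulated lifetables).
#' @examples
#' g <- generate_synthetic_model(3, 10, seed = 1)
#' fit <- disaggregate(g$aggregate$mortality, g$spec)
#' max(abs(coef(fit)$mortality - g$truth$mortality))  # recovered
#' @export
generate_synthetic_model <- function(n_strata, T, seed, n_diseases = 1,
                                     mort_range = c(0.005, 0.03),
                                     ratio_range = c(0.5, 3),
                                     yld_range = c(0.02, 0.2),
                                     inc_range = c(0.002, 0.02),
                                     fat_range = c(0.02, 0.1),
                                     prev_range = c(0.005, 0.05)) {
  stopifnot(n_strata >= 1, T >= 1, n_diseases >= 0)
  with_seed(seed, {
    runifm <- function(n, range) matrix(stats::runif(n * T, range[1], range[2]),
                                        nrow = n)
    ratios <- function() {
      r <- runifm(n_strata, ratio_range)
      r[1L, ] <- 1
      r
    }
    shares <- stats::runif(n_strata, 0.05, 1)
    shares <- shares / sum(shares)
    N <- 1e5

    Rm <- ratios()
    m1 <- stats::runif(T, mort_range[1], mort_range[2])
    m <- Rm * rep(m1, each = n_strata)
    Rw <- ratios()
    w1 <- stats::runif(T, yld_range[1], yld_range[2])
    w <- Rw * rep(w1, each = n_strata)
    strata_lt <- lapply(seq_len(n_strata), function(k) {
      simulate_mortality(N * shares[k], m[k, ], w[k, ])
    })

    A <- Reduce(`+`, lapply(strata_lt, `[[`, "alive"))
    m_agg <- implied_aggregate_rate(A[-(T + 1L)], A[-1L])
    L_agg <- (A[-1L] + A[-(T + 1L)]) / 2
    Lstar <- Reduce(`+`, lapply(strata_lt, `[[`, "halys"))
    w_agg <- 1 - Lstar / L_agg
    agg_mort <- simulate_mortality(N, m_agg, w_agg)

    diseases <- list()
    dis_truth <- list()
    dspecs <- list()
    if (n_diseases > 0) {
      for (d in seq_len(n_diseases)) {
        nm <- paste0("disease", d)
        Ri <- ratios()
        Rf <- ratios()
        rp <- stats::runif(n_strata, ratio_range[1], ratio_range[2])
        rp[1L] <- 1
        i1 <- stats::runif(T, inc_range[1], inc_range[2])
        f1 <- stats::runif(T, fat_range[1], fat_range[2])
        prev1 <- stats::runif(1, prev_range[1], prev_range[2])
        prev_k <- pmin(rp * prev1, 0.9)
        dlt_k <- lapply(seq_len(n_strata), function(k) {
          Nk <- N * shares[k]
          simulate_disease(Nk * (1 - prev_k[k]), Nk * prev_k[k],
                           Ri[k, ] * i1, Rf[k, ] * f1, disease_name = nm)
        })
        S <- Reduce(`+`, lapply(dlt_k, `[[`, "healthy"))
        C <- Reduce(`+`, lapply(dlt_k, `[[`, "diseased"))
        i_agg <- implied_aggregate_rate(S[-(T + 1L)], S[-1L])
        # aggregate fatality implied by the diseased-compartment recursion
        f_agg <- -log((C[-1L] - (S[-(T + 1L)] - S[-1L])) / C[-(T + 1L)])
        diseases[[nm]] <- simulate_disease(S[1L], C[1L], i_agg, f_agg,
                                           disease_name = nm)
        # prevalence ratios consistent with the realised stratum prevalences
        dspecs[[nm]] <- list(inc_ratios = Ri, fat_ratios = Rf,
                             prev_ratios = prev_k / prev_k[1L])
        dis_truth[[nm]] <- list(incidence = Ri * rep(i1, each = n_strata),
                                fatality = Rf * rep(f1, each = n_strata),
                                strata = dlt_k)
      }
    }

    labels <- paste0("stratum", seq_len(n_strata))
    rownames(m) <- rownames(w) <- labels
    dis_truth <- lapply(dis_truth, function(d) {
      rownames(d$incidence) <- rownames(d$fatality) <- labels
      d
    })
    spec <- strata_spec(labels, shares,
                        mort_ratios = Rm, morb_ratios = Rw,
                        diseases = dspecs)
    list(spec = spec,
         aggregate = list(mortality = agg_mort, diseases = diseases),
         truth = list(mortality = m, yld = w, strata = strata_lt,
                      diseases = dis_truth, N = N))
  })
}
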