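test_that("reference-rate solver finds the unique consistency root", {
  # two equal strata, ratio 2, aggregate rate 1 per 100: exact root computed
  # independently from the quadratic in exp(-m)
  target <- 2000 * exp(-0.01)
  x <- (-1 + sqrt(1 + 4 * target / 1000)) / 2
  m_exact <- -log(x)
  m <- solve_reference_rate(c(1000, 1000), c(1, 2), target)
  expect_equal(m, m_exact, tolerance = 1e-12)
  expect_equal(round(100 * m, 3), 0.667)  # printed as 0.667 per 100

  # homogeneous strata recover the aggregate rate
  set.seed(42)
  alive <- stats::runif(4, 100, 900)
  m <- solve_reference_rate(alive, rep(1, 4), sum(alive) * exp(-0.05))
  expect_equal(m, 0.05, tolerance = 1e-10)

  # three strata, cross-checked against an independent bisection oracle
  m <- solve_reference_rate(c(500, 300, 200), c(1, 2, 3), 900)
  expect_equal(m, oracle_solve_rate(c(500, 300, 200), c(1, 2, 3), 900),
               tolerance = 1e-10)
  expect_equal(500 * exp(-m) + 300 * exp(-2 * m) + 200 * exp(-3 * m), 900,
               tolerance = 1e-9)

  expect_error(solve_reference_rate(c(100, 100), c(1, 2), 300), "infeasible")
  expect_error(solve_reference_rate(c(100, 100), c(1, 2), -5), "positive")
  expect_error(solve_reference_rate(c(100, 100), c(2, 1), 150), "reference")
})

test_that("Newton and bisection agree on randomized instances", {
  set.seed(99)
  for (rep in 1:50) {
    inst <- random_solver_instance(n = sample(2:10, 1))
    m_newton <- solve_reference_rate(inst$alive, inst$ratios, inst$target)
    m_bisect <- oracle_solve_rate(inst$alive, inst$ratios, inst$target)
    expect_equal(m_newton, m_bisect, tolerance = 1e-10)
    expect_equal(m_newton, inst$m_true, tolerance = 1e-10)
  }
})

test_that("mortality disaggregation repairs the mis-specified stratified model", {
  fx <- make_fig1_fixture()
  # the naive model overshoots the aggregate person-years by cycle 20 ...
  naive_sum <- sum(vapply(fx$naive, function(l) l$life_years[20], numeric(1)))
  expect_equal(round(naive_sum, 1), 427.3)
  expect_gt(naive_sum, fx$aggregate$life_years[20])
  # ... while the solver-based strata sum exactly at every cycle
  solved_sum <- colSums(fx$solved$life_years)
  expect_equal(solved_sum, fx$aggregate$life_years, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fx$solved))), 1e-9 * fx$N)
  # the solved ratio-2 structure holds at every cycle
  expect_equal(fx$solved$rates[2, ] / fx$solved$rates[1, ], rep(2, 20),
               tolerance = 1e-10)
})

test_that("a single stratum reproduces the aggregate lifetable", {
  agg <- simulate_mortality(1500, 0.02 * 1.1^(0:9), yld = 0.1)
  fit <- disaggregate(agg, strata_spec("all", 1, mort_ratios = 1))
  expect_equal(fit$strata[[1]]$alive, agg$alive, tolerance = 1e-12)
  expect_equal(fit$rates[1, ], agg$mortality, tolerance = 1e-10)
  expect_equal(fit$yld[1, ], agg$yld_rate, tolerance = 1e-12)
})

test_that("disaggregation recovers the generating rates (inverse oracle)", {
  for (seed in c(7, 21)) {
    g <- generate_synthetic_model(n_strata = 5, T = 20, seed = seed)
    fit <- disaggregate(g$aggregate$mortality, g$spec)
    expect_equal(coef(fit)$mortality, g$truth$mortality, tolerance = 1e-10)
    expect_equal(coef(fit)$yld, g$truth$yld, tolerance = 1e-10)
    fd <- disaggregate(g$aggregate$diseases[[1]], g$spec)
    expect_equal(coef(fd)$incidence, g$truth$diseases[[1]]$incidence,
                 tolerance = 1e-10)
    expect_equal(coef(fd)$fatality, g$truth$diseases[[1]]$fatality,
                 tolerance = 1e-10)
  }
})

test_that("morbidity disaggregation satisfies its closed form", {
  # hand evaluation: w_k = r_k * L w / sum_j r_j L_j
  w <- disaggregate_morbidity(1000, 0.10, c(600, 400), c(1, 2))
  expect_equal(w, c(1, 2) * 100 / 1400)
  expect_equal(round(w, 7), c(0.0714286, 0.1428571))
  expect_equal(sum(c(600, 400) * w), 1000 * 0.10)  # HALY consistency

  # unit ratios collapse to the aggregate rate; zero morbidity stays zero
  expect_equal(disaggregate_morbidity(900, 0.2, c(300, 600), c(1, 1)),
               c(0.2, 0.2))
  expect_equal(disaggregate_morbidity(900, 0, c(300, 600), c(1, 3)), c(0, 0))

  expect_warning(disaggregate_morbidity(100, 0.9, c(99, 1), c(1, 20)),
                 "YLD rate >= 1")
  expect_error(disaggregate_morbidity(1000, 0.1, c(100, 100), c(1, 2)),
               "sum to the aggregate")
})

test_that("initial prevalence splits by prevalence ratios and sums exactly", {
  expect_equal(split_initial_prevalence(100, c(1000, 1000), c(1, 3)), c(25, 75))
  expect_equal(split_initial_prevalence(0, c(10, 20), c(1, 5)), c(0, 0))
  expect_equal(split_initial_prevalence(60, c(100, 200), c(1, 1)), c(20, 40))
  set.seed(3)
  sizes <- stats::runif(5, 50, 500)
  r <- c(1, stats::runif(4, 0.2, 4))
  C0 <- split_initial_prevalence(123.4, sizes, r)
  expect_equal(sum(C0), 123.4)
  expect_equal((C0 / sizes) / (C0[1] / sizes[1]), r)
  expect_error(split_initial_prevalence(1900, c(1000, 1000), c(1, 20)),
               "exceeds 1")
})

test_that("disease disaggregation is consistent and exact for symmetric strata", {
  # all ratios 1 with proportional prevalence: strata are scaled copies
  agg <- simulate_disease(9000, 1000, rep(0.01, 15), rep(0.08, 15))
  spec <- strata_spec(c("a", "b"), c(0.3, 0.7), mort_ratios = c(1, 1),
                      diseases = list(d = list(inc_ratios = c(1, 1),
                                               fat_ratios = c(1, 1),
                                               prev_ratios = c(1, 1))))
  fit <- disaggregate(agg, spec)
  expect_equal(fit$healthy[1, ], 0.3 * agg$healthy, tolerance = 1e-12)
  expect_equal(fit$diseased[2, ], 0.7 * agg$diseased, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-9 * agg$N)
})

test_that("permuting non-reference strata permutes outputs without changing them", {
  g <- generate_synthetic_model(n_strata = 4, T = 12, seed = 11, n_diseases = 0)
  fit <- disaggregate(g$aggregate$mortality, g$spec)
  perm <- c(1, 4, 2, 3)  # reference stays first
  spec_p <- strata_spec(g$spec$labels[perm], g$spec$shares[perm],
                        mort_ratios = g$spec$mort_ratios[perm, ],
                        morb_ratios = g$spec$morb_ratios[perm, ])
  fit_p <- disaggregate(g$aggregate$mortality, spec_p)
  expect_equal(fit_p$rates, fit$rates[perm, ], tolerance = 1e-12)
  expect_equal(fit_p$alive, fit$alive[perm, ], tolerance = 1e-12)
})

test_that("degenerate strata with zero share are carried as zeros", {
  agg <- simulate_mortality(1000, rep(0.02, 10))
  spec <- strata_spec(c("a", "empty", "b"), c(0.6, 0, 0.4),
                      mort_ratios = c(1, 5, 2))
  fit <- disaggregate(agg, spec)
  expect_equal(fit$alive["empty", ], rep(0, 11))
  expect_equal(colSums(fit$alive), agg$alive, tolerance = 1e-9)
})

test_that("fit accessors expose rates, residuals and stratum trajectories", {
  fx <- make_fig1_fixture()
  fit <- fx$solved
  expect_s3_class(fit, "disagg_fit")
  co <- coef(fit)
  expect_named(co, c("mortality", "yld"))
  expect_equal(dim(co$mortality), c(2L, 20L))
  ft <- fitted(fit)
  expect_true(all(c("stratum", "alive", "halys") %in% names(ft)))
  expect_equal(nrow(ft), 40L)
  sm <- summary(fit)
  expect_lt(max(sm$max_abs_residual), 1e-9 * 2000)
  expect_output(print(fit), "Disaggregated mortality/morbidity")
})
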