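---
title: "Consistent disaggregation of proportional multistate lifetables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent disaggregation of proportional multistate lifetables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmslt)
```

## The problem

Proportional multistate lifetable (PMSLT) models are discrete-time Markov
cohort macro-simulations used to project the health impact of population
interventions: a main all-cause mortality/morbidity lifetable is coupled to
independent per-disease lifetables, and intervention-induced changes in
disease incidence or case fatality propagate into all-cause mortality,
morbidity and health-adjusted life years (HALYs).

Policy questions about health *inequalities* require these projections by
population strata — deprivation quintiles, ethnicity, sex. The difficulty is
that stratified epidemiological inputs are usually weaker than aggregate
ones: we may know aggregate rates well, and the *rate ratios* between strata,
but not the stratum rates over time. Naively assigning stratum rates that
match the aggregate at baseline, then trending each stratum independently,
breaks the accounting: differential mortality shifts the population
distribution across strata over time, so stratum outputs no longer sum to
the aggregate model's.

The package's worked example makes this concrete. A cohort of 2000 with
mortality rate 1 per 100 person-years, increasing 20% per annum over 20
years, lives 367.4 person-years in the 20th cycle. Splitting it into two
strata of 1000 with rates in ratio 2:1 (baseline 2/3 and 4/3 per 100, which
reproduces the aggregate's first-year survivors), and trending each stratum
independently, yields 322.2 + 105.0 = 427.3 person-years in cycle 20 — a 16%
overshoot:

```{r}
fx <- make_fig1_fixture()
c(aggregate = fx$aggregate$life_years[20],
  naive_sum = sum(vapply(fx$naive, function(l) l$life_years[20], numeric(1))),
  solved_sum = sum(fx$solved$life_years[, 20]))
```

The package solves this *disaggregation problem*: find the unique stratum
rates per cycle, compatible with the given rate ratios, such that the
stratified simulations sum to the aggregate model exactly at every cycle.
The aggregate model is treated as the working truth; stratified outputs
inherit its fidelity.

## The model

**Mortality/morbidity lifetable.** With mortality rate $m_t$ per annual
cycle, $A_t = A_{t-1} e^{-m_t}$ from $A_0 = N$, deaths $D_t = N - A_t$,
person-years by the half-cycle (trapezoid) correction
$L_t = (A_t + A_{t-1})/2$, and HALYs $L^*_t = L_t (1 - w_t)$, where the YLD
rate $w_t \in [0, 1)$ is prevalent years lived with disability per person
(from burden-of-disease data). No further age-interval correction is
applied: this form reproduces the worked example's printed person-year
figures exactly, and its "risk of 1 per 100" is interpreted as a *rate*
applied through exponential survival, the convention consistent with all
four printed values.

**Disease lifetable.** Three compartments per disease — healthy $S$,
diseased $C$, dead $D$ — with incidence rate $i_t$ and case-fatality rate
$f_t$:
$$S_t = S_{t-1} e^{-i_t}, \qquad
  C_t = C_{t-1} e^{-f_t} + S_{t-1}(1 - e^{-i_t}), \qquad
  D_t = N - S_t - C_t.$$
Two simplifications are deliberate: no remission ($C \to S$ transitions are
not modelled), and incident cases cannot die of the disease within their
incident cycle (mitigate by shortening the cycle if this matters). Diseases
are mutually independent — the proportional-lifetable assumption.

**Time conventions.** Cycles are annual; cycle $t$ covers calendar year
`base_year` $+\,t-1$ and the cohort ages one year per cycle. Inputs
tabulated by age band are constant within the band and looked up by attained
age (`schedule_from_age_table()`); a cohort given per 5-year age group is
modelled as a single cohort centred on the group midpoint. Annual
percentage-change (APC) trends are geometric,
$m(y) = m_0 (1+\mathrm{APC})^{y - y_0}$, and are *frozen* at their final
value after the configured end year — a choice made because trend inputs are
typically published for a bounded projection window, and extrapolating a
geometric decline indefinitely is rarely defensible.

## The disaggregation method

Strata $k = 1, \dots, n$ (reference first) have fixed membership for life,
known initial shares, and known rate ratios $r_{k,t}$ with $r_{1,t} = 1$.
Writing $m_{k,t} = r_{k,t} m_{1,t}$, the consistency requirement
$\sum_k A_{k,t} = A_t$ reduces, cycle by cycle, to one scalar equation in
the reference rate:
$$g(m) = \sum_k A_{k,t-1} e^{-r_{k,t} m} - A_t = 0.$$
$g$ is strictly decreasing in $m$ whenever any stratum is non-empty, so the
root is unique; a solution exists iff the target does not exceed the
starting total. The algorithm is necessarily sequential in $t$, because the
cycle-$t$ stratum populations depend on all earlier solved rates.

**Morbidity.** Once mortality is solved, stratum life years sum to the
aggregate's, and the HALY constraint
$L_t w_t = \sum_k L_{k,t} w_{k,t}$ with $w_{k,t} = r^{\text{morb}}_{k,t} w_{1,t}$
has the closed form
$$w_{k,t} = r^{\text{morb}}_{k,t}\,
  \frac{L_t w_t}{\sum_j r^{\text{morb}}_{j,t} L_{j,t}}.$$
Morbidity ratios are accepted per cycle (a scalar per stratum is recycled),
even though in practice they are often assumed constant over time. A solved
$w_{k,t} \ge 1$ is epidemiologically meaningless but algebraically valid; it
is reported with a warning rather than an error, since whether such inputs
occur is a property of the data, not the method.

**Diseases.** Initial stratum prevalence comes from prevalence ratios:
$C_{k,0} = \text{size}_k\, r^p_k\, C_0 / \sum_j \text{size}_j\, r^p_j$,
which sums to $C_0$ exactly. Each cycle then requires two consecutive
scalar solves: incidence rates against the healthy compartment (identical in
form to the mortality problem), then case-fatality rates against the
diseased compartment — once the incidence rates are consistent, the
incidence inflow terms cancel from the diseased-compartment constraint,
leaving $\sum_k C_{k,t-1} e^{-r^f_{k,t} f} = C_{t-1} e^{-f_t}$.

## Numerical choices

The scalar solve (`solve_reference_rate()`) uses safeguarded Newton with the
analytic derivative $g'(m) = -\sum_k r_k A_k e^{-r_k m}$: every iterate is
kept inside a bisection bracket whose upper end starts at
$\max(-\log(\text{target}/\text{total}), 1)$ and doubles until the residual
changes sign, and any Newton step leaving the bracket is replaced by its
midpoint. Convergence requires an absolute residual $\le 10^{-12}$ times the
target survivors, with a bracket-width backstop of $10^{-14}$ relative on
the rate. Monotonicity makes the root unique, so no restarts or damping are
needed; the solver is fully deterministic. These tolerances were chosen so
that consistency checks hold at double precision (the sums of stratum counts
match the aggregate to well below $10^{-9} N$ over 50 cycles); the method's
own implementation details in the source literature are not stated, so the
targets here are the package's own.

Degenerate inputs: a stratum with initial share 0 is carried with all-zero
counts (its ratios are irrelevant); an empty diseased compartment makes the
fatality constraint vacuous, and the aggregate fatality rate is assigned
(times the ratios) so schedules stay well-defined; a target exceeding the
starting population raises an infeasibility error naming the compartment and
cycle. If stratum baseline rates are supplied externally they are not
trusted: the solver's cycle-1 value is used (initial rates are solvable from
the ratios, so a conflicting external value would break consistency).

## Interventions and linkage

Three scenario kinds are implemented: scaling all-cause mortality
(`scenario_acmr_scale()`), scaling disease incidence
(`scenario_incidence_scale()`), and PIF-scaled incidence
(`scenario_pif()`), where the potential impact fraction per disease comes
from the relative-risk shift method over exposure categories
(`pif_rr_shift()`):
$$\mathrm{PIF} = \frac{\sum_c p_c RR_c - \sum_c p_c RR^*_c}
                      {\sum_c p_c RR_c},$$
with $RR_c = rr^{\bar{x}_c}$ anchored at zero exposure — the PIF is
invariant to the common anchor, so this choice is safe. Exposure reductions
(e.g. the 51.5% sodium-intake reduction implied by a 59% salt substitution)
are configuration inputs, not derived internally. Intervention effect sizes
are applied identically across strata (per-stratum PIFs are nonetheless
accepted, since stratum PIFs are the modeller's input); scenario multipliers
compose multiplicatively with any APC-trended BAU schedule. Stratum PIFs are
*not* derived from stratum exposure distributions by the package.

Propagation to the main lifetable (`link_diseases()`) is the one genuinely
open design point: the linkage equations are conventions of the wider PMSLT
literature rather than part of the disaggregation method itself. The package
uses the standard form. Per disease, the disease-specific mortality rate is
$mx_{d,t} = -\log(1 - \text{deaths}_{d,t} / \text{alive}_{d,t-1})$ with
$\text{deaths}_{d,t} = C_{d,t-1}(1 - e^{-f_{d,t}})$; the intervention
all-cause rate is $m'_t = m_t - \sum_d (mx^{BAU}_{d,t} - mx^{int}_{d,t})$,
floored at 0 with a warning (flooring indicates a disease burden
inconsistent with the background rates). Morbidity is adjusted by prevalence
proportions: $w'_t = w_t - \sum_d dw_d\,(\pi^{BAU}_{d,t} - \pi^{int}_{d,t})$
with $\pi = C/(S+C)$ taken at the end of cycle $t$ and $dw_d$ the disease's
disability weight. Adjustments are additive across diseases (independence),
BAU is never altered by linkage (its disease burden is already embedded in
the aggregate inputs), and disease deaths feed back only through the rate
adjustment, not by removing people within the cycle. Published totals from a
specific application can be sensitive to this convention; a residual
mismatch when reproducing external tables should be examined against the
linkage form first.

## Inequality measures

All measures compare the most-deprived against the least-deprived stratum
(by default the last and first stratum; a generalised pairwise comparison is
available via the `least`/`most` arguments). Differences are most minus
least, so excess mortality is positive and the HALY shortfall of the most
deprived is negative. Shifts to the null are
$(RR_{BAU} - RR_{int})/(RR_{BAU} - 1) \times 100$ and
$(RD_{BAU} - RD_{int})/RD_{BAU} \times 100$; a common scaling of all stratum
rates therefore shifts the rate ratio by 0% and the rate difference by
$1 - \text{scale}$. Everything is computed at full precision and rounded
only for presentation — ratios of table-rounded values can differ in the
last digit from full-precision ratios, which is why the output CSVs carry
both a full-precision and a rounded variant.

Note that summed stratified intervention gains need *not* equal the
aggregate model's: risks are non-linear in rates
($\text{risk} = 1 - e^{-\text{rate}}$), so modelling the intervention
separately by stratum and summing — which allows for heterogeneity — differs
slightly (and more accurately) from intervening on the aggregate. Under BAU,
by construction, there is no such discrepancy.

## The synthetic generator and what the tests show

`generate_synthetic_model()` draws reference-stratum schedules and stratum
ratios from uniform ranges, simulates the strata forward, and derives the
exact aggregate inputs plus true per-cycle ratios. The defaults emulate an
older-adult annual-cycle cohort: reference mortality 0.005–0.03 per
person-year, YLD rates 0.02–0.2, disease incidence 0.002–0.02, case fatality
0.02–0.1, initial prevalence 0.005–0.05, and rate ratios 0.5–3 — the spans a
deprivation-quintile analysis of a high-income population plausibly
produces. Generation is reproducible from an explicit seed and leaves the
global RNG state untouched.

The generator gives the test suite a planted truth: consistency must hold
for *any* valid input (it does, to below $10^{-9} N$ over up to 10 strata
and 50 cycles), and disaggregating with the true ratios must recover the
generating rates (it does, to $10^{-10}$ relative). What the generator does
not emulate — correlated age structure, rate ratios that covary with rates,
input measurement error, non-annual cycles — limits what passing tests say
about real data: they certify the algorithm's mathematical guarantees, not
the realism of any particular input set. In particular, the quality of a
disaggregated projection is bounded by the quality of the aggregate inputs
and of the rate ratios, both of which are assumed, not estimated, here.

Test problem sizes (up to 10 strata, 50 cycles, $N = 10^5$) were chosen as
representative of routine applications — the per-cycle work is a handful of
scalar root-finds, so far larger problems remain cheap.

## Known limitations

* No remission: diseases with substantial recovery flows need an extended
  three-rate lifetable that this package does not provide.
* Independence between diseases: comorbidity and competing-risk coupling are
  outside the proportional-lifetable assumption.
* The discrete-time formulation means within-cycle event ordering is a
  convention; a continuous-time (differential equation) formulation would
  remove it at the cost of losing the closed-form uniqueness argument.
* Stratum membership is fixed for life; migration between strata is not
  modelled.
* Linkage to the main lifetable follows the standard PMSLT convention
  described above; alternative conventions would change intervention (not
  BAU) outputs.
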