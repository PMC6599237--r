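---
title: "Model and methods: escalation vs switching in RRMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: escalation vs switching in RRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
cohort model and its assumptions, the inputs and where each comes from, the
conventions that had to be fixed where the published description leaves
freedom, and what the synthetic placeholder inputs do and do not allow one
to conclude.

## The decision problem

Relapsing-remitting multiple sclerosis (RRMS) patients failing a first-line
self-injectable immunomodulator (interferon beta or glatiramer acetate) can
either *switch* within the class and escalate to natalizumab only when
disability reaches EDSS 4 (strategy SWI), or *escalate early* to natalizumab
at once (strategy ESC). Natalizumab is more effective on both relapses and
disability progression but costs roughly twice the blended first-line
therapy per year. The model projects both policies over a lifetime and
compares discounted societal costs and QALYs.

## State space and dynamics

States are (form, EDSS band, phase): forms RRMS/SPMS, bands 0–7 plus an
8–10 aggregate (the granularity of the published relapse and cost tables),
phases FIRST_LINE, NATALIZUMAB, NO_DMT. SPMS is always untreated; death is
absorbing; 37 states in all. Cycle length is one year, horizon 50 cycles,
and the cohort's mean age advances deterministically from 35.3 years
(65.8% female).

Within a cycle, events compose in a **fixed order**: death → EDSS shift →
RRMS→SPMS conversion (at the post-shift band) → treatment-phase update (at
the destination band). The published description does not state an
ordering; a fixed one makes results reproducible, and it is a constant of
the implementation rather than a configuration knob. No half-cycle
correction is applied anywhere; each model year is valued at its
start-of-year occupancy with discount factor $(1+r)^{-t}$, $r = 0.035$.
With zero mortality and zero discounting this makes lifetime life-years
equal the horizon exactly, which the tests exploit.

Annual EDSS shifts take values $k \in \{-1, 0, +1, +2, +3\}$. On
natalizumab the RRMS cohort follows the escalation-group vector
(0.0236, 0.8727, 0.0849, 0.0189, 0.0000 — printed sum 1.0001, renormalized
at load); on first-line treatment the switching-group vector
(0.0000, 0.8199, 0.1553, 0.0217, 0.0031). Shift mass below band 0 or above
band 8 accrues to the boundary band. Treatment multiplies the untreated
annualized relapse rate by 0.6574 (first line) or
$0.6574 \times 0.46 = 0.3024$ (natalizumab); effects are constant over time
(no efficacy waning) and treatments do not alter SPMS conversion or SPMS
progression. Mortality is the sex-blended general-population annual death
probability times an MS multiplier ≥ 1 by form and band, capped at 1; a
single blended cohort is used rather than sex strata because no other input
is sex-specific.

Phase policies are one-way: ESC prescribes natalizumab from entry until
band ≥ 7, SWI first-line until band ≥ 4 and natalizumab until band ≥ 7;
past 7, and in SPMS, no disease-modifying treatment. A patient whose EDSS
regresses below a threshold keeps the later phase (no de-escalation, no
resumption). Two consequences of reading the policy literally are worth
flagging: switching-arm patients already at bands 4–5 at model entry
(16.5% of the cohort) start directly on natalizumab; and untreated RRMS
(band ≥ 7) progresses by the switching-group vector, the closest available
stand-in for natural history since no untreated shift vector is published —
both are configurable.

## The shift-distribution estimator

The published vectors were derived from two-year patient-level EDSS series:
the annual probability of a $k$-point change is the pooled tally of the two
per-patient annual deltas (month 12 − baseline, month 24 − month 12) over
$2N$ intervals. The package implements exactly that estimator
(`estimate_shift_distribution()`), rounding half-point EDSS inputs down to
integer bands (2.5 → 2) and clamping deltas outside the support to the
nearest endpoint with a warning. Trajectories simulated from a known vector
(`simulate_edss_trajectories()`) recover each entry to within ±0.02 at
n = 10,000 patients — the problem size used by the tests, chosen so binomial
error is well below that bound.

## Inputs and conventions

Printed inputs live in `inst/extdata/base_case.yaml`: baseline EDSS
distribution (mass on bands 1–5), untreated relapse rates by form and band,
the two shift vectors, disability-related direct and indirect costs per band
and form, treatment pack prices, monitoring (year 1 vs subsequent) and
administration costs, the €4,744 relapse cost, the 0.0092 (SPMS) and 0.0437
(relapse) disutilities, discount rate, horizon, and the first-line treatment
mix (58.4% IFN beta-1a 44 µg, 8.7% IFN beta-1b, 32.9% glatiramer acetate).
Two table readings had to be fixed: the SPMS band-1 relapse-rate cell prints
"10.0000", read here as a footnote marker "1" followed by 0.0000 (ten
relapses/year in progressive disease is not clinically credible); and the
RRMS band-0 rate, absent from the table, defaults to the band-1 value.
Both are configuration fields, not code.

Annual drug cost is pack price × packs/year × (1 − rebate), rebates
defaulting to 0 (amounts are not published). Packs per year are
doses-per-year for the posology (365.25/28 for Q4W, 156.5 for three-times-
weekly, 182.6 every other day, 365.25 daily, 52.18 weekly) divided by units
per pack. Pack contents are not published either; the defaults use the
marketed Italian pack sizes (1 vial natalizumab; 12, 15, 28 and 4 units for
the self-injectables), which puts blended first-line cost at ≈ €12,036/year
and natalizumab at ≈ €23,480 + €589.78 administration — plausible Italian
annual therapy costs. All of it is overridable in the configuration. The
first-line phase is costed as a single mix-weighted blend (drug, monitoring,
adverse events), since a cohort model needs one first-line profile.
First-year vs subsequent-year monitoring is allocated by the cohort mass
newly entering each phase per cycle, recorded in the trace — exact at cohort
level for one-year cycles, with no extra tunnel states.

The utility of a live state is the band utility, minus 0.0092 in SPMS,
minus 0.0437 × the state's treatment-modified relapse rate, minus the
active treatment's expected adverse-event decrement
(incidence × disutility × fraction of the year affected). "Total direct
costs" means all categories except EDSS indirect costs (which include
productivity losses and non-healthcare direct costs); cumulative relapses
are reported undiscounted.

## Synthetic placeholder inputs

Four blocks the published analysis references but does not print are
generated by `generate_placeholder_parameters()` and shipped in
`inst/extdata/placeholders_synthetic.yaml`, each tagged
`provenance: placeholder`:

- RRMS utilities linearly decreasing from 0.88 (band 0) to 0.38 (band 8) —
  the typical EQ-5D gradient in MS trial populations;
- annual RRMS→SPMS conversion rising from 0.02 to 0.10 across bands, the
  range long-term registry analyses report;
- SPMS progression with mass (0.75, 0.20, 0.05) on shifts {0, +1, +2} and
  none on regression, since progressive disability is irreversible;
- a Gompertz–Makeham life table by single year of age and sex with male
  excess mortality, and MS mortality multipliers rising linearly with band
  (1.1–3.1 RRMS, 1.5–3.9 SPMS);
- small adverse-event profiles per treatment (flu-like symptoms and
  injection-site reactions for the self-injectables, infusion reactions and
  rare serious hypersensitivity for natalizumab), with serious/non-serious
  split and duration fractions in (0, 0.5].

These are deliberately simple parametric shapes so that property tests have
analyzable behaviour (monotone utilities, monotone mortality). They claim
**no** fidelity to the unpublished supplementary tables; anyone holding
those tables can transcribe them into the configuration schema and the
placeholders are bypassed entirely.

What passing tests therefore show: the machinery — estimation, transition
algebra, accounting, sensitivity analyses — is correct, conserves
probability, reproduces every printed-input computation exactly, and
responds to inputs in the documented directions. What they do not show:
that the shipped absolute cost and QALY levels match the published ones.
Under the placeholders the base case computes a lifetime social cost of
about €976,600 (ESC) vs €976,250 (SWI): early escalation gains 0.87 QALYs,
0.15 life years and prevents 3.1 relapses per patient, and its
relapse-cost relative difference (−27.0%) lands on the published −26.87%,
but the +€337 (+0.03%) cost increment means ESC is *not* strictly dominant
here, unlike in the published base case. The gap is attributable to the
placeholder SPMS dynamics and high-band mortality: both arms spend long,
expensive years in SPMS/high-EDSS states, diluting the between-arm
disability-cost savings that produce dominance with the original inputs.
The placeholder values were fixed once, on clinical-realism grounds, and
are not calibrated to reproduce the published verdict — the package reports
what they imply.

## Sensitivity analyses

**One-way (deterministic).** Ten scenarios: ±10% on therapy acquisition
costs (administration and monitoring untouched — the narrowest reading of
"therapy costs"), ±10% on direct disability costs, ±10% on the relapse unit
cost, ±10% on RRMS band utilities (disutilities untouched), and
switching-arm escalation thresholds of EDSS 3 and EDSS 5. Each is a full
two-strategy run; a scenario that produces an invalid parameter set is
recorded as failed without aborting the analysis.

**Probabilistic.** 1000 iterations, every scalar input drawn independently
with standard error 10% of its mean: lognormal for clinical variables
(relapse rates, adverse-event incidences, MS mortality multipliers,
utilities and disutilities — following the published family assignment even
though lognormal utilities are unusual; draws above 1 are capped with a
warning, and mortality multipliers are floored at 1 to preserve their
invariant), beta for transition probabilities (the two shift vectors
element-wise with renormalization — a Dirichlet would be the joint
alternative, but element-wise follows the published wording — plus SPMS
conversion and progression), gamma for costs. Moment matching is closed
form: lognormal $\sigma^2_{\log} = \ln(1 + (se/m)^2)$; beta
$\alpha + \beta = m(1-m)/se^2 - 1$; gamma shape $(m/se)^2$ (= 100 at a 10%
SE). Structural zeros (e.g. the switching vector's P(−1) = 0.0000) stay
degenerate at zero. Two numerical guards: infeasible beta variances fall
back to a point mass at the mean with a warning, and shape parameters above
$10^7$ (the $se \to 0$ regime) return the exact mean rather than sampling,
so a vanishing standard error reproduces the deterministic base case to
machine-level agreement. Moment matching is verified against Monte-Carlo
means at $10^6$ draws (within 3 standard errors).

Each iteration derives its own RNG substream deterministically from
(root seed, iteration), so iterations are order-independent and
reproducible individually. Cost-effectiveness at a willingness-to-pay
$\lambda$ uses the net monetary benefit
$\Delta E \cdot \lambda - \Delta C > 0$ (the primary definition; quadrant
shares are also reported), dominance the quadrant rule
$\Delta C < 0 \wedge \Delta E > 0$, and the acceptability curve evaluates
the NMB fraction over a willingness-to-pay grid always containing
€50,000/QALY.

## Numerical choices and degenerate inputs

Transition rows are validated to sum to 1 within $10^{-12}$ and occupancy
rows within $10^{-9}$ per cycle; any negative constructed probability is an
error, not a warning. Ages beyond the life table reuse its last row with a
warning. A zero-cycle horizon returns the baseline occupancy only; an
all-zero shift vector is rejected at normalization. The estimator requires
at least one trajectory and integer band deltas after rounding.

Problem sizes used by the shipped tests and analysis scripts — 10,000
patients for estimator recovery, $10^6$ draws for moment-matching checks,
1000 PSA iterations — were chosen as the smallest sizes at which the
corresponding sampling error is comfortably below the assertion bounds
(binomial ±0.02, 3 Monte-Carlo SEs, ±3 percentage points at n = 1000
respectively).

## Known limitations

- No half-cycle correction and a fixed within-cycle event order; both are
  stated conventions rather than estimated quantities, and alternative
  conventions shift totals by a few percent.
- The first-line phase is a blended average; individual first-line drugs
  are not tracked after entry.
- Treatment discontinuation occurs only at the EDSS thresholds — no
  JC-virus risk management, adverse-event dropout, or waning.
- EDSS shifts are band-homogeneous within a phase (the source study lacked
  the sample size for EDSS-dependent transition probabilities).
- The synthetic placeholder blocks bound what can be concluded about
  absolute cost/QALY levels, as discussed above; conclusions robust under
  them are the printed-input arithmetic, the direction of treatment
  effects, and every structural property of the model.
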