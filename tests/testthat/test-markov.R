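test_that("the state space enumerates 37 states with the death state last", {
  space <- build_state_space()
  expect_equal(nrow(space), 37)
  expect_equal(sum(space$form == "RRMS"), 27)
  expect_equal(sum(space$form == "SPMS"), 9)
  expect_identical(space$form[37], "DEAD")
  expect_true(all(space$phase[space$form == "SPMS"] == "NO_DMT"))
  expect_identical(space$index, 1:37)
})

test_that("strategy policies escalate and stop at the published EDSS thresholds", {
  p <- base_params()
  esc <- p$strategies$esc
  swi <- p$strategies$swi
  expect_identical(policy_phase(swi, "RRMS", 3, "FIRST_LINE"), "FIRST_LINE")
  expect_identical(policy_phase(swi, "RRMS", 4, "FIRST_LINE"), "NATALIZUMAB")
  expect_identical(policy_phase(esc, "RRMS", 7, "NATALIZUMAB"), "NO_DMT")
  expect_identical(policy_phase(esc, "RRMS", 0, "NATALIZUMAB"), "NATALIZUMAB")
  expect_identical(policy_phase(swi, "SPMS", 2, "FIRST_LINE"), "NO_DMT")
  # one-way: regression below a threshold does not de-escalate or resume
  expect_identical(policy_phase(swi, "RRMS", 3, "NATALIZUMAB"), "NATALIZUMAB")
  expect_identical(policy_phase(swi, "RRMS", 2, "NO_DMT"), "NO_DMT")
  expect_error(policy_phase(list(), "RRMS", 1, "FIRST_LINE"), "unknown strategy")
})

test_that("shift distributions are assigned by phase and form", {
  p <- base_params()
  expect_equal(shift_distribution_for("NATALIZUMAB", "RRMS", p),
               c(0.0236, 0.8727, 0.0849, 0.0189, 0) / 1.0001)
  expect_equal(shift_distribution_for("FIRST_LINE", "RRMS", p),
               c(0, 0.8199, 0.1553, 0.0217, 0.0031))
  # off-treatment RRMS defaults to the switching vector
  expect_equal(shift_distribution_for("NO_DMT", "RRMS", p), p$shift$swi)
  spms <- shift_distribution_for("NO_DMT", "SPMS", p)
  expect_equal(spms[1], 0)  # no disability regression in SPMS
})

test_that("mortality blends sexes, applies the MS multiplier, and caps at 1", {
  p <- base_params()
  p$mortality$age <- 0:1
  p$mortality$female <- c(0.01, 0.01)
  p$mortality$male <- c(0.01, 0.01)
  p$mortality$multiplier_rrms <- rep(1, 9)
  p$mortality$multiplier_spms <- rep(2, 9)
  expect_equal(mortality_probability(0, p, "RRMS", 2), 0.01)
  expect_equal(mortality_probability(0, p, "SPMS", 2), 0.02)
  p$mortality$female <- c(0.8, 0.8); p$mortality$male <- c(0.8, 0.8)
  expect_equal(mortality_probability(0, p, "SPMS", 2), 1)
  expect_warning(mortality_probability(200, p, "RRMS", 2), "beyond")
  # sex blending with distinct rates
  p$mortality$female <- c(0.01, 0.01); p$mortality$male <- c(0.03, 0.03)
  expect_equal(mortality_probability(0, p, "RRMS", 2),
               0.658 * 0.01 + 0.342 * 0.03)
})

test_that("relapse rates combine the untreated table with phase multipliers", {
  p <- base_params()
  expect_equal(relapse_rate("RRMS", 4, "NO_DMT", p), 1.7966)
  expect_equal(relapse_rate("RRMS", 4, "NATALIZUMAB", p), 1.7966 * 0.3024)
  expect_equal(relapse_rate("RRMS", 4, "FIRST_LINE", p), 1.7966 * 0.6574)
  expect_equal(relapse_rate("SPMS", 5, "NO_DMT", p), 0.1604)
})

test_that("every constructed transition matrix is row-stochastic to 1e-12", {
  p <- base_params()
  space <- build_state_space()
  for (strat in list(p$strategies$esc, p$strategies$swi)) {
    for (age in c(35.3, 60.3, 84.3)) {
      Tm <- build_transition_matrix(space, p, strat, age)
      expect_true(all(Tm >= 0))
      expect_lt(max(abs(rowSums(Tm) - 1)), 1e-12)
      expect_equal(Tm[37, 37], 1)  # death absorbing
    }
  }
})

test_that("frozen dynamics give the identity on live states", {
  p <- frozen_params()
  space <- build_state_space()
  Tm <- build_transition_matrix(space, p, p$strategies$esc, 40)
  # states whose phase is already consistent with the policy map to themselves
  for (i in which(space$form == "SPMS")) expect_equal(Tm[i, i], 1)
  i <- which(space$form == "RRMS" & space$band == 2 &
               space$phase == "NATALIZUMAB")
  expect_equal(Tm[i, i], 1)
})

test_that("no shift mass escapes above the terminal band or below band 0", {
  p <- base_params()
  space <- build_state_space()
  Tm <- build_transition_matrix(space, p, p$strategies$esc, 40)
  i <- which(space$form == "RRMS" & space$band == 8 & space$phase == "NO_DMT")
  dests <- which(Tm[i, ] > 0)
  expect_true(all(space$band[dests] %in% c(8, NA))) # band 8 or dead
  j <- which(space$form == "RRMS" & space$band == 0 &
               space$phase == "NATALIZUMAB")
  dests0 <- which(Tm[j, ] > 0)
  expect_true(all(is.na(space$band[dests0]) | space$band[dests0] >= 0))
  expect_equal(sum(Tm[j, ]), 1, tolerance = 1e-12)
})

test_that("matrix rows match an exhaustive enumeration over event paths", {
  # independent oracle: sum over (die, shift k, convert) paths with clamping
  p <- base_params()
  space <- build_state_space()
  strat <- p$strategies$swi
  age <- 47.3
  Tm <- build_transition_matrix(space, p, strat, age)
  support <- p$shift$support
  for (i in c(idx <- which(space$form == "RRMS" & space$band == 3 &
                             space$phase == "FIRST_LINE"),
              which(space$form == "RRMS" & space$band == 7 &
                      space$phase == "NO_DMT"),
              which(space$form == "SPMS" & space$band == 6))) {
    form <- space$form[i]; band <- space$band[i]; phase <- space$phase[i]
    expected <- numeric(37)
    d <- mortality_probability(age, p, form, band)
    expected[37] <- d
    s <- shift_distribution_for(phase, form, p)
    for (k in seq_along(support)) {
      b2 <- min(max(band + support[k], 0), 8)
      if (form == "RRMS") {
        conv <- p$spms$conversion[b2 + 1]
        ph2 <- policy_phase(strat, "RRMS", b2, phase)
        jr <- which(space$form == "RRMS" & space$band == b2 &
                      space$phase == ph2)
        js <- which(space$form == "SPMS" & space$band == b2)
        expected[jr] <- expected[jr] + (1 - d) * s[k] * (1 - conv)
        expected[js] <- expected[js] + (1 - d) * s[k] * conv
      } else {
        js <- which(space$form == "SPMS" & space$band == b2)
        expected[js] <- expected[js] + (1 - d) * s[k]
      }
    }
    expect_equal(unname(Tm[i, ]), expected, tolerance = 1e-14)
  }
})

test_that("the cohort trace conserves mass and absorbs deaths monotonically", {
  bc <- base_case_results()
  for (trace in list(bc$trace_esc, bc$trace_swi)) {
    expect_lt(max(abs(rowSums(trace$occupancy) - 1)), 1e-9)
    dead <- trace$occupancy[, 37]
    expect_true(all(diff(dead) >= -1e-15))
    expect_gt(dead[51], dead[1])  # strictly increasing under positive mortality
    expect_true(all(trace$phase_entry >= -1e-15))
  }
})

test_that("zero mortality keeps the whole cohort alive over the horizon", {
  p <- base_params()
  p$mortality$female[] <- 0
  p$mortality$male[] <- 0
  trace <- run_cohort(p, "ESC")
  expect_equal(max(trace$occupancy[, 37]), 0)
  expect_lt(max(abs(rowSums(trace$occupancy) - 1)), 1e-9)
})

test_that("a zero-cycle horizon returns the baseline only", {
  p <- base_params()
  p$settings$horizon <- 0L
  trace <- run_cohort(p, "SWI")
  expect_equal(nrow(trace$occupancy), 1)
  # baseline distribution placed in RRMS at the policy-prescribed phase
  sp <- trace$space
  expect_equal(sum(trace$occupancy[1, sp$form == "RRMS"]), 1, tolerance = 1e-12)
  # switching cohort at baseline bands 4-5 starts directly on natalizumab
  nat0 <- sum(trace$occupancy[1, sp$form == "RRMS" &
                                sp$phase == "NATALIZUMAB"])
  expect_equal(nat0, 0.1018 + 0.0632, tolerance = 1e-12)
})

test_that("escalation keeps more of the cohort below EDSS 5 at every cycle", {
  # identical mortality and conversion dynamics isolate the shift-vector
  # dominance (the escalation vector first-order dominates the switching one)
  p <- base_params()
  p$mortality$multiplier_rrms[] <- 1.5
  p$mortality$multiplier_spms[] <- 1.5
  p$spms$conversion[] <- 0.03
  esc <- run_cohort(p, "ESC")
  swi <- run_cohort(p, "SWI")
  expect_true(all(proportion_below_band(esc, 5) >=
                    proportion_below_band(swi, 5) - 1e-12))
})
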