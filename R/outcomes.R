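# Discounted outcome and cost accounting over a cohort trace, and
# between-strategy comparison (increments, relative differences, ICER /
# dominance).
#
# Accrual convention: each of the `horizon` model years is valued at its
# start-of-year occupancy (cycle t, discount factor (1+r)^-t); no half-cycle
# correction is applied anywhere.

MS_COST_CATEGORIES <- c("treatment_administration", "monitoring", "relapse",
                        "adverse_event", "edss_direct", "edss_indirect")

#' Discount factor for a cycle
#'
#' `(1 + rate)^(-cycle)`; cycle 0 is undiscounted.
#'
#' @param cycle non-negative integer cycle index.
#' @param rate annual discount rate (>= 0).
#' @return unitless factor.
#' @export
discount_factor <- function(cycle, rate) {
  if (rate < 0) stop("discount rate must be >= 0")
  if (any(cycle < 0)) stop("cycle must be >= 0")
  (1 + rate)^(-cycle)
}

ae_profile_for_phase <- function(phase, form, p) {
  if (form == "SPMS") return(p$phase$NO_DMT$ae)
  p$phase[[phase]]$ae
}

#' Annual utility of a live state
#'
#' The RRMS utility at the state's EDSS band, minus the SPMS-transition
#' disutility when in the progressive form, minus the relapse disutility per
#' event times the state's (treatment-modified) annual relapse rate, minus
#' the expected adverse-event disutility of the active treatment (incidence
#' x decrement x fraction of the year affected).
#'
#' @param form `"RRMS"` or `"SPMS"`.
#' @param band EDSS band 0..8.
#' @param phase a `TreatmentPhase`.
#' @param p parameter set.
#' @param floor optional lower clip for the utility (default none).
#' @return utility per year.
#' @export
cycle_utility <- function(form, band, phase, p, floor = NULL) {
  u <- p$utilities$rrms[band + 1]
  if (form == "SPMS") u <- u - p$utilities$spms_disutility
  u <- u - relapse_rate(form, band, phase, p) * p$utilities$relapse_disutility
  ae <- ae_profile_for_phase(phase, form, p)
  if (nrow(ae) > 0) {
    u <- u - sum(ae$annual_incidence * ae$disutility * ae$duration_fraction)
  }
  if (!is.null(floor)) u <- max(u, floor)
  u
}

#' Annual costs of a live state, by category
#'
#' Treatment acquisition plus administration for the active phase; monitoring
#' at the first-year tariff for the share of the state's occupancy that
#' newly entered the phase this cycle and the subsequent-year tariff for the
#' rest; relapse management at the unit relapse cost times the annual
#' relapse rate; expected adverse-event management cost; and EDSS
#' disability-related direct and indirect costs for the disease form and
#' band. Untreated states carry no treatment, administration or monitoring
#' cost.
#'
#' @inheritParams cycle_utility
#' @param entry_flow_share share in \[0, 1\] of this state's occupancy that
#'   entered its treatment phase at the start of the current cycle.
#' @return named numeric vector over the six cost categories (euro/year).
#' @export
cycle_costs <- function(form, band, phase, entry_flow_share, p) {
  ph <- if (form == "SPMS") p$phase$NO_DMT else p$phase[[phase]]
  ae <- ph$ae
  rr <- relapse_rate(form, band, phase, p)
  dc <- p$disability_costs
  direct <- if (form == "SPMS") dc$spms_direct[band + 1] else
    dc$rrms_direct[band + 1]
  indirect <- if (form == "SPMS") dc$spms_indirect[band + 1] else
    dc$rrms_indirect[band + 1]
  c(
    treatment_administration = ph$drug_cost + ph$administration,
    monitoring = entry_flow_share * ph$monitoring_year1 +
      (1 - entry_flow_share) * ph$monitoring_subsequent,
    relapse = rr * p$settings$relapse_cost,
    adverse_event = if (nrow(ae) > 0)
      sum(ae$annual_incidence * ae$unit_cost) else 0,
    edss_direct = direct,
    edss_indirect = indirect
  )
}

#' Accumulate a cohort trace into an outcome summary
#'
#' Sums occupancy-weighted per-state annual utilities, relapse rates and
#' costs over the horizon, discounted and undiscounted. Monitoring costs are
#' split between first-year and subsequent-year tariffs by the per-cycle
#' phase-entry flows recorded in the trace. Cumulative relapses are reported
#' undiscounted (a discounted variant is also carried).
#'
#' @param trace an `ms_trace` from [run_cohort()].
#' @param p the parameter set the trace was run under.
#' @return an `ms_outcomes` list with `discounted` and `undiscounted`
#'   blocks, each holding `life_years`, `qalys`, `relapses`, the six cost
#'   categories, `total_direct` and `total_social`.
#' @export
accumulate <- function(trace, p) {
  space <- trace$space
  n <- nrow(space)
  live <- which(space$form != "DEAD")
  horizon <- nrow(trace$occupancy) - 1
  rate <- p$settings$discount_rate

  util <- numeric(n)
  rr <- numeric(n)
  cost_fixed <- matrix(0, n, length(MS_COST_CATEGORIES),
                       dimnames = list(NULL, MS_COST_CATEGORIES))
  mon1 <- numeric(n)
  mon2 <- numeric(n)
  for (i in live) {
    form <- space$form[i]; band <- space$band[i]; phase <- space$phase[i]
    util[i] <- cycle_utility(form, band, phase, p)
    rr[i] <- relapse_rate(form, band, phase, p)
    cost_fixed[i, ] <- cycle_costs(form, band, phase, 0, p)
    ph <- if (form == "SPMS") p$phase$NO_DMT else p$phase[[phase]]
    mon1[i] <- ph$monitoring_year1
    mon2[i] <- ph$monitoring_subsequent
  }

  zero <- stats::setNames(numeric(length(MS_COST_CATEGORIES)),
                          MS_COST_CATEGORIES)
  acc <- list(
    discounted = list(life_years = 0, qalys = 0, relapses = 0, costs = zero),
    undiscounted = list(life_years = 0, qalys = 0, relapses = 0, costs = zero)
  )

  if (horizon >= 1) {
    for (t in 0:(horizon - 1)) {
      occ <- trace$occupancy[t + 1, ]
      df <- discount_factor(t, rate)
      ly <- sum(occ[live])
      qa <- sum(occ * util)
      rl <- sum(occ * rr)
      costs <- as.numeric(occ %*% cost_fixed)
      names(costs) <- MS_COST_CATEGORIES
      # year-1 monitoring for mass that entered its phase this cycle
      mon_extra <- 0
      for (q in c("FIRST_LINE", "NATALIZUMAB")) {
        flow <- trace$phase_entry[t + 1, q]
        sel <- which(space$form == "RRMS" & space$phase == q)
        occ_q <- sum(occ[sel])
        flow <- min(flow, occ_q)
        y1 <- mon1[sel[1]]; y2 <- mon2[sel[1]]
        mon_extra <- mon_extra + flow * y1 + (occ_q - flow) * y2
      }
      costs["monitoring"] <- mon_extra

      for (block in c("discounted", "undiscounted")) {
        w <- if (block == "discounted") df else 1
        acc[[block]]$life_years <- acc[[block]]$life_years + w * ly
        acc[[block]]$qalys <- acc[[block]]$qalys + w * qa
        acc[[block]]$relapses <- acc[[block]]$relapses + w * rl
        acc[[block]]$costs <- acc[[block]]$costs + w * costs
      }
    }
  }

  for (block in c("discounted", "undiscounted")) {
    cs <- acc[[block]]$costs
    acc[[block]]$total_social <- sum(cs)
    acc[[block]]$total_direct <- sum(cs) - cs[["edss_indirect"]]
  }

  structure(c(acc, list(strategy = trace$strategy, horizon = horizon)),
            class = "ms_outcomes")
}

#' Relative difference in percent
#'
#' `100 * (b - a) / a`, the convention used for between-strategy relative
#' differences; `NA` when the reference is zero.
#'
#' @param b comparator value.
#' @param a reference value.
#' @return percent difference.
#' @export
relative_difference <- function(b, a) {
  ifelse(a == 0, NA_real_, 100 * (b - a) / a)
}

#' Compare two strategy outcome summaries
#'
#' Computes incremental discounted costs, QALYs and life years of strategy B
#' over strategy A, per-category relative differences, and the ICER per QALY
#' gained — replaced by a dominance label when one strategy is both cheaper
#' and more effective (`"B DOMINANT"` / `"B DOMINATED"`), or by
#' `"UNDEFINED"` when the QALY increment is zero with a cost difference.
#'
#' @param b outcome summary of the comparator strategy (B).
#' @param a outcome summary of the reference strategy (A).
#' @param wtp willingness-to-pay threshold (euro/QALY) for the net monetary
#'   benefit.
#' @return an `ms_incremental` list.
#' @export
compare_strategies <- function(b, a, wtp = 50000) {
  dc <- b$discounted$total_social - a$discounted$total_social
  dq <- b$discounted$qalys - a$discounted$qalys
  dl <- b$discounted$life_years - a$discounted$life_years

  icer <- if (dc < 0 && dq > 0) {
    "B DOMINANT"
  } else if (dc > 0 && dq < 0) {
    "B DOMINATED"
  } else if (dq == 0 && dc != 0) {
    "UNDEFINED (zero QALY increment)"
  } else if (dq == 0 && dc == 0) {
    0
  } else {
    dc / dq
  }

  cats <- c(MS_COST_CATEGORIES, "total_direct", "total_social")
  bv <- c(b$discounted$costs, total_direct = unname(b$discounted$total_direct),
          total_social = unname(b$discounted$total_social))
  av <- c(a$discounted$costs, total_direct = unname(a$discounted$total_direct),
          total_social = unname(a$discounted$total_social))
  table <- data.frame(
    category = cats,
    b = as.numeric(bv[cats]),
    a = as.numeric(av[cats]),
    absolute_difference = as.numeric(bv[cats] - av[cats]),
    relative_difference_pct = relative_difference(as.numeric(bv[cats]),
                                                  as.numeric(av[cats])),
    stringsAsFactors = FALSE
  )

  structure(list(
    delta_cost = dc, delta_qalys = dq, delta_lys = dl,
    delta_relapses = b$undiscounted$relapses - a$undiscounted$relapses,
    icer = icer,
    dominant = dc < 0 && dq > 0,
    nmb = dq * wtp - dc,
    wtp = wtp,
    cost_table = table,
    qaly_relative_difference_pct = relative_difference(b$discounted$qalys,
                                                       a$discounted$qalys),
    ly_relative_difference_pct = relative_difference(
      b$discounted$life_years, a$discounted$life_years
    ),
    strategies = c(b = b$strategy, a = a$strategy)
  ), class = "ms_incremental")
}

#' Run the base-case comparison
#'
#' Runs the cohort model under both strategies and compares escalation (B)
#' against switching (A).
#'
#' @param p validated parameter set.
#' @return list with `esc` and `swi` outcome summaries, the two traces, and
#'   the `comparison`.
#' @export
run_base_case <- function(p) {
  tr_esc <- run_cohort(p, "ESC")
  tr_swi <- run_cohort(p, "SWI")
  esc <- accumulate(tr_esc, p)
  swi <- accumulate(tr_swi, p)
  list(esc = esc, swi = swi,
       trace_esc = tr_esc, trace_swi = tr_swi,
       comparison = compare_strategies(esc, swi, p$settings$wtp_threshold))
}

#' Cost-effectiveness results as a report table
#'
#' Shapes a strategy comparison into the conventional results layout: one
#' row per cost category with both strategies' discounted totals, absolute
#' and relative differences, followed by an outcomes block (QALYs, life
#' years, cumulative relapses) and the ICER / dominance verdict.
#'
#' @param cmp an `ms_incremental` from [compare_strategies()].
#' @param b,a the two `ms_outcomes` the comparison was built from.
#' @return a data.frame (euro to the unit, outcomes to 2 decimals).
#' @export
report_table <- function(cmp, b, a) {
  ct <- cmp$cost_table
  rows <- data.frame(
    quantity = ct$category,
    b = round(ct$b),
    a = round(ct$a),
    absolute_difference = round(ct$absolute_difference),
    relative_difference_pct = round(ct$relative_difference_pct, 2),
    stringsAsFactors = FALSE
  )
  out_rows <- data.frame(
    quantity = c("total_qalys", "total_lys", "cumulative_relapses"),
    b = round(c(b$discounted$qalys, b$discounted$life_years,
                b$undiscounted$relapses), 2),
    a = round(c(a$discounted$qalys, a$discounted$life_years,
                a$undiscounted$relapses), 2),
    absolute_difference = round(c(cmp$delta_qalys, cmp$delta_lys,
                                  cmp$delta_relapses), 2),
    relative_difference_pct = round(c(cmp$qaly_relative_difference_pct,
                                      cmp$ly_relative_difference_pct,
                                      relative_difference(
                                        b$undiscounted$relapses,
                                        a$undiscounted$relapses
                                      )), 2),
    stringsAsFactors = FALSE
  )
  icer_row <- data.frame(
    quantity = "icer_per_qaly",
    b = NA_real_, a = NA_real_, absolute_difference = NA_real_,
    relative_difference_pct = NA_real_, stringsAsFactors = FALSE
  )
  out <- rbind(rows, out_rows, icer_row)
  attr(out, "icer") <- if (is.character(cmp$icer)) cmp$icer else
    round(cmp$icer, 2)
  out
}

#' @export
print.ms_incremental <- function(x, ...) {
  cat(sprintf("Incremental comparison %s vs %s\n",
              x$strategies[["b"]], x$strategies[["a"]]))
  cat(sprintf("  delta cost:   %12.0f EUR\n", x$delta_cost))
  cat(sprintf("  delta QALYs:  %12.2f\n", x$delta_qalys))
  cat(sprintf("  delta LYs:    %12.2f\n", x$delta_lys))
  icer <- if (is.character(x$icer)) x$icer else sprintf("%.0f EUR/QALY", x$icer)
  cat("  ICER:        ", icer, "\n")
  invisible(x)
}
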