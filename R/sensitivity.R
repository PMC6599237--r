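# Deterministic (one-way) and probabilistic sensitivity analyses.
#
# DSA: the six published scenario families (+/-10% therapy costs, +/-10%
# direct disability costs, +/-10% relapse cost, +/-10% utility values, and
# late-escalation thresholds of EDSS 3 and 5 in the switching arm), i.e. ten
# model runs. PSA: moment-matched lognormal draws for clinical variables,
# beta for transition probabilities, gamma for costs, each with a standard
# error of 10% of the mean, N = 1000 iterations.

#' Moment-matched lognormal parameters
#'
#' Returns `meanlog`/`sdlog` such that draws have expectation `mean` and
#' standard deviation `se`: `sdlog^2 = log(1 + (se/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean target mean (> 0).
#' @param se target standard deviation (> 0).
#' @return list with `meanlog` and `sdlog`.
#' @export
lognormal_from_mean_se <- function(mean, se) {
  if (mean <= 0) stop("lognormal moment matching needs mean > 0")
  if (se <= 0) stop("lognormal moment matching needs se > 0")
  s2 <- log(1 + (se / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Moment-matched beta parameters
#'
#' Returns shape parameters with the given mean and standard deviation:
#' `alpha + beta = mean (1 - mean) / se^2 - 1`, `alpha = mean (alpha+beta)`.
#' When the requested variance is infeasible (`se^2 >= mean (1 - mean)`,
#' which includes means at 0 or 1) the draw degenerates at the mean and a
#' warning is issued.
#'
#' @param mean target mean in (0, 1) (0 and 1 allowed but degenerate).
#' @param se target standard deviation.
#' @return list with `alpha`, `beta`, and logical `degenerate`.
#' @export
beta_from_mean_se <- function(mean, se) {
  if (mean < 0 || mean > 1) stop("beta moment matching needs mean in [0, 1]")
  if (mean == 0 || mean == 1 || se^2 >= mean * (1 - mean)) {
    if (mean > 0 && mean < 1) {
      warning("infeasible beta standard error for mean ", mean,
              "; degenerating at the mean")
    }
    return(list(alpha = NA_real_, beta = NA_real_, degenerate = TRUE))
  }
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu, degenerate = FALSE)
}

#' Moment-matched gamma parameters
#'
#' Returns `shape = (mean/se)^2` and `scale = se^2 / mean`; with a 10%
#' standard error this is shape 100, scale mean/100. A non-positive mean
#' degenerates at 0 with a warning.
#'
#' @param mean target mean.
#' @param se target standard deviation (> 0).
#' @return list with `shape`, `scale`, and logical `degenerate`.
#' @export
gamma_from_mean_se <- function(mean, se) {
  if (mean <= 0) {
    warning("non-positive mean for gamma moment matching; degenerating at 0")
    return(list(shape = NA_real_, scale = NA_real_, degenerate = TRUE))
  }
  if (se <= 0) stop("gamma moment matching needs se > 0")
  list(shape = (mean / se)^2, scale = se^2 / mean, degenerate = FALSE)
}

# Shape parameters beyond ~1e7 arise only in the se -> 0 regime; sampling is
# replaced by the exact mean there (the distribution's mass is already
# indistinguishable from a point on double precision).
.max_shape <- 1e7

draw_lognormal <- function(mean, se_fraction) {
  vapply(mean, function(m) {
    if (m <= 0) return(m)
    se <- se_fraction * m
    if (se <= 0) return(m)
    par <- lognormal_from_mean_se(m, se)
    stats::rlnorm(1, par$meanlog, par$sdlog)
  }, numeric(1))
}

draw_beta <- function(mean, se_fraction) {
  vapply(mean, function(m) {
    se <- se_fraction * m
    if (m <= 0 || m >= 1 || se <= 0) return(m)
    par <- suppressWarnings(beta_from_mean_se(m, se))
    if (par$degenerate || par$alpha > .max_shape || par$beta > .max_shape) {
      return(m)
    }
    stats::rbeta(1, par$alpha, par$beta)
  }, numeric(1))
}

draw_gamma <- function(mean, se_fraction) {
  vapply(mean, function(m) {
    if (m <= 0) return(0)
    se <- se_fraction * m
    if (se <= 0) return(m)
    par <- gamma_from_mean_se(m, se)
    if (par$shape > .max_shape) return(m)
    stats::rgamma(1, shape = par$shape, scale = par$scale)
  }, numeric(1))
}

# Deterministic per-iteration seed below 2^31, so iterations are
# reproducible from (seed, iteration) and order-independent.
psa_iteration_seed <- function(seed, iteration) {
  as.integer((as.double(seed) * 48271 + as.double(iteration) * 69621) %%
               2147483587) + 1L
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Perturbs the base-case parameter set with independent draws per scalar
#' input, each with standard error `se_fraction` times its mean: lognormal
#' for clinical variables (relapse rates, adverse-event incidences, MS
#' mortality multipliers, utilities and disutilities — utility draws capped
#' at 1, multipliers floored at 1), beta for transition probabilities (the
#' two EDSS shift vectors element-wise with renormalization, SPMS conversion
#' and progression), and gamma for costs (pack prices, monitoring,
#' administration, relapse cost, disability costs, adverse-event unit
#' costs). Derived quantities are recomputed from the draws. Reproducible
#' from `(seed, iteration)`.
#'
#' @param p validated base-case parameter set.
#' @param settings list with `se_fraction` (and optionally `n_iterations`);
#'   defaults to `p$psa`.
#' @param iteration iteration index (>= 1).
#' @param seed root seed of the analysis.
#' @param max_retries redraw attempts if a draw invalidates the set.
#' @return a validated perturbed `ms_parameters`.
#' @export
draw_psa_parameter_set <- function(p, settings = p$psa, iteration = 1L,
                                   seed = 1L, max_retries = 10L) {
  sef <- settings$se_fraction
  for (attempt in 0:max_retries) {
    set.seed(psa_iteration_seed(seed + attempt * 7919L, iteration))
    q <- p

    q$relapse_rates$rrms <- draw_lognormal(p$relapse_rates$rrms, sef)
    q$relapse_rates$spms <- draw_lognormal(p$relapse_rates$spms, sef)
    q$mortality$multiplier_rrms <-
      pmax(1, draw_lognormal(p$mortality$multiplier_rrms, sef))
    q$mortality$multiplier_spms <-
      pmax(1, draw_lognormal(p$mortality$multiplier_spms, sef))
    u <- draw_lognormal(p$utilities$rrms, sef)
    if (any(u > 1)) {
      warning("utility draw above 1 capped")
      u <- pmin(u, 1)
    }
    q$utilities$rrms <- u
    q$utilities$spms_disutility <-
      draw_lognormal(p$utilities$spms_disutility, sef)
    q$utilities$relapse_disutility <-
      draw_lognormal(p$utilities$relapse_disutility, sef)

    q$shift$esc <- normalize_shift_distribution(draw_beta(p$shift$esc, sef))
    q$shift$swi <- normalize_shift_distribution(draw_beta(p$shift$swi, sef))
    q$shift$off_treatment <-
      normalize_shift_distribution(draw_beta(p$shift$off_treatment, sef))
    q$shift$esc_raw <- q$shift$esc
    q$spms$conversion <- draw_beta(p$spms$conversion, sef)
    q$spms$progression <-
      normalize_shift_distribution(draw_beta(p$spms$progression, sef))

    q$settings$relapse_cost <- draw_gamma(p$settings$relapse_cost, sef)
    for (id in names(p$treatments)) {
      tr <- p$treatments[[id]]
      qtr <- q$treatments[[id]]
      qtr$pack_price <- draw_gamma(tr$pack_price, sef)
      qtr$monitoring_year1 <- draw_gamma(tr$monitoring_year1, sef)
      qtr$monitoring_subsequent <- draw_gamma(tr$monitoring_subsequent, sef)
      qtr$administration_annual <- draw_gamma(tr$administration_annual, sef)
      qtr$annual_cost <- annual_drug_cost(qtr)
      q$treatments[[id]] <- qtr
    }
    for (nm in names(p$disability_costs)) {
      q$disability_costs[[nm]] <- draw_gamma(p$disability_costs[[nm]], sef)
    }
    for (id in names(p$adverse_events)) {
      ae <- p$adverse_events[[id]]
      if (nrow(ae) == 0) next
      qae <- q$adverse_events[[id]]
      qae$annual_incidence <- draw_lognormal(ae$annual_incidence, sef)
      qae$disutility <- draw_lognormal(ae$disutility, sef)
      qae$unit_cost <- draw_gamma(ae$unit_cost, sef)
      q$adverse_events[[id]] <- qae
    }

    q <- derive_phase_tables(q)
    if (length(validate_parameter_set(q)) == 0) return(q)
  }
  stop("could not draw a valid parameter set after ", max_retries, " retries")
}

#' Run the probabilistic sensitivity analysis
#'
#' `n` iterations of draw -> run both strategies -> record the incremental
#' cost and QALYs of escalation over switching. The cost-effective fraction
#' is the share of iterations with positive net monetary benefit at the
#' willingness-to-pay threshold; the dominant fraction is the share with
#' lower cost and higher QALYs. Failed iterations are excluded and counted.
#'
#' @param p validated base-case parameter set.
#' @param settings list with `n_iterations` and `se_fraction`; defaults to
#'   `p$psa`.
#' @param wtp willingness-to-pay threshold (euro/QALY); defaults to the
#'   configured threshold.
#' @param seed root seed.
#' @return an `ms_psa` list: per-iteration `draws` data.frame
#'   (`iteration`, `delta_cost`, `delta_qalys`, `nmb`, `dominant`),
#'   `fraction_cost_effective`, `fraction_dominant`, `n_failed`, `wtp`,
#'   `seed`.
#' @export
run_psa <- function(p, settings = p$psa, wtp = p$settings$wtp_threshold,
                    seed = 1L) {
  n <- settings$n_iterations
  rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      q <- draw_psa_parameter_set(p, settings, iteration = i, seed = seed)
      esc <- accumulate(run_cohort(q, "ESC"), q)
      swi <- accumulate(run_cohort(q, "SWI"), q)
      dc <- esc$discounted$total_social - swi$discounted$total_social
      dq <- esc$discounted$qalys - swi$discounted$qalys
      data.frame(iteration = i, delta_cost = dc, delta_qalys = dq,
                 nmb = dq * wtp - dc, dominant = dc < 0 && dq > 0)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[i]] <- res
  }
  draws <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(draws) || nrow(draws) == 0) stop("all PSA iterations failed")
  structure(list(
    draws = draws,
    fraction_cost_effective = mean(draws$nmb > 0),
    fraction_dominant = mean(draws$dominant),
    n_failed = n_failed,
    wtp = wtp,
    seed = seed
  ), class = "ms_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive net monetary benefit at each
#' willingness-to-pay value on the grid (the 50,000 euro/QALY point is
#' always included).
#'
#' @param result an `ms_psa`.
#' @param wtp_grid willingness-to-pay grid (euro/QALY).
#' @return data.frame with `wtp` and `fraction_cost_effective`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 150000, by = 5000)) {
  if (nrow(result$draws) == 0) stop("empty PSA result")
  wtp_grid <- sort(unique(c(wtp_grid, 50000)))
  frac <- vapply(wtp_grid, function(w)
    mean(result$draws$delta_qalys * w - result$draws$delta_cost > 0),
    numeric(1))
  data.frame(wtp = wtp_grid, fraction_cost_effective = frac)
}

#' @export
print.ms_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (%d failed), wtp %.0f EUR/QALY\n",
              nrow(x$draws) + x$n_failed, x$n_failed, x$wtp))
  cat(sprintf("  cost-effective: %.1f%%\n", 100 * x$fraction_cost_effective))
  cat(sprintf("  dominant:       %.1f%%\n", 100 * x$fraction_dominant))
  invisible(x)
}

# One DSA scenario: a named transform of the parameter set.
dsa_scenarios <- function() {
  scale_treatments <- function(f) function(p) {
    for (id in names(p$treatments)) {
      p$treatments[[id]]$pack_price <- p$treatments[[id]]$pack_price * f
      p$treatments[[id]]$annual_cost <- annual_drug_cost(p$treatments[[id]])
    }
    derive_phase_tables(p)
  }
  scale_disability_direct <- function(f) function(p) {
    p$disability_costs$rrms_direct <- p$disability_costs$rrms_direct * f
    p$disability_costs$spms_direct <- p$disability_costs$spms_direct * f
    p
  }
  scale_relapse_cost <- function(f) function(p) {
    p$settings$relapse_cost <- p$settings$relapse_cost * f
    p
  }
  scale_utilities <- function(f) function(p) {
    p$utilities$rrms <- pmin(1, p$utilities$rrms * f)
    p
  }
  swi_threshold <- function(th) function(p) {
    p$strategies$swi$escalation_edss_threshold <- th
    p
  }
  list(
    therapy_costs_minus10 = scale_treatments(0.9),
    therapy_costs_plus10 = scale_treatments(1.1),
    disability_direct_costs_minus10 = scale_disability_direct(0.9),
    disability_direct_costs_plus10 = scale_disability_direct(1.1),
    relapse_cost_minus10 = scale_relapse_cost(0.9),
    relapse_cost_plus10 = scale_relapse_cost(1.1),
    utilities_minus10 = scale_utilities(0.9),
    utilities_plus10 = scale_utilities(1.1),
    swi_escalation_at_edss3 = swi_threshold(3),
    swi_escalation_at_edss5 = swi_threshold(5)
  )
}

#' Run the deterministic (one-way) sensitivity analysis
#'
#' Ten scenarios: therapy acquisition costs, direct disability costs,
#' relapse unit cost and RRMS utilities each varied by +/-10%, plus
#' late-escalation thresholds of EDSS 3 and EDSS 5 in the switching arm.
#' Each scenario is a full two-strategy model run. A scenario producing an
#' invalid parameter set is recorded as failed and the analysis continues.
#'
#' @param p validated base-case parameter set.
#' @return data.frame with one row per scenario: incremental cost, QALYs and
#'   life years of escalation over switching, the ICER or dominance label,
#'   a `dominant` flag, and a `status` column.
#' @export
run_dsa <- function(p) {
  scen <- dsa_scenarios()
  rows <- lapply(names(scen), function(nm) {
    q <- scen[[nm]](p)
    viol <- validate_parameter_set(q)
    if (length(viol) > 0) {
      return(data.frame(scenario = nm, delta_cost = NA_real_,
                        delta_qalys = NA_real_, delta_lys = NA_real_,
                        icer = NA_character_, dominant = NA,
                        status = paste("failed:", viol[1]),
                        stringsAsFactors = FALSE))
    }
    esc <- accumulate(run_cohort(q, "ESC"), q)
    swi <- accumulate(run_cohort(q, "SWI"), q)
    cmp <- compare_strategies(esc, swi, q$settings$wtp_threshold)
    data.frame(scenario = nm,
               delta_cost = cmp$delta_cost,
               delta_qalys = cmp$delta_qalys,
               delta_lys = cmp$delta_lys,
               icer = if (is.character(cmp$icer)) cmp$icer else
                 sprintf("%.0f", cmp$icer),
               dominant = cmp$dominant,
               status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
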