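# Model inputs: loading, validation, and derived quantities.
#
# The model works on integer EDSS "bands" 0..8, where band 8 aggregates
# EDSS 8-10 (the granularity of the cost and relapse tables). A ParameterSet
# is a plain list (class "ms_parameters") holding every input the cohort
# engine, outcome accounting and sensitivity analyses need, plus a
# provenance tag per block so placeholder values are distinguishable from
# published ones in every export.

#' Treatment phases
#'
#' Ordered phase labels used throughout the model: first-line immunomodulator
#' (interferon beta / glatiramer acetate), natalizumab, and no
#' disease-modifying treatment.
#' @export
MS_PHASES <- c("FIRST_LINE", "NATALIZUMAB", "NO_DMT")

#' EDSS-shift support
#'
#' Annual EDSS band changes the shift distributions are defined over:
#' one-point improvement through three-point worsening.
#' @export
MS_SHIFT_SUPPORT <- -1L:3L

MS_BANDS <- 0L:8L

#' Doses per year implied by a posology code
#'
#' Dispensing-interval conventions: `q4w` every 28 days, `tiw` three times a
#' week, `every_other_day`, `od` once daily, `qw` weekly, on a 365.25-day
#' year.
#'
#' @param posology one of `"q4w"`, `"tiw"`, `"every_other_day"`, `"od"`,
#'   `"qw"`.
#' @return doses per year (numeric scalar).
#' @export
doses_per_year <- function(posology) {
  switch(posology,
    q4w = 365.25 / 28,
    tiw = 156.5,
    every_other_day = 182.6,
    od = 365.25,
    qw = 52.18,
    stop("unknown posology: '", posology, "'")
  )
}

#' Annual acquisition cost of a treatment
#'
#' `pack_price * packs_per_year * (1 - rebate_fraction)`, the net annual
#' ex-factory drug cost per patient.
#'
#' @param spec a treatment cost specification: a list with numeric
#'   `pack_price`, `packs_per_year` and `rebate_fraction` (default 0).
#' @return annual cost in euro.
#' @export
annual_drug_cost <- function(spec) {
  rebate <- if (is.null(spec$rebate_fraction)) 0 else spec$rebate_fraction
  if (rebate < 0 || rebate > 1) {
    stop("rebate_fraction must be in [0, 1], got ", rebate)
  }
  if (spec$pack_price < 0 || spec$packs_per_year < 0) {
    stop("pack_price and packs_per_year must be non-negative")
  }
  spec$pack_price * spec$packs_per_year * (1 - rebate)
}

#' Natalizumab annualized-relapse-rate multiplier
#'
#' The multiplier applied to untreated relapse rates under natalizumab:
#' product of the switching-strategy ARR multiplier and the relapse-rate
#' ratio of escalation vs switching, rounded to 4 decimals (0.6574 x 0.46 =
#' 0.3024).
#'
#' @param arr_multiplier_switching ARR multiplier of the switching strategy
#'   vs no treatment, in (0, 1].
#' @param relapse_rr_esc_vs_swi relapse-rate ratio escalation vs switching,
#'   in (0, 1].
#' @return the natalizumab ARR multiplier (unitless).
#' @export
natalizumab_arr_multiplier <- function(arr_multiplier_switching,
                                       relapse_rr_esc_vs_swi) {
  if (arr_multiplier_switching <= 0 || relapse_rr_esc_vs_swi <= 0) {
    stop("multipliers must be positive")
  }
  if (arr_multiplier_switching > 1 || relapse_rr_esc_vs_swi > 1) {
    stop("multipliers must be <= 1")
  }
  round(arr_multiplier_switching * relapse_rr_esc_vs_swi, 4)
}

required_config_fields <- list(
  settings = c("discount_rate", "horizon", "relapse_cost", "wtp_threshold"),
  cohort = c("start_age", "female_fraction", "edss_distribution"),
  relapse_rates = c("rrms", "spms"),
  treatment_effect = c("arr_multiplier_switching", "relapse_rr_esc_vs_swi"),
  shift_vectors = c("support", "esc", "swi"),
  disability_costs = c("rrms_direct", "rrms_indirect",
                       "spms_direct", "spms_indirect"),
  treatments = character(0),
  first_line_mix = character(0),
  strategies = c("esc", "swi")
)

check_required <- function(config) {
  for (block in names(required_config_fields)) {
    if (is.null(config[[block]])) {
      stop("missing required field: '", block, "'", call. = FALSE)
    }
    for (f in required_config_fields[[block]]) {
      if (is.null(config[[block]][[f]])) {
        stop("missing required field: '", block, "$", f, "'", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

as_num <- function(x, what) {
  y <- suppressWarnings(as.numeric(unlist(x)))
  if (anyNA(y)) stop("malformed number in field '", what, "'", call. = FALSE)
  y
}

#' Load and validate a model parameter set
#'
#' Reads a YAML configuration holding the published model inputs, fills any
#' block the configuration omits (RRMS utilities, SPMS conversion and
#' progression, general mortality, MS mortality multipliers, adverse-event
#' profiles) from a placeholder document, computes derived quantities
#' (normalized shift vectors, annual drug costs, the natalizumab ARR
#' multiplier, the blended first-line treatment), and validates the result.
#' Every placeholder substitution is reported via `message()` and recorded in
#' the returned object's `provenance` field.
#'
#' @param config_path path to the YAML configuration. The base-case
#'   configuration ships at
#'   `system.file("extdata", "base_case.yaml", package = "rrmsce")`.
#' @param placeholder_path path to a YAML document supplying values for
#'   blocks absent from the configuration; defaults to the bundled synthetic
#'   placeholder file.
#' @param quiet suppress placeholder-substitution messages.
#' @return a validated `ms_parameters` object.
#' @export
load_parameters <- function(config_path,
                            placeholder_path = system.file(
                              "extdata", "placeholders_synthetic.yaml",
                              package = "rrmsce"
                            ),
                            quiet = FALSE) {
  if (!file.exists(config_path)) {
    stop("configuration file not found: ", config_path, call. = FALSE)
  }
  config <- yaml::read_yaml(config_path)
  check_required(config)

  placeholders <- if (!is.null(placeholder_path) &&
                        nzchar(placeholder_path) &&
                        file.exists(placeholder_path)) {
    yaml::read_yaml(placeholder_path)
  } else {
    NULL
  }

  provenance <- sapply(names(required_config_fields), function(b) "printed",
                       simplify = FALSE)
  fill <- function(block) {
    if (!is.null(config[[block]])) {
      provenance[[block]] <<- "printed"
      return(config[[block]])
    }
    if (is.null(placeholders[[block]])) {
      stop("missing required field: '", block,
           "' (absent from configuration and placeholder document)",
           call. = FALSE)
    }
    if (!quiet) {
      message("parameter block '", block,
              "' not in configuration; using placeholder values")
    }
    provenance[[block]] <<- "placeholder"
    placeholders[[block]]
  }

  utilities <- fill("utilities")
  spms <- fill("spms")
  mortality <- fill("mortality")
  adverse_events <- fill("adverse_events")

  support <- as.integer(as_num(config$shift_vectors$support,
                               "shift_vectors$support"))
  esc_raw <- as_num(config$shift_vectors$esc, "shift_vectors$esc")
  swi_raw <- as_num(config$shift_vectors$swi, "shift_vectors$swi")
  off_raw <- if (is.null(config$shift_vectors$off_treatment)) {
    swi_raw
  } else {
    as_num(config$shift_vectors$off_treatment, "shift_vectors$off_treatment")
  }

  treatments <- lapply(config$treatments, function(tr) {
    tr$pack_price <- as_num(tr$pack_price, "pack_price")
    tr$units_per_pack <- if (is.null(tr$units_per_pack)) 1 else
      as_num(tr$units_per_pack, "units_per_pack")
    tr$rebate_fraction <- if (is.null(tr$rebate_fraction)) 0 else
      as_num(tr$rebate_fraction, "rebate_fraction")
    tr$packs_per_year <- if (!is.null(tr$packs_per_year)) {
      as_num(tr$packs_per_year, "packs_per_year")
    } else {
      doses_per_year(tr$posology) / tr$units_per_pack
    }
    tr$annual_cost <- annual_drug_cost(tr)
    tr
  })

  adverse_events <- Filter(is.list, adverse_events)  # drop provenance notes
  ae <- lapply(adverse_events, function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(
        event = r$event, serious = isTRUE(r$serious),
        annual_incidence = as_num(r$annual_incidence, "annual_incidence"),
        unit_cost = as_num(r$unit_cost, "unit_cost"),
        disutility = as_num(r$disutility, "disutility"),
        duration_fraction = as_num(r$duration_fraction, "duration_fraction"),
        stringsAsFactors = FALSE
      )
    }))
  })

  strat <- function(s, name) {
    list(
      name = name,
      initial_phase = s$initial_phase,
      escalation_edss_threshold = as_num(s$escalation_edss_threshold,
                                         "escalation_edss_threshold"),
      stop_edss_threshold = as_num(s$stop_edss_threshold,
                                   "stop_edss_threshold")
    )
  }

  eff_sw <- as_num(config$treatment_effect$arr_multiplier_switching,
                   "arr_multiplier_switching")
  eff_rr <- as_num(config$treatment_effect$relapse_rr_esc_vs_swi,
                   "relapse_rr_esc_vs_swi")

  p <- structure(list(
    settings = list(
      discount_rate = as_num(config$settings$discount_rate, "discount_rate"),
      horizon = as.integer(as_num(config$settings$horizon, "horizon")),
      relapse_cost = as_num(config$settings$relapse_cost, "relapse_cost"),
      wtp_threshold = as_num(config$settings$wtp_threshold, "wtp_threshold")
    ),
    cohort = list(
      start_age = as_num(config$cohort$start_age, "start_age"),
      female_fraction = as_num(config$cohort$female_fraction,
                               "female_fraction"),
      edss_distribution = as_num(config$cohort$edss_distribution,
                                 "edss_distribution")
    ),
    relapse_rates = list(
      rrms = as_num(config$relapse_rates$rrms, "relapse_rates$rrms"),
      spms = as_num(config$relapse_rates$spms, "relapse_rates$spms")
    ),
    effect = list(
      arr_multiplier_switching = eff_sw,
      relapse_rr_esc_vs_swi = eff_rr,
      arr_multiplier_natalizumab = natalizumab_arr_multiplier(eff_sw, eff_rr)
    ),
    shift = list(
      support = support,
      esc_raw = esc_raw,
      esc = normalize_shift_distribution(esc_raw),
      swi = normalize_shift_distribution(swi_raw),
      off_treatment = normalize_shift_distribution(off_raw)
    ),
    disability_costs = list(
      rrms_direct = as_num(config$disability_costs$rrms_direct, "rrms_direct"),
      rrms_indirect = as_num(config$disability_costs$rrms_indirect,
                             "rrms_indirect"),
      spms_direct = as_num(config$disability_costs$spms_direct, "spms_direct"),
      spms_indirect = as_num(config$disability_costs$spms_indirect,
                             "spms_indirect")
    ),
    treatments = treatments,
    first_line_mix = lapply(config$first_line_mix, as.numeric),
    utilities = list(
      rrms = as_num(utilities$rrms, "utilities$rrms"),
      spms_disutility = as_num(utilities$spms_disutility, "spms_disutility"),
      relapse_disutility = as_num(utilities$relapse_disutility,
                                  "relapse_disutility")
    ),
    spms = list(
      conversion = as_num(spms$conversion, "spms$conversion"),
      progression = normalize_shift_distribution(
        as_num(spms$progression, "spms$progression")
      )
    ),
    mortality = list(
      age = as.integer(as_num(mortality$age, "mortality$age")),
      female = as_num(mortality$female, "mortality$female"),
      male = as_num(mortality$male, "mortality$male"),
      multiplier_rrms = as_num(mortality$multiplier_rrms, "multiplier_rrms"),
      multiplier_spms = as_num(mortality$multiplier_spms, "multiplier_spms")
    ),
    adverse_events = ae,
    strategies = list(
      esc = strat(config$strategies$esc, "ESC"),
      swi = strat(config$strategies$swi, "SWI")
    ),
    psa = list(
      n_iterations = if (is.null(config$psa$n_iterations)) 1000L else
        as.integer(as_num(config$psa$n_iterations, "psa$n_iterations")),
      se_fraction = if (is.null(config$psa$se_fraction)) 0.10 else
        as_num(config$psa$se_fraction, "psa$se_fraction")
    ),
    provenance = provenance
  ), class = "ms_parameters")

  p <- derive_phase_tables(p)

  violations <- validate_parameter_set(p)
  if (length(violations) > 0) {
    stop("invalid parameter set:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  p
}

# Phase-level cost/AE lookups used by the engine: the first-line phase is a
# single blended treatment, weighted by the printed treatment mix.
derive_phase_tables <- function(p) {
  mix <- p$first_line_mix
  w <- unlist(mix)
  stopifnot(all(names(mix) %in% names(p$treatments)))
  blend <- function(f) sum(w * vapply(names(mix), function(id)
    f(p$treatments[[id]]), numeric(1)))
  blend_ae <- function() {
    pieces <- lapply(names(mix), function(id) {
      df <- p$adverse_events[[id]]
      if (is.null(df) || nrow(df) == 0 || w[[id]] == 0) return(NULL)
      df$annual_incidence <- df$annual_incidence * w[[id]]
      df
    })
    pieces <- Filter(Negate(is.null), pieces)
    if (length(pieces) == 0) empty_ae() else do.call(rbind, pieces)
  }
  nat <- p$treatments$natalizumab
  p$phase <- list(
    FIRST_LINE = list(
      drug_cost = blend(function(t) t$annual_cost),
      administration = blend(function(t) as.numeric(t$administration_annual)),
      monitoring_year1 = blend(function(t) as.numeric(t$monitoring_year1)),
      monitoring_subsequent = blend(function(t)
        as.numeric(t$monitoring_subsequent)),
      ae = blend_ae()
    ),
    NATALIZUMAB = list(
      drug_cost = nat$annual_cost,
      administration = as.numeric(nat$administration_annual),
      monitoring_year1 = as.numeric(nat$monitoring_year1),
      monitoring_subsequent = as.numeric(nat$monitoring_subsequent),
      ae = if (is.null(p$adverse_events$natalizumab)) empty_ae() else
        p$adverse_events$natalizumab
    ),
    NO_DMT = list(
      drug_cost = 0, administration = 0,
      monitoring_year1 = 0, monitoring_subsequent = 0,
      ae = empty_ae()
    )
  )
  p
}

empty_ae <- function() {
  data.frame(event = character(0), serious = logical(0),
             annual_incidence = numeric(0), unit_cost = numeric(0),
             disutility = numeric(0), duration_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and returns the
#' violations as data rather than raising: an empty character vector means
#' the set is valid. Each violation names the offending field and the broken
#' rule.
#'
#' @param p an `ms_parameters` object (possibly hand-modified).
#' @return character vector of violation messages (empty if valid).
#' @export
validate_parameter_set <- function(p) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  s <- p$settings
  if (s$discount_rate < 0) add("settings$discount_rate: must be >= 0")
  if (s$horizon < 1) add("settings$horizon: must be >= 1")
  if (s$relapse_cost < 0) add("settings$relapse_cost: must be >= 0")

  co <- p$cohort
  if (length(co$edss_distribution) != 9) {
    add("cohort$edss_distribution: must have 9 entries (bands 0-8)")
  } else {
    if (abs(sum(co$edss_distribution) - 1) > 1e-6) {
      add(sprintf("cohort$edss_distribution: sum = %.4f (must be 1 +/- 1e-6)",
                  sum(co$edss_distribution)))
    }
    if (any(co$edss_distribution < 0)) {
      add("cohort$edss_distribution: negative entry")
    }
  }
  if (co$female_fraction < 0 || co$female_fraction > 1) {
    add("cohort$female_fraction: must be in [0, 1]")
  }

  for (form in c("rrms", "spms")) {
    r <- p$relapse_rates[[form]]
    if (length(r) != 9) add(paste0("relapse_rates$", form, ": needs 9 bands"))
    if (any(r < 0)) add(paste0("relapse_rates$", form, ": negative rate"))
  }

  e <- p$effect
  for (f in c("arr_multiplier_switching", "relapse_rr_esc_vs_swi",
              "arr_multiplier_natalizumab")) {
    if (e[[f]] <= 0 || e[[f]] > 1) {
      add(paste0("effect$", f, ": must be in (0, 1]"))
    }
  }
  if (abs(e$arr_multiplier_natalizumab -
            round(e$arr_multiplier_switching * e$relapse_rr_esc_vs_swi, 4)) >
        5e-5) {
    add("effect$arr_multiplier_natalizumab: not the product of the switching multiplier and the escalation relapse-rate ratio")
  }

  for (nm in c("esc", "swi", "off_treatment")) {
    sv <- p$shift[[nm]]
    if (length(sv) != length(p$shift$support)) {
      add(paste0("shift$", nm, ": length mismatch with support"))
      next
    }
    if (any(sv < 0)) add(paste0("shift$", nm, ": negative probability"))
    if (abs(sum(sv) - 1) > 1e-6) {
      add(sprintf("shift$%s: sum = %.4f (must be 1; normalize first)",
                  nm, sum(sv)))
    }
  }

  for (nm in names(p$disability_costs)) {
    cc <- p$disability_costs[[nm]]
    if (length(cc) != 9) add(paste0("disability_costs$", nm, ": needs 9 bands"))
    if (any(cc < 0)) add(paste0("disability_costs$", nm, ": negative cost"))
  }

  for (id in names(p$treatments)) {
    tr <- p$treatments[[id]]
    if (tr$pack_price < 0 || tr$packs_per_year < 0 ||
          tr$monitoring_year1 < 0 || tr$monitoring_subsequent < 0 ||
          tr$administration_annual < 0) {
      add(paste0("treatments$", id, ": negative cost component"))
    }
    if (tr$rebate_fraction < 0 || tr$rebate_fraction > 1) {
      add(paste0("treatments$", id, ": rebate_fraction outside [0, 1]"))
    }
  }

  mixsum <- sum(unlist(p$first_line_mix))
  if (abs(mixsum - 1) > 1e-6) {
    add(sprintf("first_line_mix: weights sum to %.4f (must be 1)", mixsum))
  }

  u <- p$utilities
  if (length(u$rrms) != 9) add("utilities$rrms: needs 9 bands")
  if (any(u$rrms < -0.5 | u$rrms > 1)) {
    add("utilities$rrms: values outside [-0.5, 1]")
  }
  if (u$spms_disutility < 0) add("utilities$spms_disutility: must be >= 0")
  if (u$relapse_disutility < 0) add("utilities$relapse_disutility: must be >= 0")

  if (length(p$spms$conversion) != 9) add("spms$conversion: needs 9 bands")
  if (any(p$spms$conversion < 0 | p$spms$conversion > 1)) {
    add("spms$conversion: probabilities outside [0, 1]")
  }
  prog <- p$spms$progression
  neg_idx <- which(p$shift$support < 0)
  if (length(prog) != length(p$shift$support)) {
    add("spms$progression: length mismatch with support")
  } else if (any(prog[neg_idx] > 0)) {
    add("spms$progression: positive mass on EDSS regression (must be 0)")
  }

  m <- p$mortality
  if (length(m$age) != length(m$female) || length(m$age) != length(m$male)) {
    add("mortality: age/female/male lengths differ")
  }
  if (any(m$female < 0 | m$female > 1) || any(m$male < 0 | m$male > 1)) {
    add("mortality: death probabilities outside [0, 1]")
  }
  if (any(m$multiplier_rrms < 1) || any(m$multiplier_spms < 1)) {
    add("mortality: MS multipliers must be >= 1")
  }

  for (id in names(p$adverse_events)) {
    ae <- p$adverse_events[[id]]
    if (nrow(ae) == 0) next
    if (any(ae$annual_incidence < 0)) {
      add(paste0("adverse_events$", id, ": negative incidence"))
    }
    if (any(ae$duration_fraction <= 0 | ae$duration_fraction > 0.5)) {
      add(paste0("adverse_events$", id, ": duration_fraction outside (0, 0.5]"))
    }
    if (any(ae$unit_cost < 0)) {
      add(paste0("adverse_events$", id, ": negative unit cost"))
    }
    if (any(ae$disutility < 0)) {
      add(paste0("adverse_events$", id, ": negative disutility"))
    }
  }

  for (nm in c("esc", "swi")) {
    st <- p$strategies[[nm]]
    if (st$stop_edss_threshold <= st$escalation_edss_threshold) {
      add(paste0("strategies$", nm,
                 ": stop threshold must exceed escalation threshold"))
    }
    if (!st$initial_phase %in% MS_PHASES) {
      add(paste0("strategies$", nm, ": unknown initial_phase"))
    }
  }

  if (p$psa$n_iterations < 1) add("psa$n_iterations: must be >= 1")
  if (p$psa$se_fraction < 0) add("psa$se_fraction: must be >= 0")

  v
}

#' Serialize a parameter set back to the configuration schema
#'
#' Writes the printed-input blocks of a parameter set to YAML in the same
#' schema `load_parameters()` reads, with full numeric precision, so a
#' load -> serialize -> load round trip reproduces every table value
#' bit-identically.
#'
#' @param p an `ms_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_parameters <- function(p, path) {
  out <- list(
    settings = p$settings,
    cohort = p$cohort,
    relapse_rates = p$relapse_rates,
    treatment_effect = p$effect[c("arr_multiplier_switching",
                                  "relapse_rr_esc_vs_swi")],
    shift_vectors = list(
      support = p$shift$support,
      esc = p$shift$esc_raw,
      swi = p$shift$swi,
      off_treatment = p$shift$off_treatment
    ),
    disability_costs = p$disability_costs,
    treatments = lapply(p$treatments, function(tr)
      tr[setdiff(names(tr), "annual_cost")]),
    first_line_mix = p$first_line_mix,
    utilities = p$utilities,
    spms = p$spms,
    mortality = p$mortality,
    adverse_events = lapply(p$adverse_events, function(df)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))),
    strategies = lapply(p$strategies, function(st)
      st[setdiff(names(st), "name")]),
    psa = p$psa,
    provenance = p$provenance
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.ms_parameters <- function(x, ...) {
  cat("RRMS cost-effectiveness model parameters\n")
  cat(sprintf("  horizon: %d years, discount rate: %.2f%%\n",
              x$settings$horizon, 100 * x$settings$discount_rate))
  cat(sprintf("  cohort: start age %.1f, %.1f%% female\n",
              x$cohort$start_age, 100 * x$cohort$female_fraction))
  cat(sprintf("  ARR multipliers: first-line %.4f, natalizumab %.4f\n",
              x$effect$arr_multiplier_switching,
              x$effect$arr_multiplier_natalizumab))
  ph <- names(x$provenance)[unlist(x$provenance) == "placeholder"]
  if (length(ph)) {
    cat("  placeholder blocks:", paste(ph, collapse = ", "), "\n")
  }
  invisible(x)
}
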