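# Cohort state space and transition dynamics.
#
# 37 states: 9 RRMS EDSS bands x 3 treatment phases, 9 SPMS bands (always
# untreated), and an absorbing death state. Within each annual cycle events
# compose in a fixed order: death, then EDSS shift, then RRMS->SPMS
# conversion, then treatment-phase update at the destination band. The order
# is a model constant, not configurable.

#' Build the model state space
#'
#' Enumerates all 37 states with a stable, dense index: RRMS states ordered
#' band-major by phase, then SPMS bands (phase forced to `NO_DMT`), then the
#' absorbing death state last.
#'
#' @return data.frame with columns `index`, `form`, `band`, `phase`
#'   (class `ms_state_space`).
#' @export
build_state_space <- function() {
  rr <- expand.grid(phase = MS_PHASES, band = MS_BANDS,
                    stringsAsFactors = FALSE)
  df <- rbind(
    data.frame(form = "RRMS", band = rr$band, phase = rr$phase,
               stringsAsFactors = FALSE),
    data.frame(form = "SPMS", band = MS_BANDS, phase = "NO_DMT",
               stringsAsFactors = FALSE),
    data.frame(form = "DEAD", band = NA_integer_, phase = NA_character_,
               stringsAsFactors = FALSE)
  )
  df <- cbind(index = seq_len(nrow(df)), df)
  class(df) <- c("ms_state_space", "data.frame")
  df
}

idx_rrms <- function(band, phase) {
  3L * band + match(phase, MS_PHASES)
}
idx_spms <- function(band) 27L + band + 1L
idx_dead <- function() 37L

#' Treatment phase prescribed by a strategy policy
#'
#' Escalation (ESC) treats with natalizumab from baseline until EDSS band 7;
#' switching (SWI) treats with first-line immunomodulators until band 4,
#' then natalizumab until band 7; past band 7, and in SPMS, no
#' disease-modifying treatment is given. Phase changes are one-way: a
#' patient whose EDSS regresses below a threshold keeps the later phase.
#'
#' @param strategy a strategy specification (`p$strategies$esc` or `$swi`):
#'   list with `escalation_edss_threshold` and `stop_edss_threshold`.
#' @param form `"RRMS"` or `"SPMS"`.
#' @param band integer EDSS band 0..8.
#' @param phase current `TreatmentPhase`.
#' @return the phase after applying the policy at this band.
#' @export
policy_phase <- function(strategy, form, band, phase) {
  if (is.null(strategy$stop_edss_threshold) ||
        is.null(strategy$escalation_edss_threshold)) {
    stop("unknown strategy: expected a specification with escalation and stop thresholds")
  }
  if (form == "SPMS") return("NO_DMT")
  if (!phase %in% MS_PHASES) stop("unknown phase: ", phase)
  if (phase == "NO_DMT") return("NO_DMT")
  if (band >= strategy$stop_edss_threshold) return("NO_DMT")
  if (phase == "NATALIZUMAB") return("NATALIZUMAB")
  if (band >= strategy$escalation_edss_threshold) return("NATALIZUMAB")
  "FIRST_LINE"
}

#' Annual EDSS-shift distribution for a phase and disease form
#'
#' RRMS under natalizumab follows the escalation-group vector; RRMS under
#' first-line treatment follows the switching-group vector; untreated RRMS
#' follows the configured off-treatment vector (default: the switching
#' vector); SPMS follows the no-regression progression distribution.
#'
#' @param phase a `TreatmentPhase`.
#' @param form `"RRMS"` or `"SPMS"`.
#' @param p parameter set.
#' @return numeric vector over `p$shift$support`.
#' @export
shift_distribution_for <- function(phase, form, p) {
  if (form == "SPMS") return(p$spms$progression)
  switch(phase,
    NATALIZUMAB = p$shift$esc,
    FIRST_LINE = p$shift$swi,
    NO_DMT = p$shift$off_treatment,
    stop("unknown phase: ", phase)
  )
}

#' Annual death probability for a state
#'
#' Sex-blended general-population annual death probability (weighted by the
#' cohort female fraction) multiplied by the MS mortality multiplier for the
#' disease form and EDSS band, capped at 1. Ages beyond the life table use
#' its last row (with a warning).
#'
#' @param age age in years (>= 0).
#' @param p parameter set.
#' @param form `"RRMS"` or `"SPMS"`.
#' @param band EDSS band 0..8.
#' @return annual death probability in \[0, 1\].
#' @export
mortality_probability <- function(age, p, form, band) {
  if (age < 0) stop("age must be >= 0")
  m <- p$mortality
  i <- findInterval(age, m$age)
  if (i < 1) i <- 1
  if (age > max(m$age)) {
    warning("age ", age, " beyond mortality table; using last row")
    i <- length(m$age)
  }
  ff <- p$cohort$female_fraction
  general <- ff * m$female[i] + (1 - ff) * m$male[i]
  mult <- if (form == "SPMS") m$multiplier_spms[band + 1] else
    m$multiplier_rrms[band + 1]
  min(1, general * mult)
}

#' Annual relapse rate for a state
#'
#' The untreated annualized relapse rate for the disease form and EDSS band,
#' multiplied by the treatment-phase effect: the switching multiplier on
#' first-line treatment, the natalizumab multiplier on natalizumab, 1
#' untreated. SPMS relapse rates are never treatment-modified.
#'
#' @inheritParams mortality_probability
#' @param phase a `TreatmentPhase`.
#' @return relapses per patient-year.
#' @export
relapse_rate <- function(form, band, phase, p) {
  base <- if (form == "SPMS") p$relapse_rates$spms[band + 1] else
    p$relapse_rates$rrms[band + 1]
  if (form == "SPMS") return(base)
  mult <- switch(phase,
    FIRST_LINE = p$effect$arr_multiplier_switching,
    NATALIZUMAB = p$effect$arr_multiplier_natalizumab,
    NO_DMT = 1,
    stop("unknown phase: ", phase)
  )
  base * mult
}

# Death-free one-cycle dynamics: EDSS shift (mass clamped at bands 0 and 8),
# then RRMS->SPMS conversion at the post-shift band, then phase update by the
# strategy policy. Constant over cycles; age-dependent death is composed on
# top each cycle.
build_death_free_matrix <- function(space, p, strategy) {
  n <- nrow(space)
  M <- matrix(0, n, n)
  support <- p$shift$support
  for (i in seq_len(n - 1)) {
    form <- space$form[i]
    band <- space$band[i]
    phase <- space$phase[i]
    s <- shift_distribution_for(phase, form, p)
    for (k in seq_along(support)) {
      mass <- s[k]
      if (mass <= 0) next
      b2 <- min(max(band + support[k], 0L), 8L)
      if (form == "RRMS") {
        conv <- p$spms$conversion[b2 + 1]
        if (conv > 0) {
          j <- idx_spms(b2)
          M[i, j] <- M[i, j] + mass * conv
        }
        ph2 <- policy_phase(strategy, "RRMS", b2, phase)
        j <- idx_rrms(b2, ph2)
        M[i, j] <- M[i, j] + mass * (1 - conv)
      } else {
        j <- idx_spms(b2)
        M[i, j] <- M[i, j] + mass
      }
    }
  }
  M[n, n] <- 1
  if (any(M < 0)) stop("negative transition probability constructed")
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("death-free transition rows do not sum to 1 (max deviation ",
         max(abs(rs - 1)), ")")
  }
  M
}

# Per-state death probability vector at a given age (0 for the dead state).
state_death_probs <- function(space, p, age) {
  n <- nrow(space)
  d <- numeric(n)
  for (i in seq_len(n - 1)) {
    d[i] <- mortality_probability(age, p, space$form[i], space$band[i])
  }
  d
}

#' Build the full one-cycle transition matrix
#'
#' Composes, for each live state, death at the age-specific probability with
#' the death-free dynamics (EDSS shift, SPMS conversion, phase update) of
#' the survivors. The death state is absorbing and rows sum to 1 within
#' 1e-12.
#'
#' @param space state space from [build_state_space()].
#' @param p parameter set.
#' @param strategy a strategy specification.
#' @param age cohort age in years for this cycle.
#' @return a 37 x 37 row-stochastic matrix.
#' @export
build_transition_matrix <- function(space, p, strategy, age) {
  M <- build_death_free_matrix(space, p, strategy)
  d <- state_death_probs(space, p, age)
  Tm <- (1 - d) * M
  Tm[, idx_dead()] <- Tm[, idx_dead()] + d
  if (any(Tm < 0)) stop("negative transition probability constructed")
  Tm
}

#' Run the cohort model for one strategy
#'
#' Places the baseline EDSS distribution in RRMS at the phase the strategy
#' policy prescribes at entry, then iterates annual cycles over the horizon,
#' rebuilding the age-dependent mortality composition each cycle (cohort
#' mean age advances one year per cycle from the starting age). Records the
#' occupancy trace and, for year-one monitoring costing, the cohort mass
#' newly entering each treatment phase at each cycle.
#'
#' @param p validated parameter set.
#' @param strategy `"ESC"`, `"SWI"`, or a strategy specification.
#' @return an `ms_trace`: list with `occupancy` ((horizon+1) x 37 matrix of
#'   cohort proportions), `phase_entry` ((horizon+1) x 3 matrix of mass
#'   newly entering each phase), `ages`, `strategy`, and the `space`.
#' @export
run_cohort <- function(p, strategy) {
  if (is.character(strategy)) {
    strategy <- p$strategies[[tolower(strategy)]]
    if (is.null(strategy)) stop("unknown strategy name")
  }
  space <- build_state_space()
  n <- nrow(space)
  horizon <- p$settings$horizon
  occ <- matrix(0, horizon + 1, n,
                dimnames = list(NULL, state_labels(space)))
  entry <- matrix(0, horizon + 1, length(MS_PHASES),
                  dimnames = list(NULL, MS_PHASES))

  for (b in MS_BANDS) {
    mass <- p$cohort$edss_distribution[b + 1]
    if (mass <= 0) next
    ph <- policy_phase(strategy, "RRMS", b, strategy$initial_phase)
    j <- idx_rrms(b, ph)
    occ[1, j] <- occ[1, j] + mass
    entry[1, ph] <- entry[1, ph] + mass
  }

  M <- build_death_free_matrix(space, p, strategy)
  # mass arriving in phase q from live states currently in a different phase
  entry_weights <- matrix(0, n, length(MS_PHASES),
                          dimnames = list(NULL, MS_PHASES))
  for (q in MS_PHASES) {
    dest <- which(space$form == "RRMS" & space$phase == q)
    src <- which(space$form != "DEAD" &
                   (space$form != "RRMS" | space$phase != q))
    entry_weights[src, q] <- rowSums(M[src, dest, drop = FALSE])
  }

  ages <- p$cohort$start_age + 0:horizon
  if (horizon >= 1) {
    for (t in seq_len(horizon)) {
      d <- state_death_probs(space, p, ages[t])
      surv <- occ[t, ] * (1 - d)
      nxt <- as.numeric(surv %*% M)
      nxt[idx_dead()] <- nxt[idx_dead()] + sum(occ[t, ] * d)
      occ[t + 1, ] <- nxt
      entry[t + 1, ] <- as.numeric(surv %*% entry_weights)
    }
  }

  structure(list(occupancy = occ, phase_entry = entry, ages = ages,
                 strategy = strategy$name, space = space),
            class = "ms_trace")
}

state_labels <- function(space) {
  ifelse(space$form == "DEAD", "DEAD",
         paste0(space$form, "_", space$band,
                ifelse(space$form == "RRMS", paste0("_", space$phase), "")))
}

#' Export a cohort trace as a delimited table
#'
#' One row per cycle: cycle number, age, one column per state, and the
#' per-phase entry flows.
#'
#' @param trace an `ms_trace`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  df <- data.frame(cycle = seq_len(nrow(trace$occupancy)) - 1,
                   age = trace$ages,
                   trace$occupancy,
                   entry = trace$phase_entry, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Proportion of the cohort below an EDSS band
#'
#' Time series of the living cohort share with EDSS band strictly below a
#' cutoff (both disease forms), used to track disability burden over time.
#'
#' @param trace an `ms_trace`.
#' @param band cutoff band (default 5).
#' @return numeric vector, one entry per cycle.
#' @export
proportion_below_band <- function(trace, band = 5L) {
  sel <- which(trace$space$form != "DEAD" & trace$space$band < band)
  rowSums(trace$occupancy[, sel, drop = FALSE])
}
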