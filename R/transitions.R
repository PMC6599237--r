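# Estimation of annual EDSS-shift distributions from longitudinal
# patient-level EDSS records (baseline, month 12, month 24).

#' Round an EDSS value to an integer band
#'
#' Half-points round down (2.5 -> 2); values above 8 collapse into the
#' terminal 8-10 aggregate band.
#'
#' @param edss numeric EDSS values in \[0, 10\] (half points permitted).
#' @return integer bands in 0..8.
#' @export
edss_band <- function(edss) {
  if (any(edss < 0 | edss > 10)) stop("EDSS values must be in [0, 10]")
  pmin(as.integer(ceiling(edss - 0.5)), 8L)
}

#' Normalize a shift distribution
#'
#' Divides each entry by the total so the result sums to one (within 1e-12).
#' The published escalation-group shift vector sums to 1.0001 as printed and
#' must pass through this before use.
#'
#' @param raw non-negative numeric vector with positive sum.
#' @return the normalized vector (names preserved).
#' @export
normalize_shift_distribution <- function(raw) {
  if (any(raw < 0)) stop("shift distribution entries must be >= 0")
  total <- sum(raw)
  if (total <= 0) stop("shift distribution sums to zero; cannot normalize")
  raw / total
}

#' Read patient EDSS trajectories from a delimited file
#'
#' Expects columns `patient_id`, `edss_0`, `edss_12`, `edss_24`.
#'
#' @param path delimited text file (separator auto-detected among tab/comma).
#' @return a data.frame of trajectories.
#' @export
read_trajectories <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("patient_id", "edss_0", "edss_12", "edss_24")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("trajectory file lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Estimate an annual EDSS-shift distribution
#'
#' Pools, across all patients, the two per-patient annual EDSS band changes
#' (month 12 minus baseline, month 24 minus month 12) and tallies them over
#' the support: the probability of a k-point shift is its count divided by
#' 2N. Changes outside the support are clamped to the nearest support
#' endpoint with a warning. Half-point EDSS inputs are rounded to bands
#' first (see [edss_band()]).
#'
#' @param trajectories data.frame with columns `edss_0`, `edss_12`,
#'   `edss_24` (and any id column).
#' @param support integer vector of admissible shifts, containing 0; default
#'   one-point improvement through three-point worsening.
#' @return named numeric vector over `support`, summing to 1.
#' @export
estimate_shift_distribution <- function(trajectories,
                                        support = MS_SHIFT_SUPPORT) {
  if (is.null(trajectories) || nrow(trajectories) == 0) {
    stop("no trajectories supplied")
  }
  if (!0L %in% support) stop("support must contain 0")
  support <- sort(as.integer(support))

  b0 <- edss_band(trajectories$edss_0)
  b12 <- edss_band(trajectories$edss_12)
  b24 <- edss_band(trajectories$edss_24)
  deltas <- c(b12 - b0, b24 - b12)
  if (any(deltas != round(deltas))) {
    stop("non-integer EDSS band change after rounding")
  }

  out_of_support <- deltas < min(support) | deltas > max(support)
  if (any(out_of_support)) {
    warning(sum(out_of_support),
            " annual EDSS change(s) outside the support were clamped ",
            "to the nearest endpoint")
    deltas <- pmin(pmax(deltas, min(support)), max(support))
  }
  # non-contiguous support: snap to the nearest admissible shift
  if (!all(deltas %in% support)) {
    deltas <- vapply(deltas, function(d)
      support[which.min(abs(support - d))], integer(1))
  }

  counts <- vapply(support, function(k) sum(deltas == k), numeric(1))
  probs <- counts / length(deltas)
  names(probs) <- as.character(support)
  probs
}
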