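#' Default cardiac event timing template
#'
#' Per-cycle event times are parameterized against a reference cycle of
#' 0.8 s (75 bpm) with a systole of 0.35 s. Systolic events (AS, MC, IM,
#' S1, AO, IC, WC, RE, WT) are stored as fractions of the systolic span
#' `S(T) = sys_duration * (T / 0.8)^sys_exponent`, so they scale weakly
#' with the period; diastolic events (AC, S2, MO, RF) are fractions of the
#' diastolic span `D(T) = T - S(T)` measured from the end of systole, so
#' the diastole absorbs most heart-rate change. All values are design
#' choices (published physiology gives R->AO around 80 ms and R->AC around
#' 350 ms at 75 bpm); nothing here is a measured constant.
#'
#' @return List with `sys_duration`, `sys_exponent`, `systolic_frac`
#'   (named fractions of systole) and `diastolic_frac` (named fractions of
#'   diastole past end-systole).
#' @export
default_event_template <- function() {
  sys <- 0.35
  list(
    sys_duration = sys,
    sys_exponent = 0.3,
    systolic_frac = c(
      AS = 0.025 / sys, MC = 0.045 / sys, IM = 0.060 / sys, S1 = 0.070 / sys,
      AO = 0.080 / sys, IC = 0.100 / sys, WC = 0.110 / sys, RE = 0.130 / sys,
      WT = 0.320 / sys
    ),
    diastolic_frac = c(
      AC = (0.355 - sys) / 0.45, S2 = (0.360 - sys) / 0.45,
      MO = (0.390 - sys) / 0.45, RF = (0.450 - sys) / 0.45
    )
  )
}

# 13 event names in canonical order of the default template at 0.8 s
event_names <- function() {
  c("AS", "MC", "IM", "S1", "AO", "IC", "WC", "RE", "WT",
    "AC", "S2", "MO", "RF")
}

# the strict physiological chain whose ordering is an invariant
scg_chain <- function() c("AS", "MC", "IM", "AO", "IC", "RE", "AC", "MO", "RF")

#' Build a per-cycle cardiac event schedule
#'
#' Places the 13 fiducial events (8 SCG points plus AS, the ULF crest and
#' trough WC/WT, and the heart sounds S1/S2) inside one cardiac cycle of
#' length `period_T`, optionally jittered. Jitter is Gaussian per event but
#' clamped to 45% of the gap to the neighboring chain events (and to the
#' cycle boundaries), which makes the physiological ordering
#' AS < MC < IM < AO < IC < RE < AC < MO < RF, S1 in `[MC, IC]`,
#' `|S2 - AC| <= 40 ms` and WC < WT hold by construction for every draw.
#'
#' @param period_T Cycle length in seconds, within `[0.4, 2]`.
#' @param jitter Per-event jitter SD in seconds: scalar or vector named by
#'   event. Default 0 (deterministic template).
#' @param cycle_index Integer tag stored on the schedule.
#' @param template Timing template, see [default_event_template()].
#' @return Object of class `"cardiac_event_schedule"`: list with
#'   `cycle_index`, `period` and named numeric `events`
#'   (seconds from cycle onset).
#' @export
make_event_schedule <- function(period_T, jitter = 0, cycle_index = 1L,
                                template = default_event_template()) {
  if (!is.finite(period_T) || period_T < 0.4 || period_T > 2.0)
    stop("period_T = ", period_T,
         " s cannot host the ordered event sequence; supported range is [0.4, 2] s")
  s_span <- template$sys_duration * (period_T / 0.8)^template$sys_exponent
  d_span <- period_T - s_span
  if (d_span <= 0.02)
    stop("period too short to host the ordered event sequence")
  base <- c(template$systolic_frac * s_span,
            s_span + template$diastolic_frac * d_span)
  base <- base[event_names()]

  jit <- rep(0, length(base))
  names(jit) <- names(base)
  if (any(jitter > 0)) {
    sds <- if (length(jitter) == 1) rep(jitter, length(base)) else {
      out <- rep(0, length(base)); names(out) <- names(base)
      out[names(jitter)] <- jitter; out
    }
    names(sds) <- names(base)
    eps <- stats::rnorm(length(base), 0, sds)
    names(eps) <- names(base)
    # clamp chain events to 45% of the gap toward ordered neighbors
    chain <- scg_chain()
    bounds <- c(0, base[chain], period_T)
    for (i in seq_along(chain)) {
      gap_lo <- 0.45 * (bounds[i + 1] - bounds[i])
      gap_hi <- 0.45 * (bounds[i + 2] - bounds[i + 1])
      jit[chain[i]] <- min(max(eps[chain[i]], -gap_lo), gap_hi)
    }
    ev <- base + jit
    # dependent events ride on their jittered anchors
    jit["S1"] <- min(max(eps["S1"], 0.55 * (ev["MC"] - base["S1"])),
                     0.55 * (ev["IC"] - base["S1"]))
    jit["S2"] <- (ev["AC"] - base["AC"]) + min(max(eps["S2"], -0.035), 0.035)
    jit["WC"] <- min(max(eps["WC"], -0.45 * base["WC"]),
                     0.45 * (base["WT"] - base["WC"]))
    jit["WT"] <- min(max(eps["WT"], -0.45 * (base["WT"] - (base["WC"] + jit["WC"]))),
                     0.45 * (period_T - base["WT"]))
  }
  ev <- base + jit
  ev <- pmin(pmax(ev, 1e-4), period_T - 1e-4)
  structure(list(cycle_index = as.integer(cycle_index),
                 period = period_T, events = ev),
            class = "cardiac_event_schedule")
}

#' Validate a cardiac event schedule
#'
#' Checks the ordering chain, the S1/S2 placement rules, WC < WT and the
#' open-interval bound `(0, period)`.
#'
#' @param schedule A [make_event_schedule()] result.
#' @return `TRUE` invisibly, or a character vector of violations.
#' @export
validate_schedule <- function(schedule) {
  ev <- schedule$events
  viol <- character(0)
  ch <- ev[scg_chain()]
  if (any(diff(ch) <= 0)) viol <- c(viol, "SCG chain ordering violated")
  if (ev["S1"] < ev["MC"] || ev["S1"] > ev["IC"])
    viol <- c(viol, "S1 outside [MC, IC]")
  if (abs(ev["S2"] - ev["AC"]) > 0.040)
    viol <- c(viol, "S2 more than 40 ms from AC")
  if (ev["WC"] >= ev["WT"]) viol <- c(viol, "WC !< WT")
  if (any(ev <= 0) || any(ev >= schedule$period))
    viol <- c(viol, "event outside (0, period)")
  if (length(viol)) viol else invisible(TRUE)
}

#' @export
print.cardiac_event_schedule <- function(x, ...) {
  cat(sprintf("<cardiac cycle %d, T = %.3f s>\n", x$cycle_index, x$period))
  print(round(x$events, 4))
  invisible(x)
}
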