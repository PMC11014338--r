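#' Default band-limited mode specifications
#'
#' Three vibrational modes mirror the three analysis bands: mode 1
#' (fundamental, 1-5 Hz) carries the ULF-SCG crest/trough pair, mode 2
#' (5-30 Hz) carries the nine SCG fiducials, and mode 3 (20-200 Hz)
#' carries the S1/S2 heart sounds. Each event contributes a Gabor atom: a
#' cosine carrier at the atom's frequency under a Gaussian envelope
#' centered at the event time, so every event produces a localizable
#' extremum. RE and RF deliberately use broad, low-amplitude atoms: the
#' rapid-ejection and rapid-filling peaks are gentle waves in vivo and are
#' the hard targets downstream.
#'
#' @return List of three mode specs. Each is a list with `mode_index`,
#'   `coefficient` (the a_n weight), `band` (Hz) and `atoms`
#'   (data.frame: event, freq, width, amp, phase).
#' @export
default_mode_specs <- function() {
  atom <- function(event, freq, width, amp, phase = 0)
    data.frame(event = event, freq = freq, width = width, amp = amp,
               phase = phase, stringsAsFactors = FALSE)
  list(
    list(mode_index = 1L, coefficient = 1, band = c(1, 5),
         atoms = rbind(
           atom("WC", 2.2, 0.090,  1.5),
           atom("WT", 2.2, 0.090, -1.5))),
    list(mode_index = 2L, coefficient = 1, band = c(5, 30),
         atoms = rbind(
           atom("AS", 10, 0.040,  0.35),
           atom("MC", 12, 0.040, -0.80),
           atom("IM", 12, 0.040, -0.90),
           atom("AO", 14, 0.040,  1.00),
           atom("IC", 12, 0.040, -0.85),
           atom("RE",  8, 0.050,  0.40),
           atom("AC", 14, 0.040,  0.90),
           atom("MO", 12, 0.040, -0.70),
           atom("RF",  8, 0.050,  0.35))),
    list(mode_index = 3L, coefficient = 1, band = c(20, 200),
         atoms = rbind(
           atom("S1", 60, 0.015, 2.00),
           atom("S2", 80, 0.012, 1.60)))
  )
}

# one Gabor atom's support window and values; the caller accumulates in
# place (returning a modified full trace per atom would copy it each time)
atom_window <- function(n, tc, freq, width, amp, phase, sampling_rate) {
  lo <- max(1L, floor((tc - 6 * width) * sampling_rate) + 1L)
  hi <- min(n, ceiling((tc + 6 * width) * sampling_rate) + 1L)
  if (lo > hi) return(NULL)
  t <- (seq.int(lo, hi) - 1) / sampling_rate
  list(lo = lo, hi = hi,
       v = amp * exp(-0.5 * ((t - tc) / width)^2) *
         cos(2 * pi * freq * (t - tc) + phase))
}

#' Synthesize one mode over a single cycle
#'
#' Sums the mode's Gabor atoms on the cycle-local time axis. Atom carriers
#' must lie inside the mode's band.
#'
#' @param schedule A [make_event_schedule()] result.
#' @param mode One element of [default_mode_specs()].
#' @param sampling_rate Sampling rate in Hz.
#' @return Trace of length `round(period * sampling_rate)`.
#' @export
synthesize_mode <- function(schedule, mode, sampling_rate) {
  a <- mode$atoms
  if (any(a$freq < mode$band[1] | a$freq > mode$band[2]))
    stop("atom carrier outside mode band [", mode$band[1], ", ",
         mode$band[2], "] Hz")
  missing_ev <- setdiff(a$event, names(schedule$events))
  if (length(missing_ev))
    stop("atoms reference events absent from the schedule: ",
         paste(missing_ev, collapse = ", "))
  n <- round(schedule$period * sampling_rate)
  trace <- numeric(n)
  for (i in seq_len(nrow(a))) {
    w <- atom_window(n, schedule$events[a$event[i]], a$freq[i],
                     a$width[i], a$amp[i], a$phase[i], sampling_rate)
    if (!is.null(w)) trace[w$lo:w$hi] <- trace[w$lo:w$hi] + w$v
  }
  trace
}

# full-recording mode track: atoms placed at absolute event times so
# envelopes cross cycle boundaries smoothly
synthesize_mode_track <- function(schedules, onsets, mode, n_total,
                                  sampling_rate) {
  a <- mode$atoms
  if (any(a$freq < mode$band[1] | a$freq > mode$band[2]))
    stop("atom carrier outside mode band")
  trace <- numeric(n_total)
  for (k in seq_along(schedules)) {
    ev <- schedules[[k]]$events
    for (i in seq_len(nrow(a))) {
      w <- atom_window(n_total, onsets[k] + ev[a$event[i]], a$freq[i],
                       a$width[i], a$amp[i], a$phase[i], sampling_rate)
      if (!is.null(w)) trace[w$lo:w$hi] <- trace[w$lo:w$hi] + w$v
    }
  }
  trace
}

#' Synthesize the reference ECG channel
#'
#' One dominant narrow R spike per cycle at the cycle onset plus
#' low-amplitude T- and P-like humps; the R amplitude is at least three
#' times any other deflection, so a peak detector anchored on the R wave
#' has an unambiguous target.
#'
#' @param schedules List of cycle schedules (contiguous).
#' @param sampling_rate Sampling rate in Hz.
#' @param lead_in Seconds of silence before the first cycle (default 0).
#' @param tail_pad Seconds appended after the last cycle (default 0).
#' @param noise_sd SD of additive white noise (default 0).
#' @return List with `ecg` trace and `r_peak_times` (seconds, absolute).
#' @export
synthesize_ecg <- function(schedules, sampling_rate, lead_in = 0,
                           tail_pad = 0, noise_sd = 0) {
  periods <- vapply(schedules, function(s) s$period, 1)
  onsets <- lead_in + cumsum(c(0, periods[-length(periods)]))
  n_total <- round((lead_in + sum(periods) + tail_pad) * sampling_rate)
  ecg <- numeric(n_total)
  for (k in seq_along(schedules)) {
    t0 <- onsets[k]; Tk <- periods[k]
    waves <- list(
      c(t0, 0.008, 1.0),                              # R spike
      c(t0 + 0.030, 0.010, -0.12),                    # S dip
      c(t0 + 0.30 * (Tk / 0.8)^0.3, 0.050, 0.20),     # T hump
      c(t0 + Tk - 0.14 * (Tk / 0.8)^0.3, 0.040, 0.15) # P hump
    )
    for (wv in waves) {
      w <- atom_window(n_total, wv[1], 0, wv[2], wv[3], 0, sampling_rate)
      if (!is.null(w)) ecg[w$lo:w$hi] <- ecg[w$lo:w$hi] + w$v
    }
  }
  if (noise_sd > 0) ecg <- ecg + stats::rnorm(n_total, 0, noise_sd)
  list(ecg = ecg, r_peak_times = onsets)
}

#' Simulation configuration
#'
#' Defaults describe a resting adult recorded at 2 kHz: 75 bpm with 3 bpm
#' beat-to-beat variability, 5 ms event-timing jitter, additive white
#' noise at SD 0.05 signal units (sharp atoms have unit amplitude, so the
#' per-atom SNR is about 26 dB), and a 0.25 Hz respiratory-like baseline
#' wander of amplitude 0.2.
#'
#' @param sampling_rate Hz; must exceed twice the highest band edge.
#' @param n_cycles Number of cardiac cycles (>= 1).
#' @param mean_heart_rate Mean heart rate, bpm.
#' @param hr_jitter_sd Beat-to-beat heart-rate SD, bpm.
#' @param event_jitter_sd Per-event timing jitter SD, seconds.
#' @param noise_sd SD of additive white Gaussian noise on the vibration
#'   channel, signal units (the N term of the composite model).
#' @param baseline_amp,baseline_freq Baseline-wander amplitude and
#'   frequency (Hz, <= 0.5 for a respiratory stand-in).
#' @param a0 DC offset of the composite channel.
#' @param amplitudes Mode weights a_n, one per mode.
#' @param ecg_noise_sd Noise SD on the ECG channel.
#' @param lead_in,tail_pad Silence (s) framing the cycle train.
#' @param quantize_bits Optional ADC emulation (e.g. 12); `NULL` = off.
#' @param seed Integer RNG seed; the recording is reproducible from it.
#' @param modes Mode specifications, see [default_mode_specs()].
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(sampling_rate = 2000, n_cycles = 60,
                              mean_heart_rate = 75, hr_jitter_sd = 3,
                              event_jitter_sd = 0.005, noise_sd = 0.05,
                              baseline_amp = 0.2, baseline_freq = 0.25,
                              a0 = 0, amplitudes = c(1, 1, 1),
                              ecg_noise_sd = 0.01,
                              lead_in = 0.25, tail_pad = 0.25,
                              quantize_bits = NULL, seed = 1L,
                              modes = default_mode_specs()) {
  max_edge <- max(vapply(modes, function(m) m$band[2], 1))
  if (sampling_rate <= 2 * max_edge)
    stop("sampling_rate must exceed twice the highest band edge (",
         2 * max_edge, " Hz)")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(amplitudes) != length(modes))
    stop("need one amplitude per mode")
  structure(as.list(environment())[c(
    "sampling_rate", "n_cycles", "mean_heart_rate", "hr_jitter_sd",
    "event_jitter_sd", "noise_sd", "baseline_amp", "baseline_freq", "a0",
    "amplitudes", "ecg_noise_sd", "lead_in", "tail_pad", "quantize_bits",
    "seed", "modes")], class = "simulation_config")
}

#' Synthesize a full two-channel recording
#'
#' Draws per-cycle periods and event schedules, renders each mode as a
#' Gabor-atom track, and assembles the composite vibration channel
#' `a0 + sum(a_n * mode_n) + baseline wander + white noise` together with
#' the reference ECG. All components are retained so the composite can be
#' reconstructed exactly and oracle tests can compare against the clean
#' per-mode tracks. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return Object of class `"synthetic_recording"`: `ecg`, `vibration`,
#'   `sampling_rate`, `schedules`, `r_peak_times` (s), `onset_samples`
#'   (0-based), `components` (per-mode clean tracks), `noise`, `baseline`,
#'   and the `config`.
#' @export
synthesize_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  hr <- stats::rnorm(config$n_cycles, config$mean_heart_rate,
                     config$hr_jitter_sd)
  # quantize periods to the sample grid so every cycle onset (and hence the
  # R spike) falls exactly on a sample: exact label round-trips depend on it
  periods <- round(pmin(pmax(60 / hr, 0.4), 2.0) * fs) / fs
  schedules <- lapply(seq_len(config$n_cycles), function(k)
    make_event_schedule(periods[k], jitter = config$event_jitter_sd,
                        cycle_index = k))
  onsets <- config$lead_in + cumsum(c(0, periods[-length(periods)]))
  n_total <- round((config$lead_in + sum(periods) + config$tail_pad) * fs)

  components <- lapply(config$modes, function(m)
    synthesize_mode_track(schedules, onsets, m, n_total, fs))
  names(components) <- paste0("mode", vapply(config$modes,
                                             function(m) m$mode_index, 1L))
  t_axis <- (seq_len(n_total) - 1) / fs
  baseline <- config$baseline_amp *
    sin(2 * pi * config$baseline_freq * t_axis + stats::runif(1, 0, 2 * pi))
  noise <- if (config$noise_sd > 0) stats::rnorm(n_total, 0, config$noise_sd)
           else numeric(n_total)
  vibration <- config$a0 + baseline + noise
  for (i in seq_along(components))
    vibration <- vibration + config$amplitudes[i] * components[[i]]

  eg <- synthesize_ecg(schedules, fs, lead_in = config$lead_in,
                       tail_pad = config$tail_pad,
                       noise_sd = config$ecg_noise_sd)
  stopifnot(length(eg$ecg) == n_total)

  if (!is.null(config$quantize_bits)) {
    vibration <- quantize_trace(vibration, config$quantize_bits)
    eg$ecg <- quantize_trace(eg$ecg, config$quantize_bits)
  }

  structure(list(
    ecg = eg$ecg, vibration = vibration, sampling_rate = fs,
    schedules = schedules, r_peak_times = eg$r_peak_times,
    onset_samples = round(eg$r_peak_times * fs),
    components = components, noise = noise, baseline = baseline,
    config = config
  ), class = "synthetic_recording")
}

# symmetric mid-rise quantizer emulating an ADC of the given resolution
quantize_trace <- function(x, bits, full_scale = max(abs(x))) {
  if (full_scale == 0) return(x)
  q <- full_scale / (2^(bits - 1))
  pmin(pmax(round(x / q) * q, -full_scale), full_scale)
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording: %d cycles, %.1f s at %g Hz, %d modes>\n",
    length(x$schedules), length(x$vibration) / x$sampling_rate,
    x$sampling_rate, length(x$components)))
  invisible(x)
}
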