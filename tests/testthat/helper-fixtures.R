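# shared fixtures, built once per test run and cached
.fix <- new.env(parent = emptyenv())

# 30-cycle clean world: no noise, no jitter, no wander -- exact round trips
clean_recording <- function() {
  if (is.null(.fix$clean)) {
    cfg <- simulation_config(n_cycles = 30, seed = 5, noise_sd = 0,
                             baseline_amp = 0, ecg_noise_sd = 0,
                             event_jitter_sd = 0)
    .fix$clean <- synthesize_recording(cfg)
  }
  .fix$clean
}

# 30-cycle default world: default noise, jitter and wander
default_recording <- function() {
  if (is.null(.fix$default)) {
    .fix$default <- synthesize_recording(
      simulation_config(n_cycles = 30, seed = 3))
  }
  .fix$default
}

# full default pipeline products for a recording
pipeline_of <- function(rec, key) {
  slot <- paste0("pipe_", key)
  if (is.null(.fix[[slot]])) {
    fs <- rec$sampling_rate
    bands <- decompose_bands(rec$vibration, rec$ecg, fs)
    peaks <- detect_r_peaks(rec$ecg, fs)
    segs <- truncate_cycles(bands, peaks)
    ds <- attach_labels(segs, rec$schedules[seq_along(segs)], fs)
    .fix[[slot]] <- list(bands = bands, peaks = peaks, segs = segs, ds = ds)
  }
  .fix[[slot]]
}

# tiny labeled dataset for CNN plumbing tests: short segments would break the
# fixed-length contract, so keep L = 2048 but few cycles
tiny_dataset <- function(n_cycles = 12) {
  if (is.null(.fix$tiny_ds)) {
    rec <- synthesize_recording(
      simulation_config(n_cycles = n_cycles, seed = 9))
    fs <- rec$sampling_rate
    bands <- decompose_bands(rec$vibration, rec$ecg, fs)
    segs <- truncate_cycles(bands[c("SCG", "PCG")], rec$onset_samples)
    .fix$tiny_ds <- attach_labels(segs, rec$schedules[seq_along(segs)], fs)
  }
  .fix$tiny_ds
}

# the learnability corpus: the published study size (1255 cycles) at
# moderate noise (SD 0.3), where disturbance susceptibility of the broad
# rapid-ejection/rapid-filling atoms is non-negligible
moderate_corpus <- function() {
  if (is.null(.fix$corpus)) {
    cfg <- simulation_config(n_cycles = 1256, seed = 11, noise_sd = 0.3)
    rec <- synthesize_recording(cfg)
    fs <- rec$sampling_rate
    bands <- decompose_bands(rec$vibration, rec$ecg, fs)
    peaks <- detect_r_peaks(rec$ecg, fs)
    segs <- truncate_cycles(bands[c("SCG", "PCG")], peaks)
    ds <- attach_labels(segs, rec$schedules[seq_along(segs)], fs)
    .fix$corpus <- assign_split(ds, 0.3, seed = 1)
  }
  .fix$corpus
}

# per-cycle absolute truth sample of an event (0-based)
truth_abs <- function(rec, event, cycles = seq_along(rec$schedules)) {
  vapply(cycles, function(i)
    rec$onset_samples[i] +
      round(rec$schedules[[i]]$events[event] * rec$sampling_rate),
    numeric(1))
}
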