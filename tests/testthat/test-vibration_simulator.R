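fs <- 2000

test_that("event schedule: deterministic template, ordering, placement rules", {
  sch <- make_event_schedule(0.8)
  expect_true(isTRUE(validate_schedule(sch)))
  chain <- c("AS", "MC", "IM", "AO", "IC", "RE", "AC", "MO", "RF")
  expect_true(all(diff(sch$events[chain]) > 0))
  expect_gte(sch$events[["S1"]], sch$events[["MC"]])
  expect_lte(sch$events[["S1"]], sch$events[["IC"]])
  expect_lte(abs(sch$events[["S2"]] - sch$events[["AC"]]), 0.040)
  expect_lt(sch$events[["WC"]], sch$events[["WT"]])
  # WC-WT interval overlaps the systolic chain
  expect_lt(sch$events[["WC"]], sch$events[["RE"]])
  expect_gt(sch$events[["WT"]], sch$events[["RE"]])
  # identical calls are identical (no hidden RNG at zero jitter)
  expect_identical(sch$events, make_event_schedule(0.8)$events)
  expect_error(make_event_schedule(0.2), "ordered event sequence")
  expect_error(make_event_schedule(3), "ordered event sequence")
})

test_that("schedules scale: diastole absorbs period change, systole moves weakly", {
  s_short <- make_event_schedule(0.5)
  s_long <- make_event_schedule(1.6)
  # systolic AO shifts far less than the period change
  expect_lt(abs(s_long$events[["AO"]] - s_short$events[["AO"]]), 0.05)
  # diastolic RF absorbs most of it
  expect_gt(s_long$events[["RF"]] - s_short$events[["RF"]], 0.25)
  expect_gt(s_long$events[["RF"]] - s_short$events[["RF"]],
            5 * abs(s_long$events[["AO"]] - s_short$events[["AO"]]))
  expect_true(isTRUE(validate_schedule(s_short)))
  expect_true(isTRUE(validate_schedule(s_long)))
})

test_that("all jittered schedules satisfy every invariant (1000 draws)", {
  set.seed(1)
  for (i in 1:1000) {
    p <- runif(1, 0.45, 1.9)
    s <- make_event_schedule(p, jitter = 0.005)
    v <- validate_schedule(s)
    if (!isTRUE(v)) fail(paste("draw", i, "period", round(p, 3), ":",
                               paste(v, collapse = "; ")))
  }
  succeed()
})

test_that("synthesize_mode: zero atoms, extremum placement, band energy", {
  sch <- make_event_schedule(0.8)
  m2 <- default_mode_specs()[[2]]
  m0 <- m2; m0$atoms$amp <- 0
  expect_equal(synthesize_mode(sch, m0, fs), numeric(1600))

  # single zero-phase cosine atom peaks exactly at its event sample
  m1 <- m2
  m1$atoms <- m1$atoms[m1$atoms$event == "MC", ]
  m1$atoms$amp <- 1
  tr <- synthesize_mode(sch, m1, fs)
  expect_equal(which.max(tr) - 1, round(sch$events[["MC"]] * fs))

  # default mode-2 atoms concentrate energy in 5-30 Hz (FFT oracle)
  tr2 <- synthesize_mode(sch, m2, fs)
  expect_gte(band_energy_fraction(tr2, 5, 30, fs), 0.9)

  bad <- m2; bad$atoms$freq[1] <- 100
  expect_error(synthesize_mode(sch, bad, fs), "outside mode band")
  bad2 <- m2; bad2$atoms$event[1] <- "XX"
  expect_error(synthesize_mode(sch, bad2, fs), "absent from the schedule")
})

test_that("recording is an exact sum of its stored components", {
  rec <- default_recording()
  resyn <- rec$config$a0 + rec$baseline + rec$noise
  for (i in seq_along(rec$components))
    resyn <- resyn + rec$config$amplitudes[i] * rec$components[[i]]
  expect_identical(resyn, rec$vibration)
})

test_that("degenerate config: single unit mode equals the vibration channel", {
  cfg <- simulation_config(n_cycles = 4, seed = 2, noise_sd = 0,
                           baseline_amp = 0, a0 = 0, amplitudes = 1,
                           modes = default_mode_specs()[2])
  rec <- synthesize_recording(cfg)
  expect_identical(rec$vibration, rec$components$mode2)
  # noise-free vibration minus a0/wander is the periodic part exactly
  cfg2 <- simulation_config(n_cycles = 4, seed = 2, noise_sd = 0,
                            baseline_amp = 0, a0 = 1.5)
  rec2 <- synthesize_recording(cfg2)
  periodic <- Reduce(`+`, rec2$components)
  expect_equal(rec2$vibration - 1.5, periodic, tolerance = 1e-12)
})

test_that("identical configs give bitwise-identical recordings", {
  cfg <- simulation_config(n_cycles = 6, seed = 42)
  r1 <- synthesize_recording(cfg)
  r2 <- synthesize_recording(cfg)
  expect_identical(r1$vibration, r2$vibration)
  expect_identical(r1$ecg, r2$ecg)
  expect_identical(r1$schedules, r2$schedules)
})

test_that("band-filtered composite matches each clean component (noise off)", {
  rec <- clean_recording()
  bands <- pipeline_of(rec, "clean")$bands
  expect_gt(stats::cor(bands$`ULF-SCG`, rec$components$mode1), 0.9)
  expect_gt(stats::cor(bands$SCG, rec$components$mode2), 0.9)
  expect_gt(stats::cor(bands$PCG, rec$components$mode3), 0.9)
})

test_that("every annotated event lies inside its cycle window", {
  rec <- default_recording()
  for (s in rec$schedules) {
    idx <- round(s$events * fs)
    expect_true(all(idx >= 0 & idx < round(s$period * fs)))
  }
})

test_that("synthetic ECG: unique R maximum, exact R-R, detector round trip", {
  sch <- list(make_event_schedule(0.8))
  eg <- synthesize_ecg(sch, fs)
  expect_identical(which(eg$ecg == max(eg$ecg)), 1L)  # onset sample

  cfg <- simulation_config(n_cycles = 60, seed = 4, hr_jitter_sd = 0,
                           event_jitter_sd = 0, ecg_noise_sd = 0)
  rec <- synthesize_recording(cfg)
  expect_true(all(abs(diff(rec$r_peak_times) - 0.8) < 1e-9))

  # default-noise detector recovers every truth peak within 10 ms
  cfg2 <- simulation_config(n_cycles = 60, seed = 4)
  rec2 <- synthesize_recording(cfg2)
  det <- detect_r_peaks(rec2$ecg, fs)
  expect_identical(length(det$indices), 60L)
  expect_true(all(abs(det$indices - rec2$onset_samples) <= 0.010 * fs))
})

test_that("config validation and optional quantizer", {
  expect_error(simulation_config(sampling_rate = 300), "twice the highest")
  expect_error(simulation_config(n_cycles = 0), "n_cycles")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(amplitudes = c(1, 1)), "one amplitude per mode")
  cfg <- simulation_config(n_cycles = 3, seed = 1, quantize_bits = 12)
  rec <- synthesize_recording(cfg)
  expect_lte(length(unique(rec$vibration)), 4097)
})
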