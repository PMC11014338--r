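fs <- 2000

test_that("R-peak detector: degenerate inputs and plausibility bounds", {
  expect_error(detect_r_peaks(numeric(100), fs), "at least 3 s")
  expect_warning(p <- detect_r_peaks(numeric(3 * fs + 10), fs), "flat")
  expect_identical(length(p$indices), 0L)
  expect_identical(p$status, "no_peaks")

  rec <- default_recording()
  det <- pipeline_of(rec, "default")$peaks
  expect_true(all(diff(det$indices) >= 0.24 * fs))
  expect_true(all(diff(det$indices) <= 3.0 * fs))
})

test_that("jitter-free 75 bpm input gives R-R of exactly 0.8 s", {
  cfg <- simulation_config(n_cycles = 10, seed = 8, hr_jitter_sd = 0,
                           event_jitter_sd = 0, ecg_noise_sd = 0)
  rec <- synthesize_recording(cfg)
  det <- detect_r_peaks(rec$ecg, fs)
  expect_true(all(abs(diff(det$indices) - 0.8 * fs) <= 1))
})

test_that("truncate_cycles honors the fixed-length padding contract", {
  x <- seq_len(8000)
  # cycles: exactly 2048, shorter (1600), longer (2300)
  peaks <- c(0L, 2048L, 3648L, 5948L, 7000L)
  segs <- truncate_cycles(list(b = x), peaks, L = 2048L)
  expect_length(segs, 4)
  expect_true(all(vapply(segs, function(s) length(s$traces$b), 1L) == 2048L))

  expect_identical(segs[[1]]$traces$b, as.numeric(x[1:2048]))
  expect_identical(segs[[1]]$pad_len, 0L)
  expect_false(segs[[1]]$truncated)

  expect_identical(segs[[2]]$traces$b[1601:2048], rep(0, 448))
  expect_identical(segs[[2]]$pad_len, 448L)

  expect_true(segs[[3]]$truncated)
  expect_identical(segs[[3]]$traces$b, as.numeric(x[3649:(3648 + 2048)]))

  expect_error(truncate_cycles(list(b = x), 5L), "at least 2 R-peaks")
})

test_that("segment cores partition the source between first and last R", {
  rec <- default_recording()
  pipe <- pipeline_of(rec, "default")
  segs <- pipe$segs
  idx <- pipe$peaks$indices
  core <- unlist(lapply(segs, function(s)
    s$traces$SCG[seq_len(min(s$cycle_len, 2048))]))
  src <- pipe$bands$SCG[(idx[1] + 1):idx[length(idx)]]
  expect_identical(core, src)
})

test_that("attach_labels: unit conversion, exclusion rules, invariants", {
  seg <- function(start, clen) structure(
    list(traces = list(SCG = numeric(2048)), cycle_start = start,
         cycle_len = clen, pad_len = max(0L, 2048L - clen),
         truncated = clen > 2048), class = "cycle_segment")
  sch <- list(make_event_schedule(0.8), make_event_schedule(0.8))
  ds <- attach_labels(list(seg(0L, 1600L), seg(1600L, 1600L)), sch, fs)
  expect_identical(ds$features, extraction_targets())
  expect_false(any(c("WT", "AS") %in% ds$features))
  # event 100 ms after R at 2 kHz -> label 200
  expect_equal(unname(ds$labels[1, "IC"]),
               round(sch[[1]]$events[["IC"]] * fs))
  expect_equal(unname(ds$labels[1, "IC"]), 200)
  expect_identical(ds$n_excluded, 0L)
  expect_error(attach_labels(list(seg(0L, 1600L)), sch, fs), "align")
})

test_that("simulate -> segment -> label round trip is exact (clean world)", {
  rec <- clean_recording()
  pipe <- pipeline_of(rec, "clean")
  expect_identical(pipe$peaks$indices, as.integer(rec$onset_samples))
  ds <- pipe$ds
  expect_identical(ds$n_excluded, 0L)
  for (i in seq_along(ds$segments)) {
    truth <- round(rec$schedules[[i]]$events[ds$features] * fs)
    expect_identical(unname(ds$labels[i, ]), unname(truth))
  }
})

test_that("500 simulated cycles at 75 bpm yield zero exclusions", {
  cfg <- simulation_config(n_cycles = 500, seed = 13, hr_jitter_sd = 0)
  rec <- synthesize_recording(cfg)
  bands <- list(SCG = rec$vibration)   # band content irrelevant to labels
  segs <- truncate_cycles(bands, rec$onset_samples)
  ds <- attach_labels(segs, rec$schedules[seq_along(segs)], fs)
  expect_identical(ds$n_excluded, 0L)
  expect_length(ds$segments, 499)
})

test_that("curvature: line, circle, parabola analytic oracles", {
  expect_true(all(curvature_trace(1:100)[2:99] == 0))

  # densely sampled circular arc y = sqrt(1 - x^2), kappa = 1
  x <- seq(-0.5, 0.5, by = 1e-3)
  k <- curvature_trace(sqrt(1 - x^2), dx = 1e-3)
  expect_equal(max(abs(k[10:(length(k) - 10)] - 1)), 0, tolerance = 1e-3)

  # parabola y = x^2 has kappa(0) = 2
  x <- seq(-1, 1, by = 1e-3)
  k <- curvature_trace(x^2, dx = 1e-3)
  expect_equal(k[which(x == 0)], 2, tolerance = 1e-3)
  expect_error(curvature_trace(c(1, 2)), "at least 3")
})

test_that("ULF crest/trough: truth recovery, ordering, degenerate flat cycle", {
  rec <- clean_recording()
  pipe <- pipeline_of(rec, "clean")
  ue <- ulf_extrema(pipe$bands$`ULF-SCG`, pipe$segs)
  expect_false(any(ue$flagged))
  wc_t <- vapply(seq_along(pipe$segs), function(i)
    round(rec$schedules[[i]]$events[["WC"]] * fs), 1)
  wt_t <- vapply(seq_along(pipe$segs), function(i)
    round(rec$schedules[[i]]$events[["WT"]] * fs), 1)
  expect_true(all(abs(ue$wc - wc_t) <= 0.020 * fs))
  expect_true(all(abs(ue$wt - wt_t) <= 0.020 * fs))
  expect_true(all(ue$wc < ue$wt))

  flat <- ulf_extrema(numeric(5000),
                      truncate_cycles(list(b = numeric(5000)),
                                      c(0L, 1600L, 3200L)))
  expect_true(all(flat$flagged))
})
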