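#' Detect ECG R-peaks
#'
#' A Pan-Tompkins style detector: zero-phase 5-15 Hz band-pass,
#' differentiation, squaring, 150 ms moving-window integration, fixed
#' quantile threshold, 240 ms refractory merging, and refinement of each
#' candidate to the raw-ECG maximum within +/-100 ms. All external sample
#' indices in this package are 0-based.
#'
#' @param ecg ECG trace, at least 3 s long.
#' @param sampling_rate Sampling rate in Hz.
#' @param threshold_frac Threshold as a fraction of the 99.5th percentile
#'   of the integrated detection function (default 0.4).
#' @return Object of class `"r_peak_list"`: list with 0-based integer
#'   `indices`, `sampling_rate`, and a `status` string (`"ok"` or
#'   `"no_peaks"`).
#' @export
detect_r_peaks <- function(ecg, sampling_rate, threshold_frac = 0.4) {
  if (length(ecg) < 3 * sampling_rate)
    stop("need at least 3 s of ECG for R-peak detection")
  if (all(ecg == ecg[1])) {
    warning("flat ECG trace: no R-peaks found")
    return(structure(list(indices = integer(0),
                          sampling_rate = sampling_rate,
                          status = "no_peaks"), class = "r_peak_list"))
  }
  qrs_band <- band_definition("QRS", 5, 15)
  xf <- zero_phase_bandpass(ecg, qrs_band, sampling_rate)
  d <- c(0, diff(xf))
  sq <- d^2
  w <- max(3L, round(0.150 * sampling_rate))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * stats::quantile(integ, 0.995, names = FALSE)
  above <- integ > thr
  if (!any(above)) {
    warning("no samples above detection threshold")
    return(structure(list(indices = integer(0),
                          sampling_rate = sampling_rate,
                          status = "no_peaks"), class = "r_peak_list"))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(integ[seg])])
  }
  # refractory merge: keep the stronger of peaks closer than 240 ms
  refr <- round(0.240 * sampling_rate)
  keep <- integer(0)
  for (p in cand) {
    if (length(keep) && p - keep[length(keep)] < refr) {
      if (integ[p] > integ[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  # refine to the raw ECG maximum nearby
  half <- round(0.100 * sampling_rate)
  refined <- vapply(keep, function(p) {
    lo <- max(1, p - half); hi <- min(length(ecg), p + half)
    lo + which.max(ecg[lo:hi]) - 1
  }, numeric(1))
  refined <- sort(unique(refined))
  # plausibility: drop any peak that lands inside the refractory window
  if (length(refined) > 1) {
    ok <- c(TRUE, diff(refined) >= round(0.24 * sampling_rate))
    refined <- refined[ok]
  }
  structure(list(indices = as.integer(refined - 1L),
                 sampling_rate = sampling_rate, status = "ok"),
            class = "r_peak_list")
}

#' @export
print.r_peak_list <- function(x, ...) {
  cat(sprintf("<r_peak_list: %d peaks at %g Hz (%s)>\n",
              length(x$indices), x$sampling_rate, x$status))
  invisible(x)
}

#' Truncate band traces into fixed-length single-cycle segments
#'
#' Segment `i` covers the half-open interval `[R_i, R_{i+1})` (0-based
#' sample coordinates). Cycles shorter than `L` are zero-padded at the
#' tail, preserving the R-anchored coordinate frame; cycles longer than
#' `L` are cut at `L` and flagged `truncated`. The final (incomplete)
#' cycle after the last R-peak is dropped.
#'
#' @param bands Named list of equal-length traces (e.g. from
#'   [decompose_bands()]).
#' @param r_peaks An [detect_r_peaks()] result (or 0-based integer vector).
#' @param L Fixed segment length in samples (default 2048).
#' @return List of `"cycle_segment"` objects: each has `traces`
#'   (named list of length-`L` numeric), `cycle_start` (0-based absolute),
#'   `cycle_len`, `pad_len`, `truncated`.
#' @export
truncate_cycles <- function(bands, r_peaks, L = 2048L) {
  idx <- if (inherits(r_peaks, "r_peak_list")) r_peaks$indices else
    as.integer(r_peaks)
  if (length(idx) < 2) stop("need at least 2 R-peaks to form a cycle")
  n <- length(bands[[1]])
  if (any(vapply(bands, length, 1L) != n))
    stop("band traces must have equal length")
  out <- vector("list", length(idx) - 1)
  for (i in seq_len(length(idx) - 1)) {
    s0 <- idx[i]; s1 <- idx[i + 1]          # 0-based, half-open
    clen <- s1 - s0
    take <- min(clen, L)
    traces <- lapply(bands, function(b) {
      seg <- numeric(L)
      seg[seq_len(take)] <- b[(s0 + 1):(s0 + take)]
      seg
    })
    out[[i]] <- structure(list(
      traces = traces, cycle_start = s0, cycle_len = clen,
      pad_len = max(0L, L - clen), truncated = clen > L
    ), class = "cycle_segment")
  }
  out
}

# the 10 extraction targets; WT and AS are deliberately excluded
#' Fiducial extraction targets
#' @return Character vector of the ten regression targets.
#' @export
extraction_targets <- function() {
  c("MC", "IM", "AO", "IC", "RE", "AC", "MO", "RF", "S1", "S2")
}

# band fed to the localizer for a given feature
feature_band <- function(feature) {
  ifelse(feature %in% c("S1", "S2"), "PCG", "SCG")
}

#' Attach ground-truth labels to cycle segments
#'
#' Converts per-cycle event times into 0-based sample indices relative to
#' the segment start (the R-peak). Segments missing any requested target
#' or whose target falls at or beyond `L` are excluded and counted.
#'
#' @param segments List from [truncate_cycles()].
#' @param schedules List of schedules aligned one-to-one with segments,
#'   or a long-format annotation data.frame
#'   (`cycle_index`, `event`, `sample_index`).
#' @param sampling_rate Sampling rate in Hz (used for schedules).
#' @param targets Features to label; default [extraction_targets()].
#' @return Object of class `"labeled_dataset"`: `segments`, numeric
#'   matrix `labels` (segments x targets), `features`, `n_excluded`,
#'   `split` (NA until [assign_split()]), `sampling_rate`.
#' @export
attach_labels <- function(segments, schedules, sampling_rate,
                          targets = extraction_targets()) {
  n <- length(segments)
  if (is.data.frame(schedules)) {
    ann <- schedules
    need <- c("cycle_index", "event", "sample_index")
    if (!all(need %in% names(ann))) stop("annotation columns must be ",
                                         paste(need, collapse = ", "))
    lab_of <- function(i, ev) {
      v <- ann$sample_index[ann$cycle_index == i & ann$event == ev]
      if (length(v) == 1) v else NA_real_
    }
    labels <- t(vapply(seq_len(n), function(i)
      vapply(targets, function(ev) lab_of(i, ev), 1), numeric(length(targets))))
  } else {
    if (length(schedules) != n)
      stop("schedules (", length(schedules),
           ") do not align with segments (", n, ")")
    labels <- t(vapply(seq_len(n), function(i)
      round(schedules[[i]]$events[targets] * sampling_rate),
      numeric(length(targets))))
  }
  colnames(labels) <- targets
  L <- length(segments[[1]]$traces[[1]])
  ok <- apply(labels, 1, function(r) all(is.finite(r)) && all(r >= 0) &&
                all(r < L))
  # labels must also lie inside the (possibly truncated) source cycle
  clen <- vapply(segments, function(s) as.integer(s$cycle_len), 1L)
  for (i in seq_len(n))
    if (ok[i] && any(labels[i, ] >= min(clen[i], L))) ok[i] <- FALSE
  structure(list(
    segments = segments[ok],
    labels = labels[ok, , drop = FALSE],
    features = targets,
    n_excluded = sum(!ok),
    split = rep(NA_character_, sum(ok)),
    sampling_rate = sampling_rate
  ), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d segments, %d targets, %d excluded>\n",
              length(x$segments), length(x$features), x$n_excluded))
  invisible(x)
}

#' Assign a train/test split
#'
#' Random 70/30 split by default, seeded.
#'
#' @param dataset A [attach_labels()] result.
#' @param test_frac Test fraction (default 0.3).
#' @param seed Integer seed.
#' @return The dataset with its `split` slot filled
#'   (`"train"` / `"test"`).
#' @export
assign_split <- function(dataset, test_frac = 0.3, seed = 0L) {
  n <- length(dataset$segments)
  set.seed(seed)
  n_test <- round(test_frac * n)
  test_idx <- sample.int(n, n_test)
  split <- rep("train", n)
  split[test_idx] <- "test"
  dataset$split <- split
  dataset
}

#' Discrete curvature of a trace
#'
#' Central-difference curvature `|x''| / (1 + x'^2)^(3/2)`, endpoints
#' replicated. Provided as a labeling-aid overlay: the sharp fiducials sit
#' at curvature peaks, the rapid-ejection/filling peaks do not.
#'
#' @param x Numeric trace (length >= 3).
#' @param dx Sample spacing (default 1).
#' @return Curvature trace, same length as `x`.
#' @export
curvature_trace <- function(x, dx = 1) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  i <- 2:(n - 1)
  d1 <- (x[i + 1] - x[i - 1]) / (2 * dx)
  d2 <- (x[i + 1] - 2 * x[i] + x[i - 1]) / dx^2
  k <- abs(d2) / (1 + d1^2)^1.5
  c(k[1], k, k[length(k)])
}

#' Per-cycle ULF crest and trough
#'
#' For each cycle window, WC is the highest local maximum of the ULF-SCG
#' band and WT the deepest subsequent local minimum. These two points
#' bracket the ejection period and are reported separately from the CNN
#' targets.
#'
#' @param ulf_band ULF-SCG filtered trace (full recording).
#' @param segments List from [truncate_cycles()] (cycle windows).
#' @return data.frame with 0-based cycle-relative `wc`, `wt` and a
#'   `flagged` column for cycles without usable extrema.
#' @export
ulf_extrema <- function(ulf_band, segments) {
  out <- data.frame(cycle = seq_along(segments), wc = NA_integer_,
                    wt = NA_integer_, flagged = FALSE)
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    win <- ulf_band[(s$cycle_start + 1):(s$cycle_start + s$cycle_len)]
    ex <- find_extrema(win)
    if (length(ex$maxima) == 0) { out$flagged[i] <- TRUE; next }
    wc <- ex$maxima[which.max(win[ex$maxima])]
    mins_after <- ex$minima[ex$minima > wc]
    if (length(mins_after) == 0) { out$flagged[i] <- TRUE; next }
    wt <- mins_after[which.min(win[mins_after])]
    out$wc[i] <- wc - 1L   # 0-based
    out$wt[i] <- wt - 1L
  }
  out
}
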