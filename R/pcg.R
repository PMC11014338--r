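#' Shannon energy envelope of a PCG trace
#'
#' Normalized Shannon energy `-x^2 * log(x^2)` of the amplitude-normalized
#' signal, smoothed by a centered moving average and scaled to unit
#' maximum. Emphasizes medium-amplitude heart-sound bursts over both noise
#' floor and isolated spikes.
#'
#' @param pcg PCG-band trace (20-200 Hz).
#' @param sampling_rate Sampling rate in Hz.
#' @param window_ms Moving-average window in milliseconds (default 40).
#' @return Object of class `"energy_envelope"`: `trace` (nonnegative,
#'   same length), `window`, `normalization`.
#' @export
energy_envelope <- function(pcg, sampling_rate, window_ms = 40) {
  m <- max(abs(pcg))
  if (m == 0 || stats::sd(pcg) == 0) {
    return(structure(list(trace = numeric(length(pcg)),
                          window = 0L, normalization = 0),
                     class = "energy_envelope"))
  }
  xb <- pcg / m
  x2 <- xb^2
  se <- ifelse(x2 > 0, -x2 * log(x2), 0)
  w <- max(3L, round(window_ms / 1000 * sampling_rate))
  sm <- as.numeric(stats::filter(se, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  sm[sm < 0] <- 0
  norm <- max(sm)
  if (norm > 0) sm <- sm / norm
  structure(list(trace = sm, window = as.integer(w), normalization = norm),
            class = "energy_envelope")
}

#' @export
print.energy_envelope <- function(x, ...) {
  cat(sprintf("<energy_envelope: %d samples, window %d>\n",
              length(x$trace), x$window))
  invisible(x)
}

#' Automatically label S1 and S2 heart sounds
#'
#' Candidate peaks are local maxima of the energy envelope above an
#' adaptive per-cycle threshold. Candidates across all cycles are
#' expressed as phase-in-cycle (fraction of the R-R interval) and split by
#' 2-means clustering; the earlier-phase cluster is S1 and the later S2
#' regardless of cluster index, so the assignment is permutation-stable.
#' Per cycle the strongest candidate of each cluster is kept. Labels whose
#' phase deviates more than 3 SD from their cluster's phase median are
#' flagged (automatic stand-in for a visual check).
#'
#' @param envelope An [energy_envelope()] (or bare nonnegative trace).
#' @param r_peaks An [detect_r_peaks()] result or 0-based indices.
#' @param threshold_frac Candidate threshold as a fraction of the cycle's
#'   envelope maximum (default 0.3).
#' @return data.frame with one row per cycle: 0-based absolute
#'   `s1`, `s2`, confidences, and `flagged`.
#' @export
label_s1_s2 <- function(envelope, r_peaks, threshold_frac = 0.3) {
  env <- if (inherits(envelope, "energy_envelope")) envelope$trace else
    envelope
  idx <- if (inherits(r_peaks, "r_peak_list")) r_peaks$indices else
    as.integer(r_peaks)
  n_cyc <- length(idx) - 1
  if (n_cyc < 2) stop("need at least 2 cycles to label S1/S2")
  cand <- list()
  for (i in seq_len(n_cyc)) {
    s0 <- idx[i]; s1 <- idx[i + 1]
    win <- env[(s0 + 1):s1]
    ex <- find_extrema(win)$maxima
    thr <- threshold_frac * max(win)
    ex <- ex[win[ex] >= thr]
    if (length(ex))
      cand[[length(cand) + 1]] <- data.frame(
        cycle = i, abs = s0 + ex - 1L, height = win[ex],
        phase = (ex - 1) / (s1 - s0))
  }
  cand <- do.call(rbind, cand)
  out <- data.frame(cycle = seq_len(n_cyc), s1 = NA_integer_,
                    s2 = NA_integer_, s1_conf = NA_real_,
                    s2_conf = NA_real_, flagged = FALSE)
  if (is.null(cand) || nrow(cand) < 4) { out$flagged <- TRUE; return(out) }
  km <- stats::kmeans(cand$phase, centers = 2, nstart = 5)
  early <- which.min(km$centers)                  # ordering rule, not index
  cand$sound <- ifelse(km$cluster == early, "S1", "S2")
  for (i in seq_len(n_cyc)) {
    ci <- cand[cand$cycle == i, ]
    a <- ci[ci$sound == "S1", ]
    b <- ci[ci$sound == "S2", ]
    if (nrow(a) == 0 || nrow(b) == 0) { out$flagged[i] <- TRUE; next }
    a <- a[which.max(a$height), ]
    b <- b[which.max(b$height), ]
    if (a$abs >= b$abs) { out$flagged[i] <- TRUE; next }
    out$s1[i] <- a$abs; out$s2[i] <- b$abs
    out$s1_conf[i] <- a$height; out$s2_conf[i] <- b$height
  }
  # 3-SD phase outlier rule per cluster
  for (snd in c("S1", "S2")) {
    ph <- cand$phase[cand$sound == snd]
    med <- stats::median(ph); s <- stats::sd(ph)
    if (is.na(s) || s == 0) next
    col <- tolower(snd)
    for (i in which(!out$flagged)) {
      lab <- out[[col]][i]
      p <- (lab - idx[i]) / (idx[i + 1] - idx[i])
      if (abs(p - med) > 3 * s) out$flagged[i] <- TRUE
    }
  }
  out
}

#' Correlation between two paired position lists
#'
#' Pearson correlation and the least-squares line of `b` on `a`, as used
#' to compare fiducial positions from two detectors or sensors.
#'
#' @param positions_a,positions_b Equal-length numeric vectors, n >= 3.
#' @return List with `pearson_r`, `slope`, `intercept`, `n`, `status`
#'   (`"ok"` or `"degenerate"`; correlation is NA when either list has
#'   zero variance).
#' @export
position_correlation <- function(positions_a, positions_b) {
  a <- as.numeric(positions_a); b <- as.numeric(positions_b)
  if (length(a) != length(b)) stop("position lists must have equal length")
  if (length(a) < 3) stop("need at least 3 paired positions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(pearson_r = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(a), status = "degenerate"))
  }
  r <- stats::cor(a, b)
  slope <- stats::cov(a, b) / stats::var(a)
  list(pearson_r = r, slope = slope,
       intercept = mean(b) - slope * mean(a),
       n = length(a), status = "ok")
}
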