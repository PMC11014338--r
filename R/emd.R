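#' Locate local extrema of a trace
#'
#' Strict sign-change extrema on the first difference; flat plateaus
#' contribute their first sample. Used by the sifting loop and by the
#' ULF crest/trough picker.
#'
#' @param x Numeric trace.
#' @return List with integer vectors `maxima` and `minima` (1-based).
#' @export
find_extrema <- function(x) {
  s <- sign(diff(x))
  # carry the sign across flat runs so plateaus register once (vectorized LOCF)
  nz <- which(s != 0)
  if (length(nz) == 0) return(list(maxima = integer(0), minima = integer(0)))
  last_nz <- cummax(ifelse(s != 0, seq_along(s), 0L))
  s <- ifelse(last_nz > 0, s[pmax(last_nz, 1L)], 0)
  ch <- diff(s)
  maxima <- which(ch < 0) + 1L
  minima <- which(ch > 0) + 1L
  list(maxima = maxima, minima = minima)
}

# cubic-spline envelope through (idx, x[idx]) with two extrema mirrored
# about each endpoint to tame boundary swings
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  nm <- min(2L, k)
  pre_t <- 2 - rev(idx[seq_len(nm)])        # mirror about sample 1
  pre_v <- rev(val[seq_len(nm)])
  post_t <- 2 * n - rev(rev(idx)[seq_len(nm)])  # mirror about sample n
  post_v <- rev(rev(val)[seq_len(nm)])
  tt <- c(pre_t, idx, post_t)
  vv <- c(pre_v, val, post_v)
  keep <- !duplicated(tt)
  stats::spline(tt[keep], vv[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Standard cubic-spline sifting. Each intrinsic mode function (IMF) is
#' accepted once the Cauchy-type criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_thresh` is met or `max_sift`
#' sifts have run. Decomposition stops when the residue has fewer than
#' four extrema, is (near-)monotone, or `max_imf` IMFs were extracted.
#'
#' @param x Numeric trace.
#' @param sd_thresh Sifting stop threshold (default 0.2).
#' @param max_sift Maximum sifts per IMF (default 100).
#' @param max_imf Maximum number of IMFs (default 12).
#' @return An object of class `"imf_set"`: list with matrix `imfs`
#'   (one column per IMF, high to low frequency), `residue`, and
#'   `sift_counts`. Inputs with fewer than four extrema return zero IMFs
#'   with `residue = x`.
#' @export
emd <- function(x, sd_thresh = 0.2, max_sift = 100, max_imf = 12) {
  n <- length(x)
  imfs <- list()
  sift_counts <- integer(0)
  residue <- x
  repeat {
    ex <- find_extrema(residue)
    if (length(ex$maxima) + length(ex$minima) < 4 ||
        length(ex$maxima) < 2 || length(ex$minima) < 2 ||
        length(imfs) >= max_imf) break
    h <- residue
    sifts <- 0L
    repeat {
      exh <- find_extrema(h)
      if (length(exh$maxima) < 2 || length(exh$minima) < 2) break
      upper <- spline_envelope(exh$maxima, h[exh$maxima], n)
      lower <- spline_envelope(exh$minima, h[exh$minima], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sifts <- sifts + 1L
      sd_crit <- sum((h - h_new)^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_crit < sd_thresh || sifts >= max_sift) break
    }
    imfs[[length(imfs) + 1]] <- h
    sift_counts <- c(sift_counts, sifts)
    residue <- residue - h
  }
  structure(list(
    imfs = if (length(imfs)) do.call(cbind, imfs) else
      matrix(numeric(0), nrow = n, ncol = 0),
    residue = residue,
    sift_counts = sift_counts
  ), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set: %d IMFs over %d samples>\n",
              ncol(x$imfs), nrow(x$imfs)))
  invisible(x)
}

#' Match intrinsic mode functions to analysis bands
#'
#' Assigns to each band-filtered trace the IMF with the largest absolute
#' Pearson correlation (EMD sign is arbitrary). The mapping is reported
#' even when not injective, with `injective = FALSE` flagged.
#'
#' @param imf_set An [emd()] result.
#' @param bands Named list of band-filtered traces, equal length.
#' @return List with `mapping` (named integer vector of IMF indices),
#'   `correlation` (bands x IMFs absolute-correlation matrix) and
#'   `injective` flag.
#' @export
match_imfs_to_bands <- function(imf_set, bands) {
  stopifnot(inherits(imf_set, "imf_set"))
  k <- ncol(imf_set$imfs)
  if (k == 0) stop("no IMFs to match")
  n <- nrow(imf_set$imfs)
  if (any(vapply(bands, length, 1L) != n))
    stop("band traces must match IMF length")
  cm <- matrix(NA_real_, nrow = length(bands), ncol = k,
               dimnames = list(names(bands), paste0("IMF", seq_len(k))))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    for (j in seq_len(k)) {
      im <- imf_set$imfs[, j]
      cm[i, j] <- if (stats::sd(b) == 0 || stats::sd(im) == 0) 0 else
        abs(stats::cor(b, im))
    }
  }
  mapping <- apply(cm, 1, which.max)
  list(mapping = mapping, correlation = cm,
       injective = !anyDuplicated(mapping))
}
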