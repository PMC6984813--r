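# Baseline statistics, Savitzky-Golay smoothing and alignment-averaging.
# These are the shared primitives of every detector: current sweeps are
# smoothed with a +/- 0.5 ms 3rd-order Savitzky-Golay filter, detection
# thresholds are multiples of the raw median absolute deviation of a
# baseline window, and mean event traces are built after aligning events by
# their point of maximal rise.

# least-squares Savitzky-Golay convolution weights for the smoothed value at
# position `at` (0 = window centre) of a window of half-width m, order p
.savgol_weights <- function(m, p, at = 0L) {
  x <- -m:m
  A <- outer(x, 0:p, `^`)
  # value of the fitted polynomial at `at`: e(at)' (A'A)^-1 A' y
  pow <- at^(0:p)
  drop(pow %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay smoothing of a current sweep
#'
#' Least-squares polynomial smoothing with a window of \eqn{\pm}0.5 ms
#' (11 samples at 10 kHz) and polynomial order 3, applied to current data.
#' Edges are handled by evaluating the edge-window polynomial fit at the
#' edge positions, so the output has the same length as the input and
#' polynomials up to the filter order are reproduced exactly everywhere.
#'
#' @param sweep a `phys_sweep` with `signal_kind = "current"`, or a plain
#'   numeric vector (then `sampling_rate` is used).
#' @param half_width_ms half window in ms (default 0.5).
#' @param order polynomial order (default 3).
#' @param sampling_rate used when `sweep` is a bare vector.
#' @return smoothed sweep (same class as the input).
#' @export
savgol_smooth <- function(sweep, half_width_ms = 0.5, order = 3, sampling_rate = 10000) {
  is_sweep <- inherits(sweep, "phys_sweep")
  if (is_sweep) {
    if (sweep$signal_kind != "current")
      stop("savgol_smooth is defined for current sweeps; voltage data are left unfiltered")
    x <- sweep$samples; fs <- sweep$sampling_rate
  } else {
    x <- as.numeric(sweep); fs <- sampling_rate
  }
  m <- max(1L, round(half_width_ms * 1e-3 * fs))
  if (length(x) < 2L * m + 1L)
    stop(sprintf("sweep shorter than the filter window (%d samples)", 2L * m + 1L))
  w <- .savgol_weights(m, order, 0L)
  # interior by convolution
  y <- stats::filter(x, rev(w), sides = 2)
  y <- as.numeric(y)
  # edges: evaluate the first/last window's polynomial fit at offset positions
  for (k in seq_len(m)) {
    y[k] <- sum(.savgol_weights(m, order, at = k - m - 1L) * x[1:(2L * m + 1L)])
    nk <- length(x) - k + 1L
    y[nk] <- sum(.savgol_weights(m, order, at = m + 1L - k) * x[(length(x) - 2L * m):length(x)])
  }
  if (is_sweep) { sweep$samples <- y; sweep } else y
}

#' Baseline mean and median absolute deviation
#'
#' The detection thresholds are multiples of the *raw* median absolute
#' deviation (no 1.4826 normal-consistency factor) of the baseline current;
#' `mad_scale` exposes the factor for sensitivity analyses.
#'
#' @param sweep a `phys_sweep` or numeric vector.
#' @param window `c(start, end)` in seconds (half-open); default is the whole
#'   trace. Samples inside the sweep's artifact windows are excluded.
#' @param mad_scale multiplier on the raw MAD (default 1).
#' @return list with `mean`, `mad`, `window` (class `phys_baseline`).
#' @export
baseline_stats <- function(sweep, window = NULL, mad_scale = 1) {
  if (inherits(sweep, "phys_sweep")) {
    x <- sweep$samples; fs <- sweep$sampling_rate; t0 <- sweep$t0
    aw <- sweep$artifact_windows
  } else {
    x <- as.numeric(sweep); fs <- 10000; t0 <- 0; aw <- list()
  }
  n <- length(x)
  if (is.null(window)) window <- c(t0, t0 + n / fs)
  idx <- .window_idx(window[1], window[2], fs, n, t0)
  for (w in aw) idx <- setdiff(idx, .window_idx(w[1], w[2], fs, n, t0))
  if (length(idx) == 0L) stop("baseline window is empty after artifact exclusion")
  structure(list(mean = mean(x[idx]), mad = .raw_mad(x[idx], mad_scale),
                 window = window), class = "phys_baseline")
}

#' Align-and-average event segments
#'
#' Builds the mean trace of a set of event segments. `mode = "max_rise"`
#' aligns each segment on its point of maximal rise (maximal first
#' difference; for inward currents, maximal *downward* slope — the polarity
#' is inferred from the mean extremum). `mode = "ap_threshold"` aligns on an
#' index supplied through `align_idx` (the per-event threshold sample).
#' `mode = "none"` averages as-is (used for subthreshold EPSPs, which are
#' averaged unaligned). Segments are shifted to a common reference and the
#' pointwise mean is taken over the support common to all segments.
#'
#' @param segments list of numeric vectors.
#' @param mode `"max_rise"`, `"ap_threshold"` or `"none"`.
#' @param align_idx integer vector of per-segment alignment samples
#'   (required for `"ap_threshold"`).
#' @return numeric vector, with attribute `ref_idx` giving the alignment
#'   point's position within the averaged trace.
#' @export
align_average <- function(segments, mode = c("max_rise", "ap_threshold", "none"),
                          align_idx = NULL) {
  mode <- match.arg(mode)
  if (length(segments) == 0L) stop("align_average needs at least one segment")
  segments <- lapply(segments, as.numeric)
  if (length(segments) == 1L) {
    out <- segments[[1]]
    attr(out, "ref_idx") <- 1L
    return(out)
  }
  ref <- switch(mode,
    none = rep(1L, length(segments)),
    ap_threshold = {
      if (is.null(align_idx) || length(align_idx) != length(segments))
        stop("ap_threshold mode needs one align_idx per segment")
      as.integer(align_idx)
    },
    max_rise = vapply(segments, function(s) {
      d <- diff(s)
      # sign of the event from the largest absolute excursion from the ends
      neg <- abs(min(s) - s[1]) > abs(max(s) - s[1])
      if (neg) which.min(d) else which.max(d)
    }, integer(1))
  )
  lead <- min(ref - 1L)                      # samples available before ref in all
  trail <- min(vapply(segments, length, integer(1)) - ref)
  if (lead + trail < 0L) stop("segments have no common support after alignment")
  rows <- mapply(function(s, r) s[(r - lead):(r + trail)], segments, ref, SIMPLIFY = FALSE)
  out <- Reduce(`+`, rows) / length(rows)
  attr(out, "ref_idx") <- lead + 1L
  out
}
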