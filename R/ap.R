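# Action-potential detection and waveform measurements on current-clamp
# voltage sweeps. Threshold is the voltage at which dV/dt (centred finite
# differences on the unfiltered trace) first exceeds 20 V/s on the way up;
# amplitude is peak minus threshold; halfwidth is the time between the
# half-amplitude crossings on the up- and downslope; the AHP is the most
# hyperpolarized voltage within 100 ms of threshold (bounded by the next
# AP), measured relative to threshold.

#' Detect action potentials in a voltage sweep
#'
#' @param sweep a current-clamp `phys_sweep` (mV) or numeric vector.
#' @param dvdt_thresh threshold-crossing slope in V/s (default 20; note
#'   mV/ms = V/s).
#' @param min_amplitude minimal peak-above-threshold excursion in mV for a
#'   crossing to count as an AP (default 20; rejects noise and spikelets).
#' @param window `c(start, end)` seconds restricting the search (optional).
#' @param ahp_window_ms AHP trough search limit after threshold (default 100).
#' @param ahp_limit_t absolute time (s) past which the AHP trough search
#'   never extends (e.g. the current-step offset, so the post-step
#'   relaxation is not mistaken for an AHP).
#' @return data frame, one row per AP: `threshold_v`, `threshold_t`,
#'   `peak_v`, `peak_t`, `amplitude`, `halfwidth` (ms), `ahp_magnitude`
#'   (mV, trough minus threshold; 0 when the voltage never drops below
#'   threshold), `ahp_latency` (ms, threshold to trough), `ahp_truncated`.
#' @export
detect_aps <- function(sweep, dvdt_thresh = 20, min_amplitude = 20, window = NULL,
                       ahp_window_ms = 100, ahp_limit_t = NULL) {
  v <- if (inherits(sweep, "phys_sweep")) sweep$samples else as.numeric(sweep)
  fs <- if (inherits(sweep, "phys_sweep")) sweep$sampling_rate else 10000
  t0 <- if (inherits(sweep, "phys_sweep")) sweep$t0 else 0
  n <- length(v)
  tvec <- .i2t(seq_len(n), fs, t0)
  dt_ms <- 1000 / fs
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms), NA)   # mV/ms == V/s
  lo <- 2L; hi <- n - 1L
  if (!is.null(window)) {
    idx <- .window_idx(window[1], window[2], fs, n, t0)
    if (length(idx)) { lo <- max(lo, min(idx)); hi <- min(hi, max(idx)) }
  }
  emptyap <- data.frame(threshold_v = numeric(0), threshold_t = numeric(0),
                        peak_v = numeric(0), peak_t = numeric(0), amplitude = numeric(0),
                        halfwidth = numeric(0), ahp_magnitude = numeric(0),
                        ahp_latency = numeric(0), ahp_truncated = logical(0))
  ii <- lo:hi
  up <- ii[dvdt[ii] > dvdt_thresh & dvdt[ii - 1L] <= dvdt_thresh]
  if (length(up) == 0L) return(emptyap)
  rows <- list()
  last_end <- 0L
  for (i in up) {
    if (i <= last_end) next
    # threshold voltage by linear interpolation of dV/dt between samples
    f <- (dvdt_thresh - dvdt[i - 1L]) / (dvdt[i] - dvdt[i - 1L])
    thr_v <- v[i - 1L] + f * (v[i] - v[i - 1L])
    thr_t <- tvec[i - 1L] + f * (tvec[i] - tvec[i - 1L])
    # peak: first downturn of dV/dt after the crossing (bounded 10 ms ahead),
    # not the window maximum -- in dense trains that would jump to the next AP
    seg_end <- min(n - 1L, i + round(0.010 * fs))
    turn <- i
    while (turn < seg_end && v[turn + 1L] >= v[turn]) turn <- turn + 1L
    pk <- turn
    if (v[pk] - thr_v < min_amplitude) next
    amp <- v[pk] - thr_v
    half <- thr_v + amp / 2
    # halfwidth: crossing of `half` on the upslope before and downslope after pk
    upi <- max(which(v[max(1L, i - round(0.002 * fs)):pk] < half))
    upi <- upi + max(1L, i - round(0.002 * fs)) - 1L
    t_up <- .cross_time(tvec, v, upi, half)
    down_seg <- pk:min(n - 1L, pk + round(0.02 * fs))
    below <- down_seg[v[down_seg + 1L] < half]
    hw <- NA_real_; t_down <- NA_real_
    if (length(below)) {
      t_down <- .cross_time(tvec, v, below[1L], half)
      hw <- (t_down - t_up) * 1000
    }
    rows[[length(rows) + 1L]] <- data.frame(
      threshold_v = thr_v, threshold_t = thr_t, peak_v = v[pk], peak_t = tvec[pk],
      amplitude = amp, halfwidth = hw, ahp_magnitude = NA_real_,
      ahp_latency = NA_real_, ahp_truncated = FALSE, peak_idx = pk, thr_idx = i)
    last_end <- pk + 1L
  }
  if (length(rows) == 0L) return(emptyap)
  ap <- do.call(rbind, rows)
  # AHP per AP: trough within ahp_window_ms of threshold, bounded by the next
  # AP's threshold time when it comes sooner
  for (k in seq_len(nrow(ap))) {
    a <- ap$peak_idx[k]
    lim_t <- ap$threshold_t[k] + ahp_window_ms / 1000
    if (k < nrow(ap)) lim_t <- min(lim_t, ap$threshold_t[k + 1L])
    if (!is.null(ahp_limit_t)) lim_t <- min(lim_t, ahp_limit_t)
    b <- min(n, .t2i(lim_t, fs, n, t0))
    if (b <= a) next
    tr <- a:b
    j <- tr[which.min(v[tr])]
    ap$ahp_truncated[k] <- (b == n) && (lim_t > tvec[n])
    ap$ahp_magnitude[k] <- min(v[j] - ap$threshold_v[k], 0)  # 0 if never below threshold
    ap$ahp_latency[k] <- (tvec[j] - ap$threshold_t[k]) * 1000
  }
  ap$peak_idx <- NULL; ap$thr_idx <- NULL
  ap
}

#' Mean rheobase AP waveform and phase plot
#'
#' Aligns the rheobase-sweep APs of a cell on threshold, averages them, and
#' returns the waveform measurements of the mean AP plus its phase plot
#' (dV/dt against V).
#'
#' @param sweep the rheobase voltage sweep (`phys_sweep` or vector).
#' @param aps optional precomputed [detect_aps()] table for that sweep.
#' @param pre_ms,post_ms extraction window around threshold (defaults 2/10).
#' @return list: `ap` (one-row measurement of the mean AP), `waveform`,
#'   `phase` (data frame `v`, `dvdt`).
#' @export
ap_waveform_features <- function(sweep, aps = NULL, pre_ms = 2, post_ms = 10) {
  v <- if (inherits(sweep, "phys_sweep")) sweep$samples else as.numeric(sweep)
  fs <- if (inherits(sweep, "phys_sweep")) sweep$sampling_rate else 10000
  t0 <- if (inherits(sweep, "phys_sweep")) sweep$t0 else 0
  if (is.null(aps)) aps <- detect_aps(sweep)
  if (nrow(aps) == 0L) stop("no APs in the sweep")
  pre <- round(pre_ms / 1000 * fs); post <- round(post_ms / 1000 * fs)
  idx <- .t2i(aps$threshold_t, fs, length(v), t0)
  segs <- list(); refs <- integer(0)
  for (i in idx) {
    a <- i - pre; b <- i + post
    if (a < 1L || b > length(v)) next
    segs[[length(segs) + 1L]] <- v[a:b]; refs <- c(refs, pre + 1L)
  }
  if (length(segs) == 0L) stop("no AP with full waveform support")
  m <- align_average(segs, mode = "ap_threshold", align_idx = refs)
  mi <- detect_aps(m, window = NULL)
  meas <- if (nrow(mi)) mi[1L, ] else NULL
  dt_ms <- 1000 / fs
  nm <- length(m)
  phase <- data.frame(v = m[2:(nm - 1L)],
                      dvdt = (m[3:nm] - m[1:(nm - 2L)]) / (2 * dt_ms))
  list(ap = meas, waveform = as.numeric(m), phase = phase)
}
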