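# Evoked and unitary PSC detection. EPSCs (V_hold -70 mV) are negative
# deflections, IPSCs (V_hold 0 mV) positive, exceeding the mean baseline
# current (500 ms before stimulation) by more than 6x the raw MAD of that
# baseline, within 20 ms of the end of the stimulus artifact. A first pass
# over a 25% sweep subsample fixes the search window (median peak time
# +/- 5 ms for EPSCs, +/- 7.5 ms for IPSCs); the full-sweep pass then
# classifies successes/failures and measures amplitude and kinetics.

.pol_sign <- function(polarity) if (polarity == "negative") -1 else 1

.artifact_end <- function(sweep, artifact_ms) {
  if (length(sweep$stimulus_times) == 0L) stop("stimulus metadata missing")
  sweep$stimulus_times[1] + artifact_ms / 1000
}

#' Select the evoked-PSC detection window
#'
#' Subsamples 25% of the sweeps (or 5 sweeps when the experiment has fewer
#' than 20), finds in each the maximal correct-polarity deflection from
#' baseline within 20 ms after the stimulus artifact, and centres the
#' detection window at the median of those peak times with a polarity-
#' specific half-width (5 ms for EPSCs, 7.5 ms for IPSCs).
#'
#' @param ss an evoked voltage-clamp `phys_sweepset`.
#' @param polarity `"negative"` (EPSC) or `"positive"` (IPSC).
#' @param artifact_ms stimulus artifact width in ms (default 2).
#' @param search_ms post-artifact search limit in ms (default 20).
#' @param half_width_ms override of the polarity half-width.
#' @param baseline_s baseline length before stimulation in s (default 0.5).
#' @param seed RNG seed for the sweep subsample.
#' @return list with `center` (s), `half_width` (ms), `search_limit` (ms),
#'   `subsample` (sweep indices) of class `phys_window`.
#' @export
select_event_window <- function(ss, polarity = c("negative", "positive"),
                                artifact_ms = 2, search_ms = 20,
                                half_width_ms = NULL, baseline_s = 0.5, seed = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(ss, "phys_sweepset"))
  n <- length(ss$sweeps)
  sgn <- .pol_sign(polarity)
  if (is.null(half_width_ms)) half_width_ms <- if (polarity == "negative") 5 else 7.5
  n_sub <- if (n < 20L) min(5L, n) else round(0.25 * n)
  sub <- with_seed(seed, sort(sample.int(n, n_sub)))
  peak_t <- vapply(sub, function(i) {
    sw <- blank_artifacts(ss$sweeps[[i]])
    ref <- .artifact_end(sw, artifact_ms)
    bl <- baseline_stats(sw, c(sw$stimulus_times[1] - baseline_s, sw$stimulus_times[1]))
    idx <- .window_idx(ref, ref + search_ms / 1000, sw$sampling_rate,
                       length(sw$samples), sw$t0)
    if (length(idx) == 0L) stop("search window extends past sweep end")
    k <- idx[which.max(sgn * (sw$samples[idx] - bl$mean))]
    .i2t(k, sw$sampling_rate, sw$t0)
  }, numeric(1))
  structure(list(center = stats::median(peak_t), half_width = half_width_ms,
                 search_limit = search_ms, subsample = sub, polarity = polarity),
            class = "phys_window")
}

# 20-80% rise time and 20%-rise latency of one detected event
# returns c(rise_ms, latency_ms, t20); NA when the crossings are obscured
.rise_latency <- function(x, fs, t0, peak_idx, baseline, reference_t) {
  amp <- x[peak_idx] - baseline
  tvec <- .i2t(seq_along(x), fs, t0)
  l20 <- baseline + 0.2 * amp; l80 <- baseline + 0.8 * amp
  frac <- (x - baseline) / amp            # 1 at peak, <0.2 before onset
  # last sample before the peak still below 20% (and 80%) of the amplitude
  pre <- seq_len(peak_idx - 1L)
  i20 <- suppressWarnings(max(pre[frac[pre] < 0.2]))
  i80 <- suppressWarnings(max(pre[frac[pre] < 0.8]))
  if (!is.finite(i20) || !is.finite(i80)) return(c(NA_real_, NA_real_, NA_real_))
  t20 <- .cross_time(tvec, x, i20, l20)
  t80 <- .cross_time(tvec, x, i80, l80)
  c((t80 - t20) * 1000, (t20 - reference_t) * 1000, t20)
}

#' Detect evoked PSCs and summarise a cell
#'
#' Per sweep, a success is a correct-polarity deflection strictly exceeding
#' the mean baseline current by `mad_mult` (default 6) times the raw MAD of
#' the 500 ms pre-stimulus baseline, inside the detection window. Amplitude
#' is peak minus the sweep's baseline mean. Failure amplitude is the maximal
#' correct-polarity deflection within ±5 ms of the cell's mean peak time.
#' The cell amplitude is the mean over successes only; if every sweep fails,
#' it is the extremal deflection of the mean trace within 20 ms of the
#' artifact end.
#'
#' @param ss an evoked voltage-clamp `phys_sweepset`.
#' @param window a `phys_window` from [select_event_window()]; computed (with
#'   `seed`) when NULL.
#' @param polarity `"negative"` (EPSC) or `"positive"` (IPSC).
#' @param mad_mult detection threshold in baseline MADs (default 6).
#' @param baseline_s,artifact_ms,search_ms as in [select_event_window()].
#' @param smooth apply the Savitzky-Golay filter before detection.
#' @param seed passed to [select_event_window()].
#' @return list of class `phys_evoked` with `events` (one row per sweep) and
#'   `summary` (mean amplitude, success rate, latency, jitter, rise, tau).
#' @export
detect_evoked_psc <- function(ss, window = NULL, polarity = c("negative", "positive"),
                              mad_mult = 6, baseline_s = 0.5, artifact_ms = 2,
                              search_ms = 20, smooth = TRUE, seed = NULL) {
  polarity <- match.arg(polarity)
  sgn <- .pol_sign(polarity)
  if (is.null(window))
    window <- select_event_window(ss, polarity, artifact_ms, search_ms,
                                  baseline_s = baseline_s, seed = seed)
  raw <- lapply(ss$sweeps, blank_artifacts)
  # noise floor (MAD) from the unfiltered baseline; peak search and kinetics
  # on the Savitzky-Golay filtered trace
  sweeps <- if (smooth) lapply(raw, savgol_smooth) else raw
  fs <- sweeps[[1]]$sampling_rate
  ref <- .artifact_end(sweeps[[1]], artifact_ms)
  rows <- lapply(seq_along(sweeps), function(i) {
    sw <- sweeps[[i]]
    stim <- sw$stimulus_times[1]
    bl <- baseline_stats(raw[[i]], c(stim - baseline_s, stim))
    lo <- max(window$center - window$half_width / 1000, ref)
    hi <- min(window$center + window$half_width / 1000, ref + search_ms / 1000)
    idx <- .window_idx(lo, hi, fs, length(sw$samples), sw$t0)
    if (length(idx) == 0L) stop("detection window extends past sweep end")
    k <- idx[which.max(sgn * (sw$samples[idx] - bl$mean))]
    defl <- sgn * (sw$samples[k] - bl$mean)
    success <- defl > mad_mult * bl$mad
    amp <- sw$samples[k] - bl$mean
    if (success) {
      rl <- .rise_latency(sw$samples, fs, sw$t0, k, bl$mean, ref)
      data.frame(sweep_index = i, success = TRUE, amplitude = amp,
                 peak_time = .i2t(k, fs, sw$t0), rise_20_80 = rl[1], latency = rl[2],
                 baseline_mean = bl$mean, baseline_mad = bl$mad)
    } else {
      data.frame(sweep_index = i, success = FALSE, amplitude = amp,
                 peak_time = .i2t(k, fs, sw$t0), rise_20_80 = NA_real_,
                 latency = NA_real_, baseline_mean = bl$mean, baseline_mad = bl$mad)
    }
  })
  ev <- do.call(rbind, rows)
  # failure amplitude convention: extremal correct-polarity deflection within
  # +/- 5 ms of the cell's mean success peak time
  if (any(ev$success)) {
    mean_peak <- mean(ev$peak_time[ev$success])
    for (i in which(!ev$success)) {
      sw <- sweeps[[i]]
      idx <- .window_idx(mean_peak - 0.005, mean_peak + 0.005, fs,
                         length(sw$samples), sw$t0)
      if (length(idx)) {
        k <- idx[which.max(sgn * (sw$samples[idx] - ev$baseline_mean[i]))]
        ev$amplitude[i] <- sw$samples[k] - ev$baseline_mean[i]
        ev$peak_time[i] <- .i2t(k, fs, sw$t0)
      }
    }
  }
  summ <- summarise_psc_events(ev, sweeps, ref, search_ms, polarity)
  structure(list(events = ev, summary = summ, window = window, polarity = polarity),
            class = "phys_evoked")
}

#' Success rate in percent
#'
#' @param events a data frame with a logical `success` column (or a
#'   `phys_evoked` result).
#' @return `100 * n_success / n_total`.
#' @export
success_rate <- function(events) {
  if (inherits(events, "phys_evoked")) events <- events$events
  if (NROW(events) == 0L) stop("no event records")
  100 * sum(events$success) / nrow(events)
}

#' Per-cell PSC kinetics
#'
#' Aggregates per-sweep rise times and latencies over successes: the cell
#' latency is the mean, jitter the standard deviation of latencies, rise the
#' mean 20-80% rise time.
#'
#' @param events event table (or `phys_evoked`).
#' @return list with `mean_latency`, `jitter`, `mean_rise` (ms).
#' @export
psc_kinetics <- function(events) {
  if (inherits(events, "phys_evoked")) events <- events$events
  ok <- events$success & !is.na(events$latency)
  lat <- events$latency[ok]
  list(mean_latency = if (length(lat)) mean(lat) else NA_real_,
       jitter = if (length(lat) > 1L) stats::sd(lat) else if (length(lat) == 1L) 0 else NA_real_,
       mean_rise = if (any(ok)) mean(events$rise_20_80[ok], na.rm = TRUE) else NA_real_)
}

# mean trace + cell summary
summarise_psc_events <- function(ev, sweeps, ref, search_ms, polarity) {
  sgn <- .pol_sign(polarity)
  fs <- sweeps[[1]]$sampling_rate
  n <- min(vapply(sweeps, function(s) length(s$samples), integer(1)))
  mean_trace <- Reduce(`+`, lapply(sweeps, function(s) s$samples[seq_len(n)])) / length(sweeps)
  if (any(ev$success)) {
    mean_amp <- mean(ev$amplitude[ev$success])
  } else {
    idx <- .window_idx(ref, ref + search_ms / 1000, fs, n, sweeps[[1]]$t0)
    blm <- mean(ev$baseline_mean)
    mean_amp <- mean_trace[idx[which.max(sgn * (mean_trace[idx] - blm))]] - blm
  }
  kin <- psc_kinetics(ev)
  # decay tau from the cell's mean success trace (aligned by maximal rise)
  tau <- NA_real_
  if (sum(ev$success) >= 1L) {
    segs <- lapply(which(ev$success), function(i) {
      k <- .t2i(ev$peak_time[i], fs, n, sweeps[[i]]$t0)
      a <- max(1L, k - round(0.005 * fs)); b <- min(n, k + round(0.05 * fs))
      sweeps[[i]]$samples[a:b] - ev$baseline_mean[i]
    })
    m <- align_average(segs, mode = "max_rise")
    pk <- if (sgn < 0) which.min(m) else which.max(m)
    if (pk < length(m) - 4L)
      tau <- tryCatch(fit_decay(m[pk:length(m)], fs,
                                model = if (polarity == "negative") "single" else "double_weighted")$tau,
                      error = function(e) NA_real_)
  }
  list(mean_amplitude = mean_amp, success_rate = 100 * mean(ev$success),
       mean_latency = kin$mean_latency, jitter = kin$jitter,
       mean_rise = kin$mean_rise, tau_decay = tau, n_sweeps = nrow(ev),
       mean_trace = mean_trace)
}

#' Inhibition/excitation balance
#'
#' Ratio of IPSC to EPSC amplitude magnitude recorded in the same neuron.
#'
#' @param ipsc_amplitude,epsc_amplitude cell mean amplitudes (pA; signs ignored).
#' @return dimensionless ratio \eqn{|IPSC|/|EPSC|}.
#' @export
ie_balance <- function(ipsc_amplitude, epsc_amplitude) {
  if (epsc_amplitude == 0) stop("EPSC amplitude is zero")
  abs(ipsc_amplitude) / abs(epsc_amplitude)
}

#' Fit the decay of a mean PSC trace
#'
#' Single-exponential \eqn{f(t) = A e^{-t/\tau}} for EPSC decay; weighted
#' double exponential \eqn{f(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}} with
#' \eqn{\tau_w = (\tau_1 A_1 + \tau_2 A_2)/(A_1 + A_2)} for IPSC decay. The
#' fit runs on the mean trace from its peak onward; amplitudes are
#' constrained non-negative (on the magnitude scale) in the double fit.
#'
#' @param y numeric segment starting at the peak (baseline-subtracted; either
#'   sign).
#' @param fs sampling rate Hz.
#' @param model `"single"` or `"double_weighted"`.
#' @return list with `tau` (ms; the weighted tau for the double model),
#'   `pars`, `model`.
#' @export
fit_decay <- function(y, fs = 10000, model = c("single", "double_weighted")) {
  model <- match.arg(model)
  y <- as.numeric(y)
  if (length(y) < 5L) stop("decay segment too short to fit")
  sgn <- if (abs(min(y)) > abs(max(y))) -1 else 1
  z <- sgn * y                       # positive-going decay
  t <- (seq_along(z) - 1L) / fs * 1000   # ms
  pos <- z > max(z) * 1e-3
  init_tau <- {
    fitl <- stats::lm(log(z[pos]) ~ t[pos])
    max(as.numeric(-1 / stats::coef(fitl)[2]), t[2])
  }
  sse_single <- function(p) sum((z - p[1] * exp(-t / p[2]))^2)
  ctl <- list(maxit = 1000, factr = 1e7)
  o1 <- stats::optim(c(max(z), init_tau), sse_single, method = "L-BFGS-B",
                     lower = c(1e-9, t[2] / 10), upper = c(Inf, t[length(t)] * 100),
                     control = ctl)
  if (model == "single") {
    # L-BFGS-B can stop on a line-search warning at an already-converged
    # optimum; accept any fit that explains the decay variance
    if (o1$convergence != 0 && o1$value > 1e-6 * sum(z^2))
      stop("single-exponential fit did not converge")
    return(list(tau = o1$par[2], pars = c(A = sgn * o1$par[1], tau = o1$par[2]),
                model = model))
  }
  sse_double <- function(p) sum((z - p[1] * exp(-t / p[2]) - p[3] * exp(-t / p[4]))^2)
  o2 <- stats::optim(c(0.8 * o1$par[1], o1$par[2], 0.2 * o1$par[1], 10 * o1$par[2]),
                     sse_double, method = "L-BFGS-B",
                     lower = c(0, t[2] / 10, 0, t[2] / 10),
                     upper = rep(c(Inf, t[length(t)] * 100), 2), control = ctl)
  if (o2$convergence != 0 && o2$value > 1e-6 * sum(z^2))
    stop("double-exponential fit did not converge")
  p <- o2$par
  tau_w <- weighted_tau(p[1], p[2], p[3], p[4])
  list(tau = tau_w,
       pars = c(A1 = sgn * p[1], tau1 = p[2], A2 = sgn * p[3], tau2 = p[4]),
       model = model)
}

#' Weighted decay time constant
#'
#' \eqn{\tau_w = (\tau_1 A_1 + \tau_2 A_2)/(A_1 + A_2)}.
#'
#' @param a1,tau1,a2,tau2 double-exponential parameters.
#' @return weighted tau in the units of `tau1`/`tau2`.
#' @export
weighted_tau <- function(a1, tau1, a2, tau2) {
  if (a1 + a2 == 0) stop("zero total amplitude")
  (tau1 * a1 + tau2 * a2) / (a1 + a2)
}

#' Detect a unitary EPSC in a paired recording
#'
#' A uEPSC is a negative current deflection exceeding `mad_mult` (default 6)
#' times the raw baseline MAD that occurs within `window_ms` (default 3) of
#' the presynaptic action-potential peak.
#'
#' @param sweep postsynaptic voltage-clamp current `phys_sweep`.
#' @param ap_peak_time presynaptic AP peak time (s).
#' @param mad_mult threshold multiplier (default 6).
#' @param window_ms attribution window after the AP peak (default 3).
#' @param baseline_s baseline length before the AP peak (default 0.1 s,
#'   ending 5 ms before the peak to avoid the coupling artifact).
#' @param smooth Savitzky-Golay pre-filtering.
#' @return one-row data frame: `success`, `amplitude`, `peak_time`,
#'   `latency` (ms from AP peak to 20% rise), `rise_20_80`.
#' @export
detect_paired_uepsc <- function(sweep, ap_peak_time, mad_mult = 6, window_ms = 3,
                                baseline_s = 0.1, smooth = TRUE) {
  stopifnot(inherits(sweep, "phys_sweep"))
  fs <- sweep$sampling_rate; n <- length(sweep$samples)
  if (ap_peak_time < sweep$t0 || ap_peak_time > sweep$t0 + n / fs)
    stop("AP peak time outside the sweep")
  raw <- blank_artifacts(sweep)
  sw <- if (smooth) savgol_smooth(raw) else raw
  # noise floor from the unfiltered baseline (see detect_evoked_psc)
  bl <- baseline_stats(raw, c(ap_peak_time - baseline_s - 0.005, ap_peak_time - 0.005))
  idx <- .window_idx(ap_peak_time, ap_peak_time + window_ms / 1000, fs, n, sw$t0)
  k <- idx[which.min(sw$samples[idx])]
  defl <- bl$mean - sw$samples[k]
  if (defl > mad_mult * bl$mad) {   # strict: MAD 0 + zero deflection is a failure
    rl <- .rise_latency(sw$samples, fs, sw$t0, k, bl$mean, ap_peak_time)
    data.frame(success = TRUE, amplitude = sw$samples[k] - bl$mean,
               peak_time = .i2t(k, fs, sw$t0), latency = rl[2], rise_20_80 = rl[1])
  } else {
    data.frame(success = FALSE, amplitude = NA_real_, peak_time = NA_real_,
               latency = NA_real_, rise_20_80 = NA_real_)
  }
}
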