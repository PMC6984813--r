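# Intrinsic membrane properties from the two 600 ms square current-step
# series (-100..+100 pA at 10 pA; -200..+400 pA at 25 pA). Passive measures
# (membrane resistance, decay tau, sag, rebound) come from the fine series
# and the -200/-100 pA steps; train measures (max firing rate, latency,
# adaptation ratios, delta-AHP) come from the coarse series at rheobase and
# rheobase + 50 pA.

.step_window <- function(prot) c(prot$step_onset, prot$step_onset + prot$step_duration)

# AP tables for every sweep of a current-step set (step window only unless
# `full = TRUE`)
.step_aps <- function(ss, full = FALSE) {
  win <- .step_window(ss$protocol)
  lapply(ss$sweeps, function(sw)
    detect_aps(sw, window = if (full) NULL else win,
               ahp_limit_t = if (full) NULL else win[2]))
}

#' Rheobase of a current-step series
#'
#' Lowest injected current eliciting at least one AP during the step.
#'
#' @param ss a `current_steps_cc` `phys_sweepset`.
#' @return list: `current` (pA), `sweep` (index); errors when no sweep spikes.
#' @export
rheobase <- function(ss) {
  stopifnot(inherits(ss, "phys_sweepset"), ss$protocol$protocol_kind == "current_steps_cc")
  counts <- vapply(.step_aps(ss), nrow, integer(1))
  cur <- ss$protocol$step_currents
  idx <- which(counts > 0L & cur > 0)
  if (length(idx) == 0L) stop("no suprathreshold sweep: rheobase undefined")
  i <- idx[which.min(cur[idx])]
  list(current = cur[i], sweep = i)
}

#' Passive membrane properties
#'
#' Membrane resistance is the slope of the best-fit line of the I-V plot
#' over all sub-rheobase steps of the fine (10 pA) series, where the voltage
#' response to each step is mean(V) over 50-150 ms after step onset minus
#' mean(V) over the 100 ms before onset. Membrane decay tau is a single-
#' exponential fit to the -100 pA response onset. Sag,
#' \eqn{(V_{min}-V_{ss})/(V_{min}-V_{bl}) \times 100\%}, and rebound spikes
#' (APs within 500 ms after step offset) are measured on the -200 pA step of
#' the coarse series.
#'
#' @param fine fine-series sweep set (-100..+100 pA, 10 pA).
#' @param coarse coarse-series sweep set (-200..+400 pA, 25 pA).
#' @return list: `membrane_resistance` (MOhm), `membrane_decay_tau` (ms),
#'   `sag` (%), `rebound_spikes` (count), `iv` (the I-V table).
#' @export
passive_features <- function(fine, coarse) {
  prot <- fine$protocol
  fs <- fine$sweeps[[1]]$sampling_rate
  on <- prot$step_onset; off <- on + prot$step_duration
  rheo_cur <- tryCatch(rheobase(fine)$current, error = function(e) Inf)
  sub <- which(prot$step_currents < rheo_cur)   # all steps below rheobase
  dv <- vapply(sub, function(i) {
    sw <- fine$sweeps[[i]]
    v <- sw$samples
    resp <- mean(v[.window_idx(on + 0.05, on + 0.15, fs, length(v), sw$t0)])
    bl <- mean(v[.window_idx(on - 0.1, on, fs, length(v), sw$t0)])
    resp - bl
  }, numeric(1))
  if (length(sub) < 2L) stop("no sub-rheobase steps for the I-V fit")
  rm_mohm <- unname(stats::coef(stats::lm(dv ~ prot$step_currents[sub]))[2]) * 1000
  # decay tau from the -100 pA fine step
  i100 <- which(prot$step_currents == -100)
  tau <- NA_real_
  if (length(i100) == 1L) {
    sw <- fine$sweeps[[i100]]; v <- sw$samples
    seg <- v[.window_idx(on, on + 0.3, fs, length(v), sw$t0)]
    vss <- mean(v[.window_idx(off - 0.2, off, fs, length(v), sw$t0)])
    tau <- tryCatch(fit_decay(seg - vss, fs, "single")$tau, error = function(e) NA_real_)
  }
  # sag and rebound from the -200 pA coarse step
  sag <- NA_real_; reb <- NA_integer_
  i200 <- which(coarse$protocol$step_currents == -200)
  if (length(i200) == 1L) {
    cp <- coarse$protocol; con <- cp$step_onset; coff <- con + cp$step_duration
    sw <- coarse$sweeps[[i200]]; v <- sw$samples
    cfs <- sw$sampling_rate
    vmin <- min(v[.window_idx(con, coff, cfs, length(v), sw$t0)])
    vss <- mean(v[.window_idx(coff - 0.2, coff, cfs, length(v), sw$t0)])
    vbl <- mean(v[.window_idx(con - 0.1, con, cfs, length(v), sw$t0)])
    sag <- compute_sag(vmin, vss, vbl)
    reb <- nrow(detect_aps(sw, window = c(coff, coff + 0.5)))
  }
  list(membrane_resistance = rm_mohm, membrane_decay_tau = tau, sag = sag,
       rebound_spikes = reb,
       iv = data.frame(current = prot$step_currents[sub], delta_v = dv))
}

#' Hyperpolarization-induced sag
#'
#' \eqn{(V_{min}-V_{ss})/(V_{min}-V_{bl}) \times 100}.
#'
#' @param v_min most hyperpolarized voltage during the step (mV).
#' @param v_ss mean steady-state voltage, last 200 ms of the step (mV).
#' @param v_bl mean baseline voltage, 100 ms pre-step (mV).
#' @return sag in percent.
#' @export
compute_sag <- function(v_min, v_ss, v_bl) {
  if (v_min == v_bl) stop("no hyperpolarizing deflection: sag undefined")
  (v_min - v_ss) / (v_min - v_bl) * 100
}

#' Firing-train properties from the coarse step series
#'
#' Max firing rate is the inverse of the (by default minimum) inter-spike
#' interval during the first 200 ms of the most depolarizing step before AP
#' firing attenuates; attenuation is the first step whose AP count drops
#' below the previous step's or where any AP amplitude falls below 40 mV.
#' Latency to the first AP is measured at rheobase; firing-rate adaptation
#' (first ISI over the mean of the last two), AP broadening (second over
#' first halfwidth), AP amplitude adaptation (mean of the last three
#' amplitudes over the first) and delta-AHP (last minus first AHP magnitude)
#' are measured at rheobase + 50 pA.
#'
#' @param coarse coarse-series sweep set.
#' @param isi_mode `"min"` (default) or `"mean"` ISI for the max firing rate.
#' @param atten_amp_mv amplitude floor defining attenuation (default 40).
#' @return list of the six train properties plus `max_rate_step` (pA) and
#'   `rheobase` (pA).
#' @export
train_features <- function(coarse, isi_mode = c("min", "mean"), atten_amp_mv = 40) {
  isi_mode <- match.arg(isi_mode)
  stopifnot(coarse$protocol$protocol_kind == "current_steps_cc")
  prot <- coarse$protocol
  on <- prot$step_onset
  aps <- .step_aps(coarse)
  counts <- vapply(aps, nrow, integer(1))
  cur <- prot$step_currents
  dep <- which(cur > 0)
  rh <- rheobase(coarse)
  # most depolarizing step before AP firing attenuates
  suprathr <- dep[order(cur[dep])]
  suprathr <- suprathr[cur[suprathr] >= rh$current]
  best <- rh$sweep
  for (i in suprathr) {
    attenuated <- counts[i] < counts[best] || any(aps[[i]]$amplitude < atten_amp_mv)
    if (attenuated) break
    best <- i
  }
  ap_best <- aps[[best]]
  first200 <- ap_best$peak_t <= on + 0.2
  pk <- ap_best$peak_t[first200]
  max_fr <- if (length(pk) >= 2L) {
    isi <- diff(pk)
    1 / switch(isi_mode, min = min(isi), mean = mean(isi))
  } else NA_real_
  lat <- (aps[[rh$sweep]]$peak_t[1L] - on) * 1000
  # adaptation measures at rheobase + 50 pA
  i50 <- which(cur == rh$current + 50)
  fr_ad <- br <- amp_ad <- dahp <- NA_real_
  if (length(i50) == 1L) {
    a <- aps[[i50]]
    nap <- nrow(a)
    if (nap >= 3L) {
      isi <- diff(a$peak_t)
      fr_ad <- isi[1L] / mean(utils::tail(isi, 2L))
    }
    if (nap >= 2L) {
      br <- a$halfwidth[2L] / a$halfwidth[1L]
      dahp <- a$ahp_magnitude[nap] - a$ahp_magnitude[1L]
    }
    if (nap >= 4L) amp_ad <- mean(utils::tail(a$amplitude, 3L)) / a$amplitude[1L]
  }
  list(max_firing_rate = max_fr, latency_first_ap = lat, fr_adaptation = fr_ad,
       delta_ahp = dahp, ap_broadening = br, ap_amplitude_adaptation = amp_ad,
       max_rate_step = cur[best], rheobase = rh$current)
}

#' The 15-property membrane feature vector of one neuron
#'
#' Runs [passive_features()], [train_features()] and the rheobase AP
#' measurements and assembles the named 15-element vector used by the
#' clustering and classification stages. Missing inputs yield `NA` entries
#' (never silently imputed).
#'
#' @param fine,coarse the two current-step sweep sets.
#' @param isi_mode passed to [train_features()].
#' @return named numeric vector of length 15 with attribute `provenance`
#'   (rheobase current and sweep indices used).
#' @export
assemble_feature_vector <- function(fine, coarse, isi_mode = "min") {
  pf <- passive_features(fine, coarse)
  tf <- train_features(coarse, isi_mode = isi_mode)
  rh <- rheobase(coarse)
  win <- .step_window(coarse$protocol)
  ap <- detect_aps(coarse$sweeps[[rh$sweep]], window = win, ahp_limit_t = win[2])
  ap1 <- if (nrow(ap)) ap[1L, ] else NULL
  out <- c(
    membrane_resistance = pf$membrane_resistance,
    membrane_decay_tau = pf$membrane_decay_tau,
    sag = pf$sag,
    rebound_spikes = as.numeric(pf$rebound_spikes),
    max_firing_rate = tf$max_firing_rate,
    ap_threshold = if (is.null(ap1)) NA_real_ else mean(ap$threshold_v),
    ap_amplitude = if (is.null(ap1)) NA_real_ else mean(ap$amplitude),
    ap_halfwidth = if (is.null(ap1)) NA_real_ else mean(ap$halfwidth, na.rm = TRUE),
    ahp_magnitude = if (is.null(ap1)) NA_real_ else mean(ap$ahp_magnitude, na.rm = TRUE),
    ahp_latency = if (is.null(ap1)) NA_real_ else mean(ap$ahp_latency, na.rm = TRUE),
    delta_ahp = tf$delta_ahp,
    latency_first_ap = tf$latency_first_ap,
    fr_adaptation = tf$fr_adaptation,
    ap_broadening = tf$ap_broadening,
    ap_amplitude_adaptation = tf$ap_amplitude_adaptation)
  attr(out, "provenance") <- list(rheobase_pa = rh$current, rheobase_sweep = rh$sweep,
                                  max_rate_step_pa = tf$max_rate_step)
  out
}

#' Names of the 15 membrane properties, in canonical column order
#' @return character vector of length 15.
#' @export
membrane_property_names <- function() {
  c("membrane_resistance", "membrane_decay_tau", "sag", "rebound_spikes",
    "max_firing_rate", "ap_threshold", "ap_amplitude", "ap_halfwidth",
    "ahp_magnitude", "ahp_latency", "delta_ahp", "latency_first_ap",
    "fr_adaptation", "ap_broadening", "ap_amplitude_adaptation")
}

#' Stimulus-train response measures (current clamp, 5 stimuli at 20 Hz)
#'
#' Counts APs within 50 ms of each stimulus, measures the resting potential
#' over the 500 ms pre-stimulus baseline, and the subthreshold EPSP
#' amplitude as the maximal non-artifact voltage deflection within 40 ms of
#' each stimulus (stimuli whose window contains an AP are excluded from the
#' EPSP pool).
#'
#' @param ss an `evoked_cc` sweep set.
#' @param artifact_ms artifact width after each stimulus (default 2).
#' @return list: `aps_per_stimulus` (mean count), `v_rest` (mV),
#'   `epsp_amplitudes` (mV per stimulus, averaged across sweeps),
#'   `mean_epsp` (mV).
#' @export
stimulus_response_features <- function(ss, artifact_ms = 2) {
  stopifnot(inherits(ss, "phys_sweepset"))
  counts <- c(); epsp <- list()
  vrest <- numeric(0)
  for (sw in ss$sweeps) {
    stims <- sw$stimulus_times
    if (length(stims) == 0L) stop("stimulus metadata missing")
    fs <- sw$sampling_rate; v <- sw$samples
    vrest <- c(vrest, mean(v[.window_idx(stims[1] - 0.5, stims[1], fs, length(v), sw$t0)]))
    aps <- detect_aps(sw)
    amps <- rep(NA_real_, length(stims))
    for (k in seq_along(stims)) {
      s <- stims[k]
      n_ap <- sum(aps$peak_t >= s & aps$peak_t < s + 0.05)
      counts <- c(counts, n_ap)
      if (n_ap == 0L) {
        bl <- mean(v[.window_idx(s - 0.01, s, fs, length(v), sw$t0)])
        idx <- .window_idx(s + artifact_ms / 1000, s + 0.04, fs, length(v), sw$t0)
        amps[k] <- max(v[idx]) - bl
      }
    }
    epsp[[length(epsp) + 1L]] <- amps
  }
  em <- colMeans(do.call(rbind, epsp))
  list(aps_per_stimulus = mean(counts), v_rest = mean(vrest),
       epsp_amplitudes = em, mean_epsp = mean(em, na.rm = TRUE))
}

#' Membrane-potential drug timecourse
#'
#' Bins the membrane potential into 30 s bins and computes the change in
#' potential as mean(last 3 min of drug application) minus mean(3 min
#' baseline before drug onset).
#'
#' @param sweep a voltage `phys_sweep` (or numeric vector at `fs` Hz)
#'   spanning baseline and drug application.
#' @param drug_onset onset time in seconds.
#' @param fs sampling rate when `sweep` is a bare vector (default 10000).
#' @param bin_s bin width in seconds (default 30).
#' @return list: `binned_vm` (data frame `t`, `vm`), `delta_vm` (mV).
#' @export
drug_timecourse <- function(sweep, drug_onset, fs = 10000, bin_s = 30) {
  v <- if (inherits(sweep, "phys_sweep")) sweep$samples else as.numeric(sweep)
  if (inherits(sweep, "phys_sweep")) fs <- sweep$sampling_rate
  t0 <- if (inherits(sweep, "phys_sweep")) sweep$t0 else 0
  dur <- length(v) / fs
  if (drug_onset - t0 < 180) stop("need at least 3 min of baseline before drug onset")
  if (t0 + dur - drug_onset < 600) stop("need at least 10 min after drug onset")
  bins <- floor((.i2t(seq_along(v), fs, t0) - t0) / bin_s)
  bv <- tapply(v, bins, mean)
  binned <- data.frame(t = as.numeric(names(bv)) * bin_s + t0, vm = as.numeric(bv))
  bl <- mean(v[.window_idx(drug_onset - 180, drug_onset, fs, length(v), t0)])
  last3 <- mean(v[.window_idx(t0 + dur - 180, t0 + dur, fs, length(v), t0)])
  list(binned_vm = binned, delta_vm = last3 - bl)
}
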