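# Synthetic patch-clamp data with known ground truth. Voltage dynamics are
# phenomenological -- a leaky integrator with a slow sag relaxation on
# strong hyperpolarizing steps, rebound spikes after the -200 pA step, and
# parametric AP waveforms (cosine upstroke/downstroke plus an alpha-
# function AHP) inserted at spike times whose ISIs realize the specified
# maximum firing rate and adaptation ratios. The acceptance surface is
# feature recovery through the analysis pipeline, not biophysics.

#' Specification of a simulated neuron
#'
#' Class defaults contrast a fast-spiking (FS) phenotype (high maximum
#' firing rate, little sag, narrow APs) with a non-fast-spiking (nFS) one
#' (the converse, plus rebound spikes and stronger adaptation). The numbers
#' are non-canonical: they encode the qualitative contrasts, not published
#' population means.
#'
#' @param class_label `"FS"` or `"nFS"`.
#' @param r_m membrane resistance, MOhm.
#' @param tau_m membrane time constant, ms.
#' @param v_rest resting/holding potential, mV (steps start near -60 mV).
#' @param rheobase pA (on the 25 pA grid).
#' @param max_rate maximal firing rate, Hz.
#' @param sag_fraction sag, % (realized at the -200 pA step).
#' @param rebound_count rebound APs after the -200 pA step.
#' @param ap_shape named list/vector: `threshold` mV, `amplitude` mV,
#'   `halfwidth` ms, `ahp` mV (negative), `ahp_latency` ms.
#' @param adaptation named list/vector: `fr` (first ISI / mean last two),
#'   `broadening` (2nd/1st halfwidth), `amp` (mean last 3 / first
#'   amplitude), `dahp` mV (last minus first AHP).
#' @param latency_first_ap ms, first AP at rheobase.
#' @return list of class `sim_neuron_spec`.
#' @export
sim_neuron_spec <- function(class_label = c("FS", "nFS"), r_m = NULL, tau_m = NULL,
                            v_rest = -60, rheobase = NULL, max_rate = NULL,
                            sag_fraction = NULL, rebound_count = NULL,
                            ap_shape = NULL, adaptation = NULL,
                            latency_first_ap = NULL) {
  class_label <- match.arg(class_label)
  fs <- class_label == "FS"
  spec <- list(
    class_label = class_label,
    r_m = r_m %||% if (fs) 150 else 250,
    tau_m = tau_m %||% if (fs) 10 else 20,
    v_rest = v_rest,
    rheobase = rheobase %||% if (fs) 150 else 100,
    max_rate = max_rate %||% if (fs) 150 else 60,
    sag_fraction = sag_fraction %||% if (fs) 4 else 22,
    rebound_count = rebound_count %||% if (fs) 0L else 2L,
    ap_shape = as.list(ap_shape %||%
      if (fs) list(threshold = -40, amplitude = 65, halfwidth = 0.6, ahp = -18, ahp_latency = 4)
      else list(threshold = -42, amplitude = 72, halfwidth = 1.1, ahp = -11, ahp_latency = 11)),
    adaptation = as.list(adaptation %||%
      if (fs) list(fr = 0.95, broadening = 1.05, amp = 0.95, dahp = -1.5)
      else list(fr = 0.55, broadening = 1.30, amp = 0.80, dahp = -4)),
    latency_first_ap = latency_first_ap %||% if (fs) 40 else 110)
  if (spec$ap_shape$halfwidth < 0.2)
    stop("AP halfwidth below 2 sample periods at 10 kHz is not representable")
  structure(spec, class = "sim_neuron_spec")
}

# parametric AP: overwrite `v` (mV, vector at fs Hz) with one spike whose
# 20 V/s crossing lands at `thr`; returns the modified trace
.insert_ap <- function(v, fs, onset_idx, thr, amp, hw_ms, ahp, ahp_lat_ms,
                       base_level = NULL) {
  n <- length(v)
  dt <- 1000 / fs                               # ms per sample
  t_ramp <- 1.2                                 # slow foot below threshold
  t_up <- 0.7 * hw_ms; t_down <- 1.3 * hw_ms    # halfwidth = (t_up+t_down)/2
  base <- v[onset_idx]                          # ramp start: continuity
  if (is.null(base_level)) base_level <- base   # AHP recovery target
  # one continuous time grid: piecewise sampling avoids phase/truncation
  # distortion of narrow spikes
  spike_end <- t_ramp + t_up + t_down
  tot <- spike_end + min(6 * ahp_lat_ms, 80)
  t <- seq(0, tot, by = dt)
  wave <- numeric(length(t))
  s1 <- t < t_ramp
  wave[s1] <- base + (thr - base) * t[s1] / t_ramp
  s2 <- !s1 & t < t_ramp + t_up
  wave[s2] <- thr + amp * (1 - cos(pi * (t[s2] - t_ramp) / t_up)) / 2
  s3 <- !s1 & !s2 & t < spike_end
  wave[s3] <- thr + amp * (1 + cos(pi * (t[s3] - t_ramp - t_up) / t_down)) / 2
  s4 <- t >= spike_end
  ta <- t[s4] - spike_end
  wave[s4] <- thr + ahp * (ta / ahp_lat_ms) * exp(1 - ta / ahp_lat_ms) +
    (base_level - thr) * (1 - exp(-ta / (3 * ahp_lat_ms)))
  a <- onset_idx; b <- min(n, a + length(wave) - 1L)
  v[a:b] <- wave[seq_len(b - a + 1L)]
  v
}

# subthreshold step response with optional sag relaxation; the transient
# amplitude is calibrated numerically so the *measured* sag (min vs mean of
# the last 200 ms vs baseline) equals the requested fraction, because the
# charging and sag exponentials overlap in time
.step_voltage <- function(tt, on, off, dv_ss, tau_m_s, sag_frac, tau_sag_s) {
  v <- numeric(length(tt))
  during <- tt >= on & tt < off
  td <- tt[during] - on
  if (sag_frac > 0) {
    curve <- function(a) a * (1 - exp(-td / tau_m_s)) +
      (dv_ss - a) * (1 - exp(-td / tau_sag_s))
    realized <- function(a) {
      w <- curve(a)
      vmin <- min(w); vss <- mean(w[td >= (off - on) - 0.2])
      (vmin - vss) / vmin * 100 - sag_frac
    }
    lo <- dv_ss / (1 - sag_frac / 100)
    hi <- dv_ss * 6
    dv_min <- tryCatch(stats::uniroot(realized, c(lo, hi))$root,
                       error = function(e) lo)
    v[during] <- curve(dv_min)
  } else {
    v[during] <- dv_ss * (1 - exp(-td / tau_m_s))
  }
  after <- tt >= off
  v_off <- if (any(during)) v[which(during)[sum(during)]] else 0
  v[after] <- v_off * exp(-(tt[after] - off) / tau_m_s)
  v
}

#' Simulate one current-step series
#'
#' Generates the voltage responses of a [sim_neuron_spec()] neuron to one of
#' the two canonical 600 ms square-step series at 10 kHz, with Gaussian
#' voltage noise. Sag is applied to steps at or below `sag_threshold_pa`
#' (default -150 pA: strong hyperpolarization only, so the fine-series I-V
#' window stays ohmic); rebound spikes follow the -200 pA step; spike trains
#' on suprathreshold steps realize the specified maximum rate at the last
#' step before attenuation and the adaptation ratios at rheobase + 50 pA.
#'
#' @param spec a `sim_neuron_spec`.
#' @param protocol a `phys_protocol` from [step_series()].
#' @param seed RNG seed.
#' @param noise_sd voltage noise SD, mV (default 0.15).
#' @param fs sampling rate, Hz.
#' @param sag_threshold_pa steps at/below this get sag (default -150).
#' @param tau_sag_ms sag relaxation time constant (default 100).
#' @return `phys_sweepset` with attributes `truth` (the ground-truth
#'   15-property vector) and `spec`.
#' @export
sim_step_protocol <- function(spec, protocol = step_series("coarse"), seed = NULL,
                              noise_sd = 0.15, fs = 10000, sag_threshold_pa = -150,
                              tau_sag_ms = 100) {
  stopifnot(inherits(spec, "sim_neuron_spec"))
  with_seed(seed, {
    on <- protocol$step_onset; off <- on + protocol$step_duration
    n <- round((off + 0.3) * fs)
    tt <- (seq_len(n) - 1L) / fs
    shp <- spec$ap_shape; adp <- spec$adaptation
    coarse_step <- 25
    i_best <- .best_step_current(spec, protocol)
    sweeps <- lapply(protocol$step_currents, function(I) {
      dv_ss <- I * spec$r_m / 1000
      sagf <- if (I <= sag_threshold_pa) spec$sag_fraction else 0
      v <- spec$v_rest + .step_voltage(tt, on, off, dv_ss, spec$tau_m / 1000,
                                       sagf, tau_sag_ms / 1000)
      spike_t <- numeric(0)
      if (I >= spec$rheobase && I > 0) {
        rate <- .sim_rate(spec, I, i_best)
        if (rate > 0) {
          lat <- if (I == spec$rheobase) spec$latency_first_ap / 1000 else 0.010
          if (I == spec$rheobase + 50) {
            # first ISI shorter by the adaptation ratio, later ISIs at the
            # step's nominal rate, so the count keeps rising across steps
            isi_late <- 1 / rate
            isi1 <- adp$fr * isi_late
            st <- on + lat
            repeat {
              nxt <- st[length(st)] + if (length(st) == 1L) isi1 else isi_late
              if (nxt >= off - 0.002) break
              st <- c(st, nxt)
            }
            spike_t <- st
          } else {
            spike_t <- seq(on + lat, off - 0.002, by = 1 / rate)
          }
          # keep the voltage below threshold between spikes
          during <- tt >= on & tt < off
          v[during] <- pmin(v[during], shp$threshold - 2)
          k <- length(spike_t)
          hw <- rep(shp$halfwidth, k); am <- rep(shp$amplitude, k)
          ah <- rep(shp$ahp, k)
          attenuated <- I > i_best
          if (attenuated) am <- am * 0.45
          if (I == spec$rheobase + 50 && k >= 2L) {
            hw[2:k] <- shp$halfwidth * adp$broadening
            am[2:k] <- shp$amplitude * adp$amp
            ah <- shp$ahp + (seq_len(k) - 1L) / (k - 1L) * adp$dahp
          }
          for (s in seq_len(k)) {
            oi <- round(spike_t[s] * fs) + 1L
            v <- .insert_ap(v, fs, oi, shp$threshold, am[s], hw[s], ah[s],
                            shp$ahp_latency, base_level = shp$threshold - 2)
          }
        }
      }
      if (I == -200 && spec$rebound_count > 0) {
        for (s in seq_len(spec$rebound_count)) {
          oi <- round((off + 0.03 + (s - 1L) * 0.05) * fs) + 1L
          v <- .insert_ap(v, fs, oi, shp$threshold, shp$amplitude, shp$halfwidth,
                          shp$ahp, shp$ahp_latency)
        }
      }
      v <- v + stats::rnorm(n, 0, noise_sd)
      sweep_trace(v, fs, "voltage", holding = NA_real_)
    })
    ss <- sweep_set(sweeps, protocol = protocol, cell_id = spec$class_label)
    attr(ss, "truth") <- sim_truth_vector(spec)
    attr(ss, "spec") <- spec
    ss
  })
}

# most depolarizing step current before attenuation, for this protocol
.best_step_current <- function(spec, protocol) {
  dep <- protocol$step_currents[protocol$step_currents >= spec$rheobase]
  if (!length(dep)) return(Inf)
  # FS cells sustain to the top of the series; nFS attenuate ~150 pA above
  # rheobase
  if (spec$class_label == "FS") max(dep) else min(spec$rheobase + 150, max(dep))
}

# firing rate at step current I: linear ramp to max_rate at the best step,
# halved (attenuated) above it
.sim_rate <- function(spec, I, i_best) {
  r0 <- max(8, 0.2 * spec$max_rate)
  if (!is.finite(i_best)) return(0)
  if (I <= i_best) {
    if (i_best == spec$rheobase) return(spec$max_rate)
    r0 + (spec$max_rate - r0) * (I - spec$rheobase) / (i_best - spec$rheobase)
  } else spec$max_rate * 0.5
}

#' Ground-truth 15-property vector of a simulated neuron
#'
#' @param spec a `sim_neuron_spec`.
#' @return named numeric vector matching [membrane_property_names()].
#' @export
sim_truth_vector <- function(spec) {
  shp <- spec$ap_shape; adp <- spec$adaptation
  # timing truths are peak-referenced, matching the measurement definitions:
  # spike onsets are planted 1.2 ms (foot) + 0.7*halfwidth (upstroke) before
  # the peak, and the AHP trough follows the downstroke (1.3*halfwidth)
  c(membrane_resistance = spec$r_m, membrane_decay_tau = spec$tau_m,
    sag = spec$sag_fraction, rebound_spikes = as.numeric(spec$rebound_count),
    max_firing_rate = spec$max_rate, ap_threshold = shp$threshold,
    ap_amplitude = shp$amplitude, ap_halfwidth = shp$halfwidth,
    ahp_magnitude = shp$ahp, ahp_latency = shp$ahp_latency + 1.3 * shp$halfwidth,
    delta_ahp = adp$dahp,
    latency_first_ap = spec$latency_first_ap + 1.2 + 0.7 * shp$halfwidth,
    fr_adaptation = adp$fr, ap_broadening = adp$broadening,
    ap_amplitude_adaptation = adp$amp)
}

#' Specification of a simulated evoked (minimal-stimulation) experiment
#'
#' @param success_prob Bernoulli success probability (the minimal-
#'   stimulation tuning target is ~0.5).
#' @param u_amp event amplitude, pA (negative: EPSC at -70 mV).
#' @param latency mean onset latency after the artifact end, ms.
#' @param jitter_sd latency SD, ms.
#' @param rise kernel rise time constant, ms.
#' @param tau_decay kernel decay time constant, ms.
#' @param noise_sd baseline current noise SD, pA.
#' @param n_sweeps number of sweeps.
#' @param stim_time stimulus time, s.
#' @param stimulation_charge nC, carried as metadata.
#' @return list of class `sim_evoked_spec`.
#' @export
sim_evoked_spec <- function(success_prob = 0.5, u_amp = -20, latency = 2,
                            jitter_sd = 0.3, rise = 0.5, tau_decay = 5,
                            noise_sd = 3, n_sweeps = 200L, stim_time = 0.6,
                            stimulation_charge = NA_real_) {
  stopifnot(success_prob >= 0, success_prob <= 1, n_sweeps >= 1)
  structure(list(success_prob = success_prob, u_amp = u_amp, latency = latency,
                 jitter_sd = jitter_sd, rise = rise, tau_decay = tau_decay,
                 noise_sd = noise_sd, n_sweeps = as.integer(n_sweeps),
                 stim_time = stim_time, stimulation_charge = stimulation_charge),
            class = "sim_evoked_spec")
}

# biexponential PSC kernel with peak amplitude `amp`
.psc_kernel <- function(amp, rise_ms, tau_ms, fs, len_ms = NULL) {
  len_ms <- len_ms %||% (rise_ms * 4 + tau_ms * 6)
  t <- seq(0, len_ms, by = 1000 / fs)
  k <- exp(-t / tau_ms) - exp(-t / rise_ms)
  k / max(k) * amp
}

#' Simulate an evoked sweep set (all-or-none minimal stimulation)
#'
#' Each sweep carries Gaussian baseline noise and a stimulus artifact; with
#' probability `success_prob` a fixed-amplitude biexponential EPSC is added,
#' its onset jittered \eqn{N(latency, jitter\_sd^2)} after the artifact end.
#'
#' @param spec a [sim_evoked_spec()].
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @param duration sweep length, s.
#' @param artifact_ms artifact window after the stimulus (default 2).
#' @return `phys_sweepset` (evoked_vc) with attribute `truth`: data frame of
#'   per-sweep success and planted onset latency (ms).
#' @export
sim_evoked <- function(spec, seed = NULL, fs = 10000, duration = 1, artifact_ms = 2) {
  stopifnot(inherits(spec, "sim_evoked_spec"))
  with_seed(seed, {
    n <- round(duration * fs)
    art_end <- spec$stim_time + artifact_ms / 1000
    ker <- .psc_kernel(spec$u_amp, spec$rise, spec$tau_decay, fs)
    if (length(ker) > n) stop("kernel longer than the sweep")
    success <- stats::runif(spec$n_sweeps) < spec$success_prob
    lat <- ifelse(success, stats::rnorm(spec$n_sweeps, spec$latency, spec$jitter_sd), NA)
    sweeps <- lapply(seq_len(spec$n_sweeps), function(i) {
      x <- stats::rnorm(n, 0, spec$noise_sd)
      # biphasic stimulus artifact inside the blanking window
      ai <- round(spec$stim_time * fs) + 1L
      x[ai:(ai + 3L)] <- x[ai:(ai + 3L)] + c(150, -120, 40, -10)
      if (success[i]) {
        oi <- round((art_end + lat[i] / 1000) * fs) + 1L
        idx <- oi:min(n, oi + length(ker) - 1L)
        x[idx] <- x[idx] + ker[seq_along(idx)]
      }
      sweep_trace(x, fs, "current", stimulus_times = spec$stim_time,
                  artifact_windows = list(c(spec$stim_time, art_end)),
                  holding = -70)
    })
    prot <- protocol_metadata("evoked_vc", stim_count = 1L,
                              stimulation_charge = spec$stimulation_charge)
    ss <- sweep_set(sweeps, protocol = prot, cell_id = "sim_evoked")
    attr(ss, "truth") <- data.frame(sweep = seq_len(spec$n_sweeps),
                                    success = success, latency = lat)
    ss
  })
}

#' Specification of a spontaneous EPSC recording
#'
#' @param rate Poisson event rate, Hz.
#' @param amp_median,amp_shape lognormal amplitude magnitude (pA) median and
#'   log-SD.
#' @param rise,tau_decay kernel time constants, ms.
#' @param noise_sd baseline noise SD, pA.
#' @param duration recording length, s (study protocol: 5 min).
#' @return list of class `sim_spont_spec`.
#' @export
sim_spont_spec <- function(rate = 5, amp_median = 20, amp_shape = 0.25,
                           rise = 0.5, tau_decay = 5, noise_sd = 2, duration = 300) {
  stopifnot(rate >= 0, duration >= 1)
  structure(list(rate = rate, amp_median = amp_median, amp_shape = amp_shape,
                 rise = rise, tau_decay = tau_decay, noise_sd = noise_sd,
                 duration = duration),
            class = "sim_spont_spec")
}

#' Simulate a spontaneous EPSC trace
#'
#' Poisson event times, lognormal amplitudes, fixed biexponential kernel,
#' additive Gaussian noise.
#'
#' @param spec a [sim_spont_spec()].
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @return `phys_sweep` with attribute `truth`: data frame `time` (s),
#'   `amplitude` (pA, negative).
#' @export
sim_spontaneous <- function(spec, seed = NULL, fs = 10000) {
  stopifnot(inherits(spec, "sim_spont_spec"))
  with_seed(seed, {
    n <- round(spec$duration * fs)
    x <- stats::rnorm(n, 0, spec$noise_sd)
    k <- stats::rpois(1, spec$rate * spec$duration)
    times <- sort(stats::runif(k, 0.06, spec$duration - 0.06))
    amps <- -stats::rlnorm(k, log(spec$amp_median), spec$amp_shape)
    for (i in seq_len(k)) {
      ker <- .psc_kernel(amps[i], spec$rise, spec$tau_decay, fs)
      oi <- round(times[i] * fs) + 1L
      idx <- oi:min(n, oi + length(ker) - 1L)
      x[idx] <- x[idx] + ker[seq_along(idx)]
    }
    sw <- sweep_trace(x, fs, "current", holding = -70)
    # truth peak time = onset + kernel time-to-peak
    tp <- (seq_along(.psc_kernel(-1, spec$rise, spec$tau_decay, fs)) - 1L)[
      which.min(.psc_kernel(-1, spec$rise, spec$tau_decay, fs))] / fs
    attr(sw, "truth") <- data.frame(time = times + tp, amplitude = amps)
    sw
  })
}

# realistic location/scale used to dress the z-space feature table in
# physical units (cosmetic: clustering re-z-scores)
.feature_units <- function() {
  data.frame(
    row.names = membrane_property_names(),
    mu = c(200, 15, 12, 1, 100, -41, 68, 0.85, -14, 8, -2.5, 75, 0.8, 1.15, 0.9),
    sd = c(60, 5, 6, 1, 30, 2.5, 6, 0.2, 3, 3, 1.5, 30, 0.2, 0.12, 0.08))
}

#' Simulate a two-class 15-property feature table
#'
#' Gaussian features with class-mean differences of `separation_sd` standard
#' deviations concentrated in the salient triple (max firing rate, sag, AP
#' halfwidth) and 1 SD on a minor set, mirroring the study's 60/45 class
#' sizes. Optionally assigns uEPSC response status to a tested subset of
#' each class.
#'
#' @param n_per_class `c(FS, nFS)` row counts (default `c(60, 45)`).
#' @param separation_sd class separation on the salient features, in SDs.
#' @param seed RNG seed.
#' @param minor_features names receiving a 1 SD shift.
#' @param responders,nonresponders `c(FS, nFS)` counts of neurons marked
#'   uEPSC-present / uEPSC-absent (the remainder are untested, `NA`).
#' @return data frame of 15 numeric columns plus attributes `labels`
#'   (factor FS/nFS) and `response_status` (logical or NA).
#' @export
sim_feature_table <- function(n_per_class = c(60L, 45L), separation_sd = 4,
                              seed = NULL,
                              minor_features = c("membrane_decay_tau",
                                                 "rebound_spikes", "ahp_latency"),
                              responders = c(14L, 2L), nonresponders = c(2L, 17L)) {
  if (separation_sd < 0) stop("separation_sd must be >= 0")
  if (any(n_per_class < 2L)) stop("need at least 2 neurons per class")
  with_seed(seed, {
    props <- membrane_property_names()
    n1 <- n_per_class[1]; n2 <- n_per_class[2]
    n <- n1 + n2
    z <- matrix(stats::rnorm(n * 15L), n, 15L, dimnames = list(NULL, props))
    salient <- c("max_firing_rate", "sag", "ap_halfwidth")
    cls2 <- (n1 + 1L):n
    # nFS: lower max rate, more sag, broader APs
    z[cls2, "max_firing_rate"] <- z[cls2, "max_firing_rate"] - separation_sd
    z[cls2, "sag"] <- z[cls2, "sag"] + separation_sd
    z[cls2, "ap_halfwidth"] <- z[cls2, "ap_halfwidth"] + separation_sd
    for (f in setdiff(minor_features, salient)) z[cls2, f] <- z[cls2, f] + 1
    u <- .feature_units()
    tab <- as.data.frame(sweep(sweep(z, 2, u[props, "sd"], `*`), 2, u[props, "mu"], `+`))
    rownames(tab) <- sprintf("cell%03d", seq_len(n))
    labels <- factor(rep(c("FS", "nFS"), c(n1, n2)), levels = c("FS", "nFS"))
    resp <- rep(NA, n)
    pick1 <- sample.int(n1, min(n1, responders[1] + nonresponders[1]))
    resp[pick1[seq_len(responders[1])]] <- TRUE
    resp[pick1[responders[1] + seq_len(nonresponders[1])]] <- FALSE
    pick2 <- n1 + sample.int(n2, min(n2, responders[2] + nonresponders[2]))
    resp[pick2[seq_len(responders[2])]] <- TRUE
    resp[pick2[responders[2] + seq_len(nonresponders[2])]] <- FALSE
    attr(tab, "labels") <- labels
    attr(tab, "response_status") <- resp
    tab
  })
}

#' Simulate a full cohort of neurons (both step series each)
#'
#' Per-neuron specs are drawn around the class defaults with ~8% lognormal
#' parameter variability; rheobase stays on the 25 pA grid.
#'
#' @param n_fs,n_nfs neurons per class.
#' @param seed RNG seed.
#' @param noise_sd voltage noise SD, mV.
#' @return list of per-neuron lists: `spec`, `fine`, `coarse`, `truth`.
#' @export
sim_cohort <- function(n_fs = 20L, n_nfs = 20L, seed = NULL, noise_sd = 0.15) {
  with_seed(seed, {
    specs <- c(lapply(seq_len(n_fs), function(i) .jitter_spec("FS")),
               lapply(seq_len(n_nfs), function(i) .jitter_spec("nFS")))
    lapply(seq_along(specs), function(i) {
      sd_i <- sample.int(1e6, 2L)
      list(spec = specs[[i]],
           fine = sim_step_protocol(specs[[i]], step_series("fine"), seed = sd_i[1],
                                    noise_sd = noise_sd),
           coarse = sim_step_protocol(specs[[i]], step_series("coarse"), seed = sd_i[2],
                                      noise_sd = noise_sd),
           truth = sim_truth_vector(specs[[i]]))
    })
  })
}

.jitter_spec <- function(class_label, cv = 0.08) {
  base <- sim_neuron_spec(class_label)
  j <- function(x) x * stats::rlnorm(1, 0, cv)
  shp <- base$ap_shape
  sim_neuron_spec(class_label,
                  r_m = j(base$r_m), tau_m = j(base$tau_m),
                  rheobase = base$rheobase + sample(c(-25, 0, 25), 1),
                  max_rate = j(base$max_rate),
                  sag_fraction = j(base$sag_fraction),
                  rebound_count = base$rebound_count,
                  ap_shape = list(threshold = shp$threshold + stats::rnorm(1, 0, 1),
                                  amplitude = j(shp$amplitude),
                                  halfwidth = max(0.25, j(shp$halfwidth)),
                                  ahp = -j(-shp$ahp), ahp_latency = j(shp$ahp_latency)),
                  adaptation = base$adaptation,
                  latency_first_ap = j(base$latency_first_ap))
}
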