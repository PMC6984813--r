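# Spontaneous EPSC detection by the combined template-and-threshold method:
# a template is built from a 10% subsample of local negative peaks exceeding
# 5x the raw MAD of a rolling baseline (the 50 ms before each peak),
# truncated from its 20% rise point through the end of its fitted decay time
# constant; every candidate peak is then compared against the template
# scaled to its own peak, via a normalized charge integral, and candidates
# below the cutoff are rejected as non-physiological.

# local negative peaks exceeding mad_mult x rolling MAD of the preceding
# base_ms baseline; returns a data frame (idx, amplitude, baseline)
.sepsc_candidates <- function(x, fs, mad_mult = 5, base_ms = 50, refractory_ms = 2,
                              smooth = TRUE) {
  raw <- x                     # noise floor (rolling MAD) from the raw trace
  if (smooth && length(x) >= 11L) x <- savgol_smooth(x, sampling_rate = fs)
  n <- length(x)
  nb <- round(base_ms / 1000 * fs)
  # local minima (strictly below left neighbour, at most right neighbour)
  mid <- 2:(n - 1L)
  is_min <- x[mid] < x[mid - 1L] & x[mid] <= x[mid + 1L]
  cand <- mid[is_min]
  cand <- cand[cand > nb]
  if (length(cand) == 0L)
    return(data.frame(idx = integer(0), amplitude = numeric(0), baseline = numeric(0)))
  # cheap pre-screen against the rolling mean with a global noise scale,
  # below the final per-candidate threshold so nothing real is lost
  cs <- c(0, cumsum(raw))               # cs[i+1] = sum(raw[1:i])
  roll_mean <- (cs[cand] - cs[cand - nb]) / nb
  gmad <- .raw_mad(raw)
  keep <- (roll_mean - x[cand]) > 0.5 * mad_mult * gmad
  cand <- cand[keep]; roll_mean <- roll_mean[keep]
  if (length(cand) == 0L)
    return(data.frame(idx = integer(0), amplitude = numeric(0), baseline = numeric(0)))
  # exact rolling baseline, excluding samples already assigned to an event
  assigned <- logical(n)
  out_idx <- integer(0); out_amp <- numeric(0); out_bl <- numeric(0)
  mask_post <- round(0.01 * fs)          # samples claimed after an accepted peak
  mask_pre <- round(0.002 * fs)
  loc_n <- round(0.002 * fs)
  for (j in seq_along(cand)) {
    i <- cand[j]
    win <- (i - nb):(i - 1L)
    win <- win[!assigned[win]]
    if (length(win) < nb / 5) win <- (i - nb):(i - 1L)
    bl <- mean(raw[win]); md <- .raw_mad(raw[win])
    ok <- (bl - x[i]) > mad_mult * md
    if (ok && assigned[i]) {
      # riding on the decay of an accepted event: must also clear the
      # threshold against the immediately local level, or it is a decay
      # wiggle, not a new event
      bl_loc <- mean(raw[max(1L, i - loc_n):(i - 1L)])
      ok <- (bl_loc - x[i]) > mad_mult * md
    }
    if (ok) {
      out_idx <- c(out_idx, i); out_amp <- c(out_amp, x[i] - bl); out_bl <- c(out_bl, bl)
      assigned[max(1L, i - mask_pre):min(n, i + mask_post)] <- TRUE
    }
  }
  # refractory: collapse peaks closer than refractory_ms, keeping the deeper
  if (length(out_idx) > 1L) {
    ref_n <- round(refractory_ms / 1000 * fs)
    keep <- rep(TRUE, length(out_idx))
    for (j in 2:length(out_idx)) {
      prev <- max(which(keep[1:(j - 1L)]))
      if (out_idx[j] - out_idx[prev] < ref_n) {
        if (out_amp[j] < out_amp[prev]) keep[prev] <- FALSE else keep[j] <- FALSE
      }
    }
    out_idx <- out_idx[keep]; out_amp <- out_amp[keep]; out_bl <- out_bl[keep]
  }
  data.frame(idx = out_idx, amplitude = out_amp, baseline = out_bl)
}

#' Build the spontaneous-EPSC template
#'
#' Averages a 10% subsample of threshold-crossing local negative peaks
#' (aligned on their point of maximal rise), fits a single exponential to
#' the decay, and truncates the mean from its 20% rise point through one
#' decay time constant after the peak.
#'
#' @param sweep a voltage-clamp current `phys_sweep` (or numeric vector).
#' @param mad_mult rolling-baseline threshold multiplier (default 5).
#' @param base_ms rolling baseline width in ms (default 50).
#' @param source_fraction fraction of candidates averaged (default 0.10).
#' @param seed RNG seed for the subsample.
#' @return list of class `phys_template`: `waveform` (baseline-subtracted,
#'   negative peak), `peak_idx`, `tau` (ms), `n_candidates`.
#' @export
build_sepsc_template <- function(sweep, mad_mult = 5, base_ms = 50,
                                 source_fraction = 0.10, seed = NULL) {
  x <- if (inherits(sweep, "phys_sweep")) sweep$samples else as.numeric(sweep)
  fs <- if (inherits(sweep, "phys_sweep")) sweep$sampling_rate else 10000
  cand <- .sepsc_candidates(x, fs, mad_mult, base_ms)
  if (nrow(cand) < 10L)
    stop(sprintf("too few candidate events (%d < 10) to build a template", nrow(cand)))
  xs <- savgol_smooth(x, sampling_rate = fs)   # align/average on filtered data
  n_sub <- max(1L, round(source_fraction * nrow(cand)))
  pick <- with_seed(seed, sort(sample.int(nrow(cand), n_sub)))
  pre <- round(0.005 * fs); post <- round(0.030 * fs)
  segs <- list()
  for (i in cand$idx[pick]) {
    if (i - pre < 1L || i + post > length(x)) next
    seg <- xs[(i - pre):(i + post)]
    segs[[length(segs) + 1L]] <- seg - cand$baseline[match(i, cand$idx)]
  }
  if (length(segs) == 0L) stop("no template candidates with full support")
  # drop segments whose point of maximal rise strays > 2 ms from the pack:
  # one outlier would clip the common support of the aligned mean
  refs <- vapply(segs, function(s) which.min(diff(s)), integer(1))
  keep <- abs(refs - stats::median(refs)) <= round(0.002 * fs)
  if (sum(keep) >= 3L) segs <- segs[keep]
  m <- align_average(segs, mode = "max_rise")
  pk <- which.min(m)
  fit <- fit_decay(m[pk:length(m)], fs, model = "single")
  tau_n <- round(fit$tau / 1000 * fs)
  # 20% rise point before the peak
  amp <- m[pk]
  pre_idx <- seq_len(pk - 1L)
  below <- pre_idx[m[pre_idx] > 0.2 * amp]    # amp negative: above 20% level
  i20 <- if (length(below)) max(below) else 1L
  end <- min(length(m), pk + tau_n)
  wf <- m[i20:end]
  structure(list(waveform = wf, peak_idx = pk - i20 + 1L, tau = fit$tau,
                 n_candidates = nrow(cand), sampling_rate = fs),
            class = "phys_template")
}

#' Detect spontaneous EPSCs
#'
#' Collects all local negative peaks exceeding `mad_mult` times the rolling-
#' baseline MAD, scales the template to each candidate's peak amplitude, and
#' keeps candidates whose charge integral is at least `nci_cutoff` of the
#' scaled template's (rejecting narrow, non-physiological transients).
#'
#' @param sweep a `phys_sweep` or numeric vector.
#' @param template a `phys_template` from [build_sepsc_template()].
#' @param nci_cutoff normalized charge-integral cutoff (default 0.5).
#' @param mad_mult,base_ms as in [build_sepsc_template()].
#' @return data frame: `time` (s), `amplitude` (pA, peak minus rolling
#'   baseline), `nci`.
#' @export
detect_sepsc <- function(sweep, template, nci_cutoff = 0.5, mad_mult = 5, base_ms = 50) {
  if (!inherits(template, "phys_template")) stop("template missing or not a phys_template")
  x <- if (inherits(sweep, "phys_sweep")) sweep$samples else as.numeric(sweep)
  fs <- if (inherits(sweep, "phys_sweep")) sweep$sampling_rate else 10000
  t0 <- if (inherits(sweep, "phys_sweep")) sweep$t0 else 0
  cand <- .sepsc_candidates(x, fs, mad_mult, base_ms)
  if (nrow(cand) == 0L)
    return(data.frame(time = numeric(0), amplitude = numeric(0), nci = numeric(0)))
  xs <- if (length(x) >= 11L) savgol_smooth(x, sampling_rate = fs) else x
  wf <- template$waveform
  tpk <- template$peak_idx
  tpl_charge_unit <- sum(abs(wf)) / abs(min(wf))   # charge per unit peak
  keep <- logical(nrow(cand)); nci <- numeric(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    i <- cand$idx[j]
    a <- i - tpk + 1L; b <- i + (length(wf) - tpk)
    if (a < 1L || b > length(x)) { keep[j] <- FALSE; next }
    seg <- xs[a:b] - cand$baseline[j]
    peak_amp <- cand$amplitude[j]                 # negative
    scaled_charge <- tpl_charge_unit * abs(peak_amp)
    cand_charge <- sum(pmax(-seg, 0))             # negative-going charge only
    nci[j] <- cand_charge / scaled_charge
    keep[j] <- nci[j] >= nci_cutoff
  }
  data.frame(time = .i2t(cand$idx[keep], fs, t0),
             amplitude = cand$amplitude[keep], nci = nci[keep])
}

#' Spontaneous EPSC amplitude and frequency statistics
#'
#' Per-event frequency is the inverse of the inter-event interval; cell
#' statistics are medians.
#'
#' @param events data frame from [detect_sepsc()].
#' @return list with `median_amplitude` (pA), `median_frequency` (Hz; NA
#'   with fewer than two events), `n_events`.
#' @export
sepsc_stats <- function(events) {
  n <- nrow(events)
  freq <- if (n >= 2L) stats::median(1 / diff(sort(events$time))) else NA_real_
  list(median_amplitude = if (n) stats::median(events$amplitude) else NA_real_,
       median_frequency = freq, n_events = n)
}
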