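# Neutral data model for patch-clamp sweeps: a `phys_sweep` is one uniformly
# sampled trace (pA in voltage clamp, mV in current clamp) plus protocol
# annotations; a `phys_sweepset` is an ordered collection sharing sampling
# rate and signal kind. Interchange on disk is a CSV sample matrix (one
# column per sweep) with a JSON metadata sidecar, so nothing downstream
# depends on the acquisition vendor.

#' Construct a single sweep
#'
#' @param samples numeric vector of samples (pA for `signal_kind = "current"`,
#'   mV for `"voltage"`).
#' @param sampling_rate sampling rate in Hz (nominally 10000).
#' @param signal_kind `"current"` or `"voltage"`.
#' @param t0 time of the first sample in seconds (default 0).
#' @param stimulus_times stimulus onset times in seconds.
#' @param artifact_windows list of `c(start, end)` second pairs to be treated
#'   as stimulus artifacts (half-open `[start, end)`).
#' @param holding holding level (mV in voltage clamp, pA in current clamp).
#' @return an object of class `phys_sweep`.
#' @export
sweep_trace <- function(samples, sampling_rate = 10000, signal_kind = c("current", "voltage"),
                        t0 = 0, stimulus_times = numeric(0), artifact_windows = list(),
                        holding = NA_real_) {
  signal_kind <- match.arg(signal_kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("sweep must contain at least one sample")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) stop("sampling_rate must be > 0")
  dur <- length(samples) / sampling_rate
  for (w in artifact_windows) {
    if (length(w) != 2L || w[1] > w[2]) stop("artifact window must be c(start, end) with start <= end")
    if (w[1] < t0 - 1e-9 || w[2] > t0 + dur + 1e-9) stop("artifact window outside the sweep's time span")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 signal_kind = signal_kind, t0 = t0,
                 stimulus_times = as.numeric(stimulus_times),
                 artifact_windows = artifact_windows, holding = holding),
            class = "phys_sweep")
}

#' @export
print.phys_sweep <- function(x, ...) {
  cat(sprintf("<phys_sweep> %s, %d samples @ %g Hz (%.3f s), %d stimuli\n",
              x$signal_kind, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, length(x$stimulus_times)))
  invisible(x)
}

sweep_duration <- function(sweep) length(sweep$samples) / sweep$sampling_rate

sweep_times <- function(sweep) .i2t(seq_along(sweep$samples), sweep$sampling_rate, sweep$t0)

#' Protocol metadata
#'
#' Describes the acquisition protocol attached to a sweep set. Current-step
#' protocols carry the step currents of one of the two canonical series
#' (-100 to +100 pA at 10 pA intervals; -200 to +400 pA at 25 pA intervals),
#' both 600 ms square steps. Evoked current-clamp protocols carry 5 stimuli
#' at 20 Hz.
#'
#' @param protocol_kind one of `evoked_vc`, `paired_vc`, `spontaneous_vc`,
#'   `current_steps_cc`, `evoked_cc`, `drug_timecourse_cc`.
#' @param step_currents injected currents in pA (current_steps_cc only).
#' @param step_duration step length in seconds (default 0.6).
#' @param step_onset step/stimulus onset in seconds from sweep start.
#' @param stim_frequency,stim_count train stimulation frequency (Hz) and count.
#' @param stimulation_charge stimulation charge in nC, where recorded.
#' @return a `phys_protocol` list.
#' @export
protocol_metadata <- function(protocol_kind = c("evoked_vc", "paired_vc", "spontaneous_vc",
                                                "current_steps_cc", "evoked_cc", "drug_timecourse_cc"),
                              step_currents = numeric(0), step_duration = 0.6, step_onset = 0.2,
                              stim_frequency = NA_real_, stim_count = NA_integer_,
                              stimulation_charge = NA_real_) {
  protocol_kind <- match.arg(protocol_kind)
  structure(list(protocol_kind = protocol_kind, step_currents = as.numeric(step_currents),
                 step_duration = step_duration, step_onset = step_onset,
                 stim_frequency = stim_frequency, stim_count = stim_count,
                 stimulation_charge = stimulation_charge),
            class = "phys_protocol")
}

#' The two canonical current-step series
#'
#' @param series `"fine"` for -100..+100 pA at 10 pA, `"coarse"` for
#'   -200..+400 pA at 25 pA.
#' @return a `phys_protocol` for 600 ms square steps.
#' @export
step_series <- function(series = c("fine", "coarse")) {
  series <- match.arg(series)
  cur <- if (series == "fine") seq(-100, 100, by = 10) else seq(-200, 400, by = 25)
  protocol_metadata("current_steps_cc", step_currents = cur)
}

#' Construct a sweep set
#'
#' @param sweeps list of [sweep_trace()] objects sharing sampling rate and
#'   signal kind.
#' @param protocol a [protocol_metadata()] object.
#' @param cell_id,animal_id identifiers.
#' @return an object of class `phys_sweepset`.
#' @export
sweep_set <- function(sweeps, protocol = NULL, cell_id = NA_character_, animal_id = NA_character_) {
  if (length(sweeps) == 0L) stop("sweep set must contain at least one sweep")
  if (!all(vapply(sweeps, inherits, logical(1), "phys_sweep")))
    stop("all elements must be phys_sweep objects")
  fs <- vapply(sweeps, `[[`, numeric(1), "sampling_rate")
  kind <- vapply(sweeps, `[[`, character(1), "signal_kind")
  if (length(unique(fs)) != 1L) stop("sweeps disagree on sampling_rate")
  if (length(unique(kind)) != 1L) stop("sweeps disagree on signal_kind")
  if (!is.null(protocol)) {
    vc <- protocol$protocol_kind %in% c("evoked_vc", "paired_vc", "spontaneous_vc")
    if (vc && kind[1] != "current")
      stop(sprintf("protocol %s expects current sweeps but signal_kind is %s",
                   protocol$protocol_kind, kind[1]))
    if (!vc && kind[1] != "voltage")
      stop(sprintf("protocol %s expects voltage sweeps but signal_kind is %s",
                   protocol$protocol_kind, kind[1]))
  }
  structure(list(sweeps = sweeps, protocol = protocol,
                 cell_id = cell_id, animal_id = animal_id),
            class = "phys_sweepset")
}

#' @export
print.phys_sweepset <- function(x, ...) {
  cat(sprintf("<phys_sweepset> %d %s sweep(s) @ %g Hz, protocol %s, cell %s\n",
              length(x$sweeps), x$sweeps[[1]]$signal_kind, x$sweeps[[1]]$sampling_rate,
              if (is.null(x$protocol)) "<none>" else x$protocol$protocol_kind, x$cell_id))
  invisible(x)
}

#' @export
length.phys_sweepset <- function(x) length(x$sweeps)

#' Write a sweep set in the neutral interchange format
#'
#' Writes `<path>.csv` (samples, one column per sweep) and `<path>.json`
#' (sampling rate, signal kind, per-sweep stimulus/artifact annotations,
#' protocol metadata).
#'
#' @param ss a `phys_sweepset`.
#' @param path file stem; `.csv` / `.json` are appended.
#' @return `path`, invisibly.
#' @export
write_recording <- function(ss, path) {
  stopifnot(inherits(ss, "phys_sweepset"))
  n <- max(vapply(ss$sweeps, function(s) length(s$samples), integer(1)))
  mat <- vapply(ss$sweeps, function(s) c(s$samples, rep(NA_real_, n - length(s$samples))),
                numeric(n))
  mat <- matrix(mat, nrow = n)
  colnames(mat) <- sprintf("sweep%03d", seq_along(ss$sweeps))
  # 17 significant digits so doubles survive the text round-trip exactly
  chr <- apply(mat, 2L, function(col)
    ifelse(is.na(col), "", formatC(col, digits = 17, format = "g")))
  utils::write.table(chr, paste0(path, ".csv"), sep = ",", row.names = FALSE,
                     col.names = colnames(mat), quote = FALSE)
  meta <- list(
    format = "phystype-interchange-v1",
    sampling_rate = ss$sweeps[[1]]$sampling_rate,
    signal_kind = ss$sweeps[[1]]$signal_kind,
    cell_id = ss$cell_id, animal_id = ss$animal_id,
    protocol = if (is.null(ss$protocol)) NULL else unclass(ss$protocol),
    sweeps = lapply(ss$sweeps, function(s)
      list(n = length(s$samples), t0 = s$t0, holding = s$holding,
           stimulus_times = s$stimulus_times,
           artifact_windows = lapply(s$artifact_windows, as.numeric)))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording into a sweep set
#'
#' Reads the neutral interchange format written by [write_recording()].
#' Axon Binary Format (`format_hint = "abf"`) is recognised but not parsed:
#' ABF is a closed binary vendor format with no reader in this toolchain, so
#' the function stops with an instruction to export to interchange first.
#'
#' @param path file stem of an interchange pair (or a `.csv`/`.json` member).
#' @param format_hint `"interchange"` (default) or `"abf"`.
#' @return a `phys_sweepset`.
#' @export
read_recording <- function(path, format_hint = c("interchange", "abf")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "abf")
    stop("ABF input is not supported in this build: convert to the CSV+JSON ",
         "interchange format (see write_recording) and re-run")
  stem <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  if (!file.exists(csv) || !file.exists(js))
    stop("interchange pair not found: ", csv, " / ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(meta$sampling_rate)) stop("sampling rate missing from sidecar ", js)
  if (is.null(meta$signal_kind) || !meta$signal_kind %in% c("current", "voltage"))
    stop("unknown or missing signal kind in sidecar ", js)
  mat <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  prot <- NULL
  if (!is.null(meta$protocol)) {
    p <- meta$protocol
    prot <- protocol_metadata(p$protocol_kind,
                              step_currents = unlist(p$step_currents) %||% numeric(0),
                              step_duration = p$step_duration %||% 0.6,
                              step_onset = p$step_onset %||% 0.2,
                              stim_frequency = p$stim_frequency %||% NA_real_,
                              stim_count = p$stim_count %||% NA_integer_,
                              stimulation_charge = p$stimulation_charge %||% NA_real_)
  }
  sweeps <- lapply(seq_len(ncol(mat)), function(j) {
    sm <- meta$sweeps[[j]]
    x <- mat[, j]
    if (!is.null(sm$n)) x <- x[seq_len(sm$n)]
    x <- x[!is.na(x)]
    aw <- sm$artifact_windows %||% list()
    aw <- if (is.matrix(aw)) lapply(seq_len(nrow(aw)), function(r) as.numeric(aw[r, ]))
          else if (is.numeric(aw) && length(aw) == 2L) list(aw)
          else lapply(aw, as.numeric)
    sweep_trace(x, sampling_rate = meta$sampling_rate, signal_kind = meta$signal_kind,
                t0 = sm$t0 %||% 0,
                stimulus_times = unlist(sm$stimulus_times) %||% numeric(0),
                artifact_windows = aw,
                holding = sm$holding %||% NA_real_)
  })
  sweep_set(sweeps, protocol = prot,
            cell_id = meta$cell_id %||% NA_character_,
            animal_id = meta$animal_id %||% NA_character_)
}

#' Blank stimulus artifacts by linear interpolation
#'
#' Replaces samples inside each artifact window with a straight line between
#' the window's flanking samples. The acquisition truncates artifacts for
#' display only; blanking before detection keeps the artifact transient from
#' contaminating baselines and peak searches.
#'
#' @param sweep a `phys_sweep`.
#' @param windows artifact windows; defaults to `sweep$artifact_windows`.
#' @return the blanked sweep.
#' @export
blank_artifacts <- function(sweep, windows = sweep$artifact_windows) {
  x <- sweep$samples; fs <- sweep$sampling_rate; n <- length(x)
  m <- max(1L, round(0.0005 * fs))   # 0.5 ms mean anchors, not single samples
  for (w in windows) {
    idx <- .window_idx(w[1], w[2], fs, n, sweep$t0)
    if (length(idx) == 0L) next
    lo <- max(min(idx) - 1L, 1L); hi <- min(max(idx) + 1L, n)
    va <- mean(x[max(1L, lo - m + 1L):lo])
    vb <- mean(x[hi:min(n, hi + m - 1L)])
    x[idx] <- stats::approx(c(lo, hi), c(va, vb), xout = idx)$y
  }
  sweep$samples <- x
  sweep
}
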