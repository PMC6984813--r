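# Evoked, unitary and spontaneous PSC detection and kinetics.

test_that("select_event_window subsamples 25% (or 5 below 20 sweeps) and centres on the median peak", {
  mk <- function(n) sweep_set(lapply(1:n, function(i) evoked_sweep(latency_ms = 7)),
                              protocol_metadata("evoked_vc"))
  w40 <- select_event_window(mk(40), "negative", seed = 1)
  expect_length(w40$subsample, 10L)
  w19 <- select_event_window(mk(19), "negative", seed = 1)
  expect_length(w19$subsample, 5L)
  expect_equal(w40$half_width, 5)
  expect_equal(select_event_window(mk(19), "positive", seed = 1)$half_width, 7.5)
  # all peaks at a fixed latency: centre lands on the planted peak time
  # (alpha event peaks tau after its 7 ms-latency onset)
  expect_equal(w40$center, 0.6 + 0.002 + 0.007 + 0.002, tolerance = 5e-4)
})

test_that("detect_evoked_psc applies the 6xMAD threshold arithmetic", {
  # noise confined to the baseline (raw MAD ~2 pA), flat post-stimulus
  # region with a planted event: the threshold arithmetic is then exact
  mk <- function(amp) sweep_set(lapply(1:10, function(i) {
    x <- c(with_seed(1000 + i, rnorm(6000, 0, 2 / 0.6745)), rep(0, 4000)) +
      alpha_event(10000, 0.607, tau_ms = 2, amp = amp)
    sweep_trace(x, FS_HZ, "current", stimulus_times = 0.6,
                artifact_windows = list(c(0.6, 0.602)), holding = -70)
  }), protocol_metadata("evoked_vc"))
  det50 <- detect_evoked_psc(mk(-50), polarity = "negative", seed = 2)
  expect_true(all(det50$events$success))           # 50 > 6*2
  expect_true(all(abs(det50$events$baseline_mad - 2) < 0.8))
  det10 <- detect_evoked_psc(mk(-10), polarity = "negative", seed = 2)
  expect_true(!any(det10$events$success))          # 10 < 6*2
  # failure amplitude convention: with no successes the cell amplitude
  # falls back to the mean-trace extremum, which still sees the -10 pA event
  expect_equal(det10$summary$mean_amplitude, -10, tolerance = 2)
})

test_that("failure amplitudes are recorded near the cell mean peak time", {
  set.seed(32)
  sweeps <- c(lapply(1:8, function(i) evoked_sweep(-50, 5, 2 / 0.6745, seed = i)),
              lapply(1:4, function(i) evoked_sweep(0, 5, 2 / 0.6745, seed = 100 + i)))
  ss <- sweep_set(sweeps, protocol_metadata("evoked_vc"))
  det <- detect_evoked_psc(ss, polarity = "negative", seed = 3)
  expect_equal(sum(det$events$success), 8L)
  fails <- det$events[!det$events$success, ]
  expect_true(all(!is.na(fails$amplitude)))
  # failure amplitude is a noise extremum near the mean peak time: small
  expect_true(all(abs(fails$amplitude) < 15))
  expect_equal(det$summary$mean_amplitude, -50, tolerance = 0.1 * 50)
  expect_equal(det$summary$success_rate, 100 * 8 / 12)
})

test_that("success_rate follows its definition", {
  ev <- function(s) data.frame(success = s)
  expect_equal(success_rate(ev(rep(FALSE, 10))), 0)
  expect_equal(success_rate(ev(rep(c(TRUE, FALSE), 5))), 50)
  expect_equal(success_rate(ev(rep(TRUE, 16))), 100)
  expect_error(success_rate(ev(logical(0))), "no event")
})

test_that("rise time of a linear ramp is 60% of its duration", {
  # linear 0 -> -50 over 10 ms: t20 at 2 ms, t80 at 8 ms
  fs <- FS_HZ
  n <- 3000
  x <- numeric(n)
  ramp <- 1:100
  x[1000 + ramp] <- -50 * ramp / 100
  x[1101:n] <- -50
  rl <- phystype:::.rise_latency(x, fs, 0, 1150L, 0, 0.05)
  expect_equal(rl[1], 6, tolerance = 0.02)          # rise 6 ms
  expect_equal(rl[2], (0.1 + 0.002) * 1000 - 50, tolerance = 0.2)  # latency from 50 ms ref
})

test_that("alpha-event kinetics match a dense-grid crossing oracle", {
  tau <- 2; amp <- -50; fs <- FS_HZ
  sw <- evoked_sweep(amp = amp, latency_ms = 7, noise_sd = 0, tau_ms = tau)
  ss <- sweep_set(list(sw, sw), protocol_metadata("evoked_vc"))
  det <- detect_evoked_psc(ss, polarity = "negative", smooth = FALSE, seed = 4)
  # oracle: alpha function on a 1 MHz grid
  tg <- seq(0, 20, by = 1e-3)                      # ms
  yg <- amp * (tg / tau) * exp(1 - tg / tau)
  pk <- which.min(yg)
  t20 <- tg[min(which(yg <= 0.2 * yg[pk]))]
  t80 <- tg[min(which(yg <= 0.8 * yg[pk]))]
  onset_lat <- 7                                   # onset 7 ms after artifact end
  expect_equal(det$events$rise_20_80[1], t80 - t20, tolerance = 0.1)
  expect_equal(det$events$latency[1], onset_lat + t20, tolerance = 0.1)
  # identical latencies across sweeps -> jitter 0
  expect_equal(psc_kinetics(det)$jitter, 0, tolerance = 1e-9)
})

test_that("fit_decay recovers single and weighted-double time constants", {
  t <- seq(0, 100, by = 0.1)
  y <- 40 * exp(-t / 10)
  expect_equal(fit_decay(y, model = "single")$tau, 10, tolerance = 0.01)
  # printed weighted-tau formula: (5*80 + 50*20) / 100 = 14
  expect_equal(weighted_tau(80, 5, 20, 50), 14)
  expect_equal(weighted_tau(80, 5, 0, 50), 5)      # A2 = 0 limit
  y2 <- 80 * exp(-t / 5) + 20 * exp(-t / 50)
  expect_equal(fit_decay(y2, model = "double_weighted")$tau, 14, tolerance = 0.5)
  # negative-going events fit on magnitude
  expect_equal(fit_decay(-y, model = "single")$tau, 10, tolerance = 0.01)
  expect_error(fit_decay(y[1:3]), "too short")
})

test_that("uEPSC attribution honours the 3 ms window after the presynaptic AP peak", {
  fs <- FS_HZ
  mk <- function(lat_ms, amp = -16) {
    x <- with_seed(41, rnorm(fs, 0, 2 / 0.6745))   # raw MAD ~2 pA
    x + alpha_event(fs, 0.5 + lat_ms / 1000, tau_ms = 2, amp = amp)
  }
  flat <- sweep_trace(with_seed(42, rnorm(fs, 0, 2 / 0.6745)), fs, "current")
  expect_false(detect_paired_uepsc(flat, 0.5)$success)
  hit <- detect_paired_uepsc(sweep_trace(mk(1.2), fs, "current"), 0.5)
  expect_true(hit$success)
  expect_equal(hit$amplitude, -16, tolerance = 3)
  expect_equal(hit$latency, 1.2, tolerance = 0.4)
  # event at 4 ms: outside the window, not attributed
  late <- detect_paired_uepsc(sweep_trace(mk(4), fs, "current"), 0.5)
  expect_false(late$success)
  expect_error(detect_paired_uepsc(flat, 5), "outside the sweep")
})

test_that("sEPSC template matches the planted kernel and is decay-truncated", {
  spec <- sim_spont_spec(rate = 4, duration = 60)
  sw <- sim_spontaneous(spec, seed = 51)
  tpl <- build_sepsc_template(sw, seed = 52)
  expect_lt(min(tpl$waveform), 0)                  # negative peak
  # length ~ rise-to-peak + one decay constant
  expect_equal(length(tpl$waveform),
               tpl$peak_idx + round(tpl$tau * 10), tolerance = 3)
  ker <- phystype:::.psc_kernel(-20, spec$rise, spec$tau_decay, FS_HZ)
  kpk <- which.min(ker)
  a <- tpl$peak_idx; L <- min(length(tpl$waveform) - a, length(ker) - kpk)
  seg_t <- tpl$waveform[(a - 3):(a + L)]
  seg_k <- ker[(kpk - 3):(kpk + L)]
  expect_gt(cor(seg_t, seg_k), 0.99)
})

test_that("template construction needs at least 10 candidates", {
  sw <- sim_spontaneous(sim_spont_spec(rate = 0.05, duration = 60), seed = 53)
  expect_error(build_sepsc_template(sw, seed = 54), "too few candidate")
})

test_that("detect_sepsc: silent traces yield nothing; artifacts are NCI-rejected", {
  spec <- sim_spont_spec(rate = 4, duration = 60)
  sw <- sim_spontaneous(spec, seed = 55)
  tpl <- build_sepsc_template(sw, seed = 56)
  flat <- sweep_trace(rep(0, 10 * FS_HZ), FS_HZ, "current")
  expect_equal(nrow(detect_sepsc(flat, tpl)), 0L)
  expect_error(detect_sepsc(sw, template = NULL), "template")
  # single-sample -30 pA artifacts rejected while real events are kept
  x <- sw$samples
  art_at <- round(seq(2.5, 55, by = 2.71) * FS_HZ)
  x[art_at] <- x[art_at] - 30
  ev <- detect_sepsc(sweep_trace(x, FS_HZ, "current"), tpl)
  hits_art <- vapply(art_at / FS_HZ, function(ta) any(abs(ev$time - ta) < 5e-4), logical(1))
  expect_lt(mean(hits_art), 0.1)
  truth <- attr(sw, "truth")
  matched <- vapply(truth$time, function(tt) any(abs(ev$time - tt) < 2e-3), logical(1))
  expect_gt(mean(matched), 0.9)
})

test_that("sepsc_stats returns medians and 1/IEI frequency", {
  ev <- data.frame(time = seq(0.2, 2, by = 0.2), amplitude = -15)
  expect_equal(sepsc_stats(ev)$median_frequency, 5)
  ev2 <- data.frame(time = c(1, 2, 3), amplitude = c(-10, -20, -30))
  expect_equal(sepsc_stats(ev2)$median_amplitude, -20)
  one <- data.frame(time = 1, amplitude = -10)
  expect_true(is.na(sepsc_stats(one)$median_frequency))
})

test_that("detection is translation-equivariant and scale-covariant", {
  set.seed(61)
  base <- evoked_sweep(-40, 6, 2, seed = 62)
  ss <- sweep_set(list(base), protocol_metadata("evoked_vc"))
  w <- list(center = 0.61, half_width = 5, search_limit = 20)
  class(w) <- "phys_window"
  d0 <- detect_evoked_psc(ss, window = w, polarity = "negative")
  # shift by 100 ms
  sh <- sweep_trace(c(rep(0, 1000), base$samples), FS_HZ, "current",
                    stimulus_times = 0.7, artifact_windows = list(c(0.7, 0.702)))
  w2 <- w; w2$center <- 0.71
  d1 <- detect_evoked_psc(sweep_set(list(sh), protocol_metadata("evoked_vc")),
                          window = w2, polarity = "negative")
  expect_equal(d1$events$peak_time, d0$events$peak_time + 0.1, tolerance = 2e-4)
  expect_equal(d1$events$latency, d0$events$latency, tolerance = 0.05)
  # scaling by a > 0 scales amplitude, keeps the success partition
  sc <- sweep_trace(3 * base$samples, FS_HZ, "current", stimulus_times = 0.6,
                    artifact_windows = list(c(0.6, 0.602)))
  d2 <- detect_evoked_psc(sweep_set(list(sc), protocol_metadata("evoked_vc")),
                          window = w, polarity = "negative")
  expect_equal(d2$events$success, d0$events$success)
  expect_equal(d2$events$amplitude, 3 * d0$events$amplitude, tolerance = 1e-6)
})

test_that("I/E balance is the IPSC/EPSC magnitude ratio", {
  expect_equal(ie_balance(30, -30), 1)
  expect_equal(ie_balance(45, -15), 3)
  expect_error(ie_balance(10, 0), "zero")
})
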