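# AP detection and the 15 intrinsic membrane properties.

# voltage sweep with a parametric AP planted at `at` seconds
ap_sweep <- function(at = 0.5, thr = -40, amp = 65, hw = 0.8, ahp = -15,
                     ahp_lat = 6, v0 = -60, n = FS_HZ, base = NULL) {
  v <- rep(v0, n)
  v <- phystype:::.insert_ap(v, FS_HZ, round(at * FS_HZ) + 1L, thr, amp, hw,
                             ahp, ahp_lat, base_level = base)
  sweep_trace(v, FS_HZ, "voltage")
}

test_that("detect_aps finds nothing subthreshold and resolves close spikes", {
  flat <- sweep_trace(rep(-60, FS_HZ), FS_HZ, "voltage")
  expect_equal(nrow(detect_aps(flat)), 0L)
  v <- rep(-60, FS_HZ)
  for (at in c(0.3, 0.315))
    v <- phystype:::.insert_ap(v, FS_HZ, round(at * FS_HZ) + 1L, -40, 65, 0.8, -15, 6)
  aps <- detect_aps(sweep_trace(v, FS_HZ, "voltage"))
  expect_equal(nrow(aps), 2L)
  expect_equal(diff(aps$peak_t) * 1000, 15, tolerance = 0.3)
})

test_that("AP threshold matches a dense-grid 20 V/s crossing oracle", {
  sw <- ap_sweep()
  ap <- detect_aps(sw)
  expect_equal(nrow(ap), 1L)
  # oracle: rebuild the analytic waveform on a 1 MHz grid and find the first
  # 20 V/s upward crossing by brute force
  fs_hi <- 1e6
  vhi <- rep(-60, 2e5)
  vhi <- phystype:::.insert_ap(vhi, fs_hi, 1e5, -40, 65, 0.8, -15, 6)
  dv <- diff(vhi) * fs_hi / 1000              # V/s
  cross <- min(which(dv > 20))
  expect_equal(ap$threshold_v, vhi[cross], tolerance = 0.25)
  expect_equal(ap$peak_v, -40 + 65, tolerance = 0.2)
  expect_equal(ap$amplitude, 65, tolerance = 0.4)
})

test_that("halfwidth of a symmetric triangular spike is half the base width", {
  # triangle: rises -60 -> 20 in 1 ms, falls back in 1 ms (base 2 ms)
  v <- rep(-60, 5000)
  up <- seq(-60, 20, length.out = 11)
  v[3001:3011] <- up; v[3011:3021] <- rev(up)
  ap <- detect_aps(sweep_trace(v, FS_HZ, "voltage"), min_amplitude = 20)
  expect_equal(nrow(ap), 1L)
  # halfwidth is measured at threshold + amplitude/2; the 20 V/s threshold
  # sits at the triangle's foot, so halfwidth = half the 2 ms base
  expect_equal(ap$halfwidth, 1, tolerance = 0.11)
})

test_that("AHP magnitude is ~zero when voltage never drops below threshold", {
  # AP with no AHP term, resting at the threshold level; the measured 20 V/s
  # threshold sits a few tenths of a mV above the plateau, so the magnitude
  # is bounded near zero rather than exactly zero
  v <- rep(-40, 8000)
  v <- phystype:::.insert_ap(v, FS_HZ, 4001L, -40, 65, 0.8, -1e-9, 6)
  ap <- detect_aps(sweep_trace(v, FS_HZ, "voltage"))
  expect_equal(ap$ahp_magnitude[1], 0, tolerance = 0.5)
  expect_gte(ap$ahp_magnitude[1], -0.5)
})

test_that("halfwidth of a parametric AP matches its closed-form construction", {
  for (hw in c(0.5, 1.0, 1.4)) {
    ap <- detect_aps(ap_sweep(hw = hw))
    expect_equal(ap$halfwidth[1], hw, tolerance = max(0.05, 0.05 * hw))
  }
})

test_that("AP measures are invariant to a DC offset", {
  sw <- ap_sweep()
  a0 <- detect_aps(sw)
  sw$samples <- sw$samples + 12
  a1 <- detect_aps(sw)
  expect_equal(a1$threshold_v, a0$threshold_v + 12, tolerance = 1e-9)
  expect_equal(a1$amplitude, a0$amplitude, tolerance = 1e-9)
  expect_equal(a1$halfwidth, a0$halfwidth, tolerance = 1e-9)
})

test_that("passive features: ohmic slope, sag formula, RC decay, rebound", {
  # ohmic cell: 1 mV per 10 pA -> 100 MOhm, built from the simulator with a
  # known spec and no sag below -150 pA
  spec <- sim_neuron_spec("FS", r_m = 100, tau_m = 20, sag_fraction = 25,
                          max_rate = 100, rheobase = 150)
  fine <- sim_step_protocol(spec, step_series("fine"), seed = 71, noise_sd = 0.02)
  coarse <- sim_step_protocol(spec, step_series("coarse"), seed = 72, noise_sd = 0.02)
  pf <- passive_features(fine, coarse)
  expect_equal(pf$membrane_resistance, 100, tolerance = 2)
  expect_equal(pf$membrane_decay_tau, 20, tolerance = 0.5)
  expect_equal(pf$sag, 25, tolerance = 1)
  expect_equal(pf$rebound_spikes, 0L)
  # printed sag formula, directly
  expect_equal(compute_sag(-80, -75, -60), 25)
  expect_error(compute_sag(-60, -60, -60), "undefined")
})

test_that("sag is invariant to DC offset and to rescaled deflections", {
  expect_equal(compute_sag(-80 + 7, -75 + 7, -60 + 7), compute_sag(-80, -75, -60))
  # scaling the deflections from baseline by a > 0 leaves sag unchanged
  a <- 2.5
  expect_equal(compute_sag(-60 + a * (-20), -60 + a * (-15), -60),
               compute_sag(-80, -75, -60))
})

test_that("train features follow their printed definitions", {
  # regular ISIs -> maxFR = 1/ISI and fr_adaptation = 1
  spec <- sim_neuron_spec("FS", max_rate = 100,
                          adaptation = list(fr = 1, broadening = 1, amp = 1, dahp = 0))
  coarse <- sim_step_protocol(spec, step_series("coarse"), seed = 73, noise_sd = 0.02)
  tf <- train_features(coarse)
  expect_equal(tf$max_firing_rate, 100, tolerance = 1)
  expect_equal(tf$fr_adaptation, 1, tolerance = 0.03)
  expect_equal(tf$ap_broadening, 1, tolerance = 0.03)
  expect_equal(tf$ap_amplitude_adaptation, 1, tolerance = 0.03)
  expect_equal(tf$delta_ahp, 0, tolerance = 0.5)
  # direct evaluation of the adaptation ratio: ISIs 10, 20, 20, 20 ms
  isi <- c(10, 20, 20, 20)
  expect_equal(isi[1] / mean(tail(isi, 2)), 0.5)
  spec2 <- sim_neuron_spec("nFS", adaptation = list(fr = 0.5, broadening = 1.3,
                                                    amp = 0.8, dahp = -4))
  tf2 <- train_features(sim_step_protocol(spec2, step_series("coarse"), seed = 74,
                                          noise_sd = 0.02))
  expect_equal(tf2$fr_adaptation, 0.5, tolerance = 0.05)
  expect_equal(tf2$ap_broadening, 1.3, tolerance = 0.05)
  expect_equal(tf2$ap_amplitude_adaptation, 0.8, tolerance = 0.03)
})

test_that("maxFR is non-decreasing in the planted firing rate", {
  rates <- c(40, 80, 120, 160)
  measured <- vapply(seq_along(rates), function(i) {
    sp <- sim_neuron_spec("FS", max_rate = rates[i])
    train_features(sim_step_protocol(sp, step_series("coarse"), seed = 80 + i,
                                     noise_sd = 0.05))$max_firing_rate
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("stimulus-response features count APs and measure subthreshold EPSPs", {
  fs <- FS_HZ
  stims <- 0.6 + (0:4) / 20
  v <- rep(-60, 1.2 * fs)
  for (s in stims)   # 4 mV EPSP peaking 15 ms after each stimulus
    v <- v + 4 / -1 * alpha_event(length(v), s + 0.015 - 0.008, tau_ms = 8, amp = -1)
  sw <- sweep_trace(v, fs, "voltage", stimulus_times = stims)
  sr <- stimulus_response_features(sweep_set(list(sw),
                                             protocol_metadata("evoked_cc")))
  expect_equal(sr$aps_per_stimulus, 0)
  expect_equal(sr$v_rest, -60, tolerance = 0.01)
  expect_equal(sr$mean_epsp, 4, tolerance = 0.3)
  # one AP riding on stimulus 1 only -> 1/5 per stimulus
  v2 <- phystype:::.insert_ap(v, fs, round((stims[1] + 0.01) * fs), -40, 65, 0.8, -15, 6)
  sw2 <- sweep_trace(v2, fs, "voltage", stimulus_times = stims)
  sr2 <- stimulus_response_features(sweep_set(list(sw2),
                                              protocol_metadata("evoked_cc")))
  expect_equal(sr2$aps_per_stimulus, 0.2)
})

test_that("drug timecourse bins V_m and measures the late-window shift", {
  fs <- 100                      # 100 Hz is ample for a slow V_m series
  n <- 16 * 60 * fs              # 16 min
  const <- sweep_trace(rep(-55, n), fs, "voltage")
  expect_equal(drug_timecourse(const, drug_onset = 240)$delta_vm, 0)
  stepv <- c(rep(-55, 4 * 60 * fs), rep(-60, 12 * 60 * fs))
  expect_equal(drug_timecourse(sweep_trace(stepv, fs, "voltage"), 240)$delta_vm, -5)
  # exponential approach to -6 mV with tau = 60 s: the last-3-min mean sits
  # within 2% of the asymptote
  tt <- seq_len(12 * 60 * fs) / fs
  expv <- c(rep(-55, 4 * 60 * fs), -55 - 6 * (1 - exp(-tt / 60)))
  dt <- drug_timecourse(sweep_trace(expv, fs, "voltage"), 240)
  expect_equal(dt$delta_vm, -6, tolerance = 6 * 0.02)
  expect_equal(unique(diff(dt$binned_vm$t)), 30)
  expect_error(drug_timecourse(const, drug_onset = 100), "baseline")
})

test_that("assemble_feature_vector returns the 15 named properties and flags gaps", {
  spec <- sim_neuron_spec("nFS")
  fine <- sim_step_protocol(spec, step_series("fine"), seed = 75)
  coarse <- sim_step_protocol(spec, step_series("coarse"), seed = 76)
  fv <- assemble_feature_vector(fine, coarse)
  expect_identical(names(fv), membrane_property_names())
  expect_length(fv, 15L)
  expect_true(!anyNA(fv))
  # missing -200 pA sweep: sag and rebound flagged NA, everything else intact
  keep <- coarse$protocol$step_currents != -200
  coarse2 <- coarse
  coarse2$sweeps <- coarse$sweeps[keep]
  coarse2$protocol$step_currents <- coarse$protocol$step_currents[keep]
  fv2 <- assemble_feature_vector(fine, coarse2)
  expect_true(is.na(fv2["sag"]) && is.na(fv2["rebound_spikes"]))
  expect_false(anyNA(fv2[c("membrane_resistance", "max_firing_rate", "ap_halfwidth")]))
})
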