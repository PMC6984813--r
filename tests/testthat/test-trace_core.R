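# Sweep data model, interchange I/O, smoothing, baseline statistics and
# alignment-averaging.

test_that("interchange round-trip preserves samples and metadata exactly", {
  ss <- sim_step_protocol(sim_neuron_spec("FS"), step_series("fine"), seed = 1)
  stem <- file.path(withr::local_tempdir(), "rec")
  write_recording(ss, stem)
  back <- read_recording(stem)
  expect_length(back$sweeps, length(ss$sweeps))
  for (i in seq_along(ss$sweeps))
    expect_identical(back$sweeps[[i]]$samples, ss$sweeps[[i]]$samples)
  expect_equal(back$sweeps[[1]]$sampling_rate, 10000)
  expect_equal(back$protocol$step_currents, ss$protocol$step_currents)
  expect_equal(back$protocol$protocol_kind, "current_steps_cc")
})

test_that("read_recording validates inputs and rejects mismatched signal kinds", {
  ev <- sim_evoked(sim_evoked_spec(n_sweeps = 2), seed = 2)
  stem <- file.path(withr::local_tempdir(), "ev")
  write_recording(ev, stem)
  back <- read_recording(stem)
  expect_length(back$sweeps, 2L)
  expect_equal(back$sweeps[[1]]$sampling_rate, 10000)
  expect_error(read_recording(file.path(tempdir(), "nope")), "not found")
  expect_error(read_recording(stem, format_hint = "abf"), "ABF")
  # voltage samples under a voltage-clamp protocol contract
  expect_error(
    sweep_set(list(sweep_trace(rnorm(100), signal_kind = "voltage")),
              protocol = protocol_metadata("evoked_vc")),
    "signal_kind")
})

test_that("sweep invariants are enforced", {
  expect_error(sweep_trace(numeric(0)), "at least one sample")
  expect_error(sweep_trace(1:10, sampling_rate = 0), "sampling_rate")
  expect_error(sweep_trace(1:10, artifact_windows = list(c(0.5, 2))),
               "outside the sweep")
  s1 <- sweep_trace(1:10, signal_kind = "current")
  s2 <- sweep_trace(1:10, signal_kind = "voltage")
  expect_error(sweep_set(list(s1, s2)), "signal_kind")
})

test_that("savgol_smooth preserves polynomials and is linear", {
  expect_equal(savgol_smooth(rep(5, 100)), rep(5, 100))
  t <- seq_len(200)
  cubic <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  expect_equal(savgol_smooth(cubic), cubic, tolerance = 1e-9)
  x <- rnorm(150); y <- rnorm(150)
  expect_equal(savgol_smooth(3 * x - 2 * y),
               3 * savgol_smooth(x) - 2 * savgol_smooth(y), tolerance = 1e-12)
  expect_error(savgol_smooth(1:5), "shorter than the filter window")
})

test_that("savgol noise variance matches the convolution-weights oracle", {
  w <- phystype:::.savgol_weights(5L, 3L)   # 11-sample cubic kernel
  set.seed(7)
  x <- rnorm(200000, sd = 2)
  y <- savgol_smooth(x)
  interior <- 6:(length(y) - 5)
  expect_equal(var(y[interior]), 4 * sum(w^2), tolerance = 0.02)
})

test_that("baseline_stats computes mean and raw MAD", {
  b <- baseline_stats(rep(5, 1000))
  expect_equal(b$mean, 5); expect_equal(b$mad, 0)
  b2 <- baseline_stats(rep(c(1, -1), 500))
  expect_equal(b2$mean, 0); expect_equal(b2$mad, 1)
  set.seed(11)
  b3 <- baseline_stats(rnorm(5000, sd = 4))
  expect_equal(b3$mad, 0.6745 * 4, tolerance = 0.05)
})

test_that("MAD is shift-invariant and absolutely homogeneous", {
  set.seed(12)
  x <- rnorm(500)
  for (a in c(-3, 0.5, 2)) {
    expect_equal(baseline_stats(x + 10)$mad, baseline_stats(x)$mad)
    expect_equal(baseline_stats(a * x)$mad, abs(a) * baseline_stats(x)$mad)
  }
  # configurable scale factor
  expect_equal(baseline_stats(x, mad_scale = 1.4826)$mad,
               1.4826 * baseline_stats(x)$mad)
})

test_that("baseline window excludes artifacts and rejects empty windows", {
  sw <- sweep_trace(c(rep(0, 500), rep(100, 100), rep(0, 400)), 10000, "current",
                    artifact_windows = list(c(0.05, 0.06)))
  b <- baseline_stats(sw, c(0, 0.1))
  expect_equal(b$mean, 0)   # the 100-pA artifact block is excluded
  expect_error(baseline_stats(sw, c(0.05, 0.06)), "empty")
})

test_that("align_average recovers jittered event amplitude; unaligned attenuates", {
  set.seed(21)
  n <- 600
  # fast kernel (tau 0.5 ms): +-1 ms jitter attenuates the unaligned mean
  kernel <- alpha_event(n, 0.02, tau_ms = 0.5, amp = -50)
  segs <- lapply(1:50, function(i) {
    jit <- round(runif(1, -10, 10))      # +-1 ms jitter in samples
    x <- numeric(n)
    src <- seq_len(n) - jit
    ok <- src >= 1 & src <= n
    x[ok] <- kernel[src[ok]]
    x + rnorm(n, 0, 0.5)
  })
  m_aligned <- align_average(segs, mode = "max_rise")
  m_raw <- align_average(segs, mode = "none")
  expect_equal(min(m_aligned), -50, tolerance = 0.02)
  expect_lt(abs(min(m_raw)), abs(min(m_aligned)) * 0.95)
  # single segment is returned untouched; identical events average to one
  expect_equal(as.numeric(align_average(segs[1], mode = "max_rise")), segs[[1]])
  same <- align_average(list(kernel, kernel, kernel), mode = "max_rise")
  expect_equal(as.numeric(same), kernel[seq_along(same)], tolerance = 1e-12)
  expect_error(align_average(list()), "at least one")
})

test_that("blank_artifacts interpolates across the artifact window", {
  x <- rep(0, 1000); x[501:520] <- 100
  sw <- sweep_trace(x, 10000, "current",
                    artifact_windows = list(c(0.05, 0.052)))
  b <- blank_artifacts(sw)
  expect_lt(max(abs(b$samples)), 1e-9)
})
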