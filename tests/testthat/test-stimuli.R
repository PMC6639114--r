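test_that("continuum interpolation is linear between the endpoints", {
  amps <- matrix(c(0, 12, 10, 10, 3, 30), nrow = 3, byrow = TRUE)
  spec <- continuum_spec(endpoint_amplitudes = amps)
  steps <- design_continuum(spec)
  expect_equal(length(unique(steps$step)), 7L)

  # endpoints carry exactly the configured values
  expect_equal(steps$amplitude_db[steps$step == 1],
               spec$endpoint_amplitudes[, 1], ignore_attr = TRUE)
  expect_equal(steps$amplitude_db[steps$step == 7],
               spec$endpoint_amplitudes[, 2], ignore_attr = TRUE)
  expect_equal(steps$bandwidth_hz[steps$step == 1],
               spec$endpoint_bandwidths[, 1], ignore_attr = TRUE)

  # midpoint of 0 -> 12 dB is 6 dB at step 4
  expect_equal(steps$amplitude_db[steps$step == 4 & steps$peak == 1], 6)

  # amplitudes and bandwidths are monotone in step index for each peak
  for (p in 1:3) {
    a <- steps$amplitude_db[steps$peak == p]
    b <- steps$bandwidth_hz[steps$peak == p]
    expect_true(all(diff(a) >= -1e-9) || all(diff(a) <= 1e-9))
    expect_true(all(diff(b) >= -1e-9) || all(diff(b) <= 1e-9))
  }

  # degenerate two-step continuum returns only the endpoints
  two <- design_continuum(continuum_spec(n_steps = 2))
  expect_equal(sort(unique(two$step)), 1:2)
  expect_equal(two$amplitude_db[two$step == 2],
               default_endpoint_amplitudes()[, 2], ignore_attr = TRUE)
})

test_that("continuum spec validation names the violated field", {
  expect_error(continuum_spec(n_steps = 1), "n_steps")
  expect_error(continuum_spec(peak_centers = c(2500, 3500, 30000)),
               "peak_centers")
  expect_error(continuum_spec(onset_ramp_fraction = 0.9,
                              offset_ramp_fraction = 0.3),
               "ramp_fraction")
  expect_error(continuum_spec(endpoint_bandwidths = matrix(-1, 3, 2)),
               "bandwidths")
})

test_that("stimulus assembly respects durations, ramps, and normalization", {
  spec_long <- continuum_spec(fricative_duration = 0.300)
  spec_short <- continuum_spec(fricative_duration = 0.100)

  w <- synthesize_stimulus(4, spec_short, seed = 3)
  expect_equal(length(w$samples) / w$sample_rate, 0.100 + 0.250)
  expect_equal(sqrt(mean(w$samples^2)), 0.05, tolerance = 1e-10)

  # on-ramp spans 75% of the fricative: 225 ms long / 75 ms short
  env <- phonocat:::cosine_envelope(round(0.300 * 44100), 0.75, 0.20)
  n_on <- round(0.75 * 0.300 * 44100)
  expect_lt(env[n_on - 1], 1)
  expect_equal(env[1], 0)
  expect_equal(n_on / 44100, 0.225, tolerance = 1e-3)
  n_on_short <- round(0.75 * 0.100 * 44100)
  expect_equal(n_on_short / 44100, 0.075, tolerance = 1e-3)

  # central (non-ramp) envelope region is flat
  flat <- env[(n_on + 1):(round(0.80 * length(env)) - 1)]
  expect_true(all(flat == 1))

  # determinism under a fixed seed; seed is mandatory
  w2 <- synthesize_stimulus(4, spec_short, seed = 3)
  expect_identical(w$samples, w2$samples)
  expect_error(synthesize_stimulus(4, spec_short), "seed")

  # a supplied vowel must share the sample rate
  bad_vowel <- structure(list(samples = rnorm(100), sample_rate = 22050),
                         class = "phonocat_wave")
  expect_error(synthesize_stimulus(4, spec_long, vowel = bad_vowel, seed = 1),
               "sample rate")
})

test_that("synthesized endpoint spectra peak at the configured frequencies", {
  spec <- continuum_spec(fricative_duration = 0.300)
  fric7 <- synthesize_fricative(7, spec, seed = 42)
  pk7 <- estimate_spectral_peaks(fric7)
  bin <- attr(pk7, "bin_width_hz")
  # highest-frequency local maximum of the "s"-like endpoint sits at 6500 Hz
  expect_lt(abs(max(pk7$freq_hz) - 6500), bin / 2 + 1e-9)

  # the "sh"-like endpoint is dominated by its low peak; the oracle position
  # is the argmax of the designed composite gain curve (the 3500 Hz peak's
  # tail shifts it ~20 Hz above 2500), recovered to within one bin
  st1 <- design_continuum(spec)
  st1 <- st1[st1$step == 1, ]
  f <- seq(2000, 3000, 0.5)
  designed <- f[which.max(phonocat:::peak_gain_db(
    f, st1$center_hz, st1$amplitude_db, st1$bandwidth_hz))]
  fric1 <- synthesize_fricative(1, spec, seed = 42)
  pk1 <- estimate_spectral_peaks(fric1)
  expect_lt(abs(pk1$freq_hz[which.max(pk1$power_db)] - designed), bin)
})

test_that("WAV files round-trip 16-bit PCM mono audio", {
  spec <- continuum_spec(fricative_duration = 0.100)
  w <- synthesize_stimulus(1, spec, seed = 5)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  r <- read_wav(path)
  expect_equal(r$sample_rate, 44100)
  expect_lt(max(abs(r$samples - w$samples)), 1 / 32767)  # quantization only
})

test_that("session schedules alternate conditions and balance steps", {
  spec <- continuum_spec()
  s <- make_session_schedule(spec, "long", reps_per_step = 5, n_blocks = 6,
                             seed = 11)
  expect_equal(nrow(s), 6 * 35)
  expect_equal(as.vector(tapply(s$condition, s$block, unique)),
               c("long", "short", "long", "short", "long", "short"))
  # exactly reps_per_step of every step within each block
  for (b in 1:6)
    expect_true(all(table(s$step[s$block == b]) == 5))

  expect_identical(s, make_session_schedule(spec, "long", 5, 6, seed = 11))
  s2 <- make_session_schedule(spec, "long", 5, 6, seed = 12)
  expect_false(identical(s$step, s2$step))

  expect_error(make_session_schedule(spec, "short", 5, 5, seed = 1), "even")
  expect_error(make_session_schedule(spec, "short", 5, 6), "seed")
})
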