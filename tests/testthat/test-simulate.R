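test_that("zero response amplitude yields an all-zero ground truth", {
  loc <- make_localizer_schedule("MD", n_trials = 2)
  cfg <- simulation_config(response_amplitude_hbo = 0)
  truth <- simulate_hemodynamics(loc, cfg)
  expect_true(all(truth$data == 0))
})

test_that("the planted response equals the direct boxcar-HRF convolution", {
  loc <- make_localizer_schedule("MD", n_trials = 1)
  cfg <- simulation_config(response_amplitude_hbo = 1)
  truth <- simulate_hemodynamics(loc, cfg)
  fs <- 12.5; n <- n_samples(loc)
  # independent oracle: explicit discrete convolution of the 10-s boxcar
  # (onset 20 s) with the HRF kernel, unit-peak normalized
  box <- numeric(n)
  box[(floor(20 * fs) + 1):floor(30 * fs)] <- 1
  k <- canonical_hrf(fs)
  conv <- numeric(n)
  for (i in seq_len(n)) {
    j <- i - seq_along(k) + 1L
    ok <- j >= 1
    conv[i] <- sum(box[j[ok]] * k[ok])
  }
  conv <- conv / max(conv)
  got <- truth$data[, "C3-C5", "HbO"]
  expect_equal(got, conv, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(max(got), 1, tolerance = 1e-12)
  # every other channel silent
  other <- setdiff(dimnames(truth$data)[[2]], "C3-C5")
  expect_true(all(truth$data[, other, "HbO"] == 0))
})

test_that("HbR ground truth is minus one third of HbO everywhere", {
  enc <- make_encoding_schedule("yes")
  cfg <- simulation_config(response_amplitude_hbo = 0.8)
  truth <- simulate_hemodynamics(enc, cfg)
  expect_equal(truth$data[, , "HbR"], -truth$data[, , "HbO"] / 3,
               tolerance = 1e-12)
})

test_that("a task without a mapped channel is rejected", {
  loc <- make_localizer_schedule("SN", n_trials = 1)
  cfg <- simulation_config(responsive_channels = c(MD = "C3-C5"))
  expect_error(simulate_hemodynamics(loc, cfg), "SN")
})

test_that("noise injection is the identity at zero amplitudes and
          deterministic given the seed", {
  loc <- make_localizer_schedule("MD", n_trials = 2)
  cfg0 <- simulation_config(noise = list(
    white_sd = 0, cardiac = list(freq = 1.1, amp = 0),
    respiratory = list(freq = 0.25, amp = 0),
    mayer = list(freq = 0.1, amp = 0), drift_amp = 0))
  truth <- simulate_hemodynamics(loc, cfg0)
  expect_equal(add_noise(truth, cfg0, seed = 1)$data, truth$data)

  cfg <- simulation_config()
  a <- add_noise(truth, cfg, seed = 42)
  b <- add_noise(truth, cfg, seed = 42)
  c <- add_noise(truth, cfg, seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("pure white noise has the configured standard deviation", {
  loc <- make_localizer_schedule("MD", n_trials = 10)
  cfg <- simulation_config(response_amplitude_hbo = 0, noise = list(
    white_sd = 1, cardiac = list(freq = 1.1, amp = 0),
    respiratory = list(freq = 0.25, amp = 0),
    mayer = list(freq = 0.1, amp = 0), drift_amp = 0))
  noisy <- add_noise(simulate_hemodynamics(loc, cfg), cfg, seed = 8)
  sds <- apply(noisy$data, c(2, 3), sd)
  expect_true(all(abs(sds - 1) < 0.05))
})

test_that("noise frequencies above Nyquist are rejected", {
  expect_error(simulation_config(noise = list(
    white_sd = 0.1, cardiac = list(freq = 7, amp = 0.1),
    respiratory = list(freq = 0.25, amp = 0.1),
    mayer = list(freq = 0.1, amp = 0.1), drift_amp = 0.1)), "Nyquist")
})

test_that("the optical forward model is constant at zero concentration and
          linear in DPF", {
  loc <- make_localizer_schedule("MD", n_trials = 1)
  cfg <- simulation_config(response_amplitude_hbo = 0)
  raw <- hemo_to_intensity(simulate_hemodynamics(loc, cfg), cfg)
  expect_true(all(raw$data == 1))            # baseline intensity everywhere

  cfg1 <- simulation_config(response_amplitude_hbo = 1)
  h <- simulate_hemodynamics(loc, cfg1)
  od1 <- intensity_to_od(hemo_to_intensity(h, cfg1), reference = "stored")
  cfg2 <- cfg1
  cfg2$mbll <- mbll_parameters(dpf = c(`760` = 12, `850` = 12))
  od2 <- intensity_to_od(hemo_to_intensity(h, cfg2), reference = "stored")
  expect_equal(od2$data, 2 * od1$data, tolerance = 1e-12)
})

test_that("hemoglobin -> intensity -> OD -> hemoglobin round trip is exact
          with noise off", {
  enc <- make_encoding_schedule("no", n_pairs = 2)
  cfg <- simulation_config(response_amplitude_hbo = 1.5)
  truth <- simulate_hemodynamics(enc, cfg)
  rec <- hemo_to_intensity(truth, cfg)
  back <- od_to_hemo(intensity_to_od(rec, reference = "stored"), cfg$mbll)
  expect_lt(max(abs(back$data - truth$data)), 1e-9)
})

test_that("a simulated participant has the ten runs in paradigm order with
          consistent truth", {
  p <- get_high_snr_participant()
  expect_equal(names(p$runs),
               c("MD1", "SN1", paste0("enc", 1:6), "MD2", "SN2"))
  expect_equal(length(p$truth), 6L)
  expect_equal(sum(p$truth == "yes"), 3L)
  for (i in 1:6) {
    sch <- p$runs[[paste0("enc", i)]]$schedule
    expect_equal(sch$encoded_answer, p$truth[i])
  }
})

test_that("answers drive which task events are materialized", {
  cfg <- simulation_config(seed = 2, answers = rep("yes", 6))
  p <- simulate_participant(cfg)
  for (i in 1:6) {
    act <- schedule_events(p$runs[[paste0("enc", i)]]$schedule,
                           c("MD", "SN"))
    expect_true(all(act$condition == "MD"))
  }
  expect_error(simulate_participant(simulation_config(answers = c("yes", "no"))),
               "6 entries")
})

test_that("the truth sidecar round-trips answers and seed", {
  p <- get_high_snr_participant()
  path <- withr::local_tempfile(fileext = ".txt")
  write_truth(p, path)
  tr <- read_truth(path)
  expect_equal(tr$seed, p$config$seed)
  expect_equal(unname(tr$answers), p$truth)
})

test_that("changing the seed changes the noise but not schedules or ground
          truth", {
  cfg1 <- simulation_config(seed = 21, response_amplitude_hbo = 0.4)
  cfg2 <- simulation_config(seed = 22, response_amplitude_hbo = 0.4)
  p1 <- simulate_participant(cfg1)
  p2 <- simulate_participant(cfg2)
  expect_equal(p1$runs$enc1$schedule$events, p2$runs$enc1$schedule$events)
  expect_equal(p1$runs$MD1$truth_hemo$data, p2$runs$MD1$truth_hemo$data)
  expect_false(identical(p1$runs$MD1$raw$data, p2$runs$MD1$raw$data))
})

test_that("with responses 10x the noise floor the planted channel wins the
          localizer GLM in nearly all seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(seed = 300 + s, response_amplitude_hbo = 1.0)
    loc <- make_localizer_schedule("MD")
    noisy <- add_noise(simulate_hemodynamics(loc, cfg), cfg,
                       seed = 300 + s)
    series <- moving_average_bandpass(detrend_linear(noisy))
    des <- build_design(loc, conditions = "MD")
    tt <- contrast_t(fit_glm(series, des), c(1, 0))$t
    incl <- included_channels(standard_montage())
    t_hbo <- tt[paste0(incl, "|HbO")]
    if (names(which.max(t_hbo)) == "C3-C5|HbO") hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})
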