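test_that("empirical chance levels reproduce the binomial inverse-CDF
          thresholds", {
  s30 <- empirical_chance_level(30)
  expect_equal(s30$min_correct, 19L)
  expect_equal(s30$threshold_percent, 63.33, tolerance = 1e-4)

  s6 <- empirical_chance_level(6)
  expect_equal(s6$min_correct, 5L)
  expect_equal(s6$threshold_percent, 83.33, tolerance = 1e-4)

  expect_equal(empirical_chance_level(1)$min_correct, 1L)
  expect_equal(empirical_chance_level(1)$threshold_percent, 100)
})

test_that("chance levels match brute-force CDF enumeration for n up to 200", {
  for (n in 1:200) {
    # oracle: accumulate binomial pmf terms directly
    pmf <- choose(n, 0:n) * 0.5^n
    cdf <- cumsum(pmf)
    oracle <- which(cdf >= 0.95)[1] - 1L
    expect_equal(empirical_chance_level(n)$min_correct, oracle)
  }
})

test_that("detection rates count per-class correct fractions", {
  expect_equal(detection_rates(c("yes", "no"), c("yes", "no")),
               c(yes = 100, no = 100))
  got <- detection_rates(c("y", "y", "n", "n", "n", "n"),
                         c("y", "y", "y", "n", "n", "n"),
                         classes = c("y", "n"))
  expect_equal(got, c(y = 200 / 3, n = 100), tolerance = 1e-10)
  allyes <- detection_rates(rep("yes", 6),
                            c(rep("yes", 3), rep("no", 3)))
  expect_equal(allyes, c(yes = 100, no = 0))
  onesided <- detection_rates(rep("yes", 3), rep("yes", 3))
  expect_true(is.na(onesided[["no"]]))
})

test_that("significance flags follow the chance-level rule", {
  mk <- function(k, n) c(rep("yes", k), rep("no", n - k))
  s <- score_decisions(mk(19, 30), rep("yes", 30))
  expect_equal(s$accuracy, 100 * 19 / 30, tolerance = 1e-10)
  expect_true(s$significant)
  expect_false(score_decisions(mk(18, 30), rep("yes", 30))$significant)
  expect_true(score_decisions(rep("yes", 6), rep("yes", 6))$significant)
  expect_false(score_decisions(mk(4, 6), rep("yes", 6))$significant)
})

test_that("COI selection recovers planted channels and supports forced and
          tied choices", {
  p <- get_high_snr_participant()
  hemo_md <- preprocess_recording(p$runs$MD1$raw)
  hemo_sn <- preprocess_recording(p$runs$SN1$raw)
  locs <- list(MD = list(series = hemo_md, schedule = p$runs$MD1$schedule),
               SN = list(series = hemo_sn, schedule = p$runs$SN1$schedule))
  incl <- included_channels(p$montage)

  cois <- select_cois(locs, incl)
  expect_equal(nrow(cois), 4L)
  expect_equal(cois$channel[cois$task == "MD"], rep("C3-C5", 2))
  expect_equal(cois$channel[cois$task == "SN"], rep("CP3-CP5", 2))

  # a single included channel forces all four COIs onto it
  forced <- select_cois(locs, "FC3-FC5")
  expect_equal(forced$channel, rep("FC3-FC5", 4))

  expect_error(select_cois(locs, character(0)), "no included channels")
})

test_that("exactly tied t-values resolve to the earlier canonical channel", {
  loc <- make_localizer_schedule("MD", n_trials = 3)
  cfg <- simulation_config(seed = 5, response_amplitude_hbo = 0.5)
  noisy <- add_noise(simulate_hemodynamics(loc, cfg), cfg, seed = 5)
  # duplicate one channel's data into another: identical t by construction
  noisy$data[, "C3-FC5", ] <- noisy$data[, "C3-C5", ]
  locs <- list(MD = list(series = noisy, schedule = loc),
               SN = list(series = noisy,
                         schedule = make_localizer_schedule("SN",
                                                            n_trials = 3)))
  cois <- select_cois(locs, c("C3-FC5", "C3-C5"))
  expect_equal(cois$channel[cois$task == "MD"][1], "C3-FC5")
})

test_that("high-signal encoding runs decode to their encoded answer in both
          modes and chromophores", {
  p <- get_high_snr_participant()
  incl <- included_channels(p$montage)
  cois <- data.frame(chromophore = rep(c("HbO", "HbR"), each = 2),
                     task = rep(c("MD", "SN"), 2),
                     channel = rep(c("C3-C5", "CP3-CP5"), 2), t = NA)
  for (i in c(1, 2)) {                       # one "yes" and one "no" run
    run <- p$runs[[paste0("enc", i)]]
    hemo <- preprocess_recording(run$raw)
    for (chromo in c("HbO", "HbR")) {
      multi <- decode_answers(hemo, run$schedule, cois, chromo,
                              "multi_trial")
      expect_equal(multi$answer, p$truth[i])
      single <- decode_answers(hemo, run$schedule, cois, chromo,
                               "single_trial")
      expect_equal(nrow(single), 5L)
      expect_gte(sum(single$answer == p$truth[i]), 4L)
    }
  }
})

test_that("swapping the MD and SN COIs inverts every decision", {
  p <- get_high_snr_participant()
  run <- p$runs$enc1
  hemo <- preprocess_recording(run$raw)
  cois <- data.frame(chromophore = rep(c("HbO", "HbR"), each = 2),
                     task = rep(c("MD", "SN"), 2),
                     channel = rep(c("C3-C5", "CP3-CP5"), 2), t = NA)
  swapped <- cois
  swapped$channel <- rep(c("CP3-CP5", "C3-C5"), 2)
  d1 <- decode_answers(hemo, run$schedule, cois, "HbO", "single_trial")
  d2 <- decode_answers(hemo, run$schedule, swapped, "HbO", "single_trial")
  expect_equal(d2$answer, ifelse(d1$answer == "yes", "no", "yes"))
})

test_that("an exact t tie decodes 'no' deterministically", {
  enc <- make_encoding_schedule("yes", n_pairs = 2)
  flat <- hemo_ts(array(0, dim = c(n_samples(enc), 2, 2),
                        dimnames = list(NULL, c("A", "B"),
                                        c("HbO", "HbR"))),
                  enc$sampling_rate)
  cois <- data.frame(chromophore = rep(c("HbO", "HbR"), each = 2),
                     task = rep(c("MD", "SN"), 2),
                     channel = rep(c("A", "B"), 2), t = NA)
  d <- decode_answers(flat, enc, cois, "HbO", "multi_trial")
  expect_equal(d$t_md, 0)                   # zero effect, zero SE -> t = 0
  expect_equal(d$answer, "no")
})
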