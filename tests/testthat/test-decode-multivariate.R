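test_that("trial features have one vector per active trial with
          channels x chromophores entries", {
  p <- get_high_snr_participant()
  incl <- included_channels(p$montage)
  loc <- extract_trial_features(preprocess_recording(p$runs$MD1$raw),
                                p$runs$MD1$schedule, channels = incl)
  expect_equal(dim(loc$features), c(20L, 28L))
  expect_true(all(loc$labels == "MD"))

  enc <- extract_trial_features(preprocess_recording(p$runs$enc1$raw),
                                p$runs$enc1$schedule, channels = incl)
  expect_equal(nrow(enc$features), 5L)      # only the 5 active trials
  expect_true(all(enc$labels == if (p$truth[1] == "yes") "MD" else "SN"))
  expect_true(all(is.finite(enc$features)))
})

test_that("feature extraction is invariant to channel reordering up to
          column permutation", {
  p <- get_high_snr_participant()
  incl <- included_channels(p$montage)
  hemo <- preprocess_recording(p$runs$enc2$raw)
  f1 <- extract_trial_features(hemo, p$runs$enc2$schedule, channels = incl)
  f2 <- extract_trial_features(hemo, p$runs$enc2$schedule,
                               channels = rev(incl))
  expect_equal(f2$features[, colnames(f1$features)], f1$features,
               tolerance = 1e-12)
})

test_that("edge-truncated trials are dropped and reported", {
  loc <- make_localizer_schedule("MD", n_trials = 3, task_dur = 5,
                                 rest_dur = 10, initial_rest = 10)
  cfg <- simulation_config(seed = 31)
  noisy <- add_noise(simulate_hemodynamics(loc, cfg), cfg, seed = 31)
  # last trial onset 40 s, run 55 s: a (-2, 20) window overruns the edge
  f <- extract_trial_features(noisy, loc)
  expect_equal(f$n_dropped, 1L)
  expect_equal(nrow(f$features), 2L)
})

test_that("linearly separable planted patterns train to perfect accuracy
          and label flips mirror predictions", {
  set.seed(77)
  n <- 20
  md <- cbind(matrix(rnorm(n * 2, mean = 3), n), matrix(rnorm(n * 26), n))
  sn <- cbind(matrix(rnorm(n * 2, mean = -3), n), matrix(rnorm(n * 26), n))
  x <- rbind(md, sn)
  y <- rep(c("MD", "SN"), each = n)
  model <- train_classifier(x, y)
  expect_equal(test_classifier(model, x, y)$accuracy, 100)

  xt <- rbind(cbind(matrix(rnorm(10 * 2, mean = 3), 10),
                    matrix(rnorm(10 * 26), 10)),
              cbind(matrix(rnorm(10 * 2, mean = -3), 10),
                    matrix(rnorm(10 * 26), 10)))
  pred <- predict(model, xt)
  flipped <- train_classifier(x, ifelse(y == "MD", "SN", "MD"))
  pred_f <- predict(flipped, xt)
  expect_true(all(pred != pred_f))
})

test_that("uninformative features decode a balanced test set at exactly
          chance", {
  set.seed(12)
  x <- matrix(rnorm(40 * 6), 40)
  x_identical <- x[rep(1, 40), ]            # same vector for every trial
  y <- rep(c("MD", "SN"), each = 20)
  model <- train_classifier(x, y)
  res <- test_classifier(model, x_identical[1:30, ],
                         rep(c("MD", "SN"), 15))
  expect_equal(res$accuracy, 50)            # constant prediction, 50/50 truth
})

test_that("single-class training sets and feature-length mismatches are
          rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(train_classifier(x, rep("MD", 10)), "both classes")
  model <- train_classifier(x, rep(c("MD", "SN"), 5))
  expect_error(predict(model, matrix(0, 2, 5)), "mismatch")
})

test_that("standardization uses training-set statistics only", {
  set.seed(21)
  x <- matrix(rnorm(40 * 4, mean = 2, sd = 3), 40)
  y <- rep(c("MD", "SN"), each = 20)
  model <- train_classifier(x, y)
  expect_equal(model$center, colMeans(x))
  expect_equal(model$scale, apply(x, 2, sd))
  # a shifted test set must be judged against the *training* frame: a
  # rule that re-standardized per test set would be shift-invariant
  xt <- matrix(rnorm(10 * 4, mean = 2, sd = 3), 10)
  expect_false(all(predict(model, xt) == predict(model, xt + 100)))
})

test_that("majority voting returns the modal answer and demands an odd
          count", {
  expect_equal(majority_vote(c("yes", "yes", "yes", "no", "no")), "yes")
  expect_equal(majority_vote(rep("no", 5)), "no")
  expect_equal(majority_vote(c("yes", "no", "yes", "no", "yes")), "yes")
  expect_error(majority_vote(c("yes", "no")), "odd")
})

test_that("a strongly separable pattern attains permutation percentile 1
          and a reproducible null", {
  set.seed(55)
  n <- 20
  mk <- function(n, mu) cbind(matrix(rnorm(n, mean = mu), n),
                              matrix(rnorm(n * 5), n))
  x_tr <- rbind(mk(n, 4), mk(n, -4))
  y_tr <- rep(c("MD", "SN"), each = n)
  x_te <- rbind(mk(15, 4), mk(15, -4))
  y_te <- rep(c("MD", "SN"), each = 15)
  expect_warning(permutation_test(x_tr, y_tr, x_te, y_te, n_perm = 50,
                                  seed = 1), "100 permutations")
  r1 <- permutation_test(x_tr, y_tr, x_te, y_te, n_perm = 120, seed = 9)
  r2 <- permutation_test(x_tr, y_tr, x_te, y_te, n_perm = 120, seed = 9)
  expect_identical(r1$permutation_accuracies, r2$permutation_accuracies)
  expect_equal(r1$observed_accuracy, 100)
  expect_equal(r1$percentile, 1.0)
  expect_lt(r1$p_value, 0.2)
  # add-one p-value and percentile partition the permutation mass
  expect_equal(r1$p_value,
               (1 + sum(r1$permutation_accuracies >= 100)) / 121)
})

test_that("the SVM40-40 regime decodes a high-signal participant almost
          perfectly", {
  rep <- get_high_snr_report()
  tab <- rep$accuracy_table
  acc <- tab$accuracy[tab$regime == "SVM40-40" & tab$mode == "single_trial"]
  expect_gte(acc, 90)
})
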