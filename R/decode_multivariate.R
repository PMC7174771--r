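#' Trial-wise spatial-pattern feature extraction
#'
#' Fits one GLM per run with a per-trial HRF predictor for every active
#' mental-task event plus intercept and linear-trend confounds, and
#' stores each trial predictor's t-value across all channels and both
#' chromophores as that trial's spatial feature vector (14 channels x 2
#' chromophores = 28 features in the reference montage). For encoding
#' runs only the five "active" trials (windows matching the encoded
#' answer) carry events, so only they yield vectors. Trials whose
#' analysis window is truncated by the run edge are dropped and counted.
#'
#' @param series Preprocessed \code{"hemo_ts"}.
#' @param schedule The run's \code{"run_schedule"}.
#' @param channels Channels entering the feature vector (default: all
#'   channels of the series).
#' @param window Per-trial analysis window in seconds relative to onset
#'   (default \code{c(-2, 20)}, with 0-10 s the trial interval); used to
#'   detect edge-truncated trials.
#' @param hrf_params Optional HRF overrides.
#' @return List of class \code{"trial_features"}: \code{features}
#'   (trials x features matrix, columns \code{"channel|chromophore"}),
#'   \code{labels} (task per trial, \code{"MD"}/\code{"SN"}),
#'   \code{trial_index}, \code{n_dropped}.
#' @export
extract_trial_features <- function(series, schedule, channels = NULL,
                                   window = c(-2, 20), hrf_params = NULL) {
  stopifnot(inherits(series, "hemo_ts"))
  if (is.null(channels)) channels <- channel_names(series)
  ev <- schedule_events(schedule, c("MD", "SN"))
  if (nrow(ev) == 0L) stop("schedule contains no active task events")
  keep <- ev$onset + window[1] >= 0 &
    ev$onset + window[2] <= schedule$total_duration + 1e-9
  n_dropped <- sum(!keep)
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) stop("all trials truncated by the run edge")
  des <- build_design(schedule, events = ev, per_trial = TRUE,
                      intercept = TRUE, linear_trend = TRUE,
                      hrf_params = hrf_params)
  cols <- c(paste0(channels, "|HbO"), paste0(channels, "|HbR"))
  Y <- response_matrix(series)[, cols, drop = FALSE]
  fit <- fit_glm(Y, des)
  task_rows <- which(!des$confound_mask)
  # t for every (trial predictor, response column) pair
  se <- sqrt(outer(diag(fit$XtXinv)[task_rows], fit$sigma2))
  tmat <- fit$betas[task_rows, , drop = FALSE] / se
  rownames(tmat) <- des$names[task_rows]
  structure(list(features = tmat, labels = ev$condition,
                 trial_index = ev$trial_index, n_dropped = n_dropped),
            class = "trial_features")
}

#' Train the linear max-margin task classifier
#'
#' Linear support vector machine discriminating the MD and SN spatial
#' activation patterns. Feature standardization (when enabled) uses
#' training-set statistics only; they are stored with the model and
#' re-applied at test time.
#'
#' @param features Trials x features numeric matrix.
#' @param labels Task label per trial (two classes required).
#' @param cost Regularization constant (default 1).
#' @param standardize Z-score features with training-set mean/SD.
#' @return An object of class \code{"fnirs_svm"} wrapping the fitted
#'   model with its standardization parameters.
#' @export
train_classifier <- function(features, labels, cost = 1,
                             standardize = TRUE) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("training set must contain both classes")
  }
  stopifnot(nrow(features) == length(labels))
  if (standardize) {
    ctr <- colMeans(features)
    scl <- apply(features, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(features)); scl <- rep(1, ncol(features))
  }
  Xs <- scale(features, center = ctr, scale = scl)
  model <- e1071::svm(x = Xs, y = labels, kernel = "linear", cost = cost,
                      scale = FALSE)
  structure(list(model = model, center = ctr, scale = scl,
                 levels = levels(labels), n_features = ncol(features)),
            class = "fnirs_svm")
}

#' @export
predict.fnirs_svm <- function(object, newdata, ...) {
  if (ncol(newdata) != object$n_features) {
    stop("feature length mismatch: model expects ", object$n_features,
         ", got ", ncol(newdata))
  }
  Xs <- scale(newdata, center = object$center, scale = object$scale)
  as.character(predict(object$model, Xs))
}

#' Test the task classifier on independent trials
#'
#' @param model An \code{"fnirs_svm"}.
#' @param features Test trials x features matrix (same feature set as
#'   training).
#' @param truth True task label per test trial.
#' @return List with \code{predictions}, \code{accuracy} (\%), and
#'   per-class \code{detection_rates} (MD rate, SN rate, \%).
#' @export
test_classifier <- function(model, features, truth) {
  stopifnot(nrow(features) == length(truth))
  pred <- predict(model, features)
  list(predictions = pred,
       accuracy = 100 * mean(pred == truth),
       detection_rates = detection_rates(pred, truth,
                                         classes = model$levels))
}

#' Permutation test of classifier accuracy
#'
#' Task labels of the training set are randomly reassigned, the
#' classifier retrained and tested on the untouched test set; repeated
#' \code{n_perm} times. The percentile is the proportion of permutations
#' with accuracy lower than or equal to the observed accuracy; the
#' add-one p-value is \code{(1 + #\{perm >= obs\}) / (1 + n_perm)}.
#'
#' @param train_features,train_labels Training data.
#' @param test_features,test_truth Independent, non-permuted test data.
#' @param n_perm Number of permutations (default 2000).
#' @param seed RNG seed (required for reproducibility).
#' @param cost,standardize Passed to \code{\link{train_classifier}}.
#' @return List of class \code{"permutation_result"}:
#'   \code{observed_accuracy}, \code{permutation_accuracies},
#'   \code{percentile}, \code{p_value}, \code{n_permutations},
#'   \code{seed}.
#' @export
permutation_test <- function(train_features, train_labels,
                             test_features, test_truth,
                             n_perm = 2000, seed = 1L, cost = 1,
                             standardize = TRUE) {
  if (n_perm < 100) {
    warning("fewer than 100 permutations: unstable null tail")
  }
  obs <- test_classifier(train_classifier(train_features, train_labels,
                                          cost, standardize),
                         test_features, test_truth)$accuracy
  set.seed(seed)
  perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    repeat {
      lab <- sample(train_labels)
      if (length(unique(lab)) > 1L) break  # guard (degenerate shuffles)
    }
    perm[i] <- test_classifier(train_classifier(train_features, lab,
                                                cost, standardize),
                               test_features, test_truth)$accuracy
  }
  structure(list(observed_accuracy = obs, permutation_accuracies = perm,
                 percentile = mean(perm <= obs),
                 p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
                 n_permutations = n_perm, seed = seed),
            class = "permutation_result")
}

#' Majority vote over an odd number of per-trial decisions
#'
#' Aggregates the five per-trial answers of an encoding run into one
#' run-level answer by taking the modal decision (e.g. three "yes" and
#' two "no" votes give "yes").
#'
#' @param answers Character vector of decisions; length must be odd so
#'   no tie can occur.
#' @return The modal answer (single string).
#' @export
majority_vote <- function(answers) {
  if (length(answers) %% 2L == 0L) {
    stop("majority_vote requires an odd number of decisions")
  }
  tab <- table(answers)
  names(tab)[which.max(tab)]
}
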