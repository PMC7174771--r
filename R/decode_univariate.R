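#' Expected contrast sign per chromophore
#'
#' Task activation raises HbO and lowers HbR; selection and decoding
#' contrasts are aligned with this expectation so that for both
#' chromophores the most task-responsive channel attains the largest
#' (signed) t-value.
#'
#' @param chromophore \code{"HbO"} or \code{"HbR"}.
#' @return \code{+1} for HbO, \code{-1} for HbR.
#' @export
chromophore_sign <- function(chromophore = c("HbO", "HbR")) {
  chromophore <- match.arg(chromophore)
  if (chromophore == "HbO") 1 else -1
}

# Task-vs-rest t per channel for one localizer run and one chromophore,
# expectation-aligned sign. Returns a named vector over `channels`.
localizer_channel_t <- function(series, schedule, chromophore,
                                channels, hrf_params = NULL) {
  des <- build_design(schedule, conditions = schedule$task,
                      intercept = TRUE, hrf_params = hrf_params)
  fit <- fit_glm(series, des)
  cvec <- chromophore_sign(chromophore) *
    as.numeric(des$names == schedule$task)
  tt <- contrast_t(fit, cvec)$t
  tt[paste0(channels, "|", chromophore)]
}

#' Select channels of interest (COIs)
#'
#' For each of the four localizer GLM analyses (HbO/HbR x MD/SN), the
#' included channel with the largest expectation-aligned task-vs-rest
#' t-value in the corresponding block-1 localizer run becomes the
#' channel of interest. Ties break by canonical (source-major) channel
#' order. The same channel may be selected for both tasks.
#'
#' @param localizers Named list with elements \code{MD} and \code{SN},
#'   each \code{list(series = <hemo_ts>, schedule = <run_schedule>)} for
#'   the block-1 localizer of that task.
#' @param channels Character vector of included (CV-surviving) channel
#'   names; must be non-empty.
#' @param hrf_params Optional HRF overrides.
#' @return Data frame with columns \code{chromophore}, \code{task},
#'   \code{channel}, \code{t} (4 rows).
#' @export
select_cois <- function(localizers, channels, hrf_params = NULL) {
  if (length(channels) == 0L) {
    stop("no included channels available for COI selection")
  }
  stopifnot(all(c("MD", "SN") %in% names(localizers)))
  rows <- list()
  for (chromo in c("HbO", "HbR")) {
    for (task in c("MD", "SN")) {
      tt <- localizer_channel_t(localizers[[task]]$series,
                                localizers[[task]]$schedule,
                                chromo, channels, hrf_params)
      best <- which.max(tt)   # first maximum = canonical-order tie-break
      rows[[length(rows) + 1L]] <- data.frame(
        chromophore = chromo, task = task,
        channel = channels[best], t = unname(tt[best]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

coi_channel <- function(cois, chromophore, task) {
  ch <- cois$channel[cois$chromophore == chromophore & cois$task == task]
  if (length(ch) != 1L) {
    stop("COI table lacks a unique entry for ", chromophore, "/", task)
  }
  ch
}

#' Decode the answer(s) of one encoding run
#'
#' GLM-based t-value comparison implementing the "yes" vs "no"
#' contrast: a GLM with one predictor per answer window type is fitted,
#' and the t-value of each COI's own task predictor is read out — the
#' "yes"-window (MD task) predictor at the MD COI and the "no"-window
#' (SN task) predictor at the SN COI, with expectation-aligned sign per
#' chromophore. When the MD COI's t exceeds the SN COI's t the decoded
#' answer is "yes", otherwise "no" (ties decode "no",
#' deterministically). In \code{multi_trial} mode one GLM
#' over the run's five window pairs yields one decision; in
#' \code{single_trial} mode each pair is fitted on its own local data
#' segment (pair onset minus \code{pair_margin[1]} s to pair end plus
#' \code{pair_margin[2]} s) yielding one decision per pair.
#'
#' @param series Preprocessed \code{"hemo_ts"} of the encoding run.
#' @param schedule The run's \code{"run_schedule"}.
#' @param cois COI table from \code{\link{select_cois}}.
#' @param chromophore \code{"HbO"} or \code{"HbR"}.
#' @param mode \code{"multi_trial"} or \code{"single_trial"}.
#' @param hrf_params Optional HRF overrides.
#' @param pair_margin Flanking rest included in each single-trial fit,
#'   seconds before/after the pair.
#' @return Data frame of decisions with columns \code{pair} (NA in
#'   multi-trial mode), \code{t_md}, \code{t_sn}, \code{answer}
#'   (\code{"yes"}/\code{"no"}/\code{"invalid"}).
#' @export
decode_answers <- function(series, schedule, cois,
                           chromophore = c("HbO", "HbR"),
                           mode = c("multi_trial", "single_trial"),
                           hrf_params = NULL, pair_margin = c(5, 15)) {
  chromophore <- match.arg(chromophore)
  mode <- match.arg(mode)
  fs <- schedule$sampling_rate
  sgn <- chromophore_sign(chromophore)
  md_ch <- coi_channel(cois, chromophore, "MD")
  sn_ch <- coi_channel(cois, chromophore, "SN")
  Y <- response_matrix(series)
  kernel <- hrf_kernel(fs, hrf_params)
  decide <- function(fit, des, pair) {
    t_yes <- contrast_t(fit, sgn * as.numeric(des$names == "yes_window"))$t
    t_no <- contrast_t(fit, sgn * as.numeric(des$names == "no_window"))$t
    t_md <- unname(t_yes[paste0(md_ch, "|", chromophore)])
    t_sn <- unname(t_no[paste0(sn_ch, "|", chromophore)])
    ans <- if (is.na(t_md) || is.na(t_sn)) "invalid"
           else if (t_md > t_sn) "yes" else "no"
    data.frame(pair = pair, t_md = t_md, t_sn = t_sn, answer = ans,
               stringsAsFactors = FALSE)
  }
  if (mode == "multi_trial") {
    des <- build_design(schedule, conditions = c("yes_window", "no_window"),
                        intercept = TRUE, hrf_params = hrf_params)
    return(decide(fit_glm(Y, des), des, NA_integer_))
  }
  # single-trial: one pair-local GLM per yes/no window pair
  ev <- schedule_events(schedule, c("yes_window", "no_window"))
  pairs <- sort(unique(ev$trial_index))
  n <- nrow(Y)
  out <- list()
  for (p in pairs) {
    pe <- ev[ev$trial_index == p, , drop = FALSE]
    a <- max(1L, floor((min(pe$onset) - pair_margin[1]) * fs) + 1L)
    b <- min(n, floor((max(pe$onset + pe$duration) + pair_margin[2]) * fs))
    shift <- (a - 1L) / fs
    len <- b - a + 1L
    loc <- pe
    loc$onset <- loc$onset - shift
    X <- cbind(
      yes_window = event_regressor(loc[loc$condition == "yes_window", ,
                                       drop = FALSE], len, fs, kernel),
      no_window = event_regressor(loc[loc$condition == "no_window", ,
                                      drop = FALSE], len, fs, kernel),
      intercept = 1)
    des <- structure(list(X = X, names = colnames(X),
                          confound_mask = c(FALSE, FALSE, TRUE), fs = fs),
                     class = "design_matrix")
    out[[length(out) + 1L]] <- decide(fit_glm(Y[a:b, , drop = FALSE], des),
                                      des, p)
  }
  do.call(rbind, out)
}

#' Empirical chance level from the binomial inverse CDF
#'
#' The minimum number of correct decisions considered significant:
#' the smallest count \code{c} whose binomial CDF at chance
#' (\code{p = 1/k}) reaches \code{1 - alpha}. With \code{alpha = 0.05},
#' \code{k = 2}: 19 of 30 (63.33\%) for single-trial and 5 of 6
#' (83.33\%) for multi-trial decoding.
#'
#' @param n Number of independent decisions.
#' @param alpha Significance level.
#' @param k Number of equiprobable outcomes.
#' @return List with \code{min_correct} and \code{threshold_percent}.
#' @export
empirical_chance_level <- function(n, alpha = 0.05, k = 2) {
  stopifnot(n >= 1, alpha > 0, alpha < 1, k >= 2)
  cdf <- stats::pbinom(0:n, size = n, prob = 1 / k)
  min_correct <- which(cdf >= 1 - alpha)[1] - 1L
  list(min_correct = min_correct,
       threshold_percent = 100 * min_correct / n)
}

#' Per-class correct-detection rates
#'
#' Fraction (in percent) of encoded answers of each class that were
#' decoded correctly.
#'
#' @param decoded,truth Aligned character vectors of decisions and
#'   encoded answers.
#' @param classes Answer classes (default \code{c("yes", "no")}).
#' @return Named numeric vector of rates (\%); NA for a class absent
#'   from \code{truth}.
#' @export
detection_rates <- function(decoded, truth, classes = c("yes", "no")) {
  stopifnot(length(decoded) == length(truth))
  vapply(classes, function(cl) {
    denom <- sum(truth == cl)
    if (denom == 0L) return(NA_real_)
    100 * sum(decoded == cl & truth == cl) / denom
  }, numeric(1))
}

#' Score a set of decisions against the empirical chance level
#'
#' @param decoded,truth Aligned decision and truth vectors (decisions
#'   flagged \code{"invalid"} count as incorrect).
#' @param alpha,k Chance-level settings (see
#'   \code{\link{empirical_chance_level}}).
#' @return List with \code{n}, \code{n_correct}, \code{accuracy} (\%),
#'   \code{chance} (the chance-level spec), \code{significant}, and
#'   per-class \code{detection_rates}.
#' @export
score_decisions <- function(decoded, truth, alpha = 0.05, k = 2) {
  stopifnot(length(decoded) == length(truth), length(truth) >= 1L)
  n <- length(truth)
  n_correct <- sum(decoded == truth)
  chance <- empirical_chance_level(n, alpha = alpha, k = k)
  list(n = n, n_correct = n_correct, accuracy = 100 * n_correct / n,
       chance = chance, significant = n_correct >= chance$min_correct,
       detection_rates = detection_rates(decoded, truth))
}
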