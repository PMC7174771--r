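#' Run schedules for the binary-communication paradigm
#'
#' A run schedule holds the timed events of one run: localizer runs are
#' block designs of a single mental task (mental drawing, MD, or spatial
#' navigation, SN); answer-encoding runs contain five paired "yes" and
#' "no" answer windows, with the active task events materialized only in
#' the windows matching the encoded answer (MD in "yes" windows, SN in
#' "no" windows).
#'
#' Event times are stored in seconds; sample indices derive by flooring
#' \code{onset * fs} with half-open \code{[onset, onset + duration)}
#' intervals.
#'
#' @name run_schedule
NULL

new_run_schedule <- function(run_type, events, total_duration,
                             sampling_rate = 12.5,
                             encoded_answer = "none", task = NA_character_) {
  stopifnot(sampling_rate > 0, total_duration > 0)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(run_type = run_type, events = events,
                 total_duration = total_duration,
                 sampling_rate = sampling_rate,
                 encoded_answer = encoded_answer, task = task),
            class = "run_schedule")
}

#' Number of samples in a run
#' @param schedule A \code{"run_schedule"}.
#' @return Integer sample count (\code{round(total_duration * fs)}).
#' @export
n_samples <- function(schedule) {
  as.integer(round(schedule$total_duration * schedule$sampling_rate))
}

#' Build a localizer run schedule
#'
#' One mental task repeated in a block design: an initial rest period,
#' then \code{n_trials} repetitions of (task, rest). Defaults reproduce
#' the 20-trial, 10 s task / 20 s rest localizer (total 620 s).
#'
#' @param task \code{"MD"} (mental drawing) or \code{"SN"} (spatial
#'   navigation).
#' @param n_trials Number of task trials (>= 1).
#' @param task_dur,rest_dur,initial_rest Durations in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz.
#' @return A \code{"run_schedule"} whose events are the task trials.
#' @export
make_localizer_schedule <- function(task = c("MD", "SN"), n_trials = 20,
                                    task_dur = 10, rest_dur = 20,
                                    initial_rest = 20, sampling_rate = 12.5) {
  task <- match.arg(task)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (task_dur <= 0 || rest_dur <= 0 || initial_rest <= 0) {
    stop("all durations must be positive")
  }
  onsets <- initial_rest + (seq_len(n_trials) - 1L) * (task_dur + rest_dur)
  events <- data.frame(onset = onsets, duration = task_dur, condition = task,
                       trial_index = seq_len(n_trials),
                       stringsAsFactors = FALSE)
  total <- initial_rest + n_trials * (task_dur + rest_dur)
  new_run_schedule(paste0("localizer_", task), events, total,
                   sampling_rate, encoded_answer = "none", task = task)
}

#' Build an answer-encoding run schedule
#'
#' Each of \code{n_pairs} trial pairs contains one "yes" window followed
#' by one "no" window, each \code{window_dur} long; the first "yes" window
#' starts \code{pre_interval} seconds after run start. The active mental
#' task (MD for a "yes" answer, SN for a "no" answer) is materialized only
#' inside the windows matching the answer; the other windows are ignored
#' (rest).
#'
#' @param answer \code{"yes"} or \code{"no"} — the answer the simulated or
#'   real participant encodes.
#' @param n_pairs Number of yes/no window pairs (default 5).
#' @param window_dur Window duration in seconds (default 10).
#' @param pre_interval Rest before the first "yes" window (default 20 s).
#' @param inter_window_rest Rest between a pair's "yes" and "no" windows
#'   (default 20 s).
#' @param inter_pair_rest Rest after a pair's "no" window (default 20 s).
#' @param sampling_rate Sampling rate in Hz.
#' @return A \code{"run_schedule"} with \code{yes_window}/\code{no_window}
#'   events for every pair plus MD or SN active events, and
#'   \code{encoded_answer} set.
#' @export
make_encoding_schedule <- function(answer = c("yes", "no"), n_pairs = 5,
                                   window_dur = 10, pre_interval = 20,
                                   inter_window_rest = 20,
                                   inter_pair_rest = 20,
                                   sampling_rate = 12.5) {
  answer <- match.arg(answer)
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (any(c(window_dur, pre_interval, inter_window_rest, inter_pair_rest) <= 0)) {
    stop("all durations must be positive")
  }
  pair_len <- 2 * window_dur + inter_window_rest + inter_pair_rest
  yes_on <- pre_interval + (seq_len(n_pairs) - 1L) * pair_len
  no_on <- yes_on + window_dur + inter_window_rest
  windows <- data.frame(
    onset = c(yes_on, no_on),
    duration = window_dur,
    condition = rep(c("yes_window", "no_window"), each = n_pairs),
    trial_index = rep(seq_len(n_pairs), 2L),
    stringsAsFactors = FALSE
  )
  task <- if (answer == "yes") "MD" else "SN"
  active_on <- if (answer == "yes") yes_on else no_on
  active <- data.frame(onset = active_on, duration = window_dur,
                       condition = task, trial_index = seq_len(n_pairs),
                       stringsAsFactors = FALSE)
  total <- pre_interval + n_pairs * pair_len
  new_run_schedule("encoding", rbind(windows, active), total,
                   sampling_rate, encoded_answer = answer, task = task)
}

#' Extract events of given conditions
#' @param schedule A \code{"run_schedule"}.
#' @param conditions Character vector of condition names.
#' @return Event data frame subset, ordered by onset.
#' @export
schedule_events <- function(schedule, conditions) {
  ev <- schedule$events
  ev[ev$condition %in% conditions, , drop = FALSE]
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("run_schedule '%s': %d events, %g s @ %g Hz", x$run_type,
              nrow(x$events), x$total_duration, x$sampling_rate))
  if (x$encoded_answer != "none") cat(sprintf(", answer '%s'", x$encoded_answer))
  cat("\n")
  invisible(x)
}

#' Write / read run events as a BIDS-events-like TSV
#'
#' Three mandatory columns (\code{onset}, \code{duration},
#' \code{condition}) plus \code{trial_index}.
#'
#' @param schedule A \code{"run_schedule"} (for writing).
#' @param path File path.
#' @return \code{read_events_tsv} returns the event data frame.
#' @export
write_events_tsv <- function(schedule, path) {
  utils::write.table(schedule$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "condition") %in% names(ev)))
  if (any(ev$onset < 0) || any(ev$duration <= 0)) {
    stop("events must have onset >= 0 and duration > 0")
  }
  ev
}
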