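#' Run the full decoding pipeline on one participant
#'
#' Executes the complete analysis workflow on a (simulated or loaded)
#' participant's ten runs: CV%-based channel quality control on the
#' block-1 localizers, preprocessing of all runs, channel-of-interest
#' selection, univariate single- and multi-trial answer decoding for
#' HbO and HbR with binomial empirical chance levels, and multivariate
#' single-trial classification plus majority-vote run aggregation for
#' the SVM20-20 and SVM40-40 training regimes — the eight accuracy
#' outcomes of the study design.
#'
#' @param participant A \code{"sim_participant"} (or a structurally
#'   identical list with \code{runs}, \code{truth}, \code{montage}):
#'   runs named MD1, SN1, enc1..enc6, MD2, SN2, each holding
#'   \code{schedule} and \code{raw}.
#' @param parts Which pipelines to run: subset of
#'   \code{c("univariate", "multivariate")}.
#' @param cv_exclusion Apply the CV% exclusion before COI selection
#'   (\code{FALSE} reproduces the no-exclusion control analysis).
#' @param cv_threshold CV% threshold (default 15).
#' @param mbll \code{\link{mbll_parameters}} for preprocessing.
#' @param hrf_params Optional HRF overrides used in every GLM.
#' @param alpha Significance level for empirical chance levels.
#' @param pair_margin Single-trial pair-local window margins, s.
#' @param mvpa_regimes MVPA training regimes to evaluate.
#' @param n_permutations Permutations for MVPA significance (0 skips
#'   permutation testing).
#' @param mvpa_cv_exclusion Restrict MVPA features to CV-surviving
#'   channels (default \code{FALSE}: all montage-included channels enter
#'   the multivariate analysis).
#' @param suitability Optional \code{"suitability_record"} to attach.
#' @return An object of class \code{"participant_report"}; notably
#'   \code{$accuracy_table} (one row per outcome with accuracy,
#'   significance and detection rates), \code{$cois}, \code{$cv} and
#'   \code{$decisions}.
#' @export
run_pipeline <- function(participant,
                         parts = c("univariate", "multivariate"),
                         cv_exclusion = TRUE, cv_threshold = 15,
                         mbll = mbll_parameters(), hrf_params = NULL,
                         alpha = 0.05, pair_margin = c(5, 15),
                         mvpa_regimes = c("SVM20-20", "SVM40-40"),
                         n_permutations = 0,
                         mvpa_cv_exclusion = FALSE,
                         suitability = NULL) {
  parts <- match.arg(parts, several.ok = TRUE)
  runs <- participant$runs
  needed <- c("MD1", "SN1", paste0("enc", 1:6), "MD2", "SN2")
  if (!all(needed %in% names(runs))) {
    stop("participant must provide runs: ", paste(needed, collapse = ", "))
  }
  montage_chans <- included_channels(participant$montage)
  truth <- participant$truth

  # --- quality control (stage: qc) -----------------------------------
  cv_tables <- lapply(runs[c("MD1", "SN1")], function(r) {
    channel_cv_percent(r$raw)[montage_chans, , drop = FALSE]
  })
  cv_excluded <- exclude_channels_by_cv(cv_tables, threshold = cv_threshold)
  analysis_chans <- if (cv_exclusion) {
    setdiff(montage_chans, cv_excluded)
  } else montage_chans

  # --- preprocessing (stage: preprocess) -----------------------------
  # only the runs the requested parts consume (block-2 localizers feed
  # the SVM40-40 regime only)
  need <- c("MD1", "SN1", paste0("enc", 1:6))
  if ("multivariate" %in% parts && "SVM40-40" %in% mvpa_regimes) {
    need <- c(need, "MD2", "SN2")
  }
  hemo <- lapply(runs[need], function(r) {
    preprocess_recording(r$raw, params = mbll)
  })

  report <- list(cv = list(tables = cv_tables, excluded = cv_excluded,
                           threshold = cv_threshold,
                           applied = cv_exclusion),
                 channels = list(montage = montage_chans,
                                 analysis = analysis_chans),
                 truth = truth, suitability = suitability,
                 decisions = list())
  rows <- list()

  if ("univariate" %in% parts) {
    # --- channel-of-interest selection (stage: coi) ------------------
    cois <- select_cois(
      list(MD = list(series = hemo$MD1, schedule = runs$MD1$schedule),
           SN = list(series = hemo$SN1, schedule = runs$SN1$schedule)),
      channels = analysis_chans, hrf_params = hrf_params)
    report$cois <- cois

    # --- answer decoding (stage: decode-uni) -------------------------
    for (chromo in c("HbO", "HbR")) {
      for (mode in c("single_trial", "multi_trial")) {
        dec <- lapply(paste0("enc", 1:6), function(rn) {
          d <- decode_answers(hemo[[rn]], runs[[rn]]$schedule, cois,
                              chromophore = chromo, mode = mode,
                              hrf_params = hrf_params,
                              pair_margin = pair_margin)
          d$run <- rn
          d
        })
        dec <- do.call(rbind, dec)
        reps <- if (mode == "single_trial") 5L else 1L
        truth_vec <- rep(truth, each = reps)
        sc <- score_decisions(dec$answer, truth_vec, alpha = alpha)
        key <- sprintf("univariate_%s_%s", mode, chromo)
        report$decisions[[key]] <- dec
        rows[[key]] <- data.frame(
          pipeline = "univariate", regime = chromo, mode = mode,
          n = sc$n, n_correct = sc$n_correct, accuracy = sc$accuracy,
          chance_percent = sc$chance$threshold_percent,
          significant = sc$significant,
          yes_rate = sc$detection_rates[["yes"]],
          no_rate = sc$detection_rates[["no"]],
          stringsAsFactors = FALSE)
      }
    }
  }

  if ("multivariate" %in% parts) {
    # --- MVPA (stage: decode-mvpa) -----------------------------------
    mvpa_chans <- if (mvpa_cv_exclusion) analysis_chans else montage_chans
    feats <- function(rn) {
      extract_trial_features(hemo[[rn]], runs[[rn]]$schedule,
                             channels = mvpa_chans,
                             hrf_params = hrf_params)
    }
    train_runs <- list(`SVM20-20` = c("MD1", "SN1"),
                       `SVM40-40` = c("MD1", "SN1", "MD2", "SN2"))
    test_f <- lapply(paste0("enc", 1:6), feats)
    test_x <- do.call(rbind, lapply(test_f, `[[`, "features"))
    test_truth <- unlist(lapply(test_f, `[[`, "labels"))
    test_run <- rep(paste0("enc", 1:6),
                    vapply(test_f, function(f) length(f$labels), 1L))
    report$mvpa <- list()
    for (regime in mvpa_regimes) {
      tr <- lapply(train_runs[[regime]], feats)
      train_x <- do.call(rbind, lapply(tr, `[[`, "features"))
      train_y <- unlist(lapply(tr, `[[`, "labels"))
      model <- train_classifier(train_x, train_y)
      res <- test_classifier(model, test_x, test_truth)
      # run-level answers by majority vote over each run's 5 decisions
      pred_answer <- vapply(paste0("enc", 1:6), function(rn) {
        votes <- ifelse(res$predictions[test_run == rn] == "MD",
                        "yes", "no")
        majority_vote(votes)
      }, "")
      multi <- score_decisions(pred_answer, truth, alpha = alpha)
      single_chance <- empirical_chance_level(length(test_truth),
                                              alpha = alpha)
      n_corr <- sum(res$predictions == test_truth)
      perm <- NULL
      if (n_permutations > 0) {
        perm <- permutation_test(train_x, train_y, test_x, test_truth,
                                 n_perm = n_permutations,
                                 seed = participant$config$seed)
      }
      report$mvpa[[regime]] <- list(single = res, multi = multi,
                                    permutation = perm)
      rows[[paste0("mvpa_single_", regime)]] <- data.frame(
        pipeline = "multivariate", regime = regime, mode = "single_trial",
        n = length(test_truth), n_correct = n_corr,
        accuracy = res$accuracy,
        chance_percent = single_chance$threshold_percent,
        significant = n_corr >= single_chance$min_correct,
        yes_rate = res$detection_rates[["MD"]],
        no_rate = res$detection_rates[["SN"]],
        stringsAsFactors = FALSE)
      rows[[paste0("mvpa_multi_", regime)]] <- data.frame(
        pipeline = "multivariate", regime = regime, mode = "multi_trial",
        n = multi$n, n_correct = multi$n_correct,
        accuracy = multi$accuracy,
        chance_percent = multi$chance$threshold_percent,
        significant = multi$significant,
        yes_rate = multi$detection_rates[["yes"]],
        no_rate = multi$detection_rates[["no"]],
        stringsAsFactors = FALSE)
    }
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  report$accuracy_table <- tab
  structure(report, class = "participant_report")
}

#' @export
print.participant_report <- function(x, ...) {
  cat("participant_report\n")
  cat(sprintf("  CV-excluded channels (>%g%%): %s\n", x$cv$threshold,
              if (length(x$cv$excluded) == 0) "none"
              else paste(x$cv$excluded, collapse = ", ")))
  if (!is.null(x$cois)) {
    cat("  channels of interest:\n")
    for (i in seq_len(nrow(x$cois))) {
      cat(sprintf("    %s/%s: %s (t = %.2f)\n", x$cois$chromophore[i],
                  x$cois$task[i], x$cois$channel[i], x$cois$t[i]))
    }
  }
  cat("  accuracies:\n")
  tab <- x$accuracy_table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("    %-12s %-9s %-12s %6.2f%% (%d/%d)%s\n",
                tab$pipeline[i], tab$regime[i], tab$mode[i],
                tab$accuracy[i], tab$n_correct[i], tab$n[i],
                if (tab$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Simulate and analyze a cohort of participants
#'
#' Draws \code{n_participants} independent synthetic participants from a
#' base configuration (seeds \code{base seed + 0 ... n-1}), runs the
#' pipeline on each, and summarizes group accuracies (mean, SD, number
#' of individually significant participants) per outcome.
#'
#' @param n_participants Number of participants (>= 1).
#' @param config Base \code{"sim_config"}; its seed anchors the cohort
#'   seed sequence.
#' @param snr_levels Optional per-participant HbO response amplitudes
#'   (uM; recycled across the cohort), e.g. a monotone ladder for
#'   psychometric-style sweeps. \code{NULL} keeps the base amplitude.
#' @param ... Passed to \code{\link{run_pipeline}} (e.g. \code{parts}).
#' @return List of class \code{"cohort_result"}: \code{reports} (one
#'   per participant), \code{summary} (data frame of group means/SDs
#'   per pipeline/regime/mode), \code{table} (per-participant rows,
#'   with the amplitude used).
#' @export
generate_cohort <- function(n_participants, config = simulation_config(),
                            snr_levels = NULL, ...) {
  stopifnot(n_participants >= 1L)
  amps <- if (is.null(snr_levels)) {
    rep(config$response_amplitude_hbo, n_participants)
  } else rep_len(snr_levels, n_participants)
  reports <- lapply(seq_len(n_participants) - 1L, function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    cfg$response_amplitude_hbo <- amps[i + 1L]
    run_pipeline(simulate_participant(cfg), ...)
  })
  tabs <- do.call(rbind, lapply(seq_along(reports), function(i) {
    t <- reports[[i]]$accuracy_table
    t$participant <- i
    t$amplitude <- amps[i]
    t
  }))
  key <- interaction(tabs$pipeline, tabs$regime, tabs$mode, drop = TRUE)
  summ <- do.call(rbind, lapply(split(tabs, key), function(g) {
    data.frame(pipeline = g$pipeline[1], regime = g$regime[1],
               mode = g$mode[1], mean_accuracy = mean(g$accuracy),
               sd_accuracy = stats::sd(g$accuracy),
               n_significant = sum(g$significant),
               n_participants = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(reports = reports, summary = summ, table = tabs),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d participants\n", length(x$reports)))
  print(x$summary)
  invisible(x)
}
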