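#' Simulation configuration for synthetic participants
#'
#' Bundles every knob of the synthetic-data generator: planted response
#' amplitudes, the task-to-channel map, physiological noise components,
#' HRF parameters, and the optical forward model constants. Defaults
#' describe a realistic mid-quality participant; see the methods
#' vignette for the rationale behind each value.
#'
#' @param seed Integer seed fixing all randomness.
#' @param response_amplitude_hbo Peak HbO response amplitude, uM.
#' @param hbr_ratio HbR amplitude = \code{-hbr_ratio} x HbO (default 1/3).
#' @param responsive_channels Named character vector mapping tasks to the
#'   channel carrying their response.
#' @param noise List with \code{white_sd} (uM), \code{cardiac},
#'   \code{respiratory}, \code{mayer} (each \code{list(freq, amp)}; Hz,
#'   uM) and \code{drift_amp} (uM, random-walk SD).
#' @param hrf_params Optional \code{\link{canonical_hrf}} overrides.
#' @param baseline_intensity Baseline intensity per wavelength
#'   (arbitrary units).
#' @param mbll An \code{\link{mbll_parameters}} object (extinction
#'   coefficients, DPF, source-detector distance).
#' @param answers Character vector of 6 encoded answers
#'   (\code{"yes"}/\code{"no"}); default alternates, 3 of each.
#' @param sampling_rate Sampling rate, Hz.
#' @return A list of class \code{"sim_config"}.
#' @export
simulation_config <- function(seed = 1L,
                              response_amplitude_hbo = 0.5,
                              hbr_ratio = 1 / 3,
                              responsive_channels = c(MD = "C3-C5",
                                                      SN = "CP3-CP5"),
                              noise = list(
                                white_sd = 0.1,
                                cardiac = list(freq = 1.1, amp = 0.2),
                                respiratory = list(freq = 0.25, amp = 0.1),
                                mayer = list(freq = 0.1, amp = 0.15),
                                drift_amp = 0.3
                              ),
                              hrf_params = NULL,
                              baseline_intensity = c(`760` = 1, `850` = 1),
                              mbll = mbll_parameters(),
                              answers = c("yes", "no", "yes",
                                          "no", "yes", "no"),
                              sampling_rate = 12.5) {
  stopifnot(response_amplitude_hbo >= 0, hbr_ratio >= 0,
            all(answers %in% c("yes", "no")), sampling_rate > 0)
  nyq <- sampling_rate / 2
  for (comp in c("cardiac", "respiratory", "mayer")) {
    if (noise[[comp]]$freq >= nyq) {
      stop(comp, " frequency must be below the Nyquist frequency (",
           nyq, " Hz)")
    }
    if (noise[[comp]]$amp < 0) stop(comp, " amplitude must be >= 0")
  }
  stopifnot(noise$white_sd >= 0, noise$drift_amp >= 0)
  structure(list(seed = as.integer(seed),
                 response_amplitude_hbo = response_amplitude_hbo,
                 hbr_ratio = hbr_ratio,
                 responsive_channels = responsive_channels,
                 noise = noise, hrf_params = hrf_params,
                 baseline_intensity = baseline_intensity,
                 mbll = mbll, answers = answers,
                 sampling_rate = sampling_rate),
            class = "sim_config")
}

#' Noise-free ground-truth hemodynamics for one run
#'
#' For every active task event the unit-peak boxcar-convolved-HRF
#' regressor scaled by \code{response_amplitude_hbo} is added to the
#' mapped channel's HbO trace, and \code{-hbr_ratio} times that to its
#' HbR trace. All other channels stay flat zero.
#'
#' @param schedule A \code{"run_schedule"}.
#' @param config A \code{"sim_config"}.
#' @param channels Channel names of the simulated montage (default: the
#'   18 channels of \code{\link{standard_montage}}).
#' @return A noise-free \code{"hemo_ts"}.
#' @export
simulate_hemodynamics <- function(schedule, config,
                                  channels = standard_montage()$channels$name) {
  fs <- schedule$sampling_rate
  n <- n_samples(schedule)
  dat <- array(0, dim = c(n, length(channels), 2L),
               dimnames = list(NULL, channels, c("HbO", "HbR")))
  active <- schedule_events(schedule, c("MD", "SN"))
  tasks <- unique(active$condition)
  missing <- setdiff(tasks, names(config$responsive_channels))
  if (length(missing) > 0L) {
    stop("no responsive channel mapped for task(s): ",
         paste(missing, collapse = ", "))
  }
  kernel <- hrf_kernel(fs, config$hrf_params)
  for (task in tasks) {
    ch <- config$responsive_channels[[task]]
    if (!ch %in% channels) stop("responsive channel not in montage: ", ch)
    resp <- config$response_amplitude_hbo *
      event_regressor(active[active$condition == task, , drop = FALSE],
                      n, fs, kernel)
    dat[, ch, "HbO"] <- dat[, ch, "HbO"] + resp
    dat[, ch, "HbR"] <- dat[, ch, "HbR"] - config$hbr_ratio * resp
  }
  hemo_ts(dat, fs)
}

#' Add physiological noise to a hemodynamic series
#'
#' Per channel and chromophore, independently: white Gaussian noise,
#' sinusoids at the cardiac, respiratory and Mayer-wave frequencies with
#' uniform random phases, and a low-frequency random-walk drift rescaled
#' to \code{drift_amp}.
#'
#' @param hemo A \code{"hemo_ts"}.
#' @param config A \code{"sim_config"}.
#' @param seed If non-NULL, seed the RNG locally (for standalone,
#'   reproducible use); inside \code{\link{simulate_participant}} the
#'   participant-level seed governs the stream.
#' @return The noisy \code{"hemo_ts"}.
#' @export
add_noise <- function(hemo, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- hemo$data
  n <- dim(d)[1]; m <- dim(d)[2] * dim(d)[3]
  fs <- hemo$sampling_rate
  t <- (seq_len(n) - 1L) / fs
  nz <- config$noise
  out <- matrix(d, n, m)
  if (nz$white_sd > 0) {
    out <- out + matrix(stats::rnorm(n * m, sd = nz$white_sd), n, m)
  }
  for (comp in c("cardiac", "respiratory", "mayer")) {
    a <- nz[[comp]]$amp
    if (a > 0) {
      phase <- stats::runif(m, 0, 2 * pi)
      out <- out + a * sin(outer(2 * pi * nz[[comp]]$freq * t, phase, "+"))
    }
  }
  if (nz$drift_amp > 0) {
    w <- apply(matrix(stats::rnorm(n * m), n, m), 2, cumsum)
    sds <- apply(w, 2, stats::sd)
    sds[sds == 0] <- 1
    out <- out + sweep(w, 2, nz$drift_amp / sds, "*")
  }
  hemo$data[] <- out
  hemo
}

#' Forward optical model: hemodynamics to raw light intensities
#'
#' Per channel and wavelength the modified Beer-Lambert law gives the
#' optical-density change
#' \code{dOD = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF} (dHbO/dHbR in
#' mM, eps in 1/(mM mm), d in mm), and the recorded intensity is
#' \code{I(t) = I0 * 10^(-dOD(t))}.
#'
#' @param hemo A \code{"hemo_ts"} (uM).
#' @param config A \code{"sim_config"} (supplies \code{mbll} constants and
#'   baseline intensities).
#' @return A \code{"nirs_recording"} with the baseline intensities stored
#'   in its \code{reference} field.
#' @export
hemo_to_intensity <- function(hemo, config) {
  p <- config$mbll
  wl <- colnames(p$extinction)
  n <- dim(hemo$data)[1]; nch <- dim(hemo$data)[2]
  chs <- channel_names(hemo)
  dat <- array(NA_real_, dim = c(n, nch, length(wl)),
               dimnames = list(NULL, chs, paste0("wl", wl)))
  ref <- matrix(NA_real_, nch, length(wl), dimnames = list(chs, wl))
  conc_mM <- cbind(HbO = 1e-3, HbR = 1e-3) # uM -> mM
  for (j in seq_along(wl)) {
    w <- wl[j]
    i0 <- config$baseline_intensity[[w]]
    if (is.null(i0) || is.na(i0)) {
      stop("no baseline intensity configured for wavelength ", w, " nm")
    }
    dod <- (hemo$data[, , "HbO"] * 1e-3 * p$extinction["HbO", w] +
              hemo$data[, , "HbR"] * 1e-3 * p$extinction["HbR", w]) *
      p$distance * p$dpf[[w]]
    dat[, , j] <- i0 * 10^(-dod)
    ref[, j] <- i0
  }
  nirs_recording(dat, hemo$sampling_rate,
                 wavelengths = as.numeric(wl), reference = ref)
}

#' Simulate a complete participant
#'
#' Generates the ten runs of the paradigm in order — localizer block 1
#' (MD1, SN1), six answer-encoding runs, localizer block 2 (MD2, SN2) —
#' with ground-truth hemodynamics, physiological noise, and
#' forward-modeled raw intensities on a consistent montage.
#'
#' @param config A \code{"sim_config"}; \code{config$answers} must have 6
#'   entries.
#' @param montage The montage (default \code{\link{standard_montage}}).
#' @return An object of class \code{"sim_participant"}: list with
#'   \code{runs} (each: \code{name}, \code{schedule}, \code{raw},
#'   \code{truth_hemo}), \code{truth} (the 6 encoded answers),
#'   \code{montage}, \code{config}.
#' @export
simulate_participant <- function(config = simulation_config(),
                                 montage = standard_montage()) {
  if (length(config$answers) != 6L) {
    stop("config$answers must contain exactly 6 entries, got ",
         length(config$answers))
  }
  fs <- config$sampling_rate
  schedules <- c(
    list(MD1 = make_localizer_schedule("MD", sampling_rate = fs),
         SN1 = make_localizer_schedule("SN", sampling_rate = fs)),
    stats::setNames(lapply(config$answers, make_encoding_schedule,
                           sampling_rate = fs),
                    paste0("enc", 1:6)),
    list(MD2 = make_localizer_schedule("MD", sampling_rate = fs),
         SN2 = make_localizer_schedule("SN", sampling_rate = fs))
  )
  set.seed(config$seed)
  chans <- montage$channels$name
  runs <- lapply(names(schedules), function(nm) {
    sch <- schedules[[nm]]
    truth <- simulate_hemodynamics(sch, config, channels = chans)
    noisy <- add_noise(truth, config)
    list(name = nm, schedule = sch, raw = hemo_to_intensity(noisy, config),
         truth_hemo = truth)
  })
  names(runs) <- names(schedules)
  structure(list(runs = runs, truth = config$answers, montage = montage,
                 config = config),
            class = "sim_participant")
}

#' Write / read the ground-truth sidecar of a simulated participant
#'
#' Plain-text key-value file recording the encoded answer of every
#' encoding run plus the seed, for test harnesses that load recordings
#' from disk.
#'
#' @param participant A \code{"sim_participant"} (for writing).
#' @param path File path.
#' @return \code{read_truth} returns a list with \code{seed} and
#'   \code{answers} (named character vector, enc1..enc6).
#' @export
write_truth <- function(participant, path) {
  stopifnot(inherits(participant, "sim_participant"))
  lines <- c(sprintf("seed=%d", participant$config$seed),
             sprintf("enc%d=%s", 1:6, participant$truth))
  writeLines(lines, path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  ans <- vals[grep("^enc", keys)]
  names(ans) <- keys[grep("^enc", keys)]
  list(seed = as.integer(vals[keys == "seed"]), answers = ans)
}

#' @export
print.sim_participant <- function(x, ...) {
  cat(sprintf("sim_participant: %d runs (%s), answers: %s\n",
              length(x$runs), paste(names(x$runs), collapse = ", "),
              paste(x$truth, collapse = "/")))
  invisible(x)
}
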