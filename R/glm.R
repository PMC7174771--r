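#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking at
#' \code{peak_delay} seconds minus an undershoot peaking at
#' \code{undershoot_delay} seconds scaled by
#' \code{1/peak_undershoot_ratio}, rescaled to unit peak. Gamma shapes
#' are parameterized so the mode of each component equals its delay
#' (shape = 1 + delay/dispersion, scale = dispersion).
#'
#' @param fs Sampling rate in Hz.
#' @param peak_delay Time-to-peak of the positive lobe, s.
#' @param undershoot_delay Time-to-peak of the undershoot, s.
#' @param peak_dispersion,undershoot_dispersion Dispersions, s.
#' @param peak_undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @param kernel_length Kernel support, s.
#' @return Numeric kernel sampled at \code{1/fs}, max value exactly 1.
#' @export
canonical_hrf <- function(fs, peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          peak_undershoot_ratio = 6, kernel_length = 32) {
  stopifnot(fs > 0, peak_delay > 0, undershoot_delay > 0,
            peak_dispersion > 0, undershoot_dispersion > 0,
            peak_undershoot_ratio > 0)
  if (kernel_length < peak_delay) {
    stop("kernel_length must be at least peak_delay")
  }
  t <- seq(0, kernel_length, by = 1 / fs)
  h <- stats::dgamma(t, shape = 1 + peak_delay / peak_dispersion,
                     scale = peak_dispersion) -
    stats::dgamma(t, shape = 1 + undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion) / peak_undershoot_ratio
  h / max(h)
}

#' Resolve HRF parameters (a list overriding the canonical defaults)
#' @noRd
hrf_kernel <- function(fs, hrf_params = NULL) {
  do.call(canonical_hrf, c(list(fs = fs), hrf_params))
}

# Boxcar regressor for a set of events, sampled on n points at fs.
# Half-open [onset, onset + duration): samples floor(onset*fs) ..
# floor((onset+duration)*fs) - 1 (0-based).
event_boxcar <- function(events, n, fs) {
  x <- numeric(n)
  for (i in seq_len(nrow(events))) {
    a <- floor(events$onset[i] * fs) + 1L
    b <- floor((events$onset[i] + events$duration[i]) * fs)
    x[a:min(b, n)] <- 1
  }
  x
}

# Boxcar convolved with the HRF kernel, truncated to n samples and
# rescaled to unit peak (so GLM betas / simulator amplitudes read as peak
# response in the series' units).
event_regressor <- function(events, n, fs, kernel) {
  box <- event_boxcar(events, n, fs)
  r <- stats::convolve(box, rev(kernel), type = "open")[seq_len(n)]
  m <- max(abs(r))
  if (m > 0) r <- r / m
  r
}

#' Build a GLM design matrix from a run schedule
#'
#' Task predictors are event boxcars convolved with the canonical
#' double-gamma HRF (unit-peak). With \code{per_trial = FALSE} all
#' selected events share one predictor; with \code{per_trial = TRUE}
#' each event gets its own column. Optional confounds: intercept and a
#' linear trend.
#'
#' @param schedule A \code{"run_schedule"}.
#' @param conditions Conditions whose events become task predictors
#'   (default: the schedule's active task(s), \code{"MD"}/\code{"SN"}).
#' @param per_trial One predictor per event instead of one per condition.
#' @param hrf_params Optional list of \code{\link{canonical_hrf}}
#'   overrides.
#' @param intercept,linear_trend Confound flags.
#' @param events Optional explicit event data frame overriding
#'   \code{conditions}.
#' @param n Number of rows (samples); defaults to the schedule length.
#' @return A list of class \code{"design_matrix"}: \code{X} (n x p
#'   matrix), \code{names}, \code{confound_mask} (logical), \code{fs}.
#' @export
build_design <- function(schedule, conditions = c("MD", "SN"),
                         per_trial = FALSE, hrf_params = NULL,
                         intercept = TRUE, linear_trend = FALSE,
                         events = NULL, n = NULL) {
  fs <- schedule$sampling_rate
  if (is.null(n)) n <- n_samples(schedule)
  if (is.null(events)) events <- schedule_events(schedule, conditions)
  if (nrow(events) > 0 &&
      any(events$onset + events$duration > schedule$total_duration + 1e-9)) {
    stop("events extend beyond the run duration")
  }
  kernel <- hrf_kernel(fs, hrf_params)
  cols <- list(); nms <- character(0)
  if (nrow(events) == 0L) {
    flagged_empty <- TRUE
  } else {
    flagged_empty <- FALSE
    if (per_trial) {
      for (i in seq_len(nrow(events))) {
        cols[[length(cols) + 1L]] <- event_regressor(events[i, , drop = FALSE],
                                                     n, fs, kernel)
        nms <- c(nms, sprintf("%s_trial%02d", events$condition[i],
                              events$trial_index[i]))
      }
    } else {
      for (cond in unique(events$condition)) {
        ev <- events[events$condition == cond, , drop = FALSE]
        cols[[length(cols) + 1L]] <- event_regressor(ev, n, fs, kernel)
        nms <- c(nms, cond)
      }
    }
  }
  n_task <- length(cols)
  if (intercept) {
    cols[[length(cols) + 1L]] <- rep(1, n)
    nms <- c(nms, "intercept")
  }
  if (linear_trend) {
    cols[[length(cols) + 1L]] <- seq(-1, 1, length.out = n)
    nms <- c(nms, "linear_trend")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nms
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear columns among: ",
         paste(nms, collapse = ", "), ")")
  }
  structure(list(X = X, names = nms,
                 confound_mask = c(rep(FALSE, n_task),
                                   rep(TRUE, length(nms) - n_task)),
                 fs = fs, empty_task = flagged_empty),
            class = "design_matrix")
}

# Coerce a hemodynamic series (or plain matrix) to a named response
# matrix, columns "channel|chromophore".
response_matrix <- function(series) {
  if (is.matrix(series)) return(series)
  stopifnot(inherits(series, "hemo_ts"))
  d <- series$data
  Y <- cbind(d[, , "HbO", drop = TRUE], d[, , "HbR", drop = TRUE])
  colnames(Y) <- c(paste0(dimnames(d)[[2]], "|HbO"),
                   paste0(dimnames(d)[[2]], "|HbR"))
  Y
}

#' Fit an ordinary-least-squares GLM
#'
#' Plain OLS per response column (channel x chromophore); no
#' prewhitening. Residual variance is RSS divided by the residual degrees
#' of freedom.
#'
#' @param series A \code{"hemo_ts"} object or a numeric response matrix
#'   (rows = samples).
#' @param design A \code{"design_matrix"} with matching row count.
#' @return An object of class \code{"glm_fit"}: \code{betas} (p x m),
#'   \code{sigma2} (length m), \code{df}, \code{XtXinv}, \code{design}.
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- response_matrix(series)
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("design rows must equal series samples")
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("non-positive residual degrees of freedom")
  qx <- qr(X)
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  dimnames(XtXinv) <- list(design$names, design$names)
  rownames(betas) <- design$names
  structure(list(betas = betas, sigma2 = sigma2, df = df,
                 XtXinv = XtXinv, design = design),
            class = "glm_fit")
}

#' Contrast t-statistics from a GLM fit
#'
#' \code{t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)} per response column.
#'
#' @param fit A \code{"glm_fit"}.
#' @param contrast Numeric contrast vector, length = number of
#'   predictors, or a single predictor name (unit contrast on it).
#' @return A list of class \code{"contrast_result"}: \code{t},
#'   \code{effect}, \code{se} (named by response column), and
#'   \code{contrast}. Responses with zero standard error get \code{t = NA}
#'   (undefined flag).
#' @export
contrast_t <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(fit$betas)
  if (is.character(contrast)) {
    cv <- as.numeric(fit$design$names == contrast)
    if (sum(cv) != 1L) stop("unknown predictor: ", contrast)
    contrast <- cv
  }
  if (length(contrast) != p) stop("contrast length must equal predictor count")
  effect <- drop(crossprod(contrast, fit$betas))
  quad <- drop(crossprod(contrast, fit$XtXinv %*% contrast))
  se <- sqrt(fit$sigma2 * quad)
  t <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, NA_real_))
  structure(list(t = t, effect = effect, se = se, contrast = contrast,
                 df = fit$df),
            class = "contrast_result")
}

#' Event-related average
#'
#' Extracts epochs in a time window relative to each event onset,
#' anchors each epoch at its onset sample (value at onset subtracted),
#' and returns the mean and across-epoch SD traces.
#'
#' @param series A \code{"hemo_ts"}.
#' @param schedule The run's \code{"run_schedule"}.
#' @param window Two-element window in seconds relative to onset,
#'   half-open; e.g. \code{c(-5, 20)}.
#' @param conditions Event conditions to epoch on.
#' @return List with \code{time} (s), \code{mean} and \code{sd} (time x
#'   channel x chromophore arrays), \code{n_epochs}, \code{n_dropped}
#'   (epochs falling outside the run).
#' @export
event_related_average <- function(series, schedule, window = c(-5, 20),
                                  conditions = c("MD", "SN")) {
  stopifnot(inherits(series, "hemo_ts"), length(window) == 2L,
            window[2] > window[1])
  fs <- series$sampling_rate
  ev <- schedule_events(schedule, conditions)
  nt <- dim(series$data)[1]
  off <- seq(floor(window[1] * fs), ceiling(window[2] * fs) - 1L)
  epochs <- list(); dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    anchor <- floor(ev$onset[i] * fs) + 1L
    idx <- anchor + off
    if (idx[1] < 1L || idx[length(idx)] > nt) { dropped <- dropped + 1L; next }
    ep <- series$data[idx, , , drop = FALSE]
    base <- series$data[anchor, , , drop = FALSE]
    epochs[[length(epochs) + 1L]] <- sweep(ep, c(2, 3), base, "-")
  }
  if (length(epochs) == 0L) stop("no epochs fit inside the run")
  arr <- array(unlist(epochs),
               dim = c(length(off), dim(series$data)[2], dim(series$data)[3],
                       length(epochs)))
  m <- apply(arr, c(1, 2, 3), mean)
  s <- apply(arr, c(1, 2, 3), stats::sd)
  dimnames(m) <- dimnames(s) <- dimnames(series$data[seq_along(off), , ,
                                                     drop = FALSE])
  list(time = off / fs, mean = m, sd = s, n_epochs = length(epochs),
       n_dropped = dropped)
}
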