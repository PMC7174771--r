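#' Modified Beer-Lambert law constants
#'
#' Extinction coefficients, differential pathlength factors (DPF) and
#' source-detector distance used to convert optical-density changes to
#' chromophore concentration changes. Defaults: published molar
#' extinction coefficients at 760/850 nm (in 1/(mM mm)), DPF 6.0 at both
#' wavelengths, 30 mm separation.
#'
#' @param extinction 2 x 2 matrix, rows \code{c("HbO", "HbR")}, columns
#'   the wavelengths (as character, nm); units 1/(mM mm).
#' @param dpf Named numeric, DPF per wavelength.
#' @param distance Source-detector distance, mm.
#' @return A list of class \code{"mbll_parameters"}.
#' @export
mbll_parameters <- function(extinction = matrix(c(0.0586, 0.1548,
                                                  0.1058, 0.0691),
                                                nrow = 2,
                                                dimnames = list(
                                                  c("HbO", "HbR"),
                                                  c("760", "850"))),
                            dpf = c(`760` = 6.0, `850` = 6.0),
                            distance = 30) {
  stopifnot(nrow(extinction) == 2L, ncol(extinction) == 2L,
            all(rownames(extinction) == c("HbO", "HbR")),
            distance > 0, all(dpf > 0),
            identical(sort(names(dpf)), sort(colnames(extinction))))
  if (abs(det(t(extinction))) < 1e-12) {
    stop("extinction matrix is singular; chromophores cannot be separated")
  }
  structure(list(extinction = extinction, dpf = dpf, distance = distance),
            class = "mbll_parameters")
}

#' Convert raw intensities to optical-density changes
#'
#' \code{dOD(t) = -log10(I(t) / I_ref)} per channel and wavelength.
#' The reference intensity is the whole-run temporal mean
#' (\code{"mean"}, the conventional choice), the baseline intensities
#' stored by the simulator (\code{"stored"}), or the mean over the first
#' \code{baseline_seconds} of the run (\code{"baseline_window"}).
#'
#' @param raw A \code{"nirs_recording"} (strictly positive intensities,
#'   validated at construction).
#' @param reference Referencing mode, see above.
#' @param baseline_seconds Window length for
#'   \code{reference = "baseline_window"}.
#' @return A list of class \code{"od_series"}: \code{data} (time x
#'   channel x wavelength, dimensionless), \code{reference_intensity}
#'   (channel x wavelength), \code{sampling_rate}, \code{wavelengths}.
#' @export
intensity_to_od <- function(raw, reference = c("mean", "stored",
                                               "baseline_window"),
                            baseline_seconds = 5) {
  stopifnot(inherits(raw, "nirs_recording"))
  reference <- match.arg(reference)
  d <- raw$data
  ref <- switch(reference,
    mean = apply(d, c(2, 3), mean),
    stored = {
      if (is.null(raw$reference)) {
        stop("recording carries no stored reference intensities")
      }
      raw$reference
    },
    baseline_window = {
      nb <- max(1L, round(baseline_seconds * raw$sampling_rate))
      apply(d[seq_len(min(nb, dim(d)[1])), , , drop = FALSE], c(2, 3), mean)
    })
  od <- array(NA_real_, dim = dim(d), dimnames = dimnames(d))
  for (j in seq_len(dim(d)[3])) {
    od[, , j] <- -log10(sweep(d[, , j, drop = FALSE], 2, ref[, j], "/"))
  }
  structure(list(data = od, reference_intensity = ref,
                 sampling_rate = raw$sampling_rate,
                 wavelengths = raw$wavelengths),
            class = "od_series")
}

#' Convert optical densities to hemoglobin concentration changes
#'
#' Per channel and time point, solves the 2 x 2 modified Beer-Lambert
#' system \code{dOD_lambda = (eps_HbO,lambda dHbO + eps_HbR,lambda dHbR)
#' * d * DPF_lambda} for \code{(dHbO, dHbR)}.
#'
#' @param od An \code{"od_series"} with both wavelengths.
#' @param params An \code{\link{mbll_parameters}} object.
#' @return A \code{"hemo_ts"} in uM.
#' @export
od_to_hemo <- function(od, params = mbll_parameters()) {
  stopifnot(inherits(od, "od_series"), inherits(params, "mbll_parameters"))
  wl <- as.character(od$wavelengths)
  if (!all(wl %in% colnames(params$extinction))) {
    stop("extinction table lacks wavelength(s): ",
         paste(setdiff(wl, colnames(params$extinction)), collapse = ", "))
  }
  # M[lambda, chromophore] in OD per mM
  M <- t(params$extinction[, wl, drop = FALSE]) *
    params$distance * params$dpf[wl]
  Minv <- solve(M)
  n <- dim(od$data)[1]; nch <- dim(od$data)[2]
  dat <- array(NA_real_, dim = c(n, nch, 2L),
               dimnames = list(NULL, dimnames(od$data)[[2]],
                               c("HbO", "HbR")))
  # concentrations in mM -> uM
  dat[, , "HbO"] <- (od$data[, , 1] * Minv[1, 1] +
                       od$data[, , 2] * Minv[1, 2]) * 1e3
  dat[, , "HbR"] <- (od$data[, , 1] * Minv[2, 1] +
                       od$data[, , 2] * Minv[2, 2]) * 1e3
  hemo_ts(dat, od$sampling_rate)
}

# Least-squares line removal per column of a matrix.
detrend_matrix <- function(Y) {
  n <- nrow(Y)
  t <- seq_len(n) - (n + 1) / 2           # centered time
  slope <- crossprod(t, Y) / sum(t * t)
  Y - outer(t, drop(slope)) - rep(colMeans(Y), each = n)
}

#' Remove the linear trend from a hemodynamic series
#'
#' Per channel and chromophore, subtracts the least-squares line; output
#' has (numerically) zero mean and zero linear trend.
#'
#' @param series A \code{"hemo_ts"} with at least 3 samples.
#' @return The detrended \code{"hemo_ts"}.
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "hemo_ts"), dim(series$data)[1] >= 3L)
  d <- series$data
  Y <- matrix(d, nrow = dim(d)[1])
  series$data[] <- detrend_matrix(Y)
  series
}

# One zero-phase boxcar running-mean pass with reflection padding,
# O(n) via cumulative sums. Window w >= 1; centered (half-sample shift
# for even w).
boxcar_pass <- function(Y, w) {
  n <- nrow(Y)
  if (w <= 1L) return(Y)
  lpad <- ceiling((w - 1) / 2); rpad <- floor((w - 1) / 2)
  idx <- c(rev(seq_len(lpad) + 1L), seq_len(n),
           n - seq_len(rpad))                       # reflection
  P <- Y[idx, , drop = FALSE]
  S <- apply(P, 2, cumsum)
  S <- rbind(0, S)
  (S[(w + 1):(nrow(S)), , drop = FALSE] -
      S[1:(nrow(S) - w), , drop = FALSE]) / w
}

boxcar_smooth <- function(Y, w, passes) {
  for (i in seq_len(passes)) Y <- boxcar_pass(Y, w)
  Y
}

#' Moving-average band filtering
#'
#' The paper-style "moving average" band filter: the low-pass is a
#' centered boxcar running mean of length \code{round(fs / low_cut)}
#' applied \code{low_order} times (reflection padding, zero phase); the
#' high-pass is the identity minus the analogous running mean at
#' \code{high_cut} applied \code{high_order} times. Low-pass is applied
#' first, then the high-pass. Defaults: 0.3 Hz / order 2 low-pass and
#' 0.01 Hz / order 1 high-pass.
#'
#' @param series A \code{"hemo_ts"}.
#' @param low_cut,low_order Low-pass cutoff (Hz) and number of passes.
#' @param high_cut,high_order High-pass cutoff (Hz) and number of passes.
#' @return The filtered \code{"hemo_ts"} (same length and channels).
#' @export
moving_average_bandpass <- function(series, low_cut = 0.3, low_order = 2,
                                    high_cut = 0.01, high_order = 1) {
  stopifnot(inherits(series, "hemo_ts"))
  fs <- series$sampling_rate
  if (!(high_cut > 0 && high_cut < low_cut && low_cut < fs / 2)) {
    stop("require 0 < high_cut < low_cut < fs/2")
  }
  n <- dim(series$data)[1]
  w_lo <- max(1L, round(fs / low_cut))
  w_hi <- max(1L, round(fs / high_cut))
  if (max(w_lo, w_hi) > n) {
    stop(sprintf("filter window (%d samples) exceeds series length (%d)",
                 max(w_lo, w_hi), n))
  }
  Y <- matrix(series$data, nrow = n)
  Y <- boxcar_smooth(Y, w_lo, low_order)
  Y <- Y - boxcar_smooth(Y, w_hi, high_order)
  series$data[] <- Y
  series
}

#' Standard preprocessing chain
#'
#' Raw intensities to filtered hemoglobin concentration changes:
#' optical-density conversion, modified Beer-Lambert inversion, linear
#' detrending, moving-average band filtering.
#'
#' @param raw A \code{"nirs_recording"}.
#' @param params \code{\link{mbll_parameters}}.
#' @param reference Optical-density referencing mode (see
#'   \code{\link{intensity_to_od}}).
#' @param low_cut,low_order,high_cut,high_order Filter settings (see
#'   \code{\link{moving_average_bandpass}}).
#' @return A preprocessed \code{"hemo_ts"}.
#' @export
preprocess_recording <- function(raw, params = mbll_parameters(),
                                 reference = "mean",
                                 low_cut = 0.3, low_order = 2,
                                 high_cut = 0.01, high_order = 1) {
  hemo <- od_to_hemo(intensity_to_od(raw, reference = reference), params)
  hemo <- detrend_linear(hemo)
  moving_average_bandpass(hemo, low_cut = low_cut, low_order = low_order,
                          high_cut = high_cut, high_order = high_order)
}
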