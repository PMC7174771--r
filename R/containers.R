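#' Hemodynamic time series container
#'
#' Concentration-change series (micromolar, uM) of oxygenated (HbO) and
#' deoxygenated (HbR) hemoglobin, time x channel x chromophore.
#'
#' @param data Numeric array \code{[time, channel, 2]} with third
#'   dimension named \code{c("HbO", "HbR")}, or a time x channel matrix
#'   to be replicated into both chromophores.
#' @param sampling_rate Sampling rate, Hz.
#' @param channel_names Channel names (used if \code{data} lacks
#'   dimnames).
#' @return An object of class \code{"hemo_ts"}.
#' @export
hemo_ts <- function(data, sampling_rate, channel_names = NULL) {
  stopifnot(sampling_rate > 0)
  if (is.matrix(data)) {
    data <- array(rep(data, 2L), dim = c(dim(data), 2L))
  }
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == 2L)
  if (is.null(dimnames(data)[[2]])) {
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(dim(data)[2]))
    }
    dimnames(data) <- list(NULL, channel_names, c("HbO", "HbR"))
  }
  if (is.null(dimnames(data)[[3]])) dimnames(data)[[3]] <- c("HbO", "HbR")
  if (any(!is.finite(data))) stop("hemo_ts requires finite values")
  structure(list(data = data, sampling_rate = sampling_rate),
            class = "hemo_ts")
}

#' @export
print.hemo_ts <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hemo_ts: %d samples x %d channels x HbO/HbR @ %g Hz (%.1f s)\n",
              d[1], d[2], x$sampling_rate, d[1] / x$sampling_rate))
  invisible(x)
}

#' Raw dual-wavelength intensity recording
#'
#' Light intensities (arbitrary units), time x channel x wavelength.
#'
#' @param data Numeric array \code{[time, channel, n_wavelengths]},
#'   strictly positive.
#' @param sampling_rate Sampling rate, Hz.
#' @param wavelengths Wavelengths in nm (default \code{c(760, 850)}).
#' @param channel_names Channel names.
#' @param reference Optional channel x wavelength matrix of baseline
#'   intensities (stored by the simulator; used for exact optical-density
#'   referencing).
#' @return An object of class \code{"nirs_recording"}.
#' @export
nirs_recording <- function(data, sampling_rate, wavelengths = c(760, 850),
                           channel_names = NULL, reference = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(wavelengths),
            sampling_rate > 0)
  if (any(data <= 0)) {
    bad <- which(data <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at sample %d, channel %d, wavelength %g nm",
                 bad[1], bad[2], wavelengths[bad[3]]))
  }
  if (is.null(dimnames(data)[[2]])) {
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(dim(data)[2]))
    }
    dimnames(data) <- list(NULL, channel_names, paste0("wl", wavelengths))
  }
  structure(list(data = data, sampling_rate = sampling_rate,
                 wavelengths = wavelengths, reference = reference),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("nirs_recording: %d samples x %d channels x {%s} nm @ %g Hz\n",
              d[1], d[2], paste(x$wavelengths, collapse = ", "),
              x$sampling_rate))
  invisible(x)
}

#' Channel names of a recording or hemodynamic series
#' @param x A \code{"nirs_recording"} or \code{"hemo_ts"}.
#' @return Character vector.
#' @export
channel_names <- function(x) dimnames(x$data)[[2]]
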