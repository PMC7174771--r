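#' Channel-wise coefficient of variation (CV%)
#'
#' Signal-quality index computed on the unfiltered raw wavelength data:
#' \code{CV\% = 100 * sd(I) / mean(I)} per channel and wavelength over
#' the whole run (sample SD, n-1 denominator). Channels whose mean
#' intensity is not strictly positive are flagged invalid
#' (\code{CV = Inf}).
#'
#' @param raw A \code{"nirs_recording"} of raw (pre-preprocessing)
#'   intensities.
#' @return A channel x wavelength matrix of CV percentages.
#' @export
channel_cv_percent <- function(raw) {
  stopifnot(inherits(raw, "nirs_recording"))
  m <- apply(raw$data, c(2, 3), mean)
  s <- apply(raw$data, c(2, 3), stats::sd)
  cv <- ifelse(m > 0, 100 * s / m, Inf)
  dimnames(cv) <- list(channel_names(raw), as.character(raw$wavelengths))
  cv
}

#' Exclude channels by the CV% criterion
#'
#' A channel is excluded when its CV% exceeds the threshold for any
#' (wavelength, run) combination among the supplied runs — conventionally
#' the two block-1 localizer runs. The comparison is strictly greater:
#' CV exactly at the threshold survives.
#'
#' @param cv_tables Named list of channel x wavelength CV matrices, one
#'   per run (both block-1 localizers).
#' @param threshold CV% threshold (default 15).
#' @return Character vector of excluded channel names (possibly empty).
#' @export
exclude_channels_by_cv <- function(cv_tables, threshold = 15) {
  if (!is.list(cv_tables) || length(cv_tables) < 1L) {
    stop("cv_tables must be a non-empty list of CV matrices")
  }
  chans <- rownames(cv_tables[[1]])
  bad <- rep(FALSE, length(chans))
  for (cv in cv_tables) {
    if (!identical(rownames(cv), chans) || ncol(cv) < 2L) {
      stop("each CV table must cover the same channels and both wavelengths")
    }
    bad <- bad | apply(cv > threshold, 1, any)
  }
  chans[bad]
}

# Per-feature rating maxima. The printed constraints are a 0-4 scale per
# feature and a total maximum of 21; this split across the seven features
# is a reconstruction (configurable everywhere it is used).
#' Default per-feature maxima of the fNIRS suitability questionnaire
#' @return Named integer vector summing to 21.
#' @export
suitability_feature_maxima <- function() {
  c(hair_length = 3L, hair_color = 4L, hair_thickness = 3L,
    hair_density = 3L, hair_structure = 2L, skin_color = 3L,
    head_size = 3L)
}

#' Score the fNIRS suitability questionnaire
#'
#' Seven physical features (hair length/color/thickness/density/
#' structure, skin color, head size) are each rated from 0 (desirable
#' for fNIRS) up to a feature-specific maximum (undesirable); the total
#' score is their sum, at most 21. Higher totals indicate participants
#' less suited to optical recording.
#'
#' @param ratings Named integer vector covering all seven features.
#' @param maxima Named per-feature maxima (default
#'   \code{\link{suitability_feature_maxima}}).
#' @return A list of class \code{"suitability_record"}: \code{ratings},
#'   \code{total}, \code{max_total}.
#' @export
score_suitability <- function(ratings, maxima = suitability_feature_maxima()) {
  missing <- setdiff(names(maxima), names(ratings))
  if (length(missing) > 0L) {
    stop("missing rating(s) for: ", paste(missing, collapse = ", "))
  }
  ratings <- ratings[names(maxima)]
  bad <- ratings < 0 | ratings > maxima
  if (any(bad)) {
    stop("rating out of range for: ",
         paste(names(maxima)[bad], collapse = ", "))
  }
  structure(list(ratings = ratings, total = sum(ratings),
                 max_total = sum(maxima)),
            class = "suitability_record")
}

#' Correlate suitability scores with signal quality
#'
#' One-tailed Pearson correlation between per-participant questionnaire
#' totals and the number of channels passing the CV% criterion, testing
#' the directional hypothesis that less suitable participants (higher
#' score) have fewer good channels (negative correlation).
#'
#' @param scores Numeric vector of suitability totals.
#' @param good_channel_counts Numeric vector of good-channel counts,
#'   same length (>= 3 pairs).
#' @return List with \code{r}, \code{p} (one-tailed, alternative
#'   "less"), \code{n}, and \code{undefined} (TRUE when either variable
#'   has zero variance, in which case r and p are NA).
#' @export
correlate_suitability_with_snr <- function(scores, good_channel_counts) {
  stopifnot(length(scores) == length(good_channel_counts),
            length(scores) >= 3L)
  if (stats::sd(scores) == 0 || stats::sd(good_channel_counts) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(scores),
                undefined = TRUE))
  }
  ct <- stats::cor.test(scores, good_channel_counts,
                        alternative = "less", method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores),
       undefined = FALSE)
}
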