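#' Optode specification
#'
#' An optode is a light source or detector placed on the scalp at a
#' 10-20/10-10 position. A channel is formed by a unique source-detector
#' pair.
#'
#' @param label Position name in the international 10-20/10-10 system
#'   (e.g. \code{"FC3"}).
#' @param role Either \code{"source"} or \code{"detector"}.
#' @return A list of class \code{"optode"} with fields \code{label} and
#'   \code{role}.
#' @export
optode <- function(label, role = c("source", "detector")) {
  role <- match.arg(role)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(label = label, role = role), class = "optode")
}

#' Form all source-detector channels
#'
#' Exhaustively pairs every source with every detector; a montage with
#' \code{S} sources and \code{D} detectors therefore yields \code{S * D}
#' channels before any exclusion (3 sources x 6 detectors = 18 in the
#' reference montage).
#'
#' @param sources Character vector of source optode labels.
#' @param detectors Character vector of detector optode labels.
#' @return A data frame with one row per channel: \code{source},
#'   \code{detector}, \code{name} (\code{"SRC-DET"}), \code{included}
#'   (all \code{TRUE}), \code{reason} (\code{NA}).
#' @export
build_channels <- function(sources, detectors) {
  stopifnot(length(sources) >= 1L, length(detectors) >= 1L)
  labels <- c(sources, detectors)
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L) {
    stop("duplicate optode label(s): ", paste(unique(dup), collapse = ", "))
  }
  grid <- expand.grid(detector = detectors, source = sources,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # order by source (outer) then detector, the canonical channel order
  data.frame(
    source = grid$source,
    detector = grid$detector,
    name = paste0(grid$source, "-", grid$detector),
    included = TRUE,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Construct a montage
#'
#' @param sources,detectors Character vectors of optode labels.
#' @param cap_size Cap circumference in cm.
#' @return An object of class \code{"fnirs_montage"}: list with
#'   \code{optodes} (data frame label/role), \code{channels} (see
#'   \code{\link{build_channels}}) and \code{cap_size}.
#' @export
make_montage <- function(sources, detectors, cap_size = 56) {
  channels <- build_channels(sources, detectors)
  optodes <- data.frame(
    label = c(sources, detectors),
    role = rep(c("source", "detector"), c(length(sources), length(detectors))),
    stringsAsFactors = FALSE
  )
  structure(list(optodes = optodes, channels = channels, cap_size = cap_size),
            class = "fnirs_montage")
}

#' The reference 9-optode fronto-parietal montage
#'
#' Three sources (FC3, C3, CP3) and six detectors (FC5, C5, CP5, FC1, C1,
#' CP1) over left fronto-parietal cortex, giving 18 channels. The four
#' diagonal pairs whose separation exceeds 60 mm in the largest cap
#' (FC3-CP1, FC3-CP5, CP3-FC1, CP3-FC5) are flagged excluded by default,
#' leaving the 14 analyzed channels.
#'
#' @param exclude_long If \code{TRUE} (default) flag the four
#'   long-separation channels as excluded.
#' @param cap_size Cap circumference in cm.
#' @return An \code{"fnirs_montage"} object.
#' @export
standard_montage <- function(exclude_long = TRUE, cap_size = 56) {
  m <- make_montage(sources = c("FC3", "C3", "CP3"),
                    detectors = c("FC5", "C5", "CP5", "FC1", "C1", "CP1"),
                    cap_size = cap_size)
  if (exclude_long) {
    m <- exclude_channels(m, long_separation_channels())
  }
  m
}

#' Names of the long-separation channels in the reference montage
#' @return Character vector of four channel names.
#' @export
long_separation_channels <- function() {
  c("FC3-CP1", "FC3-CP5", "CP3-FC1", "CP3-FC5")
}

#' Flag channels as excluded
#'
#' @param montage An \code{"fnirs_montage"} object.
#' @param names Channel names (\code{"SRC-DET"}) to exclude. An empty
#'   vector returns the montage unchanged.
#' @param reason Reason tag stored on the excluded channels.
#' @return The montage with the named channels flagged
#'   \code{included = FALSE}.
#' @export
exclude_channels <- function(montage, names, reason = "long-separation") {
  stopifnot(inherits(montage, "fnirs_montage"))
  if (length(names) == 0L) return(montage)
  unknown <- setdiff(names, montage$channels$name)
  if (length(unknown) > 0L) {
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  }
  hit <- montage$channels$name %in% names
  montage$channels$included[hit] <- FALSE
  montage$channels$reason[hit] <- reason
  montage
}

#' Exclude channels by source-detector distance
#'
#' Optional geometry-based exclusion for user-supplied optode
#' coordinates: channels whose source-detector separation exceeds the
#' threshold are flagged excluded. (The reference montage's exclusion is
#' name-based because per-cap optode coordinates are not standardized;
#' this mode serves montages where they are known.)
#'
#' @param montage An \code{"fnirs_montage"}.
#' @param coordinates Numeric matrix with one row per optode label
#'   (rownames) and 2 or 3 coordinate columns, in mm.
#' @param threshold Maximum acceptable separation, mm (default 60).
#' @return The montage with over-long channels flagged
#'   \code{included = FALSE}, reason \code{"long-separation"}, and a
#'   \code{nominal_distance} column filled in.
#' @export
exclude_channels_by_distance <- function(montage, coordinates,
                                         threshold = 60) {
  stopifnot(inherits(montage, "fnirs_montage"), is.matrix(coordinates))
  labs <- unique(c(montage$channels$source, montage$channels$detector))
  missing <- setdiff(labs, rownames(coordinates))
  if (length(missing) > 0L) {
    stop("no coordinates for optode(s): ", paste(missing, collapse = ", "))
  }
  d <- sqrt(rowSums((coordinates[montage$channels$source, , drop = FALSE] -
                       coordinates[montage$channels$detector, ,
                                   drop = FALSE])^2))
  montage$channels$nominal_distance <- d
  long <- d > threshold
  montage$channels$included[long] <- FALSE
  montage$channels$reason[long] <- "long-separation"
  montage
}

#' Included channel names of a montage
#' @param montage An \code{"fnirs_montage"} object.
#' @return Character vector, in canonical (source-major) order.
#' @export
included_channels <- function(montage) {
  montage$channels$name[montage$channels$included]
}

#' @export
print.fnirs_montage <- function(x, ...) {
  n_src <- sum(x$optodes$role == "source")
  n_det <- sum(x$optodes$role == "detector")
  cat(sprintf("fNIRS montage: %d sources x %d detectors, %d channels (%d included), cap %g cm\n",
              n_src, n_det, nrow(x$channels), sum(x$channels$included),
              x$cap_size))
  invisible(x)
}

#' Write / read a montage as a plain-text table
#'
#' Serializes optode labels, roles and cap size plus the channel inclusion
#' table as a TSV with a small key-value header.
#'
#' @param montage An \code{"fnirs_montage"}.
#' @param path File path.
#' @return \code{read_montage} returns an \code{"fnirs_montage"}.
#' @export
write_montage <- function(montage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cap_size=%g", montage$cap_size), con)
  writeLines(sprintf("# sources=%s",
                     paste(montage$optodes$label[montage$optodes$role == "source"],
                           collapse = ",")), con)
  writeLines(sprintf("# detectors=%s",
                     paste(montage$optodes$label[montage$optodes$role == "detector"],
                           collapse = ",")), con)
  utils::write.table(montage$channels, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  header <- readLines(path, n = 3L)
  kv <- function(key) sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="),
                                                            header, value = TRUE))
  sources <- strsplit(kv("sources"), ",")[[1]]
  detectors <- strsplit(kv("detectors"), ",")[[1]]
  m <- make_montage(sources, detectors, cap_size = as.numeric(kv("cap_size")))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(identical(sort(tab$name), sort(m$channels$name)))
  m$channels <- tab[match(m$channels$name, tab$name), , drop = FALSE]
  rownames(m$channels) <- NULL
  m$channels$reason <- as.character(m$channels$reason)
  m
}
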