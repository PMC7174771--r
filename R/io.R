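#' Write / read recordings in the package's CSV dialect
#'
#' A plain-text container for raw intensity recordings and hemodynamic
#' series: a small \code{# key=value} header (type, sampling rate,
#' wavelengths, optional stored reference intensities) followed by a
#' regular CSV whose columns are \code{"CHANNEL@wavelength"} (raw) or
#' \code{"CHANNEL|chromophore"} (hemoglobin).
#'
#' @param x A \code{"nirs_recording"} or \code{"hemo_ts"}.
#' @param path File path.
#' @return \code{read_recording} returns the typed object the file was
#'   written from.
#' @export
write_recording <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- x$data
  chs <- dimnames(d)[[2]]
  if (inherits(x, "nirs_recording")) {
    writeLines(c("# type=raw",
                 sprintf("# sampling_rate=%.10g", x$sampling_rate),
                 sprintf("# wavelengths=%s",
                         paste(x$wavelengths, collapse = ","))), con)
    if (!is.null(x$reference)) {
      for (j in seq_along(x$wavelengths)) {
        writeLines(sprintf("# reference_%g=%s", x$wavelengths[j],
                           paste(sprintf("%.17g", x$reference[, j]),
                                 collapse = ",")), con)
      }
    }
    cols <- do.call(cbind, lapply(seq_along(x$wavelengths), function(j) {
      m <- d[, , j, drop = FALSE]; dim(m) <- dim(d)[1:2]; m
    }))
    colnames(cols) <- c(outer(chs, x$wavelengths,
                              function(a, b) paste0(a, "@", b)))
  } else if (inherits(x, "hemo_ts")) {
    writeLines(c("# type=hemo",
                 sprintf("# sampling_rate=%.10g", x$sampling_rate)), con)
    cols <- cbind(d[, , "HbO"], d[, , "HbR"])
    dim(cols) <- c(dim(d)[1], 2L * length(chs))
    colnames(cols) <- c(paste0(chs, "|HbO"), paste0(chs, "|HbR"))
  } else {
    stop("x must be a nirs_recording or hemo_ts")
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), con,
                   row.names = FALSE)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path, n = 12L)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- function(key, required = TRUE) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(hit) == 0L) {
      if (required) stop("malformed recording file: missing header '", key,
                         "' in ", path)
      return(NULL)
    }
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  type <- kv("type")
  fs <- as.numeric(kv("sampling_rate"))
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(tab)
  if (type == "raw") {
    wls <- as.numeric(strsplit(kv("wavelengths"), ",")[[1]])
    parts <- strsplit(colnames(m), "@", fixed = TRUE)
    chs <- unique(vapply(parts, `[`, "", 1L))
    if (!setequal(colnames(m), c(outer(chs, wls, paste, sep = "@")))) {
      stop("malformed recording file: column set does not match a ",
           "channel x wavelength grid in ", path)
    }
    d <- array(NA_real_, dim = c(nrow(m), length(chs), length(wls)),
               dimnames = list(NULL, chs, paste0("wl", wls)))
    for (j in seq_along(wls)) {
      d[, , j] <- m[, paste0(chs, "@", wls[j])]
    }
    ref <- NULL
    refs <- lapply(wls, function(w) kv(sprintf("reference_%g", w),
                                       required = FALSE))
    if (!any(vapply(refs, is.null, TRUE))) {
      ref <- vapply(refs, function(r) as.numeric(strsplit(r, ",")[[1]]),
                    numeric(length(chs)))
      dimnames(ref) <- list(chs, wls)
    }
    nirs_recording(d, fs, wavelengths = wls, reference = ref)
  } else if (type == "hemo") {
    chs <- unique(sub("\\|(HbO|HbR)$", "", colnames(m)))
    d <- array(NA_real_, dim = c(nrow(m), length(chs), 2L),
               dimnames = list(NULL, chs, c("HbO", "HbR")))
    d[, , "HbO"] <- m[, paste0(chs, "|HbO")]
    d[, , "HbR"] <- m[, paste0(chs, "|HbR")]
    hemo_ts(d, fs)
  } else {
    stop("unknown recording type '", type, "' in ", path)
  }
}

#' Write a participant report as TSV
#'
#' One row per analysis outcome (chromophore/regime x mode), mirroring
#' the per-participant accuracy tables of the study design.
#'
#' @param report A \code{"participant_report"} from
#'   \code{\link{run_pipeline}}.
#' @param path File path.
#' @return The accuracy table, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  tab <- report$accuracy_table
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
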