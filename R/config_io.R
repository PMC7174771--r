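#' Write / read a simulation configuration as YAML
#'
#' Lossless plain-text round trip for \code{\link{simulation_config}}
#' objects: every stage of a simulated analysis is reproducible from
#' the file alone (plus the package version).
#'
#' @param config A \code{"sim_config"}.
#' @param path File path (conventionally \code{.yaml}).
#' @return \code{read_sim_config} returns the reconstructed, validated
#'   \code{"sim_config"}.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$mbll
  obj <- list(
    seed = config$seed,
    response_amplitude_hbo = config$response_amplitude_hbo,
    hbr_ratio = config$hbr_ratio,
    responsive_channels = as.list(config$responsive_channels),
    noise = config$noise,
    hrf_params = config$hrf_params,
    baseline_intensity = as.list(config$baseline_intensity),
    mbll = list(extinction = list(
                  wavelengths = colnames(p$extinction),
                  HbO = as.numeric(p$extinction["HbO", ]),
                  HbR = as.numeric(p$extinction["HbR", ])),
                dpf = as.list(p$dpf),
                distance = p$distance),
    answers = config$answers,
    sampling_rate = config$sampling_rate
  )
  yaml::write_yaml(obj, path, precision = 17)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  o <- yaml::read_yaml(path)
  ext <- matrix(c(unlist(o$mbll$extinction$HbO),
                  unlist(o$mbll$extinction$HbR)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("HbO", "HbR"),
                                unlist(o$mbll$extinction$wavelengths)))
  simulation_config(
    seed = o$seed,
    response_amplitude_hbo = o$response_amplitude_hbo,
    hbr_ratio = o$hbr_ratio,
    responsive_channels = unlist(o$responsive_channels),
    noise = o$noise,
    hrf_params = o$hrf_params,
    baseline_intensity = unlist(o$baseline_intensity),
    mbll = mbll_parameters(extinction = ext,
                           dpf = unlist(o$mbll$dpf),
                           distance = o$mbll$distance),
    answers = unlist(o$answers),
    sampling_rate = o$sampling_rate
  )
}
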