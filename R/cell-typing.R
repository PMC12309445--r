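#' Putative dopamine (DA) vs nondopamine (non-DA) cell typing
#'
#' VTA units are typed from two electrophysiological criteria: basal firing
#' rate below `da_rate_max_hz` (12 Hz) and action-potential waveform
#' duration. With the default `da_duration_rule = "ge"`, DA units are the
#' wide-waveform cells (duration >= 1.2 ms), matching the optogenetically
#' tagged DA phenotype in this literature; `"lt"` selects the opposite
#' (narrow-waveform) convention. Units without a waveform duration are
#' `untyped`.
#'
#' @param rate_hz numeric vector of basal firing rates (see [basal_rate()]).
#' @param waveform_ms numeric vector of waveform durations (ms), NA allowed.
#' @param config an [analysis_config()] carrying the typing thresholds.
#' @return character vector: `"DA"`, `"nonDA"` or `"untyped"`.
#' @examples
#' cfg <- analysis_config()
#' classify_cell_type(c(3.8, 14, 3), c(1.5, 1.5, 0.8), cfg)
#' @export
classify_cell_type <- function(rate_hz, waveform_ms,
                               config = analysis_config()) {
  stopifnot(length(rate_hz) == length(waveform_ms))
  dur_ok <- if (config$da_duration_rule == "ge")
    waveform_ms >= config$da_duration_ms
  else
    waveform_ms < config$da_duration_ms
  out <- ifelse(rate_hz < config$da_rate_max_hz & dur_ok, "DA", "nonDA")
  out[is.na(waveform_ms)] <- "untyped"
  out
}

#' Cell-type table for a session
#'
#' Computes basal rates and applies [classify_cell_type()] to the session's
#' VTA units; units from other areas are `untyped`.
#'
#' @param tensor an [align_and_bin()] result.
#' @param config an [analysis_config()].
#' @return data.frame with `unit_id`, `area`, `rate_hz`, `waveform_ms`,
#'   `cell_type`.
#' @export
cell_type_table <- function(tensor, config = analysis_config()) {
  br <- basal_rate(tensor)
  u <- tensor$units[match(br$unit_id, tensor$units$unit_id), ]
  ct <- classify_cell_type(br$rate_hz, u$waveform_ms, config)
  ct[u$area != "VTA"] <- "untyped"
  data.frame(unit_id = br$unit_id, area = u$area, rate_hz = br$rate_hz,
             waveform_ms = u$waveform_ms, cell_type = ct,
             stringsAsFactors = FALSE, row.names = NULL)
}
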