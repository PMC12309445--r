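#' Peri-event bin grid
#'
#' The analysis grid spans -1 s to +4 s around cue onset, divided into
#' half-open 50 ms bins: bin \eqn{b} covers
#' \eqn{[t_{start} + (b-1)\,w,\ t_{start} + b\,w)}. With the defaults this
#' gives 100 bins and places cue onset at the left edge of bin 21.
#'
#' @param t_start window start relative to cue onset (s).
#' @param t_end window end relative to cue onset (s).
#' @param bin_width bin width (s); must divide the window length.
#' @return An object of class `bin_grid`: list with `t_start`, `t_end`,
#'   `bin_width`, `n_bins` and the vector of `breaks`.
#' @examples
#' g <- bin_grid()
#' g$n_bins            # 100
#' bin_index(g, 0)     # cue onset falls in bin 21
#' @export
bin_grid <- function(t_start = -1, t_end = 4, bin_width = 0.05) {
  stopifnot(t_end > t_start, bin_width > 0)
  n <- (t_end - t_start) / bin_width
  if (abs(n - round(n)) > 1e-9)
    stop("bin_width must divide the window length exactly")
  n <- as.integer(round(n))
  structure(
    list(t_start = t_start, t_end = t_end, bin_width = bin_width,
         n_bins = n, breaks = t_start + bin_width * (0:n)),
    class = "bin_grid"
  )
}

#' @rdname bin_grid
#' @param grid a `bin_grid`.
#' @param t_rel time(s) relative to cue onset (s).
#' @return `bin_index()`: integer bin index (1-based), `NA` outside the grid.
#' @export
bin_index <- function(grid, t_rel) {
  # the small epsilon guards against 1/0.05-style floating-point error at
  # bin edges (a spike at exactly a bin's left edge belongs to that bin)
  b <- floor((t_rel - grid$t_start) / grid$bin_width + 1e-9) + 1L
  b[t_rel < grid$t_start | t_rel >= grid$t_end] <- NA_integer_
  as.integer(b)
}

#' Bins fully covered by a time interval
#'
#' Returns the indices of all grid bins lying entirely inside the half-open
#' interval `[from, to)`. Used to map epoch and baseline windows onto the
#' 50 ms grid.
#'
#' @param grid a [bin_grid()].
#' @param from,to interval bounds in seconds relative to cue onset.
#' @return integer vector of bin indices.
#' @export
bins_in_interval <- function(grid, from, to) {
  lo <- grid$breaks[-length(grid$breaks)]
  hi <- grid$breaks[-1]
  which(lo >= from - 1e-9 & hi <= to + 1e-9)
}

#' Task epoch definitions
#'
#' Three analysis epochs are defined relative to cue onset: a rapid tone
#' response (`ToneR`, 0--0.4 s), a sustained tone response (`ToneS`,
#' 0.5--3 s) and the lever-presentation response (`Lever`, 3--3.4 s; the
#' lever extends 3 s after tone onset). `ToneR` and `ToneS` are referenced
#' to the pre-cue baseline (-1--0 s); `Lever` is referenced to the late-tone
#' baseline (2--3 s). `m` is the minimum number of significant 200 ms
#' sliding windows required to call a unit responsive in that epoch.
#'
#' @return Named list of epoch specs, each with `name`, `analysis`
#'   (c(from, to)), `baseline` (c(from, to)) and `m`.
#' @export
epoch_specs <- function() {
  list(
    ToneR = list(name = "ToneR", analysis = c(0, 0.4),  baseline = c(-1, 0), m = 1L),
    ToneS = list(name = "ToneS", analysis = c(0.5, 3),  baseline = c(-1, 0), m = 6L),
    Lever = list(name = "Lever", analysis = c(3, 3.4),  baseline = c(2, 3),  m = 1L)
  )
}

#' Analysis configuration
#'
#' Central container for every tunable of the pipeline. Defaults implement
#' the standard analysis: 50 ms bins on -1..+4 s, 200 ms sliding windows
#' advancing in 50 ms steps, |z| > 2 responsiveness, putative-DA typing at
#' < 12 Hz and waveform duration >= 1.2 ms, 10 label-shuffle replicates for
#' the auROC null, and a LASSO decoder with 100 repeated 80/20 splits,
#' 5-fold cross-validation and top-10 feature refits.
#'
#' @param grid a [bin_grid()].
#' @param window_bins width of the sliding window in bins (4 = 200 ms).
#' @param z_threshold responsiveness/selectivity threshold on |z|.
#' @param z_mode `"baseline"` (mean/SD from the epoch's baseline bins of the
#'   trial-averaged trace; default) or `"full_trace"` (mean/SD over all bins).
#' @param sd_type `"population"` (divide by n; default) or `"sample"`.
#' @param include_omissions keep omission trials in neural averages (default
#'   TRUE; the classification uses cue identity, not the response).
#' @param epochs epoch definitions, see [epoch_specs()].
#' @param ambiguous_responsive count units meeting both the activated and the
#'   inhibited criterion with equal window counts as responsive in totals
#'   (default FALSE: reported separately, excluded from both columns).
#' @param da_rate_max_hz,da_duration_ms,da_duration_rule putative-dopamine
#'   typing thresholds; `da_duration_rule = "ge"` labels wide waveforms
#'   (duration >= threshold) as DA, `"lt"` the opposite convention.
#' @param n_shuffles label-shuffle replicates for the auROC null.
#' @param decoder list of decoder settings: `n_repeats`, `train_frac`,
#'   `top_k`, `n_folds`, `n_lambda`, `accuracy_mode` (`"epoch"`,
#'   `"top_k_refit"` or `"global"`; see [repeated_decoding()]),
#'   `tone_bins`, `lever_bins`.
#' @param seed master random seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(grid = bin_grid(),
                            window_bins = 4L,
                            z_threshold = 2,
                            z_mode = c("baseline", "full_trace"),
                            sd_type = c("population", "sample"),
                            include_omissions = TRUE,
                            epochs = epoch_specs(),
                            ambiguous_responsive = FALSE,
                            da_rate_max_hz = 12,
                            da_duration_ms = 1.2,
                            da_duration_rule = c("ge", "lt"),
                            n_shuffles = 10L,
                            decoder = list(),
                            seed = 1L) {
  z_mode <- match.arg(z_mode)
  sd_type <- match.arg(sd_type)
  da_duration_rule <- match.arg(da_duration_rule)
  stopifnot(z_threshold > 0, da_rate_max_hz > 0, da_duration_ms > 0,
            window_bins >= 1, n_shuffles >= 1)
  dec <- utils::modifyList(
    list(n_repeats = 100L, train_frac = 0.8, top_k = 10L, n_folds = 5L,
         n_lambda = 30L, accuracy_mode = "epoch",
         tone_bins = bins_in_interval(grid, 0, 3),
         lever_bins = bins_in_interval(grid, 3, 4)),
    decoder)
  stopifnot(dec$train_frac > 0, dec$train_frac < 1, dec$n_folds >= 2)
  structure(
    list(grid = grid, window_bins = as.integer(window_bins),
         z_threshold = z_threshold, z_mode = z_mode, sd_type = sd_type,
         include_omissions = include_omissions, epochs = epochs,
         ambiguous_responsive = ambiguous_responsive,
         da_rate_max_hz = da_rate_max_hz, da_duration_ms = da_duration_ms,
         da_duration_rule = da_duration_rule,
         n_shuffles = as.integer(n_shuffles), decoder = dec,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}
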