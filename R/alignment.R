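#' Align spikes to cue onset and bin on the peri-event grid
#'
#' For every unit and retained trial, counts spikes falling in each
#' half-open 50 ms bin of the -1..+4 s grid around cue onset. A spike at
#' exactly `cue_onset` lands in the first post-cue bin; a spike at exactly
#' `cue_onset + 4` is outside the window.
#'
#' @param bundle a [session_bundle()].
#' @param config an [analysis_config()]; `config$include_omissions` controls
#'   whether omission trials are retained.
#' @return An object of class `aligned_tensor`: list with `counts`
#'   (3-d array unit x trial x bin), `units` (the bundle's unit table),
#'   `trials` (retained trials) and `grid`.
#' @export
align_and_bin <- function(bundle, config = analysis_config()) {
  grid <- config$grid
  tr <- bundle$trials
  if (!config$include_omissions) tr <- tr[!tr$omission, , drop = FALSE]
  n_tr <- nrow(tr)
  uids <- bundle$units$unit_id
  counts <- array(0L, dim = c(length(uids), n_tr, grid$n_bins),
                  dimnames = list(uids, NULL, NULL))
  # trial windows around successive cues do not overlap when cues are spaced
  # by more than the window length; then each spike maps to at most one trial
  # and the whole unit can be binned in one vectorized pass
  disjoint <- n_tr == 1 ||
    min(diff(tr$cue_onset_s)) > (grid$t_end - grid$t_start)
  for (i in seq_along(uids)) {
    st <- bundle$spikes[[uids[i]]]
    if (!length(st)) next
    if (disjoint) {
      j <- findInterval(st, tr$cue_onset_s + grid$t_start)
      ok <- j >= 1L & st < tr$cue_onset_s[pmax(j, 1L)] + grid$t_end
      if (any(ok)) {
        b <- bin_index(grid, st[ok] - tr$cue_onset_s[j[ok]])
        lin <- (j[ok] - 1L) * grid$n_bins + b
        counts[i, , ] <- matrix(tabulate(lin, nbins = n_tr * grid$n_bins),
                                nrow = n_tr, byrow = TRUE)
      }
    } else {
      for (t in seq_len(n_tr)) {
        rel <- st - tr$cue_onset_s[t]
        rel <- rel[rel >= grid$t_start & rel < grid$t_end]
        if (length(rel))
          counts[i, t, ] <- counts[i, t, ] +
            tabulate(bin_index(grid, rel), nbins = grid$n_bins)
      }
    }
  }
  structure(list(counts = counts, units = bundle$units, trials = tr,
                 grid = grid),
            class = "aligned_tensor")
}

#' @export
print.aligned_tensor <- function(x, ...) {
  cat(sprintf("<aligned_tensor> %d units x %d trials x %d bins\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3]))
  invisible(x)
}

#' Per-trial firing-rate matrix of one unit
#'
#' @param tensor an [align_and_bin()] result.
#' @param unit_id unit identifier.
#' @param cue_type optional `"DSplus"`/`"DSminus"` to subset trials.
#' @return trials x bins matrix of rates in spikes/s (counts / bin width).
#' @export
unit_rates <- function(tensor, unit_id, cue_type = NULL) {
  stopifnot(unit_id %in% dimnames(tensor$counts)[[1]])
  keep <- if (is.null(cue_type)) seq_len(nrow(tensor$trials)) else
    which(tensor$trials$cue_type == cue_type)
  m <- tensor$counts[unit_id, keep, , drop = FALSE]
  matrix(m, nrow = length(keep), ncol = tensor$grid$n_bins) / tensor$grid$bin_width
}

.spread <- function(x, sd_type) {
  mu <- mean(x)
  if (sd_type == "population") sqrt(mean((x - mu)^2))
  else stats::sd(x)
}

#' Baseline-referenced z-score profile of one unit
#'
#' Averages the unit's binned rate over trials of one cue type, then
#' normalizes the trace against its own baseline: \eqn{z_b = (r_b - \mu)/\sigma}
#' with \eqn{\mu,\sigma} taken over the baseline bins of the trial-averaged
#' trace (population SD by default). Sliding-window values are means of
#' `window_bins` (default 4 = 200 ms) consecutive z values advancing one bin
#' (50 ms) at a time. With `z_mode = "full_trace"` the reference statistics
#' are taken over the whole trace instead.
#'
#' A flat baseline (\eqn{\sigma = 0}) yields a degenerate profile: `z` and
#' `windows` are NA and the unit is excluded from responsiveness
#' classification downstream.
#'
#' @param tensor an [align_and_bin()] result.
#' @param unit_id unit identifier.
#' @param cue_type `"DSplus"` or `"DSminus"`.
#' @param baseline c(from, to) baseline interval in s (default -1..0; the
#'   lever analysis re-references to 2..3 s).
#' @param config an [analysis_config()].
#' @return An object of class `z_profile`: list with `rate` (trial-averaged
#'   spikes/s per bin), `mu`, `sigma`, `z`, `windows`, `degenerate`,
#'   `n_trials`, plus identifiers.
#' @export
zscore_profile <- function(tensor, unit_id, cue_type,
                           baseline = c(-1, 0),
                           config = analysis_config()) {
  rates <- unit_rates(tensor, unit_id, cue_type)
  if (nrow(rates) == 0) stop("no trials of cue type ", cue_type)
  rate <- colMeans(rates)
  ref_bins <- if (config$z_mode == "full_trace") seq_along(rate) else
    bins_in_interval(config$grid, baseline[1], baseline[2])
  mu <- mean(rate[ref_bins])
  sigma <- .spread(rate[ref_bins], config$sd_type)
  degenerate <- !(sigma > 0)
  z <- if (degenerate) rep(NA_real_, length(rate)) else (rate - mu) / sigma
  w <- config$window_bins
  n_win <- length(z) - w + 1L
  windows <- vapply(seq_len(n_win), function(k) mean(z[k:(k + w - 1L)]),
                    numeric(1))
  structure(list(unit_id = unit_id, cue_type = cue_type, rate = rate,
                 mu = mu, sigma = sigma, z = z, windows = windows,
                 degenerate = degenerate, baseline = baseline,
                 n_trials = nrow(rates), grid = config$grid,
                 window_bins = w),
            class = "z_profile")
}

#' Basal firing rate
#'
#' Mean rate over the 1 s pre-cue baseline (-1..0 s) across all retained
#' trials, per unit.
#'
#' @param tensor an [align_and_bin()] result.
#' @return data.frame with `unit_id` and `rate_hz`.
#' @export
basal_rate <- function(tensor) {
  bl <- bins_in_interval(tensor$grid, -1, 0)
  dur <- length(bl) * tensor$grid$bin_width
  uids <- dimnames(tensor$counts)[[1]]
  rate <- vapply(uids, function(u) {
    mean(rowSums(matrix(tensor$counts[u, , bl, drop = FALSE],
                        nrow = dim(tensor$counts)[2]))) / dur
  }, numeric(1))
  data.frame(unit_id = uids, rate_hz = unname(rate),
             stringsAsFactors = FALSE)
}

#' Export per-unit z traces as a long table
#'
#' One row per unit x cue type x bin, suitable for heat-map plotting or
#' file export.
#'
#' @param tensor an [align_and_bin()] result.
#' @param config an [analysis_config()].
#' @return data.frame with `unit_id`, `cue_type`, `bin`, `time_s` (bin left
#'   edge) and `z` (NA for degenerate units).
#' @export
z_trace_table <- function(tensor, config = analysis_config()) {
  uids <- dimnames(tensor$counts)[[1]]
  grid <- config$grid
  out <- list()
  for (u in uids) for (ct in c("DSplus", "DSminus")) {
    zp <- zscore_profile(tensor, u, ct, config = config)
    out[[paste(u, ct)]] <- data.frame(
      unit_id = u, cue_type = ct, bin = seq_len(grid$n_bins),
      time_s = grid$breaks[seq_len(grid$n_bins)], z = zp$z,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
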