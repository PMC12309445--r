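# windows (of `window_bins` consecutive bins) lying entirely inside the
# epoch's analysis interval: ToneR and Lever each contain 5, ToneS 47
.epoch_window_starts <- function(grid, epoch, window_bins) {
  bins <- bins_in_interval(grid, epoch$analysis[1], epoch$analysis[2])
  starts <- bins[bins + window_bins - 1L <= max(bins)]
  starts[starts >= min(bins)]
}

#' Classify one unit's response in one epoch
#'
#' Applies the sliding-window criterion to a baseline-referenced z profile:
#' the unit is `activated` if at least `m` of the epoch's 200 ms windows
#' have mean z above the threshold, `inhibited` if at least `m` windows fall
#' below its negative. A unit meeting both criteria is labelled by the
#' direction with more significant windows; an exact tie is `ambiguous`.
#' Degenerate profiles (flat baseline) are labelled `none`.
#'
#' The caller must supply a profile referenced to the epoch's own baseline
#' (`Lever` uses 2--3 s; see [classify_responses()] which handles this).
#'
#' @param zprofile a [zscore_profile()] computed with `epoch$baseline`.
#' @param epoch one element of [epoch_specs()].
#' @param z_threshold threshold on window mean z (default 2).
#' @return data.frame row: `unit_id`, `cue_type`, `epoch`, `label`,
#'   `n_sig_pos`, `n_sig_neg`, `degenerate`.
#' @export
classify_unit_epoch <- function(zprofile, epoch, z_threshold = 2) {
  if (!isTRUE(all.equal(zprofile$baseline, epoch$baseline)) &&
      !is.null(zprofile$baseline))
    warning("z profile baseline differs from epoch baseline for unit ",
            zprofile$unit_id)
  starts <- .epoch_window_starts(zprofile$grid, epoch, zprofile$window_bins)
  if (zprofile$degenerate) {
    n_pos <- n_neg <- 0L
    label <- "none"
  } else {
    w <- zprofile$windows[starts]
    n_pos <- sum(w > z_threshold)
    n_neg <- sum(w < -z_threshold)
    act <- n_pos >= epoch$m
    inh <- n_neg >= epoch$m
    label <- if (act && inh) {
      if (n_pos > n_neg) "activated"
      else if (n_neg > n_pos) "inhibited"
      else "ambiguous"
    } else if (act) "activated" else if (inh) "inhibited" else "none"
  }
  data.frame(unit_id = zprofile$unit_id, cue_type = zprofile$cue_type,
             epoch = epoch$name, label = label,
             n_sig_pos = n_pos, n_sig_neg = n_neg,
             degenerate = zprofile$degenerate, stringsAsFactors = FALSE)
}

#' Mean z over an epoch's bins
#'
#' The per-unit population-activity measure: the arithmetic mean of the
#' baseline-referenced z trace over the epoch's analysis bins (`Lever`
#' relative to the 2--3 s baseline).
#'
#' @inheritParams classify_unit_epoch
#' @return numeric scalar (NA for degenerate profiles).
#' @export
epoch_mean_activity <- function(zprofile, epoch) {
  if (zprofile$degenerate) return(NA_real_)
  bins <- bins_in_interval(zprofile$grid, epoch$analysis[1], epoch$analysis[2])
  mean(zprofile$z[bins])
}

#' Classify every unit of a session across epochs and cue types
#'
#' Computes, per unit and cue type, the z profile against the pre-cue
#' baseline (for `ToneR`/`ToneS`) and against the late-tone baseline (for
#' `Lever`), applies [classify_unit_epoch()] to each epoch, and records the
#' epoch mean activity.
#'
#' @param tensor an [align_and_bin()] result.
#' @param config an [analysis_config()].
#' @return data.frame with one row per unit x cue type x epoch: identifiers
#'   (`unit_id`, `area`, `group`, `session`, `cue_type`, `epoch`), `label`,
#'   `n_sig_pos`, `n_sig_neg`, `degenerate` and `mean_z`.
#' @export
classify_responses <- function(tensor, config = analysis_config()) {
  uids <- dimnames(tensor$counts)[[1]]
  meta <- tensor$units[match(uids, tensor$units$unit_id),
                       c("unit_id", "area", "group", "session")]
  out <- vector("list", length(uids) * 2L)
  k <- 0L
  for (u in uids) for (ct in c("DSplus", "DSminus")) {
    zp_by_bl <- list()
    rows <- lapply(config$epochs, function(ep) {
      key <- paste(ep$baseline, collapse = ",")
      if (is.null(zp_by_bl[[key]]))
        zp_by_bl[[key]] <<- zscore_profile(tensor, u, ct,
                                           baseline = ep$baseline,
                                           config = config)
      zp <- zp_by_bl[[key]]
      r <- classify_unit_epoch(zp, ep, config$z_threshold)
      r$mean_z <- epoch_mean_activity(zp, ep)
      r
    })
    k <- k + 1L
    out[[k]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  cbind(meta[match(res$unit_id, meta$unit_id), c("area", "group", "session")],
        res, row.names = NULL)
}

#' Tabulate responsive-unit proportions
#'
#' Counts activated / inhibited / none / ambiguous units per stratum and
#' adds percentages rounded to the nearest integer. Ambiguous units (equal
#' numbers of significant windows in both directions) are reported in their
#' own column and counted in neither the activated nor the inhibited one.
#'
#' @param labels output of [classify_responses()] (rows may be pooled across
#'   sessions).
#' @param by character vector of stratification columns (default
#'   `c("area", "group", "session", "cue_type", "epoch")`).
#' @return data.frame with counts `n_activated`, `n_inhibited`, `n_none`,
#'   `n_ambiguous`, `n_total` and integer percentages `pct_activated`,
#'   `pct_inhibited` per stratum.
#' @export
proportion_summary <- function(labels,
                               by = c("area", "group", "session",
                                      "cue_type", "epoch")) {
  stopifnot(all(by %in% names(labels)))
  f <- interaction(labels[by], drop = TRUE, lex.order = TRUE)
  res <- lapply(split(labels, f), function(d) {
    n <- nrow(d)
    na <- sum(d$label == "activated")
    ni <- sum(d$label == "inhibited")
    amb <- sum(d$label == "ambiguous")
    data.frame(d[1, by, drop = FALSE],
               n_activated = na, n_inhibited = ni,
               n_none = sum(d$label == "none"), n_ambiguous = amb,
               n_total = n,
               pct_activated = as.integer(round(100 * na / n)),
               pct_inhibited = as.integer(round(100 * ni / n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
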