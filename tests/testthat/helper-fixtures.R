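# Hand-written two-unit / four-trial bundle used by the I/O tests.
make_tiny_bundle <- function() {
  trials <- data.frame(
    trial_id = 1:4,
    cue_type = c("DSplus", "DSminus", "DSplus", "DSminus"),
    cue_onset_s = c(30, 66, 102, 138),
    lever_onset_s = c(33, 69, 105, 141),
    press_time_s = c(33.9, NA, 34 + 102 - 30, 144.8),
    omission = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  units <- data.frame(
    unit_id = c("u1", "u2"), animal_id = "A1", group = "control",
    session = "day1", area = c("dmPFC", "VTA"),
    waveform_ms = c(NA, 1.4), stringsAsFactors = FALSE)
  spikes <- list(u1 = c(29.5, 30.0, 31.2, 66.4, 103.1),
                 u2 = c(30.25, 65.1, 102.0, 140.9))
  session_bundle(units, spikes, trials,
                 metadata = list(animal_id = "A1", group = "control",
                                 session = "day1"))
}

# Build an aligned_tensor directly from a trials x bins count matrix for a
# single synthetic unit (or a list of such matrices for several units).
make_tensor <- function(counts, cue_type = NULL, grid = bin_grid(),
                        area = "dmPFC") {
  if (is.matrix(counts)) counts <- list(u1 = counts)
  n_tr <- nrow(counts[[1]])
  cue_type <- cue_type %||% rep(c("DSplus", "DSminus"), length.out = n_tr)
  arr <- array(0L, dim = c(length(counts), n_tr, grid$n_bins),
               dimnames = list(names(counts), NULL, NULL))
  for (i in seq_along(counts)) arr[i, , ] <- counts[[i]]
  units <- data.frame(unit_id = names(counts), animal_id = "A1",
                      group = "control", session = "day1", area = area,
                      waveform_ms = NA_real_, stringsAsFactors = FALSE)
  trials <- data.frame(trial_id = seq_len(n_tr), cue_type = cue_type,
                       cue_onset_s = 30 + 40 * (seq_len(n_tr) - 1),
                       stringsAsFactors = FALSE)
  trials$lever_onset_s <- trials$cue_onset_s + 3
  trials$press_time_s <- NA_real_
  trials$omission <- FALSE
  structure(list(counts = arr, units = units, trials = trials, grid = grid),
            class = "aligned_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic z profile from a given z trace (windows recomputed from z).
fake_zprofile <- function(z, baseline = c(-1, 0), config = analysis_config(),
                          unit_id = "u1", cue_type = "DSplus") {
  w <- config$window_bins
  windows <- vapply(seq_len(length(z) - w + 1L),
                    function(k) mean(z[k:(k + w - 1L)]), numeric(1))
  structure(list(unit_id = unit_id, cue_type = cue_type, rate = z,
                 mu = 0, sigma = 1, z = z, windows = windows,
                 degenerate = FALSE, baseline = baseline,
                 n_trials = 2L, grid = config$grid, window_bins = w),
            class = "z_profile")
}

# --- independent oracles -------------------------------------------------

# auROC by explicit pair enumeration with 0.5 tie credit
auroc_pairs <- function(x, y) {
  s <- 0
  for (a in x) for (b in y) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x) * length(y))
}

# auROC by threshold-sweep ROC integration (trapezoid over all thresholds)
auroc_sweep <- function(x, y) {
  th <- sort(unique(c(x, y, -Inf, Inf)))
  tpr <- vapply(th, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(y >= t), numeric(1))
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities <= observed's)
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(k) stats::dhyper(k, c1, n - c1, r1), numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
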