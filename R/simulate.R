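# lognormal parameters from a target mean and SD on the natural scale
.lnorm_pars <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulation configuration for DS-task sessions
#'
#' Defines the statistical structure of a simulated animal-session:
#' inhomogeneous-Poisson units whose rate is a baseline multiplied by an
#' epoch- and cue-dependent gain. Defaults emulate the recorded populations:
#' dmPFC baseline rates lognormal around 6 Hz; VTA rates a DA/non-DA
#' mixture around 3.8 / 6.4 Hz with a bimodal waveform-duration mixture
#' (1.5 / 0.8 ms); per-epoch responsive fractions from the control
#' proportions of each area; 50 DS+ and 50 DS- trials in pseudorandom order
#' (at most 3 consecutive same-cue trials), tone 3 s before lever, 30 s
#' intertrial interval.
#'
#' Effect presets scale the activated/inhibited fractions and the response
#' gains to mimic the published group/time effect directions: `isd_day1`
#' lowers dmPFC cue-responsive fractions and gains while raising VTA ones;
#' `isd_day15` lowers both areas' gains (VTA strongly), leaving fractions
#' near control.
#'
#' @param area `"dmPFC"` or `"VTA"`.
#' @param preset `"control"`, `"isd_day1"` or `"isd_day15"`.
#' @param n_units units per animal (defaults: 35 dmPFC, 9 VTA).
#' @param n_trials_per_cue trials per cue type (default 50).
#' @param baseline_mean_hz,baseline_sd_hz baseline-rate distribution
#'   (dmPFC; for VTA the DA/non-DA mixture below is used).
#' @param da_fraction,da_mean_hz,da_sd_hz,nonda_mean_hz,nonda_sd_hz VTA
#'   mixture settings.
#' @param frac_act,frac_inh named per-epoch responsive fractions
#'   (`ToneR`, `ToneS`, `Lever`); defaults come from the preset.
#' @param gain_act,gain_inh multiplicative rate gains of activated /
#'   inhibited units during their responsive epochs (DS+ trials).
#' @param gain_scale preset multiplier applied to `gain_act - 1` (and to
#'   the inhibited depth) to move population activity up or down.
#' @param ds_contrast named per-epoch attenuation of the DS- gain:
#'   `gain_minus = 1 + (gain_plus - 1) * ds_contrast`.
#' @param gain_jitter_sdlog lognormal jitter SD applied to unit gains.
#' @param omission_p named probabilities of an omitted (no-press) trial for
#'   `DSplus` and `DSminus`.
#' @param iti_s intertrial interval (s).
#' @param pad_s spikes are generated from `-1 - pad_s` to `4 + pad_s`
#'   around each cue; no analysis reads outside that window.
#' @param seed default seed used by [simulate_session()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(area = c("dmPFC", "VTA"),
                       preset = c("control", "isd_day1", "isd_day15"),
                       n_units = NULL,
                       n_trials_per_cue = 50L,
                       baseline_mean_hz = 6, baseline_sd_hz = 4.5,
                       da_fraction = 0.75,
                       da_mean_hz = 3.8, da_sd_hz = 2.2,
                       nonda_mean_hz = 6.4, nonda_sd_hz = 4.0,
                       frac_act = NULL, frac_inh = NULL,
                       gain_act = 2.5, gain_inh = 0.2,
                       gain_scale = NULL,
                       ds_contrast = c(ToneR = 0.9, ToneS = 0.3, Lever = 0.35),
                       gain_jitter_sdlog = 0.1,
                       omission_p = c(DSplus = 0.035, DSminus = 0.73),
                       iti_s = 30, pad_s = 0.5,
                       seed = 1L) {
  area <- match.arg(area)
  preset <- match.arg(preset)
  defaults <- .sim_presets()[[preset]][[area]]
  frac_act <- frac_act %||% defaults$frac_act
  frac_inh <- frac_inh %||% defaults$frac_inh
  gain_scale <- gain_scale %||% defaults$gain_scale
  n_units <- n_units %||% if (area == "dmPFC") 35L else 9L
  stopifnot(all(frac_act >= 0), all(frac_inh >= 0),
            all(frac_act + frac_inh <= 1),
            gain_act > 0, gain_inh >= 0, gain_scale > 0,
            baseline_mean_hz > 0, n_trials_per_cue >= 1)
  structure(
    list(area = area, preset = preset, n_units = as.integer(n_units),
         n_trials_per_cue = as.integer(n_trials_per_cue),
         baseline_mean_hz = baseline_mean_hz, baseline_sd_hz = baseline_sd_hz,
         da_fraction = da_fraction, da_mean_hz = da_mean_hz,
         da_sd_hz = da_sd_hz, nonda_mean_hz = nonda_mean_hz,
         nonda_sd_hz = nonda_sd_hz,
         frac_act = frac_act, frac_inh = frac_inh,
         gain_act = gain_act, gain_inh = gain_inh, gain_scale = gain_scale,
         ds_contrast = ds_contrast, gain_jitter_sdlog = gain_jitter_sdlog,
         omission_p = omission_p, iti_s = iti_s, pad_s = pad_s,
         seed = as.integer(seed)),
    class = "sim_config")
}

# per-area, per-preset responsive fractions (DS+ trials) and gain scaling;
# control fractions follow the observed control proportions of each area,
# presets follow the published effect directions (dmPFC down at both time
# points; VTA up at day 1, down at day 15)
.sim_presets <- function() {
  list(
    control = list(
      dmPFC = list(frac_act = c(ToneR = 0.10, ToneS = 0.13, Lever = 0.11),
                   frac_inh = c(ToneR = 0.04, ToneS = 0.05, Lever = 0.08),
                   gain_scale = 1.0),
      VTA = list(frac_act = c(ToneR = 0.34, ToneS = 0.22, Lever = 0.84),
                 frac_inh = c(ToneR = 0.03, ToneS = 0.03, Lever = 0.03),
                 gain_scale = 1.0)),
    isd_day1 = list(
      dmPFC = list(frac_act = c(ToneR = 0.01, ToneS = 0.03, Lever = 0.11),
                   frac_inh = c(ToneR = 0.01, ToneS = 0.05, Lever = 0.07),
                   gain_scale = 0.7),
      VTA = list(frac_act = c(ToneR = 0.60, ToneS = 0.33, Lever = 0.74),
                 frac_inh = c(ToneR = 0.04, ToneS = 0.01, Lever = 0.09),
                 gain_scale = 1.4)),
    isd_day15 = list(
      dmPFC = list(frac_act = c(ToneR = 0.07, ToneS = 0.07, Lever = 0.09),
                   frac_inh = c(ToneR = 0.04, ToneS = 0.05, Lever = 0.07),
                   gain_scale = 0.65),
      VTA = list(frac_act = c(ToneR = 0.29, ToneS = 0.19, Lever = 0.80),
                 frac_inh = c(ToneR = 0.03, ToneS = 0.03, Lever = 0.03),
                 gain_scale = 0.6))
  )
}

# pseudorandom cue order with at most max_run consecutive same-cue trials
.pseudorandom_order <- function(n_per_cue, max_run = 3L) {
  repeat {
    left <- c(DSplus = n_per_cue, DSminus = n_per_cue)
    out <- character(2 * n_per_cue)
    run <- 0L; last <- ""
    ok <- TRUE
    for (i in seq_along(out)) {
      cand <- names(left)[left > 0]
      if (run >= max_run) cand <- setdiff(cand, last)
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1) cand else
        sample(cand, 1, prob = left[cand])
      out[i] <- pick
      run <- if (identical(pick, last)) run + 1L else 1L
      last <- pick
      left[pick] <- left[pick] - 1L
    }
    if (ok) return(out)
  }
}

#' Simulate one DS-task session
#'
#' Generates a full animal-session: pseudorandom trial schedule with 3 s
#' tone-to-lever latency, behavioral presses/omissions, and per-unit spike
#' trains drawn from a piecewise-constant-rate Poisson process (rate =
#' baseline x epoch gain, with the gain depending on the trial's cue type).
#' Ground truth (cell types, epoch response labels, gains) is returned
#' alongside the bundle.
#'
#' @param cfg a [sim_config()].
#' @param animal_id animal identifier.
#' @param group `"control"` or `"stress"` (defaults to `"control"` for the
#'   control preset, `"stress"` otherwise).
#' @param session `"day1"` or `"day15"` (defaults to the preset's day).
#' @param seed random seed (defaults to `cfg$seed`).
#' @return list with `bundle` (a validated [session_bundle()]) and `truth`
#'   (data.frame: per-unit cell type, baseline rate and per-epoch response
#'   status and DS+ gain).
#' @export
simulate_session <- function(cfg = sim_config(), animal_id = "A1",
                             group = NULL, session = NULL,
                             seed = cfg$seed) {
  group <- group %||% if (cfg$preset == "control") "control" else "stress"
  session <- session %||%
    if (cfg$preset == "isd_day15") "day15" else "day1"
  set.seed(seed)
  n_tr <- 2L * cfg$n_trials_per_cue
  cue_type <- .pseudorandom_order(cfg$n_trials_per_cue)

  # behavioral schedule: tone 3 s, lever out up to 10 s, 30 s ITI
  latency <- ifelse(cue_type == "DSplus",
                    pmin(pmax(stats::rnorm(n_tr, 0.9, 0.2), 0.2), 9.9),
                    pmin(pmax(stats::rnorm(n_tr, 3.8, 0.8), 0.5), 9.9))
  omission <- stats::runif(n_tr) < cfg$omission_p[cue_type]
  resp_dur <- ifelse(omission, 10, latency)
  cue_onset <- 30 + cumsum(c(0, (3 + resp_dur + cfg$iti_s)[-n_tr]))
  trials <- data.frame(
    trial_id = seq_len(n_tr), cue_type = cue_type,
    cue_onset_s = cue_onset, lever_onset_s = cue_onset + 3,
    press_time_s = ifelse(omission, NA_real_, cue_onset + 3 + latency),
    omission = omission, stringsAsFactors = FALSE)

  # unit identities, baseline rates, cell types, waveforms
  n_u <- cfg$n_units
  uid <- sprintf("%s_u%03d", animal_id, seq_len(n_u))
  if (cfg$area == "VTA") {
    is_da <- stats::runif(n_u) < cfg$da_fraction
    p_da <- .lnorm_pars(cfg$da_mean_hz, cfg$da_sd_hz)
    p_nd <- .lnorm_pars(cfg$nonda_mean_hz, cfg$nonda_sd_hz)
    base_hz <- ifelse(is_da,
                      stats::rlnorm(n_u, p_da$meanlog, p_da$sdlog),
                      stats::rlnorm(n_u, p_nd$meanlog, p_nd$sdlog))
    waveform <- ifelse(is_da,
                       pmax(stats::rnorm(n_u, 1.5, 0.15), 0.3),
                       pmax(stats::rnorm(n_u, 0.8, 0.10), 0.2))
    true_type <- ifelse(is_da, "DA", "nonDA")
  } else {
    p <- .lnorm_pars(cfg$baseline_mean_hz, cfg$baseline_sd_hz)
    base_hz <- stats::rlnorm(n_u, p$meanlog, p$sdlog)
    waveform <- rep(NA_real_, n_u)
    true_type <- rep("untyped", n_u)
  }

  # per-unit epoch response status and DS+ gains
  epochs <- c("ToneR", "ToneS", "Lever")
  status <- matrix("none", n_u, 3, dimnames = list(uid, epochs))
  gain <- matrix(1, n_u, 3, dimnames = list(uid, epochs))
  for (e in epochs) {
    r <- stats::runif(n_u)
    act <- r < cfg$frac_act[e]
    inh <- !act & r < cfg$frac_act[e] + cfg$frac_inh[e]
    status[act, e] <- "activated"; status[inh, e] <- "inhibited"
    jit <- stats::rlnorm(n_u, 0, cfg$gain_jitter_sdlog)
    g_act <- 1 + (cfg$gain_act - 1) * cfg$gain_scale * jit
    g_inh <- pmax(1 - (1 - cfg$gain_inh) * pmin(cfg$gain_scale, 1) * jit, 0.02)
    gain[act, e] <- g_act[act]
    gain[inh, e] <- g_inh[inh]
  }

  # spike trains: piecewise-constant-rate Poisson per trial, padded window
  segs <- rbind(c(-1 - cfg$pad_s, 0), c(0, 0.4), c(0.4, 0.5),
                c(0.5, 3), c(3, 3.4), c(3.4, 4 + cfg$pad_s))
  seg_epoch <- c(NA, "ToneR", NA, "ToneS", "Lever", NA)
  is_plus <- cue_type == "DSplus"
  spikes <- vector("list", n_u); names(spikes) <- uid
  for (i in seq_len(n_u)) {
    all_t <- numeric(0)
    for (s in seq_len(nrow(segs))) {
      len <- segs[s, 2] - segs[s, 1]
      g <- if (is.na(seg_epoch[s])) rep(1, n_tr) else {
        gp <- gain[i, seg_epoch[s]]
        gm <- 1 + (gp - 1) * cfg$ds_contrast[seg_epoch[s]]
        ifelse(is_plus, gp, gm)
      }
      n_spk <- stats::rpois(n_tr, base_hz[i] * g * len)
      if (sum(n_spk) == 0) next
      all_t <- c(all_t, rep(cue_onset, n_spk) + segs[s, 1] +
                   stats::runif(sum(n_spk)) * len)
    }
    spikes[[i]] <- unique(sort(all_t))
  }

  units <- data.frame(unit_id = uid, animal_id = animal_id, group = group,
                      session = session, area = cfg$area,
                      waveform_ms = waveform, stringsAsFactors = FALSE)
  bundle <- session_bundle(units, spikes, trials,
                           metadata = list(animal_id = animal_id,
                                           group = group, session = session,
                                           area = cfg$area,
                                           preset = cfg$preset, seed = seed))
  truth <- data.frame(unit_id = uid, cell_type = true_type,
                      baseline_hz = base_hz,
                      status_ToneR = status[, "ToneR"],
                      status_ToneS = status[, "ToneS"],
                      status_Lever = status[, "Lever"],
                      gain_ToneR = gain[, "ToneR"],
                      gain_ToneS = gain[, "ToneS"],
                      gain_Lever = gain[, "Lever"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(bundle = bundle, truth = truth)
}

#' Simulate a cohort of animals
#'
#' Independent sessions with per-animal seeds derived from the master seed.
#'
#' @param cfg a [sim_config()].
#' @param n_animals number of animals (>= 1).
#' @param group,session passed to [simulate_session()].
#' @param seed master seed; animal `i` uses `seed * 100 + i`.
#' @param animal_prefix prefix for animal identifiers.
#' @return list with `bundles` (list of session bundles) and `truths`
#'   (list of ground-truth tables).
#' @export
simulate_cohort <- function(cfg = sim_config(), n_animals = 7L,
                            group = NULL, session = NULL,
                            seed = cfg$seed, animal_prefix = "A") {
  if (n_animals < 1) stop("n_animals must be >= 1")
  sims <- lapply(seq_len(n_animals), function(i)
    simulate_session(cfg, animal_id = sprintf("%s%02d", animal_prefix, i),
                     group = group, session = session,
                     seed = seed * 100L + i))
  list(bundles = lapply(sims, `[[`, "bundle"),
       truths = lapply(sims, `[[`, "truth"))
}
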