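cfg <- analysis_config()

null_sim_config <- function(area = "dmPFC", ...) {
  sim_config(area,
             frac_act = c(ToneR = 0, ToneS = 0, Lever = 0),
             frac_inh = c(ToneR = 0, ToneS = 0, Lever = 0), ...)
}

test_that("a fixed seed reproduces the session bit-for-bit", {
  s1 <- simulate_session(sim_config("VTA", n_units = 5), seed = 19)
  s2 <- simulate_session(sim_config("VTA", n_units = 5), seed = 19)
  expect_identical(s1$bundle$spikes, s2$bundle$spikes)
  expect_identical(s1$bundle$trials, s2$bundle$trials)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_session(sim_config("VTA", n_units = 5), seed = 20)
  expect_false(identical(s1$bundle$spikes, s3$bundle$spikes))
})

test_that("sessions respect the task structure", {
  sim <- simulate_session(sim_config("dmPFC", n_units = 2), seed = 1)
  tr <- sim$bundle$trials
  expect_equal(nrow(tr), 100)
  expect_equal(sum(tr$cue_type == "DSplus"), 50)
  expect_equal(tr$lever_onset_s, tr$cue_onset_s + 3)
  expect_true(all(diff(tr$cue_onset_s) >= 33 + cfg$grid$t_start))
  expect_true(all(is.na(tr$press_time_s[tr$omission])))
  # pseudorandom constraint: never more than 3 consecutive same-cue trials
  runs <- rle(tr$cue_type)$lengths
  expect_lte(max(runs), 3)
  expect_silent(validate_session_bundle(sim$bundle))
})

test_that("window spike counts are Poisson with the configured mean", {
  # pool baseline-window counts across sessions of a single fixed-rate unit
  scfg <- null_sim_config(baseline_sd_hz = 1e-6)  # pin the rate at 6 Hz
  counts <- unlist(lapply(1:10, function(r) {
    sim <- simulate_session(scfg, seed = 300 + r)
    tensor <- align_and_bin(sim$bundle, cfg)
    rowSums(matrix(tensor$counts[1, , 1:20], nrow = 100))
  }))
  expect_length(counts, 1000)
  lambda <- 6
  # chi-square goodness of fit with the upper tail pooled
  breaks <- c(0:12, Inf)
  obs <- table(cut(counts, c(-1, breaks[-1])))
  pr <- diff(ppois(c(-1, breaks[-1]), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr,
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("null sessions produce near-zero responsive fractions", {
  scfg <- null_sim_config(n_units = 60)
  sim <- simulate_session(scfg, seed = 41)
  lab <- classify_responses(align_and_bin(sim$bundle, cfg), cfg)
  fp <- mean(lab$label != "none")
  expect_lte(fp, 0.05)
})

test_that("ground truth is consistent with the emitted bundle", {
  sim <- simulate_session(sim_config("VTA", n_units = 12), seed = 23)
  expect_equal(sim$truth$unit_id, sim$bundle$units$unit_id)
  # wide waveforms belong to DA ground truth under the default convention
  wide <- sim$bundle$units$waveform_ms >= 1.2
  expect_true(all(sim$truth$cell_type[wide & sim$truth$baseline_hz < 12] == "DA"))
  # activated units carry gains > 1, inhibited < 1
  expect_true(all(sim$truth$gain_ToneR[sim$truth$status_ToneR == "activated"] > 1))
  expect_true(all(sim$truth$gain_ToneR[sim$truth$status_ToneR == "inhibited"] < 1))
})

test_that("cohorts derive per-animal seeds and reject empty cohorts", {
  co <- simulate_cohort(sim_config("dmPFC", n_units = 3), n_animals = 3,
                        seed = 5)
  expect_length(co$bundles, 3)
  ids <- vapply(co$bundles, function(b) b$metadata$animal_id, "")
  expect_equal(anyDuplicated(ids), 0L)
  # different animals get different data
  expect_false(identical(co$bundles[[1]]$spikes, co$bundles[[2]]$spikes))
  expect_error(simulate_cohort(sim_config("dmPFC"), n_animals = 0), "n_animals")
})

test_that("stress presets move population activity in the documented directions", {
  # single-replicate sign check (the full replicate suite runs in the
  # acceptance tests): dmPFC ToneS activity lower after stress at day 1
  mean_act <- function(preset, area, seed) {
    co <- simulate_cohort(sim_config(area, preset, n_units = 15),
                          n_animals = 3, seed = seed)
    z <- unlist(lapply(co$bundles, function(b) {
      lab <- classify_responses(align_and_bin(b, cfg), cfg)
      lab$mean_z[lab$cue_type == "DSplus" & lab$epoch == "ToneS"]
    }))
    mean(z, na.rm = TRUE)
  }
  expect_lt(mean_act("isd_day1", "dmPFC", 71), mean_act("control", "dmPFC", 72))
})
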