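cfg <- analysis_config()

test_that("spikes land in the correct half-open 50 ms bins", {
  b <- make_tiny_bundle()
  # u1 spikes relative to trial cues: 29.5 -> -0.5 (trial 1), 30.0 -> 0.0,
  # 31.2 -> +1.2, 66.4 -> +0.4 (trial 2), 103.1 -> +1.1 (trial 3)
  tensor <- align_and_bin(b, cfg)
  expect_equal(bin_index(cfg$grid, 0), 21L)
  expect_equal(sum(tensor$counts["u1", 1, ]), 3)
  expect_equal(unname(tensor$counts["u1", 1, 11]), 1L)  # -0.5 s
  expect_equal(unname(tensor$counts["u1", 1, 21]), 1L)  # 0.0 s: left edge of bin 21
  expect_equal(unname(tensor$counts["u1", 1, 45]), 1L)  # +1.2 s
  expect_equal(unname(tensor$counts["u1", 2, 29]), 1L)  # +0.4 s
})

test_that("hand-placed spikes at -0.97, 0.049, 0.050 fall in bins 1, 21, 22", {
  trials <- data.frame(trial_id = 1L, cue_type = "DSplus", cue_onset_s = 100,
                       lever_onset_s = 103, press_time_s = NA_real_,
                       omission = FALSE)
  # validation needs one trial per cue type; add a distant DS- trial
  trials <- rbind(trials,
                  data.frame(trial_id = 2L, cue_type = "DSminus",
                             cue_onset_s = 200, lever_onset_s = 203,
                             press_time_s = NA_real_, omission = FALSE))
  units <- data.frame(unit_id = "u1", animal_id = "A1", group = "control",
                      session = "day1", area = "dmPFC", waveform_ms = NA_real_)
  b <- session_bundle(units, list(u1 = 100 + c(-0.97, 0.049, 0.050)), trials)
  tensor <- align_and_bin(b, cfg)
  expect_equal(which(tensor$counts["u1", 1, ] > 0), c(1L, 21L, 22L))
  expect_equal(sum(tensor$counts), 3)
})

test_that("unit with no spikes yields an all-zero tensor", {
  b <- make_tiny_bundle()
  b$spikes$u1 <- numeric(0)
  tensor <- align_and_bin(b, cfg)
  expect_true(all(tensor$counts["u1", , ] == 0))
})

test_that("binning conserves spikes and is invariant to a common time shift", {
  sim <- simulate_session(sim_config("dmPFC", n_units = 3,
                                     n_trials_per_cue = 8), seed = 3)
  b <- sim$bundle
  tensor <- align_and_bin(b, cfg)
  for (u in b$units$unit_id) {
    st <- b$spikes[[u]]
    inside <- sum(vapply(b$trials$cue_onset_s, function(c0)
      sum(st >= c0 - 1 & st < c0 + 4), numeric(1)))
    expect_equal(sum(tensor$counts[u, , ]), inside)
  }
  b2 <- b
  b2$spikes <- lapply(b$spikes, function(x) x + 5)
  b2$trials$cue_onset_s <- b$trials$cue_onset_s + 5
  b2$trials$lever_onset_s <- b$trials$lever_onset_s + 5
  b2$trials$press_time_s <- b$trials$press_time_s + 5
  expect_equal(align_and_bin(b2, cfg)$counts, tensor$counts)
})

test_that("baseline z-score matches hand arithmetic and flags flat baselines", {
  # two identical trials; baseline bins alternate 0/1 spikes -> rates 0/20 Hz,
  # mu = 10, population SD = 10; one epoch bin with 2 spikes -> 40 Hz -> z = 3
  m <- matrix(0L, nrow = 2, ncol = 100)
  m[, seq(2, 20, by = 2)] <- 1L
  m[, 25] <- 2L
  tensor <- make_tensor(m, cue_type = c("DSplus", "DSplus"))
  zp <- zscore_profile(tensor, "u1", "DSplus", config = cfg)
  expect_equal(zp$mu, 10)
  expect_equal(zp$sigma, 10)
  expect_equal(zp$z[25], 3)
  expect_false(zp$degenerate)
  expect_length(zp$windows, 97)

  flat <- make_tensor(matrix(1L, 2, 100), cue_type = c("DSplus", "DSplus"))
  zf <- zscore_profile(flat, "u1", "DSplus", config = cfg)
  expect_true(zf$degenerate)
  expect_true(all(is.na(zf$z)))
})

test_that("z is invariant to a common positive scaling of all counts", {
  set.seed(9)
  m <- matrix(rpois(400, 2), nrow = 4, ncol = 100)
  t1 <- make_tensor(m, cue_type = rep("DSplus", 4))
  t3 <- make_tensor(m * 3L, cue_type = rep("DSplus", 4))
  z1 <- zscore_profile(t1, "u1", "DSplus", config = cfg)
  z3 <- zscore_profile(t3, "u1", "DSplus", config = cfg)
  expect_equal(z1$z, z3$z, tolerance = 1e-12)
})

test_that("basal rate equals pre-cue spike count per second", {
  m <- matrix(0L, nrow = 10, ncol = 100)
  m[, 1:20] <- 0L
  for (t in 1:10) m[t, sample(1:20, 6)] <- 1L  # 6 baseline spikes per trial
  tensor <- make_tensor(m)
  expect_equal(basal_rate(tensor)$rate_hz, 6)

  silent <- make_tensor(matrix(0L, 3, 100), cue_type = rep("DSplus", 3))
  expect_equal(basal_rate(silent)$rate_hz, 0)
})

test_that("simulated baseline rate is recovered within 3 standard errors", {
  cfg_sim <- sim_config("dmPFC", n_units = 1, frac_act = c(ToneR = 0, ToneS = 0, Lever = 0),
                        frac_inh = c(ToneR = 0, ToneS = 0, Lever = 0))
  sim <- simulate_session(cfg_sim, seed = 21)
  lambda <- sim$truth$baseline_hz[1]
  tensor <- align_and_bin(sim$bundle, cfg)
  est <- basal_rate(tensor)$rate_hz[1]
  se <- sqrt(lambda / (1 * nrow(sim$bundle$trials)))  # Poisson SE over 1 s x trials
  expect_lt(abs(est - lambda), 3 * se)
})
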