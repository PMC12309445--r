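cfg <- analysis_config()
eps <- epoch_specs()

test_that("epoch windows are the 200 ms windows fully inside each epoch", {
  starts <- cuephys:::.epoch_window_starts
  expect_length(starts(cfg$grid, eps$ToneR, 4L), 5)   # 0..0.4 s
  expect_length(starts(cfg$grid, eps$ToneS, 4L), 47)  # 0.5..3 s
  expect_length(starts(cfg$grid, eps$Lever, 4L), 5)   # 3..3.4 s
  expect_equal(min(starts(cfg$grid, eps$ToneR, 4L)), 21L)
})

test_that("a single supra-threshold window activates ToneR (m = 1)", {
  # 2.4 on bins 21-24: window 21 has W = 2.4, the overlapping window 22
  # only 1.8, so exactly one significant window
  z <- rep(0, 100); z[21:24] <- 2.4
  r <- classify_unit_epoch(fake_zprofile(z), eps$ToneR, 2)
  expect_equal(r$label, "activated")
  expect_equal(r$n_sig_pos, 1L)

  r0 <- classify_unit_epoch(fake_zprofile(rep(0, 100)), eps$ToneR, 2)
  expect_equal(r0$label, "none")
})

test_that("ToneS requires at least six significant windows", {
  # z = 10 on bins 31..34+k yields window means 10, 10, ..., 7.5, 5, 2.5 so
  # k+1 of the in-epoch windows exceed 2
  z5 <- rep(0, 100); z5[31:35] <- 10   # 5 significant windows
  z6 <- rep(0, 100); z6[31:36] <- 10   # 6 significant windows
  r5 <- classify_unit_epoch(fake_zprofile(z5), eps$ToneS, 2)
  r6 <- classify_unit_epoch(fake_zprofile(z6), eps$ToneS, 2)
  expect_equal(r5$n_sig_pos, 5L)
  expect_equal(r5$label, "none")
  expect_equal(r6$n_sig_pos, 6L)
  expect_equal(r6$label, "activated")
})

test_that("mixed responses use the more-frequent direction, ties are ambiguous", {
  z <- rep(0, 100)
  z[31:34] <- 10; z[41:44] <- 10        # 2 clean positive bursts
  z[61:64] <- -10                        # 1 negative burst
  # lower ToneS m so both criteria can be met
  ep <- eps$ToneS; ep$m <- 1L
  r <- classify_unit_epoch(fake_zprofile(z), ep, 2)
  expect_equal(r$label, "activated")

  # symmetric bursts away from the epoch edges touch the same number of
  # overlapping windows in each direction
  z2 <- rep(0, 100); z2[41:44] <- 10; z2[61:64] <- -10
  r2 <- classify_unit_epoch(fake_zprofile(z2), ep, 2)
  expect_equal(r2$n_sig_pos, r2$n_sig_neg)
  expect_equal(r2$label, "ambiguous")
})

test_that("epoch mean activity averages z over the epoch's bins", {
  expect_equal(epoch_mean_activity(fake_zprofile(rep(0, 100)), eps$ToneS), 0)
  z1 <- rep(0, 100); z1[31:80] <- 1
  expect_equal(epoch_mean_activity(fake_zprofile(z1), eps$ToneS), 1)
  z2 <- rep(0, 100); z2[31:80] <- rep(c(2, 0), 25)
  expect_equal(epoch_mean_activity(fake_zprofile(z2), eps$ToneS), 1)
})

test_that("lever classification is referenced to the 2-3 s baseline", {
  # unit with a sustained plateau through 0.5-3 s and no further change at
  # lever time: activated for ToneS but NOT for Lever (flat vs 2-3 s)
  m <- matrix(0L, nrow = 10, ncol = 100)
  m[, seq(2, 20, 2)] <- 1L                 # noisy pre-cue baseline
  m[, 31:88] <- 3L                         # plateau spanning ToneS and Lever
  m[, seq(61, 79, 2)] <- 2L                # jitter in the 2-3 s window so the
  m[, seq(62, 80, 2)] <- 4L                # lever baseline is not degenerate
  tensor <- make_tensor(m)  # alternating DS+/DS- trials, identical counts
  lab <- classify_responses(tensor, cfg)
  lab <- lab[lab$cue_type == "DSplus", ]
  expect_equal(lab$label[lab$epoch == "ToneS"], "activated")
  expect_equal(lab$label[lab$epoch == "Lever"], "none")
})

test_that("labels are stable under trial-order permutation", {
  sim <- simulate_session(sim_config("VTA", n_units = 6,
                                     n_trials_per_cue = 15), seed = 5)
  tensor <- align_and_bin(sim$bundle, cfg)
  lab1 <- classify_responses(tensor, cfg)
  set.seed(1)
  perm <- sample(nrow(tensor$trials))
  tensor2 <- tensor
  tensor2$counts <- tensor$counts[, perm, , drop = FALSE]
  tensor2$trials <- tensor$trials[perm, ]
  lab2 <- classify_responses(tensor2, cfg)
  expect_equal(lab1$label, lab2$label)
})

test_that("raising the z threshold never increases activated counts", {
  sim <- simulate_session(sim_config("dmPFC", n_units = 25,
                                     n_trials_per_cue = 20), seed = 8)
  tensor <- align_and_bin(sim$bundle, cfg)
  n_act <- vapply(c(1.5, 2, 2.5, 3), function(th) {
    cfg_th <- cfg; cfg_th$z_threshold <- th
    sum(classify_responses(tensor, cfg_th)$label == "activated")
  }, numeric(1))
  expect_true(all(diff(n_act) <= 0))
})

test_that("proportion summary reproduces the published rounding convention", {
  lab <- data.frame(
    area = "dmPFC", group = "control", session = "day1",
    cue_type = "DSplus", epoch = "ToneR",
    unit_id = sprintf("u%03d", 1:130),
    label = c(rep("activated", 13), rep("inhibited", 5), rep("none", 112)),
    stringsAsFactors = FALSE)
  p <- proportion_summary(lab)
  expect_equal(p$n_total, 130)
  expect_equal(p$pct_activated, 10L)  # 13/130
  expect_equal(p$pct_inhibited, 4L)   # 5/130 = 3.8 -> 4
  lab$label <- "none"
  p0 <- proportion_summary(lab)
  expect_equal(c(p0$pct_activated, p0$pct_inhibited), c(0L, 0L))
})

test_that("planted ToneR activation is recovered at 50 trials", {
  # every unit activated at ToneR with the default gain (well above 3
  # baseline SDs at these rates); >= 90% must be recovered
  cfg_sim <- sim_config("dmPFC", n_units = 40,
                        frac_act = c(ToneR = 1, ToneS = 0, Lever = 0),
                        frac_inh = c(ToneR = 0, ToneS = 0, Lever = 0))
  sim <- simulate_session(cfg_sim, seed = 31)
  tensor <- align_and_bin(sim$bundle, cfg)
  lab <- classify_responses(tensor, cfg)
  hit <- lab$label[lab$epoch == "ToneR" & lab$cue_type == "DSplus"] == "activated"
  expect_gte(mean(hit), 0.9)
})
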