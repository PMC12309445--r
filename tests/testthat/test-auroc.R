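cfg <- analysis_config()

test_that("binwise auROC equals the pair-counting statistic", {
  expect_equal(binwise_auroc(c(2, 3, 4), c(1, 2, 3)), 7 / 9)
  expect_equal(binwise_auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)   # identical
  expect_equal(binwise_auroc(c(5, 6), c(1, 2)), 1)           # separated
  expect_equal(binwise_auroc(c(1, 2), c(5, 6)), 0)
  expect_error(binwise_auroc(numeric(0), 1), "non-empty")
})

test_that("auROC matches both oracles on random instances", {
  set.seed(11)
  for (i in 1:200) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- sample(0:5, n1, replace = TRUE)  # discrete -> many ties
    y <- sample(0:5, n2, replace = TRUE)
    a <- binwise_auroc(x, y)
    expect_equal(a, auroc_pairs(x, y), tolerance = 1e-12)
    expect_equal(a, auroc_sweep(x, y), tolerance = 1e-12)
    # label-swap antisymmetry
    expect_equal(binwise_auroc(y, x), 1 - a, tolerance = 1e-12)
    # agreement with the Mann-Whitney U statistic
    u <- suppressWarnings(wilcox.test(x, y)$statistic)
    expect_equal(a, unname(u) / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("auROC is invariant under strictly increasing transforms", {
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(8); y <- rnorm(10)
    a <- binwise_auroc(x, y)
    expect_equal(binwise_auroc(exp(x), exp(y)), a, tolerance = 1e-12)
    expect_equal(binwise_auroc(2 * x + 7, 2 * y + 7), a, tolerance = 1e-12)
  }
})

test_that("epoch selectivity statistics match hand arithmetic", {
  au <- rep(0.5, 100)
  s0 <- epoch_selectivity(au, cfg)
  expect_true(all(s0$delta_auroc == 0))
  expect_true(all(s0$degenerate))      # flat baseline
  expect_true(all(!s0$selective))

  # baseline alternating 0.45/0.55 (mu 0.5, population SD 0.05), ToneR
  # epoch bins at 0.7 -> Z = 4, delta = 0.2, selective
  au <- rep(c(0.45, 0.55), 50)
  au[21:28] <- 0.7
  s <- epoch_selectivity(au, cfg)
  tr <- s[s$epoch == "ToneR", ]
  expect_equal(tr$baseline_mean, 0.5)
  expect_equal(tr$baseline_sd, 0.05)
  expect_equal(tr$z, 4)
  expect_equal(tr$delta_auroc, 0.2)
  expect_true(tr$selective)
})

test_that("lever selectivity is referenced to the 2-3 s auROC baseline", {
  au <- rep(c(0.45, 0.55), 50)
  au[31:80] <- rep(c(0.65, 0.75), 25)  # elevated sustained-tone discrimination
  au[81:88] <- 0.7                     # lever epoch at the late-tone level
  s <- epoch_selectivity(au, cfg)
  expect_false(s$selective[s$epoch == "Lever"])   # 0.7 vs lever baseline mu 0.7
  expect_true(s$selective[s$epoch == "ToneS"])    # 0.7 vs pre-cue mu 0.5
})

test_that("a planted DS+ lever gain makes units selective at 50+50 trials", {
  cfg_sim <- sim_config("VTA", n_units = 6,
                        da_fraction = 1, da_mean_hz = 8, da_sd_hz = 2,
                        frac_act = c(ToneR = 0, ToneS = 0, Lever = 1),
                        frac_inh = c(ToneR = 0, ToneS = 0, Lever = 0),
                        gain_act = 6,
                        ds_contrast = c(ToneR = 0.9, ToneS = 0.3, Lever = 0.05))
  hits <- unlist(lapply(1:5, function(r) {
    sim <- simulate_session(cfg_sim, seed = 100 + r)
    tensor <- align_and_bin(sim$bundle, cfg)
    st <- selectivity_table(tensor, cfg)
    st$selective[st$epoch == "Lever"]
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("shuffled delta auROC is centered at zero", {
  sim <- simulate_session(sim_config("VTA", n_units = 1, gain_act = 4),
                          seed = 9)
  tensor <- align_and_bin(sim$bundle, cfg)
  labs <- tensor$trials$cue_type
  set.seed(33)
  deltas <- vapply(1:500, function(i) {
    pr <- auroc_profile(tensor, dimnames(tensor$counts)[[1]][1], cfg,
                        trial_labels = sample(labs))
    pr$epochs$delta_auroc[pr$epochs$epoch == "Lever"]
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("the shuffle null is deterministic under a fixed seed", {
  sim <- simulate_session(sim_config("VTA", n_units = 4,
                                     n_trials_per_cue = 12), seed = 6)
  tensor <- align_and_bin(sim$bundle, cfg)
  n1 <- shuffle_null(tensor, cfg, n_shuffles = 10, seed = 77)
  n2 <- shuffle_null(tensor, cfg, n_shuffles = 10, seed = 77)
  expect_identical(n1, n2)
})
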