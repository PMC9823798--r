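test_that("generation is deterministic under a fixed seed", {
  r1 <- quick_recording(seed = 11, dur = 60)
  r2 <- quick_recording(seed = 11, dur = 60)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$bursts, r2$bursts)
  r3 <- quick_recording(seed = 12, dur = 60)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("full synchrony couples every burst across hemispheres", {
  rec <- quick_recording(seed = 2, sync = 1, dur = 300)
  expect_equal(burst_cooccurrence(rec, "F3", "F4", tol = 0.5), 1.0)
})

test_that("zero synchrony gives the chance co-occurrence of independent trains", {
  cfg <- sim_cohort_config(n_subjects = 2, duration_pre = 3600,
                           duration_post = 3600)
  rec <- synthesize_recording(
    sim_subject_params(sync_level = 0, rng_seed = 5), cfg)
  obs <- burst_cooccurrence(rec, "F3", "F4", tol = 0.5)
  # a stationary renewal with rate lambda and min gaps >> 1 s puts a burst
  # onset in a 1 s window with probability ~ lambda * 1
  lam <- nrow(rec$bursts$F4) / 7200
  nb <- nrow(rec$bursts$F3)
  expect_lt(abs(obs - lam), 2.6 * sqrt(lam * (1 - lam) / nb))
})

test_that("co-occurrence is nondecreasing in sync_level", {
  frac <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    rec <- quick_recording(seed = 7, sync = s, dur = 600)
    burst_cooccurrence(rec, "F3", "F4", tol = 0.5)
  }, numeric(1))
  expect_true(all(diff(frac) >= -0.02))
  expect_gt(frac[5] - frac[1], 0.5)
})

test_that("realized burst peak-to-peak tracks the target amplitude within 15%", {
  rec <- quick_recording(seed = 9, amp = 100, dur = 600)
  x <- derive(rec, "F3")
  tr <- rec$bursts$F3
  fs <- rec$sfreq
  rel <- vapply(seq_len(nrow(tr)), function(i) {
    i0 <- floor(tr$onset[i] * fs) + 1
    i1 <- min(length(x), i0 + round(tr$dur[i] * fs) - 1)
    (max(x[i0:i1]) - min(x[i0:i1])) / tr$amp[i]
  }, numeric(1))
  expect_true(all(rel > 0.85 & rel < 1.15))
})

test_that("interburst background stays far below burst amplitude", {
  rec <- quick_recording(seed = 3, amp = 100, dur = 600)
  x <- derive(rec, "F3")
  fs <- rec$sfreq
  tr <- rec$bursts$F3
  in_burst <- rep(FALSE, length(x))
  for (i in seq_len(nrow(tr))) {
    i0 <- floor(tr$onset[i] * fs) + 1
    i1 <- min(length(x), i0 + round(tr$dur[i] * fs) - 1)
    in_burst[i0:i1] <- TRUE
  }
  bg_p2p <- quantile(abs(x[!in_burst]), 0.999) * 2
  expect_lt(bg_p2p, 0.15 * 100)
})

test_that("no drug effect leaves pre and post amplitude equal within 5%", {
  rec <- quick_recording(seed = 21, slope = 0, dur = 1800, sfreq = 100)
  tr <- reeg(derive(rec, "F3"), rec$sfreq)
  pre <- mean(tr$value[tr$time < 1800])
  post <- mean(tr$value[tr$time >= 1800])
  expect_lt(abs(post - pre) / pre, 0.05)
})

test_that("a positive slope steps post-drug amplitude down in proportion", {
  p <- sim_subject_params(drug_effect_slope = 0.5, normalized_baseline = 1,
                          rng_seed = 4)
  cfg <- sim_cohort_config(n_subjects = 2, duration_pre = 900,
                           duration_post = 900, sfreq = 100)
  rec <- synthesize_recording(p, cfg)
  tr <- reeg(derive(rec, "F3"), rec$sfreq)
  pre <- mean(tr$value[tr$time < 900])
  post <- mean(tr$value[tr$time >= 900])
  expect_lt(post / pre, 0.65)  # bursts halved; background dilutes slightly
})

test_that("too-short recordings are rejected with a message", {
  cfg <- sim_cohort_config(n_subjects = 2, duration_pre = 2, duration_post = 2)
  expect_error(synthesize_recording(sim_subject_params(), cfg), "too short")
})

test_that("inconsistent burst rate and durations are rejected", {
  expect_error(sim_subject_params(burst_rate = 20), "inconsistent")
})

test_that("cohort draws are reproducible and span the amplitude range", {
  cfg <- sim_cohort_config(n_subjects = 8, duration_pre = 300,
                           duration_post = 300, rng_seed = 4)
  co1 <- synthesize_cohort(cfg)
  co2 <- synthesize_cohort(cfg)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$recordings$S03$samples, co2$recordings$S03$samples)
  amps <- vapply(co1$recordings, function(r) mean(r$bursts$F3$amp), numeric(1))
  expect_gt(max(amps) / min(amps), 3)
})

test_that("ground-truth delta is anticorrelated with baseline by construction", {
  cfg <- sim_cohort_config(n_subjects = 21, duration_pre = 300,
                           duration_post = 300, rng_seed = 6)
  # deltas follow from the truth table alone; no EEG processing involved
  co <- synthesize_cohort(cfg, drug_effect_slope = 0.5, out_dir = NULL)
  truth <- co$truth
  delta_true <- truth$baseline_amplitude * (truth$post_multiplier - 1)
  expect_lte(rho_ranks(truth$baseline_amplitude, delta_true), -0.8)
})

test_that("degenerate heterogeneity warns and proceeds", {
  cfg <- sim_cohort_config(n_subjects = 2, duration_pre = 60,
                           duration_post = 60, rng_seed = 1)
  expect_warning(
    co <- synthesize_cohort(cfg, heterogeneity = list(
      baseline_amplitude = c(50, 50), sync_level = c(0.5, 0.9))),
    "degenerate")
  expect_equal(co$truth$baseline_amplitude, c(50, 50))
})
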