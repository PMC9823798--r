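test_that("rEEG of simple analytic signals", {
  fs <- 250
  expect_true(all(reeg(rep(7.5, fs * 10), fs)$value == 0))
  tr <- reeg(50 * sin(2 * pi * 5 * seq(0, 60, by = 1 / fs)), fs)
  expect_true(all(abs(tr$value - 100) < 1))
})

test_that("rEEG equals the brute-force scan on random fixtures", {
  fs <- 250
  for (s in 1:3) {
    set.seed(s)
    x <- rnorm(60 * fs, sd = 30)
    expect_identical(reeg(x, fs)$value, reeg_brute(x, fs))
  }
})

test_that("rEEG is invariant to negation and constant offset", {
  set.seed(4)
  x <- rnorm(30 * 250, sd = 20)
  v <- reeg(x, 250)$value
  expect_equal(reeg(-x, 250)$value, v)
  expect_equal(reeg(x + 123.4, 250)$value, v)
})

test_that("short signals give an empty trend", {
  expect_equal(nrow(reeg(rnorm(100), 250)), 0)
})

test_that("running mean is centred and shrinks at the edges", {
  expect_equal(running_mean(c(1, 2, 3, 4), k = 3), c(1.5, 2, 3, 3.5))
  expect_equal(running_mean(c(1, NA, 3), k = 3), c(1, 2, 3))
})

test_that("identical channels reach the self-information bound", {
  set.seed(10)
  a <- rnorm(600 * 250)
  v <- asi(a, a, 250, asi_params(rng_seed = 1))
  expect_equal(attr(v, "mi0"), 2)  # log2(4) bits: envelopes identical
  expect_gt(as.numeric(v), quantile(attr(v, "surrogates"), 0.99))
})

test_that("independent channels score near zero", {
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    as.numeric(asi(rnorm(300 * 250), rnorm(300 * 250), 250,
                   asi_params(rng_seed = s + 100, min_shift = 30)))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.5)
})

test_that("ASI is invariant to amplitude rescaling of either channel", {
  set.seed(11)
  a <- rnorm(300 * 250); b <- rnorm(300 * 250)
  p <- asi_params(rng_seed = 42, min_shift = 30)
  v1 <- as.numeric(asi(a, b, 250, p))
  v2 <- as.numeric(asi(a * 35, b / 7, 250, p))
  expect_equal(v1, v2)
})

test_that("zero-variance envelopes are flagged undefined", {
  expect_warning(v <- asi(rep(1, 250 * 120), rep(1, 250 * 120), 250,
                          asi_params(rng_seed = 1, min_shift = 10)),
                 "zero-variance")
  expect_true(is.na(v))
})

test_that("ASI increases with generator synchrony", {
  meds <- vapply(c(0, 0.5, 1), function(s) {
    v <- vapply(1:4, function(k) {
      rec <- quick_recording(seed = k + 50 * s, sync = s, dur = 300,
                             sfreq = 100)
      as.numeric(asi(bandpass(derive(rec, "F3"), 100),
                     bandpass(derive(rec, "F4"), 100), 100,
                     asi_params(rng_seed = k)))
    }, numeric(1))
    median(v)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("a four-hour recording divides into 96 trend epochs", {
  expect_equal(nrow(epoch_grid(0, 14400, 150)), 96)
  g <- epoch_grid(0, 14400, 150)
  expect_equal(g$start[1], 0)
  expect_equal(g$end[96], 14400)
})

test_that("epoch summaries respect the valid-fraction rule", {
  fs <- 100
  x <- 50 * sin(2 * pi * 5 * seq(0, 600 - 1 / fs, by = 1 / fs))
  grid <- epoch_grid(0, 600, 150)
  tr <- reeg(x, fs)
  ep <- reeg_epochs(tr, grid)
  # stationary fixture: epoch means equal within 2%
  expect_lt(diff(range(ep$value)) / mean(ep$value), 0.02)
  # epoch fully masked -> missing
  mask <- rep(TRUE, 300)
  mask[1:75] <- FALSE                     # first 150 s invalid
  ep2 <- reeg_epochs(reeg(x, fs, mask = mask), grid)
  expect_true(is.na(ep2$value[1]))
  expect_false(any(is.na(ep2$value[-1])))
  # 60% masked epoch -> missing under the 50% rule
  mask2 <- rep(TRUE, 300)
  mask2[76:120] <- FALSE                  # 45 of 75 windows of epoch 2
  ep3 <- reeg_epochs(reeg(x, fs, mask = mask2), grid)
  expect_true(is.na(ep3$value[2]))
})

test_that("ASI epochs go missing when the segment is mostly invalid", {
  rec <- quick_recording(seed = 13, dur = 300, sfreq = 100)
  a <- bandpass(derive(rec, "F3"), 100)
  b <- bandpass(derive(rec, "F4"), 100)
  mask <- detect_artifacts(a, 100)
  mask$valid[mask$segment_start < 200] <- FALSE
  v <- asi(a, b, 100, asi_params(rng_seed = 1, min_shift = 30),
           mask_a = mask, interval = c(0, 300))
  expect_true(is.na(v))
})
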