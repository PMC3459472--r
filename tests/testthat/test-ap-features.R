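test_that("constructed two-beat waveform yields its designed features", {
  tr <- synthetic_beats(cl = 300, mdp = -65, peak = 20, n_beats = 5)
  f <- compute_features(tr)
  expect_equal(f$cycle_length, 300, tolerance = 1e-3)
  expect_equal(f$rate, 200, tolerance = 1e-3)
  expect_equal(f$mdp, -65, tolerance = 1e-6)
  expect_equal(f$overshoot, 20, tolerance = 1e-6)
  expect_equal(f$amplitude, 85, tolerance = 1e-6)
  expect_identical(f$amplitude, f$overshoot - f$mdp)
  expect_identical(f$rate, 60000 / f$cycle_length)
  expect_true(f$apd50 <= f$apd90)
  expect_lt(f$apd90, f$cycle_length)
})

test_that("features are invariant under time translation", {
  f1 <- compute_features(synthetic_beats(cl = 250, n_beats = 5))
  f2 <- compute_features(synthetic_beats(cl = 250, n_beats = 5, t0 = 1234.5))
  for (col in c("cycle_length", "mdp", "overshoot", "apd50", "apd90")) {
    expect_equal(f1[[col]], f2[[col]], tolerance = 1e-12)
  }
})

test_that("detected period matches a known sawtooth-plus-spike period", {
  for (P in c(180, 300, 420)) {
    tr <- synthetic_beats(cl = P, n_beats = 6, dt = 0.1)
    b <- detect_beats(tr)
    expect_equal(mean(b$t_next - b$t_upstroke), P, tolerance = 0.1 / P)
  }
})

test_that("flat and sub-threshold traces signal insufficient beats", {
  flat <- tibble::tibble(time = seq(0, 1000, 0.5), vm = rep(-60, 2001))
  expect_error(detect_beats(flat), class = "sanpace_insufficient_beats")
  wobble <- tibble::tibble(time = seq(0, 1000, 0.5),
                           vm = -60 + 3 * sin(seq(0, 1000, 0.5) / 30))
  expect_error(detect_beats(wobble), class = "sanpace_insufficient_beats")
})

test_that("beat count is consistent with span / cycle length", {
  tr <- short_steady(build_model("boyett-central"))
  b <- detect_beats(tr)
  f <- compute_features(tr, b)
  span <- max(tr$time) - min(tr$time)
  expect_lte(abs(nrow(b) - floor(span / f$cycle_length)), 1)
})

test_that("delta tables obey the rate / cycle-length algebra", {
  a <- tibble::tibble(rate = 150, cycle_length = 60000 / 150, mdp = -60,
                      overshoot = 15, apd50 = 100)
  b <- tibble::tibble(rate = 180, cycle_length = 60000 / 180, mdp = -66,
                      overshoot = 18, apd50 = 90)
  d <- delta_features(a, b)
  expect_equal(d$delta_rate_pct, 20, tolerance = 1e-12)
  expect_equal(d$delta_mdp_mv, -6)
  # rate-based and cycle-length-based changes are algebraically linked
  expect_equal(1 - 1 / (1 + d$delta_rate_pct / 100), d$delta_cl_pct / 100,
               tolerance = 1e-12)
  # identical inputs give all-zero deltas
  z <- delta_features(a, a)
  expect_true(all(abs(as.numeric(z)) < 1e-12))
  # CL 300 -> 240 is a +25% rate change
  x <- tibble::tibble(rate = 60000 / 300, cycle_length = 300, mdp = 0,
                      overshoot = 0, apd50 = 1)
  y <- tibble::tibble(rate = 60000 / 240, cycle_length = 240, mdp = 0,
                      overshoot = 0, apd50 = 1)
  expect_equal(delta_features(x, y)$delta_rate_pct, 25, tolerance = 1e-12)
})

test_that("feature extraction is stable under 2x resampling of a model trace", {
  tr <- run_to_steady(build_model("kurata-central"),
                      settle_ms = 6000, window_ms = 4000, output_dt = 0.2)
  tr2 <- run_to_steady(build_model("kurata-central"),
                       settle_ms = 6000, window_ms = 4000, output_dt = 0.1)
  f1 <- compute_features(tr); f2 <- compute_features(tr2)
  for (col in c("cycle_length", "mdp", "overshoot", "apd50", "apd90")) {
    expect_lt(abs(f2[[col]] / f1[[col]] - 1), 1e-3)
  }
})
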