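test_that("stance detection follows the 30 N inclusive-threshold convention", {
  # clean step function: contact spans samples 101..350 (1-based)
  fz <- c(rep(0, 100), rep(800, 250), rep(0, 100))
  expect_equal(detect_stance(fz, 1000), c(start = 101, end = 350))

  expect_error(detect_stance(rep(0, 500), 1000), class = "gaitsym_no_contact")

  # >= 30 N, inclusive at both ends: samples 4..6 of the ramp
  ramp <- c(0, 10, 20, 30, 40, 30, 20, 10, 0)
  expect_equal(detect_stance(ramp, 1000, min_duration = 0), c(start = 4, end = 6))

  # two contact episodes: the longest wins
  two <- c(rep(0, 50), rep(500, 120), rep(0, 40), rep(500, 200), rep(0, 50))
  expect_equal(detect_stance(two, 1000), c(start = 211, end = 410))

  # runs shorter than min_duration are ignored
  short <- c(rep(0, 50), rep(500, 20), rep(0, 50))
  expect_error(detect_stance(short, 1000, min_duration = 0.1),
               class = "gaitsym_no_contact")
})

test_that("spline time normalization reproduces exact and analytic cases", {
  # identity: already 101 evenly spaced samples
  y <- sin(seq(0, 3, length.out = 101)) + seq(0, 1, length.out = 101)
  expect_equal(time_normalize(y, 101), y, tolerance = 1e-9)

  # cubic splines reproduce linear functions exactly
  ramp <- seq(0, 1, length.out = 57)
  out <- time_normalize(ramp, 101)
  expect_equal(out, seq(0, 1, length.out = 101), tolerance = 1e-9)

  # analytic-function oracle: sin(2*pi*t) at 250 samples
  t250 <- seq(0, 1, length.out = 250)
  out <- time_normalize(sin(2 * pi * t250), 101)
  expect_equal(out, sin(2 * pi * seq(0, 1, length.out = 101)), tolerance = 1e-4)

  # endpoints preserved
  seg <- rnorm(40)
  out <- time_normalize(seg, 101)
  expect_equal(out[1], seg[1], tolerance = 1e-12)
  expect_equal(out[101], seg[40], tolerance = 1e-12)

  expect_error(time_normalize(c(1, 2, 3), 101), class = "gaitsym_segment_too_short")
})

test_that("body-weight normalization divides by ten times the mass", {
  expect_equal(normalize_bw(700, 70), 1.0)
  expect_equal(normalize_bw(0, 55), 0)
  expect_equal(normalize_bw(1750, 70), 2.5)
  expect_equal(normalize_bw(c(140, 280), 70), c(0.2, 0.4))
  expect_error(normalize_bw(100, 0), class = "gaitsym_invalid_arg")
  expect_error(normalize_bw(100, -5), class = "gaitsym_invalid_arg")
})

test_that("trial preprocessing crops all axes with one window and scales linearly", {
  l <- make_trial(noise = noise_spec(0, 10), side = "L", mass = 70, seed = 4)
  r <- make_trial(noise = noise_spec(0, 10), side = "R", mass = 70, seed = 4)
  pl <- preprocess_trial(l); pr <- preprocess_trial(r)
  expect_equal(pl$X, pr$X)
  expect_equal(pl$Z, pr$Z)
  expect_length(pl$Z, 101)
  expect_equal(pl$window, pr$window)

  # doubling mass halves every BW node value (same raw forces)
  t70 <- make_trial(noise = noise_spec(0, 10), mass = 70, seed = 4)
  t140 <- t70; t140$mass <- 140
  p70 <- preprocess_trial(t70); p140 <- preprocess_trial(t140)
  expect_equal(p140$Z, p70$Z / 2)
  expect_equal(p140$Y, p70$Y / 2)

  # two contact episodes: window comes from the longest (hand-computed)
  n <- 600
  fz <- c(rep(0, 50), rep(400, 120), rep(0, 40), rep(600, 250), rep(0, 140))
  tr <- structure(list(time_s = (seq_len(n) - 1) / 1000, fx_N = rep(1, n),
                       fy_N = rep(2, n), fz_N = fz, fs = 1000, mass = 70,
                       side = "R", condition = "pre", subject = "S01",
                       trial = 1L), class = "grf_trial")
  p <- preprocess_trial(tr)
  expect_equal(p$window, c(start = 211, end = 460))
  expect_equal(p$Z, rep(600 / 700, 101))
})

test_that("preprocessing an already-normalized curve is idempotent", {
  node_vals <- build_template("Z", n = 101)
  node_vals[node_vals < 0.05] <- 0.05    # keep everything above threshold
  mass <- 70
  tr <- structure(list(time_s = (0:100) / 1000, fx_N = node_vals * 10 * mass,
                       fy_N = node_vals * 10 * mass,
                       fz_N = node_vals * 10 * mass, fs = 1000, mass = mass,
                       side = "R", condition = "pre", subject = "S01",
                       trial = 1L), class = "grf_trial")
  p <- preprocess_trial(tr, min_duration = 0.05)
  expect_equal(p$Z, node_vals, tolerance = 1e-6)
})
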